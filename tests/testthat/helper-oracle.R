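# Independent exhaustive oracle for the species-change rules. Works from
# raw probabilities and the registry table only, recomputing suitability
# itself and scanning candidates with explicit loops; it shares no code
# with the scenario engine.

oracle_suitable <- function(prob, registry) {
  cut <- registry$cutoff[match(names(prob), registry$code)]
  names(prob)[prob >= cut]
}

oracle_relative <- function(code, prob, registry) {
  prob[[code]] / registry$cutoff[registry$code == code]
}

# Explicit max-scan with the documented tie-breaks (higher relative, then
# higher standardized increment, then lexicographically smaller code).
oracle_best <- function(codes, prob, registry) {
  best <- NULL
  for (c in sort(codes)) {
    if (is.null(best)) { best <- c; next }
    rc <- oracle_relative(c, prob, registry)
    rb <- oracle_relative(best, prob, registry)
    ic <- registry$increment_std[registry$code == c]
    ib <- registry$increment_std[registry$code == best]
    if (rc > rb || (rc == rb && ic > ib)) best <- c
  }
  best
}

# shares: named vector (> 0); prob: named probability vector covering every
# occurring species and all candidates; returns list(shares, volume,
# unstocked).
oracle_apply <- function(shares, volume, prob, scenario, registry) {
  suitable_set <- oracle_suitable(prob, registry)
  occ <- names(shares)
  failing <- setdiff(occ, suitable_set)
  failing <- failing[order(match(failing, occ))]
  keep <- intersect(occ, suitable_set)

  if (length(failing) == 0) {
    return(list(shares = shares, volume = volume, unstocked = FALSE))
  }

  if (scenario == "no_adaptation") {
    if (length(keep) == 0) {
      return(list(shares = stats::setNames(numeric(0), character(0)),
                  volume = 0, unstocked = TRUE))
    }
    lost <- sum(shares[failing])
    new_shares <- shares[keep] + lost * shares[keep] / sum(shares[keep])
    new_volume <- volume * sum(shares[keep]) / sum(shares)
    return(list(shares = new_shares, volume = new_volume, unstocked = FALSE))
  }

  pool <- if (scenario %in% c("native_mss", "native_ccbb")) {
    registry$code[registry$native]
  } else {
    registry$code
  }
  ccbb <- scenario %in% c("native_ccbb", "combi_ccbb")

  new_shares <- shares[keep]
  lost_fraction <- 0
  for (f in failing) {
    cands <- setdiff(intersect(suitable_set, pool), f)
    cands <- intersect(cands, names(prob))
    chosen <- NULL
    if (length(cands) > 0) {
      if (ccbb) {
        f_con <- registry$conifer[registry$code == f]
        same_form <- cands[vapply(cands, function(c)
          registry$conifer[registry$code == c] == f_con, logical(1))]
        chosen <- if (length(same_form) > 0) {
          oracle_best(same_form, prob, registry)
        } else {
          oracle_best(cands, prob, registry)
        }
      } else {
        chosen <- oracle_best(cands, prob, registry)
      }
    }
    if (is.null(chosen)) {
      lost_fraction <- lost_fraction + shares[[f]] / sum(shares)
    } else if (chosen %in% names(new_shares)) {
      new_shares[[chosen]] <- new_shares[[chosen]] + shares[[f]]
    } else {
      new_shares[[chosen]] <- shares[[f]]
    }
  }
  new_shares <- new_shares[new_shares > 0]
  unstocked <- length(new_shares) == 0
  list(shares = new_shares,
       volume = if (unstocked) 0 else volume * (1 - lost_fraction),
       unstocked = unstocked)
}

# Compare a scenario_outcome against an oracle result.
expect_outcome_equal <- function(outcome, oracle, info = NULL) {
  expect_equal(outcome$unstocked, oracle$unstocked, info = info)
  expect_equal(sort(names(outcome$shares)), sort(names(oracle$shares)),
               info = info)
  expect_equal(outcome$shares[sort(names(outcome$shares))],
               oracle$shares[sort(names(oracle$shares))],
               tolerance = 1e-10, info = info)
  expect_equal(outcome$volume, oracle$volume, tolerance = 1e-10, info = info)
}
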