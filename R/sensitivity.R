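# Uncertainty analysis: one-way (tornado) sensitivity, probabilistic
# sensitivity analysis by Monte Carlo over parameter distributions,
# cost-effectiveness plane points, and cost-effectiveness acceptability
# curves.

owsa_parameters <- function(ps) {
  m <- sync_meta_values(ps)
  flat <- ifelse(is.na(m$age_lower), m$parameter,
                 sprintf("%s[%d-%d]", m$parameter, m$age_lower, m$age_upper))
  keep <- !is.na(m$owsa_low) & !is.na(m$owsa_high)
  data.frame(parameter = flat[keep], base = m$value[keep],
             low = m$owsa_low[keep], high = m$owsa_high[keep],
             stringsAsFactors = FALSE)
}

#' One-way (tornado) sensitivity analysis
#'
#' For every parameter with a one-way range in the parameter set's metadata,
#' reruns the full model with that parameter at its low and at its high value
#' (all others at base) and records the ICER of the chosen comparison. All
#' ranges are validated before any model run. Output is sorted by descending
#' swing, ready for a tornado diagram.
#'
#' @param ps a `ht_parameter_set`.
#' @param comparison character vector of two strategy names,
#'   `c(intervention, comparator)`.
#' @return data.frame `parameter`, `base`, `low`, `high`, `icer_at_low`,
#'   `icer_at_high`, `swing`, sorted by descending `swing`. The base-case
#'   ICER is in attribute `icer_base`.
#' @export
one_way_sensitivity <- function(ps, comparison = c("Serial1", "CBPM")) {
  stopifnot(length(comparison) == 2L)
  assert_valid(ps)
  grid <- owsa_parameters(ps)
  if (nrow(grid) == 0L) stop("no parameters carry a one-way range")

  # validate every bound before any model run
  for (i in seq_len(nrow(grid))) {
    for (val in c(grid$low[i], grid$high[i])) {
      v <- validate_parameter_set(set_param(ps, grid$parameter[i], val))
      if (length(v) > 0L)
        stop("one-way range for ", grid$parameter[i],
             " violates parameter invariants:\n  ",
             paste(v, collapse = "\n  "))
    }
  }

  pair_icer <- function(p) {
    e1 <- accrue(run_cohort(p, comparison[1L]), p, comparison[1L])
    e0 <- accrue(run_cohort(p, comparison[2L]), p, comparison[2L])
    dq <- e1$total_qaly - e0$total_qaly
    if (dq == 0) NA_real_ else (e1$total_cost - e0$total_cost) / dq
  }

  icer_lo <- icer_hi <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    icer_lo[i] <- pair_icer(set_param(ps, grid$parameter[i], grid$low[i]))
    icer_hi[i] <- pair_icer(set_param(ps, grid$parameter[i], grid$high[i]))
  }
  out <- data.frame(parameter = grid$parameter, base = grid$base,
                    low = grid$low, high = grid$high,
                    icer_at_low = icer_lo, icer_at_high = icer_hi,
                    swing = abs(icer_hi - icer_lo),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  attr(out, "icer_base") <- pair_icer(ps)
  attr(out, "comparison") <- comparison
  out
}

# Method-of-moments conversion and a single draw on the natural scale.
draw_one <- function(family, mean, se, parameter) {
  if (family == "fixed" || is.na(se) || se == 0) return(mean)
  v <- se^2
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) {
      if (v > 0) stop("beta draw infeasible for ", parameter,
                      ": mean at the boundary with nonzero SE")
      return(mean)
    }
    if (v >= mean * (1 - mean))
      stop("beta draw infeasible for ", parameter,
           ": SE too large for mean (variance must be < mean*(1-mean))")
    k <- mean * (1 - mean) / v - 1
    stats::rbeta(1L, mean * k, (1 - mean) * k)
  } else if (family == "gamma") {
    if (mean <= 0) stop("gamma draw infeasible for ", parameter,
                        ": mean must be > 0")
    stats::rgamma(1L, shape = mean^2 / v, rate = mean / v)
  } else {
    stop("unknown distribution family for ", parameter, ": ", family)
  }
}

# Deterministic sub-seed for (seed, replication); kept below 2^31.
combine_seed <- function(seed, replication) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(replication) * 1009) %%
               2147483647)
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Every parameter whose metadata names a `beta` or `gamma` family is redrawn
#' on its natural scale by method-of-moments matching of (mean, SE);
#' `fixed` parameters keep their base value. The draw is deterministic given
#' `(rng_seed, replication)` and leaves the caller's RNG state untouched.
#'
#' @param ps a `ht_parameter_set`.
#' @param rng_seed integer seed of the PSA run.
#' @param replication 1-based replication index.
#' @return a valid `ht_parameter_set`.
#' @export
draw_psa_parameters <- function(ps, rng_seed, replication) {
  m <- sync_meta_values(ps)
  flat <- ifelse(is.na(m$age_lower), m$parameter,
                 sprintf("%s[%d-%d]", m$parameter, m$age_lower, m$age_upper))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(combine_seed(rng_seed, replication))
  out <- ps
  for (i in seq_len(nrow(m))) {
    if (m$dist_family[i] == "fixed") next
    out <- set_param(out, flat[i],
                     draw_one(m$dist_family[i], m$value[i], m$dist_se[i],
                              flat[i]))
  }
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the parameter distributions: per replication one joint
#' parameter draw is shared by all strategies (common random parameters), the
#' cohort model and economic accrual run per strategy, and the discounted
#' totals are recorded. Reproducible given the seed.
#'
#' @param ps a `ht_parameter_set`.
#' @param replications number of Monte Carlo replications (default 1000).
#' @param rng_seed integer seed.
#' @param strategies strategy names to evaluate.
#' @return a `psa_result`: data.frame with columns `replication`, `strategy`,
#'   `total_cost`, `total_qaly`, `total_ly`; attributes `seed` and
#'   `replications`.
#' @export
run_psa <- function(ps, replications = 1000L, rng_seed = 1L,
                    strategies = STRATEGY_NAMES) {
  stopifnot(replications >= 1L)
  assert_valid(ps)
  rows <- vector("list", replications)
  for (r in seq_len(replications)) {
    draw <- tryCatch(draw_psa_parameters(ps, rng_seed, r), error = function(e)
      stop("PSA draw failed at replication ", r, ": ", conditionMessage(e)))
    res <- lapply(strategies, function(s) {
      tryCatch(accrue(run_cohort(draw, s), draw, s), error = function(e)
        stop("PSA model run failed at replication ", r, " (", s, "): ",
             conditionMessage(e)))
    })
    rows[[r]] <- data.frame(
      replication = r, strategy = strategies,
      total_cost = vapply(res, `[[`, numeric(1), "total_cost"),
      total_qaly = vapply(res, `[[`, numeric(1), "total_qaly"),
      total_ly = vapply(res, `[[`, numeric(1), "total_ly"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- rng_seed
  attr(out, "replications") <- replications
  class(out) <- c("psa_result", "data.frame")
  out
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, a strategy's probability of being
#' cost-effective is the fraction of replications in which it attains the
#' maximum net monetary benefit among all strategies; ties split the mass
#' equally. Probabilities across strategies sum to 1 at every threshold.
#'
#' @param psa a `psa_result`.
#' @param wtp_grid vector of willingness-to-pay values (baht/QALY); default
#'   0 to 500,000 in 10,000 steps (the Thai threshold 160,000 included).
#' @return data.frame `wtp`, one probability column per strategy.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 500000, by = 10000)) {
  stopifnot(length(wtp_grid) > 0L)
  strategies <- unique(psa$strategy)
  reps <- sort(unique(psa$replication))
  psa <- psa[order(psa$replication, match(psa$strategy, strategies)), ]
  C <- matrix(psa$total_cost, nrow = length(reps), byrow = TRUE,
              dimnames = list(NULL, strategies))
  Q <- matrix(psa$total_qaly, nrow = length(reps), byrow = TRUE,
              dimnames = list(NULL, strategies))
  prob <- vapply(wtp_grid, function(w) {
    nmb <- w * Q - C
    best <- nmb == apply(nmb, 1L, max)
    share <- best / rowSums(best)
    colMeans(share)
  }, numeric(length(strategies)))
  out <- data.frame(wtp = wtp_grid, t(prob))
  names(out) <- c("wtp", strategies)
  rownames(out) <- NULL
  out
}

#' Cost-effectiveness plane points
#'
#' Per replication and non-comparator strategy, the incremental cost and
#' QALYs against the comparator on the same parameter draw; plot-ready for a
#' CE-plane scatter.
#'
#' @param psa a `psa_result`.
#' @param comparator comparator strategy name.
#' @return data.frame `replication`, `strategy`, `delta_cost`, `delta_qaly`.
#' @export
ce_plane_points <- function(psa, comparator) {
  strategies <- unique(psa$strategy)
  if (!comparator %in% strategies)
    stop("comparator not in PSA result: ", comparator)
  base <- psa[psa$strategy == comparator, ]
  base <- base[order(base$replication), ]
  rows <- lapply(setdiff(strategies, comparator), function(s) {
    x <- psa[psa$strategy == s, ]
    x <- x[order(x$replication), ]
    data.frame(replication = x$replication, strategy = s,
               delta_cost = x$total_cost - base$total_cost,
               delta_qaly = x$total_qaly - base$total_qaly,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(replication = integer(0), strategy = character(0),
                      delta_cost = numeric(0), delta_qaly = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
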