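# Calibration of age-banded hypertension incidence (optionally background
# mortality) so modeled prevalence by age band matches external targets,
# e.g. national survey prevalence.

#' Calibration targets
#' @param lower,upper inclusive age bounds per band.
#' @param prevalence target hypertension prevalence per band, in \[0,1\].
#' @return data.frame of class `calibration_targets`.
#' @export
calibration_targets <- function(lower, upper, prevalence) {
  stopifnot(length(lower) == length(upper),
            length(lower) == length(prevalence),
            all(lower <= upper),
            all(prevalence >= 0), all(prevalence <= 1))
  structure(data.frame(lower = as.integer(lower), upper = as.integer(upper),
                       prevalence = prevalence),
            class = c("calibration_targets", "data.frame"))
}

# Incidence bands that overlap any target band; only these get a scalar.
bands_to_adjust <- function(ps, targets, param) {
  tbl <- ps[[param]]
  overlaps <- vapply(seq_len(nrow(tbl)), function(i) {
    any(tbl$lower[i] <= targets$upper & targets$lower <= tbl$upper[i])
  }, logical(1))
  which(overlaps)
}

apply_scalars <- function(ps, param, idx, scalars, clip_log = NULL) {
  tbl <- ps[[param]]
  newv <- tbl$value[idx] * scalars
  clipped <- newv > 1
  if (any(clipped) && !is.null(clip_log)) {
    for (j in which(clipped)) {
      clip_log(sprintf("%s[%d-%d]: scalar %.4g clipped (value %.4g -> 1)",
                       param, tbl$lower[idx[j]], tbl$upper[idx[j]],
                       scalars[j], newv[j]))
    }
  }
  tbl$value[idx] <- pmin(pmax(newv, 0), 1)
  ps[[param]] <- tbl
  ps
}

#' Calibrate banded incidence to prevalence targets
#'
#' Multiplies each overlapping age band's hypertension incidence (and, if
#' requested, background mortality) by a band-specific scalar chosen by
#' deterministic coordinate-wise bounded search to minimise the sum of squared
#' differences between modeled and target prevalence per band. Bands are swept
#' in ascending age order (prevalence is cumulative, so earlier bands feed
#' later ones); a sweep's coordinate update is accepted only if it improves
#' the objective, so the objective is non-increasing across accepted
#' iterations. Scalars are bounded so every probability stays in \[0,1\];
#' any clipping is logged in the report.
#'
#' @param ps a valid `ht_parameter_set`.
#' @param targets a `calibration_targets` data.frame.
#' @param max_iter maximum number of coordinate sweeps (default 10).
#' @param tol stop when the root-mean-square prevalence residual falls below
#'   this (default 1e-4).
#' @param strategy strategy under which prevalence is evaluated (default
#'   `"CBPM"`, current practice; prevalence of true hypertension is nearly
#'   strategy-invariant).
#' @param adjust_mortality also scale background mortality bands (default
#'   `FALSE`).
#' @return list: `ps` (adjusted set), `scalars` (named, one per adjusted
#'   band), `report` (per-band modeled vs target prevalence and residuals),
#'   `objective` (final sum of squared residuals), `converged`, `iterations`,
#'   `clipped` (character log of any clipping).
#' @export
calibrate <- function(ps, targets, max_iter = 10L, tol = 1e-4,
                      strategy = "CBPM", adjust_mortality = FALSE) {
  assert_valid(ps)
  stopifnot(nrow(targets) > 0L,
            all(targets$lower >= ps$start_age),
            all(targets$lower < ps$end_age))

  params <- "ht_incidence"
  if (adjust_mortality) params <- c(params, "p_death_other")
  idx <- lapply(params, function(p) bands_to_adjust(ps, targets, p))
  names(idx) <- params

  coord <- do.call(rbind, lapply(params, function(p) {
    tbl <- ps[[p]]
    data.frame(param = p, band = idx[[p]],
               lower = tbl$lower[idx[[p]]], upper = tbl$upper[idx[[p]]],
               base = tbl$value[idx[[p]]], stringsAsFactors = FALSE)
  }))
  coord <- coord[order(coord$lower, coord$param), ]
  scalars <- rep(1, nrow(coord))
  names(scalars) <- sprintf("%s[%d-%d]", coord$param, coord$lower, coord$upper)

  clip_msgs <- character(0)
  clip_log <- function(msg) clip_msgs <<- c(clip_msgs, msg)

  build <- function(sc) {
    out <- ps
    for (k in seq_len(nrow(coord))) {
      out <- apply_scalars(out, coord$param[k], coord$band[k], sc[k])
    }
    out
  }
  residuals_of <- function(sc) {
    prev <- prevalence_by_age_band(run_cohort(build(sc), strategy), targets)
    prev$prevalence - targets$prevalence
  }
  # target band(s) each coordinate overlaps; prevalence in a target band
  # responds only to incidence at ages at or below it, so sweeping
  # coordinates in ascending age order and zeroing each coordinate's own
  # target residual is a (block-)triangular solve
  overlap_targets <- lapply(seq_len(nrow(coord)), function(k) {
    which(coord$lower[k] <= targets$upper & targets$lower <= coord$upper[k])
  })

  n_t <- nrow(targets)
  f_cur <- sum(residuals_of(scalars)^2)
  iterations <- 0L
  converged <- sqrt(f_cur / n_t) <= tol
  while (!converged && iterations < max_iter) {
    iterations <- iterations + 1L
    sc_try <- scalars
    for (k in seq_len(nrow(coord))) {
      hi <- min(20, 1 / max(coord$base[k], 1e-12))
      jj <- overlap_targets[[k]]
      if (length(jj) == 0L) next
      if (length(jj) == 1L) {
        # modeled prevalence is monotone increasing in own-band incidence:
        # root-solve the band residual, clip at the bounds if unreachable
        g <- function(x) {
          sc <- sc_try; sc[k] <- x; residuals_of(sc)[jj]
        }
        g_lo <- g(1e-3); g_hi <- g(hi)
        sc_try[k] <- if (g_lo >= 0) 1e-3 else if (g_hi <= 0) hi else
          stats::uniroot(g, c(1e-3, hi), tol = 1e-5)$root
      } else {
        opt <- stats::optimize(function(x) {
          sc <- sc_try; sc[k] <- x; sum(residuals_of(sc)[jj]^2)
        }, interval = c(1e-3, hi), tol = 1e-5)
        sc_try[k] <- opt$minimum
      }
    }
    f_try <- sum(residuals_of(sc_try)^2)
    if (f_try < f_cur) {  # accept the sweep only if it improves the fit
      scalars <- sc_try
      f_cur <- f_try
    } else {
      break
    }
    converged <- sqrt(f_cur / n_t) <= tol
  }
  if (!converged) {
    warning("calibration did not converge (", iterations,
            " sweeps); best-found scalars returned (RMS residual ",
            signif(sqrt(f_cur / n_t), 3), ")")
  }

  ps_fit <- build(scalars)
  # rebuild with clip logging for the report
  clip_msgs <- character(0)
  tmp <- ps
  for (k in seq_len(nrow(coord))) {
    tmp <- apply_scalars(tmp, coord$param[k], coord$band[k], scalars[k],
                         clip_log)
  }
  report <- validation_report(ps_fit, targets, strategy = strategy)

  list(ps = ps_fit, scalars = scalars, report = report,
       objective = f_cur, converged = converged, iterations = iterations,
       clipped = clip_msgs)
}

#' Modeled-versus-target prevalence report
#'
#' Runs the model once and tabulates modeled against target prevalence per
#' band, with absolute and relative deviations. No fitting is performed.
#'
#' @param ps a valid `ht_parameter_set`.
#' @param targets a `calibration_targets` data.frame.
#' @param strategy strategy under which prevalence is evaluated.
#' @return data.frame `lower`, `upper`, `modeled`, `target`, `abs_dev`,
#'   `rel_dev`.
#' @export
validation_report <- function(ps, targets, strategy = "CBPM") {
  prev <- prevalence_by_age_band(run_cohort(ps, strategy), targets)
  data.frame(
    lower = targets$lower, upper = targets$upper,
    modeled = prev$prevalence, target = targets$prevalence,
    abs_dev = prev$prevalence - targets$prevalence,
    rel_dev = ifelse(targets$prevalence > 0,
                     (prev$prevalence - targets$prevalence) /
                       targets$prevalence, NA_real_)
  )
}
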