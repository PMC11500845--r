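# Parameter-set container, validation and (de)serialization.
#
# A `ht_parameter_set` is a plain list: scalar model inputs as named fields,
# age-banded inputs as data.frames with columns (lower, upper, value), and a
# `meta` data.frame carrying per-parameter PSA distribution metadata, one-way
# sensitivity ranges and a provenance tag. Age-banded parameters are addressed
# in flat form as "name[lower-upper]", e.g. "ht_incidence[40-49]".

PROB_SCALARS <- c(
  "p_controlled_to_uncontrolled", "p_uncontrolled_to_controlled",
  "p_cvd_death_young", "p_cvd_death_old",
  "prop_stroke", "prop_cad", "prop_hemorrhagic", "prop_ischemic",
  "se_cbpm", "sp_cbpm", "se_hbpm", "sp_hbpm"
)
COST_SCALARS <- c(
  "cost_screen_cbpm", "cost_screen_hbpm",
  "cost_ht_controlled", "cost_ht_uncontrolled",
  "cost_cvd_acute", "cost_cvd_chronic",
  "nonmed_visit_cost", "nonmed_inpatient_cost_per_day"
)
UTIL_SCALARS <- c("u_healthy", "u_ht", "u_stroke", "u_cad", "u_death")
COUNT_SCALARS <- c(
  "visits_controlled", "visits_uncontrolled", "visits_cvd_chronic",
  "acute_admission_days"
)
BAND_PARAMS <- c(
  "ht_incidence", "p_cvd_given_uncontrolled", "p_cvd_given_controlled",
  "p_death_other"
)
CONFIG_SCALARS <- c("start_age", "end_age", "discount_rate", "wtp", "seed")
ALL_SCALARS <- c(PROB_SCALARS, COST_SCALARS, UTIL_SCALARS, COUNT_SCALARS)

#' Construct a hypertension-model parameter set
#'
#' Bundles every input of the screening cost-utility model: annual transition
#' probabilities (scalar and age-banded), diagnostic sensitivities and
#' specificities of the clinic (CBPM) and home (HBPM) blood-pressure tests,
#' unit costs in baht, utility weights, the annual discount rate and the
#' willingness-to-pay threshold, plus per-parameter metadata for sensitivity
#' analyses.
#'
#' @param scalars named list of scalar parameter values (probabilities, costs,
#'   utilities, visit counts; see `htcue:::ALL_SCALARS`).
#' @param bands named list of age-banded parameters; each element a data.frame
#'   with columns `lower`, `upper` (inclusive ages) and `value`.
#' @param config named list with `start_age`, `end_age`, `discount_rate`,
#'   `wtp` and `seed`.
#' @param meta data.frame with columns `parameter`, `age_lower`, `age_upper`,
#'   `value`, `dist_family`, `dist_se`, `owsa_low`, `owsa_high`, `provenance`;
#'   if `NULL` a default is built (all parameters `fixed`, no ranges).
#' @return object of class `ht_parameter_set`.
#' @export
parameter_set <- function(scalars, bands, config, meta = NULL) {
  missing_sc <- setdiff(ALL_SCALARS, names(scalars))
  if (length(missing_sc) > 0L) {
    stop("missing required scalar parameter(s): ",
         paste(missing_sc, collapse = ", "))
  }
  missing_bd <- setdiff(BAND_PARAMS, names(bands))
  if (length(missing_bd) > 0L) {
    stop("missing required age-banded parameter(s): ",
         paste(missing_bd, collapse = ", "))
  }
  missing_cf <- setdiff(CONFIG_SCALARS, names(config))
  if (length(missing_cf) > 0L) {
    stop("missing required config field(s): ",
         paste(missing_cf, collapse = ", "))
  }
  ps <- c(config[CONFIG_SCALARS], scalars[ALL_SCALARS], bands[BAND_PARAMS])
  ps$meta <- if (is.null(meta)) default_meta(ps) else meta
  class(ps) <- "ht_parameter_set"
  ps
}

default_meta <- function(ps) {
  nm <- flat_parameter_names(ps)
  vals <- vapply(nm, function(n) get_param(ps, n), numeric(1))
  parsed <- parse_flat_names(nm)
  data.frame(
    parameter = parsed$parameter,
    age_lower = parsed$lower, age_upper = parsed$upper,
    value = unname(vals),
    dist_family = "fixed", dist_se = NA_real_,
    owsa_low = NA_real_, owsa_high = NA_real_,
    provenance = "stand-in",
    stringsAsFactors = FALSE
  )
}

#' Flat parameter names of a parameter set
#'
#' Scalar parameters are their own names; age-banded parameters expand to
#' `"name[lower-upper]"`, one per band.
#' @param ps a `ht_parameter_set`.
#' @return character vector.
#' @export
flat_parameter_names <- function(ps) {
  banded <- unlist(lapply(BAND_PARAMS, function(p) {
    tbl <- ps[[p]]
    sprintf("%s[%d-%d]", p, tbl$lower, tbl$upper)
  }))
  c(ALL_SCALARS, banded)
}

parse_flat_names <- function(nm) {
  m <- regmatches(nm, regexec("^([^\\[]+)(\\[(\\d+)-(\\d+)\\])?$", nm))
  parameter <- vapply(m, `[`, character(1), 2L)
  lower <- suppressWarnings(as.integer(vapply(m, `[`, character(1), 4L)))
  upper <- suppressWarnings(as.integer(vapply(m, `[`, character(1), 5L)))
  list(parameter = parameter, lower = lower, upper = upper)
}

#' Get a parameter value by flat name
#' @param ps a `ht_parameter_set`.
#' @param name flat name, e.g. `"u_ht"` or `"ht_incidence[40-49]"`.
#' @return numeric scalar.
#' @export
get_param <- function(ps, name) {
  p <- parse_flat_names(name)
  if (is.na(p$lower)) {
    v <- ps[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    return(v)
  }
  tbl <- ps[[p$parameter]]
  if (is.null(tbl)) stop("unknown parameter: ", name)
  i <- which(tbl$lower == p$lower & tbl$upper == p$upper)
  if (length(i) != 1L) stop("unknown band in parameter: ", name)
  tbl$value[i]
}

#' Set a parameter value by flat name
#' @inheritParams get_param
#' @param value new numeric value.
#' @return modified `ht_parameter_set` (copy).
#' @export
set_param <- function(ps, name, value) {
  p <- parse_flat_names(name)
  if (is.na(p$lower)) {
    if (is.null(ps[[name]])) stop("unknown parameter: ", name)
    ps[[name]] <- value
  } else {
    tbl <- ps[[p$parameter]]
    if (is.null(tbl)) stop("unknown parameter: ", name)
    i <- which(tbl$lower == p$lower & tbl$upper == p$upper)
    if (length(i) != 1L) stop("unknown band in parameter: ", name)
    tbl$value[i] <- value
    ps[[p$parameter]] <- tbl
  }
  ps
}

# Value of an age-banded table at a given (integer) age.
band_value <- function(tbl, age) {
  i <- which(tbl$lower <= age & age <= tbl$upper)
  if (length(i) != 1L) stop("age ", age, " not covered by parameter bands")
  tbl$value[i]
}

#' Validate a parameter set
#'
#' Checks every structural invariant: probabilities, sensitivities,
#' specificities and utilities in \[0,1\]; costs and visit counts nonnegative;
#' disease-mix fractions summing to one; discount rate nonnegative; age range
#' nondegenerate; age bands disjoint and covering the model age range; PSA
#' distribution metadata consistent with each family.
#'
#' @param ps a `ht_parameter_set`.
#' @return character vector of violation descriptions; empty when valid. Each
#'   entry names the parameter, its value and the violated rule.
#' @export
validate_parameter_set <- function(ps) {
  v <- character(0)
  bad <- function(...) v <<- c(v, sprintf(...))

  for (p in PROB_SCALARS) {
    x <- ps[[p]]
    if (!is.finite(x) || x < 0 || x > 1)
      bad("%s = %g violates: probability must be in [0,1]", p, x)
  }
  for (p in c(COST_SCALARS, COUNT_SCALARS)) {
    x <- ps[[p]]
    if (!is.finite(x) || x < 0)
      bad("%s = %g violates: must be >= 0", p, x)
  }
  for (p in UTIL_SCALARS) {
    x <- ps[[p]]
    if (!is.finite(x) || x < 0 || x > 1)
      bad("%s = %g violates: utility must be in [0,1]", p, x)
  }
  if (!is.finite(ps$discount_rate) || ps$discount_rate < 0)
    bad("discount_rate = %g violates: must be >= 0", ps$discount_rate)
  if (!is.finite(ps$wtp) || ps$wtp < 0)
    bad("wtp = %g violates: must be >= 0", ps$wtp)
  if (!(ps$start_age < ps$end_age))
    bad("start_age = %g, end_age = %g violates: start_age < end_age",
        ps$start_age, ps$end_age)
  s <- ps$prop_stroke + ps$prop_cad
  if (abs(s - 1) > 1e-9)
    bad("prop_stroke + prop_cad = %g violates: must sum to 1", s)
  s <- ps$prop_hemorrhagic + ps$prop_ischemic
  if (abs(s - 1) > 1e-9)
    bad("prop_hemorrhagic + prop_ischemic = %g violates: must sum to 1", s)

  for (p in BAND_PARAMS) {
    tbl <- ps[[p]]
    if (any(tbl$lower > tbl$upper))
      bad("%s violates: band lower must be <= upper", p)
    o <- order(tbl$lower)
    tbl <- tbl[o, ]
    if (nrow(tbl) > 1L && any(tbl$lower[-1L] != tbl$upper[-nrow(tbl)] + 1L))
      bad("%s violates: bands must be disjoint and contiguous", p)
    if (tbl$lower[1L] > ps$start_age || tbl$upper[nrow(tbl)] < ps$end_age - 1)
      bad("%s violates: bands must cover ages %g to %g", p,
          ps$start_age, ps$end_age - 1)
    for (i in seq_len(nrow(tbl))) {
      x <- tbl$value[i]
      if (!is.finite(x) || x < 0 || x > 1)
        bad("%s[%d-%d] = %g violates: probability must be in [0,1]",
            p, tbl$lower[i], tbl$upper[i], x)
    }
  }

  m <- ps$meta
  known <- flat_parameter_names(ps)
  flat_m <- ifelse(is.na(m$age_lower), m$parameter,
                   sprintf("%s[%d-%d]", m$parameter, m$age_lower, m$age_upper))
  for (i in seq_len(nrow(m))) {
    fam <- m$dist_family[i]
    if (!fam %in% c("beta", "gamma", "fixed")) {
      bad("%s violates: dist_family must be beta, gamma or fixed (got %s)",
          flat_m[i], fam)
      next
    }
    if (!flat_m[i] %in% known) {
      bad("%s violates: PSA metadata refers to an unknown parameter", flat_m[i])
      next
    }
    mu <- m$value[i]
    if (fam == "beta" && (mu < 0 || mu > 1))
      bad("%s = %g violates: beta mean must be in [0,1]", flat_m[i], mu)
    if (fam == "gamma" && mu <= 0)
      bad("%s = %g violates: gamma mean must be > 0", flat_m[i], mu)
    if (fam != "fixed" && (!is.finite(m$dist_se[i]) || m$dist_se[i] < 0))
      bad("%s violates: dist_se must be >= 0 for family %s", flat_m[i], fam)
    lo <- m$owsa_low[i]; hi <- m$owsa_high[i]
    if (!is.na(lo) && !is.na(hi) && lo > hi)
      bad("%s violates: owsa_low must be <= owsa_high", flat_m[i])
  }
  v
}

# Stop with all violations listed if the set is invalid.
assert_valid <- function(ps) {
  v <- validate_parameter_set(ps)
  if (length(v) > 0L) {
    stop("invalid parameter set:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(ps)
}

#' Write a parameter set to a text file
#'
#' The format is a scalar-config header (`key: value` lines) followed by one
#' comma-separated table with header
#' `parameter,age_lower,age_upper,value,dist_family,dist_se,owsa_low,owsa_high,provenance`.
#' UTF-8, `.` decimal separator. [load_parameter_set()] reads it back; the
#' round trip is the identity on valid sets.
#'
#' @param ps a `ht_parameter_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_parameter_set <- function(ps, path) {
  m <- sync_meta_values(ps)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in CONFIG_SCALARS) {
    writeLines(sprintf("%s: %s", k, format(ps[[k]], digits = 17,
                                           scientific = FALSE)), con)
  }
  writeLines("", con)
  utils::write.csv(m, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Refresh the meta table's value column from the live parameter values.
sync_meta_values <- function(ps) {
  m <- ps$meta
  flat_m <- ifelse(is.na(m$age_lower), m$parameter,
                   sprintf("%s[%d-%d]", m$parameter, m$age_lower, m$age_upper))
  m$value <- vapply(flat_m, function(n) get_param(ps, n), numeric(1))
  m
}

#' Load a parameter set from a text file
#'
#' Reads the format written by [save_parameter_set()]. The loaded set is
#' validated; a file that violates any invariant raises an error listing all
#' violations.
#'
#' @param path file path.
#' @return a valid `ht_parameter_set`.
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr_i <- grep("^parameter,", lines)
  if (length(hdr_i) != 1L)
    stop("schema error: expected exactly one table header line starting ",
         "with 'parameter,'")
  cfg_lines <- grep("^[A-Za-z_]+:", lines[seq_len(hdr_i - 1L)], value = TRUE)
  cfg <- list()
  for (ln in cfg_lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    cfg[[trimws(kv[1L])]] <- as.numeric(trimws(paste(kv[-1L], collapse = ":")))
  }
  missing_cf <- setdiff(CONFIG_SCALARS, names(cfg))
  if (length(missing_cf) > 0L)
    stop("schema error: missing config field(s): ",
         paste(missing_cf, collapse = ", "))

  m <- utils::read.csv(text = paste(lines[hdr_i:length(lines)],
                                    collapse = "\n"),
                       stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need_cols <- c("parameter", "age_lower", "age_upper", "value",
                 "dist_family", "dist_se", "owsa_low", "owsa_high",
                 "provenance")
  miss <- setdiff(need_cols, names(m))
  if (length(miss) > 0L)
    stop("schema error: table missing column(s): ",
         paste(miss, collapse = ", "))
  m$age_lower <- as.integer(m$age_lower)
  m$age_upper <- as.integer(m$age_upper)

  is_band <- !is.na(m$age_lower)
  scalars <- as.list(m$value[!is_band])
  names(scalars) <- m$parameter[!is_band]
  missing_sc <- setdiff(ALL_SCALARS, names(scalars))
  if (length(missing_sc) > 0L)
    stop("schema error: missing required parameter(s): ",
         paste(missing_sc, collapse = ", "))
  bands <- lapply(BAND_PARAMS, function(p) {
    sub <- m[is_band & m$parameter == p, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("schema error: missing required age-banded parameter: ", p)
    data.frame(lower = sub$age_lower, upper = sub$age_upper,
               value = sub$value)
  })
  names(bands) <- BAND_PARAMS

  ps <- parameter_set(scalars, bands, cfg, meta = m[, need_cols])
  assert_valid(ps)
  ps
}

#' @export
print.ht_parameter_set <- function(x, ...) {
  cat("<ht_parameter_set>\n")
  cat(sprintf("  cohort: age %g to %g, discount %g/yr, WTP %s baht/QALY\n",
              x$start_age, x$end_age, x$discount_rate,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  tests: CBPM Se/Sp %.3g/%.3g, HBPM Se/Sp %.3g/%.3g\n",
              x$se_cbpm, x$sp_cbpm, x$se_hbpm, x$sp_hbpm))
  cat(sprintf("  %d flat parameters (%d age-banded rows); seed %g\n",
              length(flat_parameter_names(x)),
              sum(!is.na(x$meta$age_lower)), x$seed))
  invisible(x)
}
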