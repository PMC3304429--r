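#' @keywords internal
"_PACKAGE"

# Names of the scalar probability/utility fields of a parameter set, in the
# order they appear in the sensitivity-range table.
.param_fields <- c(
  "p_node_positive", "p_slnb_fail", "p_slnb_fn",
  "p_lymph_alnd", "p_lymph_slnb",
  "p_local_recur_first", "p_axillary_recur_first", "p_axillary_recur_given_fn",
  "p_dm_first_node_pos", "p_dm_first_node_neg",
  "p_dm_after_local_pos", "p_dm_after_local_neg",
  "p_dm_after_axillary_pos", "p_dm_after_axillary_neg",
  "p_death_after_dm",
  "u_disease_free", "u_recurrence", "u_dm",
  "lymphoedema_disutility"
)

#' Sensitivity ranges for all model probabilities and utilities
#'
#' Returns the base-case value, low and high sensitivity bounds, and whether
#' the parameter is subject to the time-halving rule (first-event recurrence
#' probabilities halve after year 5 and halve again after year 10), for every
#' scalar parameter of the model.
#'
#' @return A data.frame with columns `name`, `base`, `low`, `high`,
#'   `time_varying` (one row per parameter) and a `description` column.
#' @export
parameter_ranges <- function() {
  r <- function(name, base, low, high, tv, desc) {
    data.frame(name = name, base = base, low = low, high = high,
               time_varying = tv, description = desc,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    r("p_node_positive", 0.269, 0.20, 0.46, FALSE,
      "Proportion of patients with axillary node-positive disease"),
    r("p_slnb_fail", 0.06, 0.001, 0.071, FALSE,
      "Proportion of SLNB procedures failing to identify a sentinel node"),
    r("p_slnb_fn", 0.055, 0.024, 0.166, FALSE,
      "False-negative SLNB rate among node-positive patients with successful mapping"),
    r("p_lymph_alnd", 0.176, 0.1312, 0.2112, FALSE,
      "Probability of moderate-severe arm lymphoedema after ALND"),
    r("p_lymph_slnb", 0.119, 0.0416, 0.1428, FALSE,
      "Probability of moderate-severe arm lymphoedema after SLNB alone"),
    r("p_local_recur_first", 0.0055, 0.0044, 0.0066, TRUE,
      "Annual probability of local (ipsilateral) recurrence as first event"),
    r("p_axillary_recur_first", 0.0008, 0.0006, 0.0010, TRUE,
      "Annual probability of axillary recurrence as first event"),
    r("p_axillary_recur_given_fn", 0.0160, 0.0102, 0.0689, TRUE,
      "Annual probability of axillary recurrence given a false-negative SLNB"),
    r("p_dm_first_node_pos", 0.0126, 0.0109, 0.0144, FALSE,
      "Annual probability of distant metastases as first event, node positive"),
    r("p_dm_first_node_neg", 0.0063, 0.0050, 0.0075, FALSE,
      "Annual probability of distant metastases as first event, node negative"),
    r("p_dm_after_local_pos", 0.1246, 0.0997, 0.1496, FALSE,
      "Annual probability of distant metastases after local recurrence, node positive"),
    r("p_dm_after_local_neg", 0.0772, 0.0429, 0.0927, FALSE,
      "Annual probability of distant metastases after local recurrence, node negative"),
    r("p_dm_after_axillary_pos", 0.2063, 0.1305, 0.2759, FALSE,
      "Annual probability of distant metastases after axillary recurrence, node positive"),
    r("p_dm_after_axillary_neg", 0.2259, 0.1674, 0.2834, FALSE,
      "Annual probability of distant metastases after axillary recurrence, node negative"),
    r("p_death_after_dm", 0.2970, 0.2729, 0.3313, FALSE,
      "Annual probability of breast-cancer death following distant metastases"),
    r("u_disease_free", 0.989, 0.79, 1, FALSE,
      "Utility of the disease-free state"),
    r("u_recurrence", 0.911, 0.73, 1, FALSE,
      "Utility of the local and axillary recurrence states"),
    r("u_dm", 0.796, 0.64, 0.96, FALSE,
      "Utility of the distant-metastases state"),
    r("lymphoedema_disutility", 0.03, 0.01, 0.05, FALSE,
      "Utility decrement applied to patients with moderate-severe lymphoedema")
  )
  rownames(out) <- NULL
  out
}

#' Construct the model parameter set
#'
#' All arguments default to the base-case values in [parameter_ranges()].
#' `other_cause_mortality` is a schedule of annual non-breast-cancer death
#' probabilities by age; the default is [default_mortality_schedule()].
#'
#' @param ... Named overrides for any field listed in [parameter_ranges()],
#'   or `other_cause_mortality` (a data.frame with columns `age` and `q`).
#' @param validate Run [validate_parameters()] on the result (default TRUE).
#' @return An object of class `ax_parameters`: a named list of scalar
#'   probabilities/utilities plus the mortality schedule.
#' @export
#' @examples
#' p <- parameter_set()
#' p$p_slnb_fn
#' p2 <- parameter_set(p_node_positive = 0.5)
parameter_set <- function(..., validate = TRUE) {
  ranges <- parameter_ranges()
  p <- as.list(stats::setNames(ranges$base, ranges$name))
  p$other_cause_mortality <- default_mortality_schedule()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), c(names(p)))
    if (length(bad))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  class(p) <- "ax_parameters"
  if (validate) validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks that every probability and utility lies in \[0, 1\], that the
#' lymphoedema disutility does not exceed the disease-free utility, and that
#' the mortality schedule is a well-formed, non-decreasing age schedule.
#'
#' @param params An `ax_parameters` object.
#' @return `params`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_parameters <- function(params) {
  for (f in .param_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
    if (v < 0 || v > 1)
      stop("parameter '", f, "' = ", v, " is outside [0, 1]")
  }
  if (params$lymphoedema_disutility > params$u_disease_free)
    stop("lymphoedema_disutility exceeds u_disease_free")
  m <- params$other_cause_mortality
  if (!is.data.frame(m) || !all(c("age", "q") %in% names(m)))
    stop("other_cause_mortality must be a data.frame with columns 'age' and 'q'")
  if (any(m$q < 0 | m$q > 1)) stop("mortality schedule probabilities outside [0, 1]")
  if (is.unsorted(m$age, strictly = TRUE)) stop("mortality schedule ages must be strictly increasing")
  if (is.unsorted(m$q)) stop("mortality schedule must be non-decreasing in age")
  invisible(params)
}

# Gompertz coefficients of the built-in other-cause mortality schedule
# (annual probability q(age) = q0 * exp(b * (age - 58))). Calibrated so that
# a routine-ALND cohort starting at age 58 accumulates ~18.4/1000 other-cause
# deaths by 5 years and ~160/1000 by 20 years, consistent with early-2000s
# Australian female all-cause mortality with breast-cancer deaths excluded.
.mortality_q0 <- 0.0029924415
.mortality_b  <- 0.1041605154

#' Built-in other-cause mortality schedule (ages 58-78)
#'
#' An approximation of early-2000s Australian female all-cause mortality with
#' breast-cancer deaths excluded, as a Gompertz schedule
#' `q(age) = q0 * exp(b * (age - 58))` rising from about 0.003 at age 58 to
#' about 0.022 at age 77. The two coefficients were calibrated so that the
#' ALND arm of the base-case cohort model accumulates approximately 18.4
#' other-cause deaths per 1000 patients by 5 years and 160 per 1000 by
#' 20 years.
#'
#' @return A data.frame with columns `age` (58 to 78) and `q` (annual death
#'   probability), strictly increasing in age.
#' @export
#' @examples
#' m <- default_mortality_schedule()
#' plot(m$age, m$q, type = "b")
default_mortality_schedule <- function() {
  age <- 58:78
  data.frame(age = age, q = .mortality_q0 * exp(.mortality_b * (age - 58)))
}

# Annual other-cause death probability at given ages; geometric extrapolation
# beyond the tabulated range keeps long-horizon runs well defined.
mortality_at_age <- function(schedule, ages) {
  idx <- match(ages, schedule$age)
  q <- schedule$q[idx]
  if (anyNA(q)) {
    over <- which(is.na(q) & ages > max(schedule$age))
    if (length(over)) {
      n <- nrow(schedule)
      ratio <- if (n > 1 && schedule$q[n - 1] > 0) schedule$q[n] / schedule$q[n - 1] else 1
      q[over] <- pmin(1, schedule$q[n] * ratio^(ages[over] - schedule$age[n]))
    }
    under <- which(is.na(q) & ages < min(schedule$age))
    if (length(under)) q[under] <- schedule$q[1]
    if (anyNA(q)) stop("ages not covered by mortality schedule")
  }
  q
}

#' Construct the cost set
#'
#' Unit and aggregate direct health-care costs (2000s AUD, Australian
#' health-system perspective). Adjuvant therapy unit costs carry per-arm
#' uptake proportions; whether the uptake difference between arms enters the
#' comparison is controlled by `model_settings(differential_adjuvant_uptake=)`.
#'
#' @param ... Named overrides for any cost field.
#' @param validate Check all costs are non-negative and uptakes are
#'   probabilities (default TRUE).
#' @return An object of class `ax_costs`.
#' @export
cost_set <- function(..., validate = TRUE) {
  cs <- list(
    # upfront surgical pathway costs
    c_alnd               = 5576.45,
    c_slnb_neg           = 4206.38,
    c_slnb_pos_then_alnd = 7771.28,
    c_slnb_fail_then_alnd = 5576.45,
    # adjuvant therapy unit costs and uptake proportions
    c_radiotherapy       = 5130.40,
    uptake_radiotherapy_alnd = 0.86,
    uptake_radiotherapy_slnb = 0.89,
    c_chemo_first_line   = 16160.43,
    uptake_chemo_alnd    = 0.30,
    uptake_chemo_slnb    = 0.31,
    c_endocrine_5yr      = 10960.95,
    uptake_endocrine     = 0.81,
    c_herceptin_1yr      = 64032.80,
    uptake_herceptin     = 0.29,
    # annual state costs
    c_followup_annual    = 254.10,
    c_lymph_annual       = 1198.60,
    c_dm_annual          = 24340.11,
    # one-off transition costs
    c_local_recur_event  = 7658.40,
    c_axillary_recur_event = 24555.97,
    c_death_cancer       = 29615.97,
    c_death_other        = 8659.10
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cs))
    if (length(bad)) stop("unknown cost field(s): ", paste(bad, collapse = ", "))
    cs[names(over)] <- over
  }
  class(cs) <- "ax_costs"
  if (validate) validate_costs(cs)
  cs
}

#' @rdname cost_set
#' @param costs An `ax_costs` object.
#' @export
validate_costs <- function(costs) {
  for (f in names(unclass(costs))) {
    v <- costs[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("cost field '", f, "' must be a single finite number")
    if (v < 0) stop("cost field '", f, "' is negative")
    if (startsWith(f, "uptake_") && v > 1)
      stop("uptake '", f, "' = ", v, " is outside [0, 1]")
  }
  invisible(costs)
}

#' Construct the model run settings
#'
#' @param start_age Cohort age at entry, years (default 58).
#' @param horizon Number of 1-year cycles (default 20).
#' @param cycle_length Cycle length in years (only 1 is supported).
#' @param discount_rate Annual discount rate applied to all future costs and
#'   outcomes (default 0.05).
#' @param half_cycle_correction Average state occupancy over cycle boundaries
#'   when accruing utilities and annual state costs (default TRUE).
#' @param differential_adjuvant_uptake If TRUE, each arm's adjuvant therapy
#'   cost uses that arm's printed uptake proportions; if FALSE (default) the
#'   comparator (ALND) uptakes are applied to both arms, so staging strategy
#'   is assumed not to alter adjuvant therapy use.
#' @return An object of class `ax_settings`.
#' @export
model_settings <- function(start_age = 58, horizon = 20, cycle_length = 1,
                           discount_rate = 0.05, half_cycle_correction = TRUE,
                           differential_adjuvant_uptake = FALSE) {
  if (horizon < 1 || horizon != round(horizon)) stop("horizon must be a positive integer")
  if (discount_rate < 0) stop("discount_rate must be >= 0")
  if (cycle_length != 1) stop("only 1-year cycles are supported")
  structure(list(start_age = start_age, horizon = as.integer(horizon),
                 cycle_length = cycle_length, discount_rate = discount_rate,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 differential_adjuvant_uptake = isTRUE(differential_adjuvant_uptake)),
            class = "ax_settings")
}

.settings_fields <- c("start_age", "horizon", "cycle_length", "discount_rate",
                      "half_cycle_correction", "differential_adjuvant_uptake")

#' Read model configuration from a YAML file
#'
#' The configuration is a flat `key: value` YAML document with an explicit
#' `schema_version`. Any field of [parameter_set()], [cost_set()] or
#' [model_settings()] may be overridden; missing fields fall back to the
#' base-case defaults. An optional `other_cause_mortality` block (mapping of
#' age to annual probability) replaces the built-in schedule.
#'
#' @param path Path to a YAML file, or `NULL` for the full base case.
#' @return A list with elements `params`, `costs`, `settings`.
#' @seealso [write_parameters()]
#' @export
load_parameters <- function(path = NULL) {
  if (is.null(path)) {
    return(list(params = parameter_set(), costs = cost_set(),
                settings = model_settings()))
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.null(doc$schema_version) && doc$schema_version != 1L)
    stop("unsupported schema_version: ", doc$schema_version)
  doc$schema_version <- NULL

  known_p <- .param_fields
  known_c <- names(unclass(cost_set(validate = FALSE)))
  known_s <- .settings_fields
  p_over <- doc[names(doc) %in% known_p]
  c_over <- doc[names(doc) %in% known_c]
  s_over <- doc[names(doc) %in% known_s]
  extra <- setdiff(names(doc), c(known_p, known_c, known_s, "other_cause_mortality"))
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))

  if (!is.null(doc$other_cause_mortality)) {
    m <- doc$other_cause_mortality
    p_over$other_cause_mortality <-
      data.frame(age = as.numeric(names(m)), q = as.numeric(unlist(m)))
  }
  params <- do.call(parameter_set, p_over)
  costs <- do.call(cost_set, c_over)
  settings <- do.call(model_settings, s_over)
  list(params = params, costs = costs, settings = settings)
}

#' Write model configuration to a YAML file
#'
#' Writes a flat YAML document (schema_version 1) that [load_parameters()]
#' reads back losslessly.
#'
#' @param params,costs,settings Model objects as returned by [load_parameters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, costs, settings, path) {
  doc <- c(list(schema_version = 1L),
           lapply(stats::setNames(.param_fields, .param_fields),
                  function(f) params[[f]]),
           unclass(costs),
           unclass(settings))
  m <- params$other_cause_mortality
  doc$other_cause_mortality <- stats::setNames(as.list(m$q), as.character(m$age))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Parameter dictionary
#'
#' One row per model input: probabilities and utilities with their base-case
#' values and sensitivity ranges, followed by cost items (varied by +/-20% in
#' sensitivity analyses) and run settings, with the evidence source of each.
#'
#' @param file Optional path; if given, the dictionary is also written as CSV.
#' @return A data.frame with columns `name`, `type`, `base`, `low`, `high`,
#'   `units`, `source`, `description`.
#' @export
parameter_dictionary <- function(file = NULL) {
  pr <- parameter_ranges()
  src <- c(
    p_node_positive = "SNAC trial", p_slnb_fail = "SNAC trial",
    p_slnb_fn = "SNAC trial (upper range from other randomised trials)",
    p_lymph_alnd = "SNAC trial (arm volume increase >15% at 3 years)",
    p_lymph_slnb = "SNAC trial (arm volume increase >15% at 3 years)",
    p_local_recur_first = "NSABP B-32 trial",
    p_axillary_recur_first = "NSABP B-32 trial",
    p_axillary_recur_given_fn = "NSABP B-32 trial (excess regional recurrence attributed to FN)",
    p_dm_first_node_pos = "published cohort data",
    p_dm_first_node_neg = "published cohort data",
    p_dm_after_local_pos = "published cohort data",
    p_dm_after_local_neg = "published cohort data",
    p_dm_after_axillary_pos = "published cohort data",
    p_dm_after_axillary_neg = "published cohort data",
    p_death_after_dm = "published cohort data",
    u_disease_free = "standard-gamble utilities, breast cancer population",
    u_recurrence = "standard-gamble utilities, breast cancer population",
    u_dm = "standard-gamble utilities, breast cancer population",
    lymphoedema_disutility = "assumption (smallest clinically important difference)"
  )
  probs <- data.frame(name = pr$name, type = "probability/utility",
                      base = pr$base, low = pr$low, high = pr$high,
                      units = ifelse(grepl("^u_|disutility", pr$name), "utility", "probability"),
                      source = unname(src[pr$name]),
                      description = pr$description, stringsAsFactors = FALSE)
  cs <- unclass(cost_set())
  cost_names <- names(cs)[!startsWith(names(cs), "uptake_")]
  up_names <- names(cs)[startsWith(names(cs), "uptake_")]
  costs <- data.frame(name = cost_names, type = "cost",
                      base = unlist(cs[cost_names]),
                      low = 0.8 * unlist(cs[cost_names]),
                      high = 1.2 * unlist(cs[cost_names]),
                      units = "AUD",
                      source = "AR-DRG cost weights / MBS / PBS",
                      description = "Unit or aggregate cost; varied by 20% in sensitivity analyses",
                      stringsAsFactors = FALSE)
  upt <- data.frame(name = up_names, type = "uptake",
                    base = unlist(cs[up_names]), low = NA_real_, high = NA_real_,
                    units = "proportion", source = "SNAC trial",
                    description = "Adjuvant therapy uptake proportion",
                    stringsAsFactors = FALSE)
  st <- model_settings()
  sets <- data.frame(name = .settings_fields, type = "setting",
                     base = as.numeric(unlist(unclass(st))),
                     low = NA_real_, high = NA_real_,
                     units = c("years", "cycles", "years", "per annum", "flag", "flag"),
                     source = "model convention",
                     description = c("Cohort start age", "Time horizon",
                                     "Cycle length", "Annual discount rate",
                                     "Half-cycle correction",
                                     "Arm-specific adjuvant uptake"),
                     stringsAsFactors = FALSE)
  out <- rbind(probs, costs, upt, sets)
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
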