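# Patient-level microsimulation. Deliberately implemented from the clinical
# rules directly (its own decision tree and yearly transition logic, no use of
# build_strata()/build_schedule()), so that agreement with the cohort engine
# is a genuine cross-check rather than a tautology.

.ms_states <- c(DF = 1L, LR = 2L, AR = 3L, DM = 4L, DEAD_CANCER = 5L,
                DEAD_OTHER = 6L)

#' Simulate individual patients through one staging strategy
#'
#' Draws each patient through the upfront staging tree (nodal status, mapping
#' failure, false-negative finding, lymphoedema) and then steps them year by
#' year with the same annual probabilities as the cohort model. Utilities and
#' annual costs accrue for the state occupied at the start of each year, with
#' no half-cycle correction (transitions are realised at year end); one-off
#' event costs accrue at the transition; year-t accruals are discounted by
#' `(1 + r)^-t`; upfront surgical and adjuvant costs are undiscounted. The
#' expectation of this process equals a [run_cohort()] run with
#' `half_cycle_correction = FALSE`.
#'
#' @param arm `"SLNB"` or `"ALND"`.
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Integer random seed; required, for reproducibility.
#' @param params,costs,settings Model objects.
#' @param records If TRUE, also return per-patient records including the
#'   yearly state sequence (memory scales with `n_patients * horizon`).
#' @return A list with `summary` (a data.frame of per-1000 means and
#'   Monte-Carlo standard errors for QALYs and costs, discounted and
#'   undiscounted, life years, and cumulative first axillary recurrences,
#'   distant metastases and deaths at the horizon) and, when
#'   `records = TRUE`, `records` (one row per patient: pathway, nodal status,
#'   lymphoedema flag, accrued outcomes) plus `state_sequence`, an
#'   `n_patients x horizon` character matrix of end-of-year states.
#' @export
#' @examples
#' sim <- simulate_arm("SLNB", n_patients = 2000, seed = 7,
#'                     params = parameter_set(), costs = cost_set())
#' sim$summary
simulate_arm <- function(arm = c("SLNB", "ALND"), n_patients, seed,
                         params = parameter_set(), costs = cost_set(),
                         settings = model_settings(), records = FALSE) {
  arm <- match.arg(arm)
  if (missing(seed) || is.null(seed))
    stop("a seed is required: microsimulation runs must be reproducible")
  if (n_patients < 1) stop("n_patients must be >= 1")
  n <- as.integer(n_patients)
  set.seed(seed)
  H <- settings$horizon
  r <- settings$discount_rate
  disc <- (1 + r)^(-(seq_len(H)))

  # ---- upfront decision tree (independent of build_strata) ----
  node_pos <- stats::runif(n) < params$p_node_positive
  if (arm == "ALND") {
    pathway <- rep("ALND_direct", n)
    surgical <- rep(costs$c_alnd, n)
    p_lymph <- rep(params$p_lymph_alnd, n)
    fn <- rep(FALSE, n)
  } else {
    fail <- stats::runif(n) < params$p_slnb_fail
    fn <- !fail & node_pos & (stats::runif(n) < params$p_slnb_fn)
    pathway <- ifelse(fail, "SLNB_fail_to_ALND",
               ifelse(node_pos & !fn, "SLNB_positive_to_ALND",
               ifelse(fn, "SLNB_false_negative", "SLNB_true_negative")))
    surgical <- ifelse(fail, costs$c_slnb_fail_then_alnd,
                ifelse(node_pos & !fn, costs$c_slnb_pos_then_alnd,
                       costs$c_slnb_neg))
    # completion ALND (positive or failed SLNB) carries the ALND-level
    # lymphoedema risk
    to_alnd <- fail | (node_pos & !fn)
    p_lymph <- ifelse(to_alnd, params$p_lymph_alnd, params$p_lymph_slnb)
  }
  lymph <- stats::runif(n) < p_lymph
  use_arm_uptake <- settings$differential_adjuvant_uptake && arm == "SLNB"
  adjuvant <- (if (use_arm_uptake) costs$uptake_radiotherapy_slnb else
                 costs$uptake_radiotherapy_alnd) * costs$c_radiotherapy +
    (if (use_arm_uptake) costs$uptake_chemo_slnb else
       costs$uptake_chemo_alnd) * costs$c_chemo_first_line +
    costs$uptake_endocrine * costs$c_endocrine_5yr +
    costs$uptake_herceptin * costs$c_herceptin_1yr

  cost_acc <- surgical + adjuvant
  cost_acc_disc <- cost_acc
  qaly <- numeric(n); qaly_disc <- numeric(n); ly <- numeric(n)
  state <- rep(.ms_states[["DF"]], n)
  had_lr <- rep(FALSE, n); had_ar <- rep(FALSE, n)
  first_ar <- rep(FALSE, n); got_dm <- rep(FALSE, n)
  seq_mat <- if (records) matrix(NA_character_, n, H) else NULL

  u_state <- c(params$u_disease_free, params$u_recurrence, params$u_recurrence,
               params$u_dm, 0, 0)
  c_state <- c(costs$c_followup_annual, costs$c_followup_annual,
               costs$c_followup_annual, costs$c_dm_annual, 0, 0)
  qo <- mortality_at_age(params$other_cause_mortality,
                         settings$start_age + seq_len(H) - 1)

  for (t in seq_len(H)) {
    h <- halving_factor(t)
    q <- qo[t]
    alive <- state <= 4L
    # accrue for the state occupied during year t
    u_t <- u_state[state] - ifelse(lymph & alive, params$lymphoedema_disutility, 0)
    c_t <- c_state[state] + ifelse(lymph & alive, costs$c_lymph_annual, 0)
    qaly <- qaly + u_t
    qaly_disc <- qaly_disc + u_t * disc[t]
    cost_acc <- cost_acc + c_t
    cost_acc_disc <- cost_acc_disc + c_t * disc[t]
    ly <- ly + alive

    # annual DM probability from recurrence history (axillary dominates local);
    # history includes a recurrence state currently occupied
    p_dm <- ifelse(had_ar,
                   ifelse(node_pos, params$p_dm_after_axillary_pos,
                          params$p_dm_after_axillary_neg),
            ifelse(had_lr,
                   ifelse(node_pos, params$p_dm_after_local_pos,
                          params$p_dm_after_local_neg),
                   ifelse(node_pos, params$p_dm_first_node_pos,
                          params$p_dm_first_node_neg)))
    u <- stats::runif(n)
    new_state <- state
    ev_cost <- numeric(n)

    in_df <- state == .ms_states[["DF"]]
    if (any(in_df)) {
      p_ar <- h * ifelse(fn & !had_ar, params$p_axillary_recur_given_fn,
                         params$p_axillary_recur_first)
      p_lr <- h * params$p_local_recur_first
      c1 <- p_dm; c2 <- c1 + p_lr; c3 <- c2 + p_ar; c4 <- c3 + q
      i <- in_df
      new_state[i & u < c1] <- .ms_states[["DM"]]
      new_state[i & u >= c1 & u < c2] <- .ms_states[["LR"]]
      new_state[i & u >= c2 & u < c3] <- .ms_states[["AR"]]
      new_state[i & u >= c3 & u < c4] <- .ms_states[["DEAD_OTHER"]]
    }
    in_rec <- state == .ms_states[["LR"]] | state == .ms_states[["AR"]]
    if (any(in_rec)) {
      c1 <- p_dm; c2 <- c1 + q
      i <- in_rec
      new_state[i] <- .ms_states[["DF"]]  # tunnel: recover unless progressing
      new_state[i & u < c1] <- .ms_states[["DM"]]
      new_state[i & u >= c1 & u < c2] <- .ms_states[["DEAD_OTHER"]]
    }
    in_dm <- state == .ms_states[["DM"]]
    if (any(in_dm)) {
      c1 <- params$p_death_after_dm; c2 <- c1 + q
      i <- in_dm
      new_state[i & u < c1] <- .ms_states[["DEAD_CANCER"]]
      new_state[i & u >= c1 & u < c2] <- .ms_states[["DEAD_OTHER"]]
    }

    entered_lr <- new_state == .ms_states[["LR"]] & state != .ms_states[["LR"]]
    entered_ar <- new_state == .ms_states[["AR"]] & state != .ms_states[["AR"]]
    entered_dm <- new_state == .ms_states[["DM"]] & state != .ms_states[["DM"]]
    died_ca <- new_state == .ms_states[["DEAD_CANCER"]] & state != .ms_states[["DEAD_CANCER"]]
    died_ot <- new_state == .ms_states[["DEAD_OTHER"]] & state != .ms_states[["DEAD_OTHER"]]
    first_ar <- first_ar | (entered_ar & !had_ar)
    got_dm <- got_dm | entered_dm
    ev_cost <- entered_lr * costs$c_local_recur_event +
      entered_ar * costs$c_axillary_recur_event +
      died_ca * costs$c_death_cancer + died_ot * costs$c_death_other
    cost_acc <- cost_acc + ev_cost
    cost_acc_disc <- cost_acc_disc + ev_cost * disc[t]
    had_lr <- had_lr | entered_lr
    had_ar <- had_ar | entered_ar
    state <- new_state
    if (records) seq_mat[, t] <- names(.ms_states)[state]
  }

  per1000 <- function(x) c(mean = 1000 * mean(x),
                           se = 1000 * stats::sd(x) / sqrt(n))
  vals <- rbind(
    qaly_discounted = per1000(qaly_disc),
    qaly_undiscounted = per1000(qaly),
    cost_discounted = per1000(cost_acc_disc),
    cost_undiscounted = per1000(cost_acc),
    total_life_years = per1000(ly),
    cum_axillary_recurrence = per1000(as.numeric(first_ar)),
    cum_distant_metastases = per1000(as.numeric(got_dm)),
    cum_death_cancer = per1000(as.numeric(state == .ms_states[["DEAD_CANCER"]])),
    cum_death_other = per1000(as.numeric(state == .ms_states[["DEAD_OTHER"]]))
  )
  summary <- data.frame(measure = rownames(vals), horizon = H,
                        mean_per_1000 = vals[, "mean"], se_per_1000 = vals[, "se"],
                        row.names = NULL, stringsAsFactors = FALSE)
  out <- list(arm = arm, n_patients = n, seed = seed, summary = summary)
  if (records) {
    out$records <- data.frame(
      id = seq_len(n), arm = arm,
      nodal_status = ifelse(node_pos, "positive", "negative"),
      pathway = pathway, lymphoedema = lymph,
      qaly_discounted = qaly_disc, qaly_undiscounted = qaly,
      cost_discounted = cost_acc_disc, cost_undiscounted = cost_acc,
      life_years = ly, first_axillary_recurrence = first_ar,
      stringsAsFactors = FALSE)
    out$state_sequence <- seq_mat
  }
  out
}

#' Draw random parameter/cost sets within the sensitivity ranges
#'
#' Draws each probability and utility uniformly within its tabulated low-high
#' range and each cost uniformly within +/-20% of its base value
#' (independent draws; the tables give ranges, not distributions). Draws that
#' fail validation or produce an infeasible transition schedule are redrawn
#' (bounded retries).
#'
#' @param n Number of sets (>= 1).
#' @param seed Integer random seed; required.
#' @param settings Settings used for the feasibility check.
#' @param max_retries Redraw budget per set.
#' @return A list of length `n`; each element is a list with `params` and
#'   `costs`.
#' @export
draw_parameter_sets <- function(n, seed, settings = model_settings(),
                                max_retries = 100L) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  pr <- parameter_ranges()
  base_costs <- cost_set()
  cost_fields <- names(unclass(base_costs))[!startsWith(names(unclass(base_costs)), "uptake_")]
  one <- function() {
    for (k in seq_len(max_retries)) {
      vals <- stats::runif(nrow(pr), pr$low, pr$high)
      p_over <- as.list(stats::setNames(vals, pr$name))
      costs <- base_costs
      for (f in cost_fields) costs[[f]] <- costs[[f]] * stats::runif(1, 0.8, 1.2)
      ok <- tryCatch({
        params <- do.call(parameter_set, p_over)
        validate_costs(costs)
        # feasibility: competing probabilities must sum <= 1 in every state
        for (nodal in c("positive", "negative"))
          for (prof in c("baseline", "fn_elevated"))
            build_schedule(list(nodal_status = nodal, profile = prof),
                           params, settings)
        TRUE
      }, error = function(e) FALSE)
      if (ok) return(list(params = params, costs = costs))
    }
    stop("failed to draw a feasible parameter set after ", max_retries, " tries")
  }
  lapply(seq_len(n), function(i) one())
}
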