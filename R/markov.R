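# Internal state space. The public six-state space (disease free, local
# recurrence, axillary recurrence, distant metastases, cancer death, other
# death) is expanded so that recurrence history is Markovian:
#  - local and axillary recurrence are 1-year tunnel states;
#  - survivors return to disease free in a post-recurrence tier whose annual
#    distant-metastasis probability is the "after local/axillary recurrence"
#    value, permanently (axillary history dominates local);
#  - on the false-negative pathway the elevated axillary-recurrence risk
#    applies only until the first axillary recurrence (the post-axillary tier
#    reverts to the baseline first-event axillary risk).
.mk_states <- c("df_0", "lr_0", "df_lr", "lr_lr", "ar_1",
                "df_ar", "lr_ar", "ar_2", "dm", "dead_cancer", "dead_other")
.mk_public <- c(df_0 = "DISEASE_FREE", lr_0 = "LOCAL_RECURRENCE",
                df_lr = "DISEASE_FREE", lr_lr = "LOCAL_RECURRENCE",
                ar_1 = "AXILLARY_RECURRENCE", df_ar = "DISEASE_FREE",
                lr_ar = "LOCAL_RECURRENCE", ar_2 = "AXILLARY_RECURRENCE",
                dm = "DISTANT_METASTASES", dead_cancer = "DEAD_CANCER",
                dead_other = "DEAD_OTHER")
.mk_alive <- setdiff(.mk_states, c("dead_cancer", "dead_other"))
.mk_df <- c("df_0", "df_lr", "df_ar")
.mk_lr <- c("lr_0", "lr_lr", "lr_ar")
.mk_ar <- c("ar_1", "ar_2")

#' Time-halving factor for first-event recurrence probabilities
#'
#' First-event local and axillary recurrence probabilities (including the
#' elevated probability after a false-negative SLNB) halve after the first
#' 5 years and halve again after 10 years.
#'
#' @param t Cycle index (1-based; cycle t spans year t-1 to t).
#' @return 1 for t <= 5, 0.5 for 5 < t <= 10, 0.25 for t > 10.
#' @export
halving_factor <- function(t) ifelse(t <= 5, 1, ifelse(t <= 10, 0.5, 0.25))

#' Build the per-cycle transition schedule for one stratum
#'
#' Constructs the time-inhomogeneous transition probability array for a
#' stratum over the model horizon. From disease free, competing annual
#' probabilities of distant metastases, first-event local and axillary
#' recurrence (subject to [halving_factor()]) and other-cause death apply;
#' the remainder stays disease free. On the `fn_elevated` profile the
#' axillary-recurrence probability is the elevated given-FN value until the
#' first axillary recurrence. Recurrences are 1-year tunnel states from which
#' patients progress to distant metastases, die of other causes, or return to
#' disease free in a post-recurrence tier whose annual distant-metastasis
#' probability is permanently the "after recurrence" value for that history
#' (axillary dominating local). From distant metastases patients may die of
#' breast cancer or other causes; cancer death is reachable only from distant
#' metastases. Other-cause death is reachable from every alive state at the
#' age-specific annual probability.
#'
#' @param stratum One row of [build_strata()] (data.frame or list with
#'   `nodal_status` and `profile`).
#' @param params An [parameter_set()] object.
#' @param settings An [model_settings()] object.
#' @return An array `[from, to, cycle]` over the internal expanded state
#'   space, every row summing to 1; rows from dead states are identity.
#' @export
build_schedule <- function(stratum, params, settings = model_settings()) {
  H <- settings$horizon
  pos <- stratum$nodal_status == "positive"
  p_dm_first <- if (pos) params$p_dm_first_node_pos else params$p_dm_first_node_neg
  p_dm_lr <- if (pos) params$p_dm_after_local_pos else params$p_dm_after_local_neg
  p_dm_ar <- if (pos) params$p_dm_after_axillary_pos else params$p_dm_after_axillary_neg
  p_ar_pre <- if (identical(stratum$profile, "fn_elevated"))
    params$p_axillary_recur_given_fn else params$p_axillary_recur_first

  n <- length(.mk_states)
  P <- array(0, dim = c(n, n, H), dimnames = list(.mk_states, .mk_states, NULL))
  ages <- settings$start_age + seq_len(H) - 1
  qo <- mortality_at_age(params$other_cause_mortality, ages)

  check <- function(tot, state, t) {
    if (tot > 1 + 1e-12)
      stop("infeasible parameters: competing probabilities sum to ", tot,
           " in state ", state, " at cycle ", t)
  }
  for (t in seq_len(H)) {
    h <- halving_factor(t)
    q <- qo[t]
    M <- matrix(0, n, n, dimnames = list(.mk_states, .mk_states))
    # disease-free tiers: (state, DM probability, LR tunnel, AR tunnel, AR rate)
    df_rows <- list(
      list("df_0",  p_dm_first, "lr_0",  "ar_1", p_ar_pre),
      list("df_lr", p_dm_lr,    "lr_lr", "ar_1", p_ar_pre),
      list("df_ar", p_dm_ar,    "lr_ar", "ar_2", params$p_axillary_recur_first)
    )
    for (row in df_rows) {
      s <- row[[1]]
      p_lr <- h * params$p_local_recur_first
      p_ar <- h * row[[5]]
      tot <- row[[2]] + p_lr + p_ar + q
      check(tot, s, t)
      M[s, "dm"] <- row[[2]]
      M[s, row[[3]]] <- p_lr
      M[s, row[[4]]] <- p_ar
      M[s, "dead_other"] <- q
      M[s, s] <- 1 - tot
    }
    # recurrence tunnels: (state, DM probability during and after, return tier)
    tun_rows <- list(
      list("lr_0", p_dm_lr, "df_lr"), list("lr_lr", p_dm_lr, "df_lr"),
      list("lr_ar", p_dm_ar, "df_ar"),
      list("ar_1", p_dm_ar, "df_ar"), list("ar_2", p_dm_ar, "df_ar")
    )
    for (row in tun_rows) {
      s <- row[[1]]
      tot <- row[[2]] + q
      check(tot, s, t)
      M[s, "dm"] <- row[[2]]
      M[s, "dead_other"] <- q
      M[s, row[[3]]] <- 1 - tot
    }
    tot <- params$p_death_after_dm + q
    check(tot, "dm", t)
    M["dm", "dead_cancer"] <- params$p_death_after_dm
    M["dm", "dead_other"] <- q
    M["dm", "dm"] <- 1 - tot
    M["dead_cancer", "dead_cancer"] <- 1
    M["dead_other", "dead_other"] <- 1
    P[, , t] <- M
  }
  P
}

# Run one stratum and return its per-cycle trace and accruals (expectations
# for a cohort of size 1).
run_stratum <- function(stratum, params, costs, settings) {
  H <- settings$horizon
  P <- build_schedule(stratum, params, settings)
  n <- length(.mk_states)
  u <- ifelse(.mk_states %in% .mk_df, params$u_disease_free,
       ifelse(.mk_states %in% c(.mk_lr, .mk_ar), params$u_recurrence,
       ifelse(.mk_states == "dm", params$u_dm, 0)))
  state_cost <- ifelse(.mk_states %in% c(.mk_df, .mk_lr, .mk_ar),
                       costs$c_followup_annual,
                       ifelse(.mk_states == "dm", costs$c_dm_annual, 0))
  plymph <- stratum$p_lymphoedema
  d <- params$lymphoedema_disutility
  r <- settings$discount_rate
  alive <- .mk_states %in% .mk_alive
  dfs <- .mk_states %in% .mk_df
  i_lr <- match(.mk_lr, .mk_states)
  i_ar <- match(.mk_ar, .mk_states)

  occ <- matrix(0, H + 1L, n, dimnames = list(NULL, .mk_states))
  occ[1L, "df_0"] <- 1
  cyc <- data.frame(cycle = seq_len(H), qaly = 0, cost = 0, ly = 0, df_years = 0,
                    new_axillary = 0, new_local = 0, new_dm = 0,
                    new_death_cancer = 0, new_death_other = 0, disc = 0)
  for (t in seq_len(H)) {
    prev <- occ[t, ]
    Pt <- P[, , t]
    nxt <- as.numeric(prev %*% Pt)
    occ[t + 1L, ] <- nxt
    # new entrants this cycle: inflow[s] = sum_{from != s} prev[from] P[from, s]
    inflow <- nxt - prev * diag(Pt)
    mid <- if (settings$half_cycle_correction) (prev + nxt) / 2 else prev
    lymph_alive <- plymph * sum(mid[alive])
    cyc$qaly[t] <- sum(mid * u) - lymph_alive * d
    cyc$cost[t] <- sum(mid * state_cost) + lymph_alive * costs$c_lymph_annual +
      sum(inflow[i_lr]) * costs$c_local_recur_event +
      sum(inflow[i_ar]) * costs$c_axillary_recur_event +
      inflow[[which(.mk_states == "dead_cancer")]] * costs$c_death_cancer +
      inflow[[which(.mk_states == "dead_other")]] * costs$c_death_other
    cyc$ly[t] <- sum(mid[alive])
    cyc$df_years[t] <- sum(mid[dfs])
    cyc$new_axillary[t] <- inflow[[which(.mk_states == "ar_1")]]
    cyc$new_local[t] <- sum(inflow[i_lr])
    cyc$new_dm[t] <- inflow[[which(.mk_states == "dm")]]
    cyc$new_death_cancer[t] <- inflow[[which(.mk_states == "dead_cancer")]]
    cyc$new_death_other[t] <- inflow[[which(.mk_states == "dead_other")]]
    cyc$disc[t] <- (1 + r)^(-t)
  }
  if (any(abs(rowSums(occ) - 1) > 1e-12))
    stop("cohort mass not conserved in stratum ", stratum$pathway)
  list(occupancy = occ, cycles = cyc)
}

#' Run the Markov cohort model for one strategy arm
#'
#' Runs every stratum of the arm for `settings$horizon` one-year cycles,
#' starting 100% disease free, and aggregates by stratum weight. Utilities
#' and annual state costs are accrued on half-cycle-corrected occupancy (the
#' average of the occupancies at the two cycle boundaries) when
#' `settings$half_cycle_correction` is TRUE, and on start-of-cycle occupancy
#' otherwise. One-off transition costs (entering local or axillary
#' recurrence, cancer death, other-cause death) are applied to the flow of
#' new entrants without half-cycle correction. Cycle-t accruals are
#' discounted by `(1 + discount_rate)^-t`; upfront surgical and adjuvant
#' costs are accrued undiscounted before the first cycle. Lymphoedema is a
#' permanent baseline attribute: in each stratum a fixed fraction
#' `p_lymphoedema` of alive occupancy accrues the lymphoedema disutility and
#' annual lymphoedema cost.
#'
#' @param strategy `"SLNB"` or `"ALND"` (used when `strata` is NULL).
#' @param params,costs,settings Model objects; see [parameter_set()],
#'   [cost_set()], [model_settings()].
#' @param strata Optionally a precomputed [build_strata()] table.
#' @return An object of class `ax_arm_result`: list with the strata, a tidy
#'   per-cycle `trace` (stratum x cycle x state occupancy over the public
#'   six-state space), per-cycle arm `cycles` accruals, `upfront_cost` per
#'   patient, and `measures`, a data.frame of per-1000-patient outcomes at
#'   5 years and at the horizon: cumulative first axillary recurrences, local
#'   recurrence events, distant metastases, cancer and other-cause deaths,
#'   disease-free years, life years, QALYs and costs (discounted and
#'   undiscounted).
#' @export
#' @examples
#' res <- run_cohort("ALND", parameter_set(), cost_set(), model_settings())
#' subset(res$measures, horizon == 20)
run_cohort <- function(strategy = c("SLNB", "ALND"), params, costs,
                       settings = model_settings(), strata = NULL) {
  if (is.null(strata)) {
    strategy <- match.arg(strategy)
    strata <- build_strata(strategy, params, costs, settings)
  } else {
    strategy <- strata$strategy[1]
  }
  H <- settings$horizon
  w <- strata$weight
  runs <- lapply(seq_len(nrow(strata)), function(i)
    run_stratum(strata[i, ], params, costs, settings))

  cyc <- runs[[1]]$cycles
  acc_cols <- c("qaly", "cost", "ly", "df_years", "new_axillary", "new_local",
                "new_dm", "new_death_cancer", "new_death_other")
  for (cl in acc_cols) {
    cyc[[cl]] <- Reduce(`+`, lapply(seq_along(runs), function(i)
      w[i] * runs[[i]]$cycles[[cl]]))
  }
  upfront <- sum(w * strata$upfront_cost)

  pub_states <- unique(unname(.mk_public))
  trace <- do.call(rbind, lapply(seq_along(runs), function(i) {
    occ <- runs[[i]]$occupancy
    agg <- sapply(pub_states, function(s)
      rowSums(occ[, .mk_public[.mk_states] == s, drop = FALSE]))
    data.frame(stratum = i, pathway = strata$pathway[i],
               nodal_status = strata$nodal_status[i],
               cycle = rep(0:H, times = ncol(agg)),
               state = rep(colnames(agg), each = H + 1L),
               occupancy = as.numeric(agg), stringsAsFactors = FALSE)
  }))

  horizons <- unique(c(min(5L, H), H))
  measures <- do.call(rbind, lapply(horizons, function(h) {
    i <- seq_len(h)
    data.frame(
      measure = c("cum_axillary_recurrence", "cum_local_recurrence",
                  "cum_distant_metastases", "cum_death_cancer",
                  "cum_death_other", "years_disease_free", "total_life_years",
                  "qaly_discounted", "qaly_undiscounted",
                  "cost_discounted", "cost_undiscounted"),
      horizon = h,
      value = 1000 * c(
        sum(cyc$new_axillary[i]), sum(cyc$new_local[i]), sum(cyc$new_dm[i]),
        sum(cyc$new_death_cancer[i]), sum(cyc$new_death_other[i]),
        sum(cyc$df_years[i]), sum(cyc$ly[i]),
        sum(cyc$qaly[i] * cyc$disc[i]), sum(cyc$qaly[i]),
        upfront + sum(cyc$cost[i] * cyc$disc[i]), upfront + sum(cyc$cost[i])),
      stringsAsFactors = FALSE)
  }))
  rownames(measures) <- NULL
  structure(list(strategy = strategy, settings = settings, strata = strata,
                 trace = trace, cycles = cyc, upfront_cost = upfront,
                 measures = measures),
            class = "ax_arm_result")
}

#' Compare the two staging strategies
#'
#' @param slnb,alnd `ax_arm_result` objects from [run_cohort()] run under the
#'   same settings.
#' @return An object of class `ax_comparison`: a data.frame with one row per
#'   measure and horizon (`slnb`, `alnd`, `difference` = SLNB - ALND columns)
#'   and a `classification` attribute per horizon based on discounted QALYs
#'   and costs: `"SLNB dominant"`, `"ALND dominant"`, or `"ICER = <value>"`
#'   (incremental cost per QALY gained) when one strategy is more effective
#'   and more costly.
#' @export
compare <- function(slnb, alnd) {
  if (!identical(unclass(slnb$settings), unclass(alnd$settings)))
    stop("arm results were produced under different settings")
  m <- merge(slnb$measures, alnd$measures, by = c("measure", "horizon"),
             suffixes = c(".slnb", ".alnd"))
  out <- data.frame(measure = m$measure, horizon = m$horizon,
                    slnb = m$value.slnb, alnd = m$value.alnd,
                    difference = m$value.slnb - m$value.alnd,
                    stringsAsFactors = FALSE)
  out <- out[order(out$horizon, match(out$measure, slnb$measures$measure)), ]
  rownames(out) <- NULL
  cls <- vapply(unique(out$horizon), function(h) {
    dq <- out$difference[out$measure == "qaly_discounted" & out$horizon == h]
    dc <- out$difference[out$measure == "cost_discounted" & out$horizon == h]
    classify_dominance(dq, dc)
  }, character(1))
  names(cls) <- unique(out$horizon)
  structure(out, classification = cls, class = c("ax_comparison", "data.frame"))
}

classify_dominance <- function(d_qaly, d_cost, tol = 1e-10) {
  if (abs(d_qaly) < tol && abs(d_cost) < tol) return("tie")
  if (d_qaly >= 0 && d_cost <= 0) return("SLNB dominant")
  if (d_qaly <= 0 && d_cost >= 0) return("ALND dominant")
  sprintf("ICER = %.2f", d_cost / d_qaly)
}

#' Incremental outcomes of SLNB versus ALND
#'
#' Convenience wrapper running both arms and returning the per-1000-patient
#' SLNB-minus-ALND differences at the horizon. Used heavily by the
#' sensitivity machinery.
#'
#' @inheritParams run_cohort
#' @return A list with `d_qaly_disc`, `d_cost_disc`, `d_qaly_undisc`,
#'   `d_cost_undisc` (per 1000 patients, at `settings$horizon`) and the full
#'   [compare()] table as `comparison`.
#' @export
incremental <- function(params, costs, settings = model_settings()) {
  cmp <- compare(run_cohort("SLNB", params, costs, settings),
                 run_cohort("ALND", params, costs, settings))
  H <- settings$horizon
  g <- function(meas) cmp$difference[cmp$measure == meas & cmp$horizon == H]
  list(d_qaly_disc = g("qaly_discounted"), d_cost_disc = g("cost_discounted"),
       d_qaly_undisc = g("qaly_undiscounted"),
       d_cost_undisc = g("cost_undiscounted"), comparison = cmp)
}
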