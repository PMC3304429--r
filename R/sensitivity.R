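#' Override a single model input by name
#'
#' Maps a parameter name to a modified `(params, costs)` pair. Names may be
#' any field of [parameter_set()] or [cost_set()], or the derived quantity
#' `cum5_axillary_recur_given_fn`: the 5-year cumulative axillary-recurrence
#' risk after a false-negative SLNB, converted to the annual probability via
#' `annual = 1 - (1 - cum5)^(1/5)` (the halving after years 5 and 10 still
#' applies to the annual probability).
#'
#' @param params,costs Model objects.
#' @param name Input name.
#' @param value New value.
#' @return A list with modified `params` and `costs`.
#' @export
set_model_input <- function(params, costs, name, value) {
  if (name == "cum5_axillary_recur_given_fn") {
    params$p_axillary_recur_given_fn <- 1 - (1 - value)^(1 / 5)
  } else if (name %in% .param_fields) {
    params[[name]] <- value
  } else if (name %in% names(unclass(costs))) {
    costs[[name]] <- value
  } else {
    stop("unknown model input: ", name)
  }
  list(params = params, costs = costs)
}

# Incremental outcome (SLNB - ALND, per 1000 at the horizon) as a function of
# one model input.
outcome_fn <- function(parameter, outcome, params, costs, settings) {
  outcome <- match.arg(outcome, c("incremental_QALY", "incremental_cost"))
  force(parameter)
  function(x) {
    mod <- set_model_input(params, costs, parameter, x)
    inc <- incremental(mod$params, mod$costs, settings)
    if (outcome == "incremental_QALY") inc$d_qaly_disc else inc$d_cost_disc
  }
}

#' One-way threshold analysis
#'
#' Finds, by bisection, the value of one model input at which the 20-year
#' discounted incremental outcome (SLNB minus ALND) crosses zero, all other
#' inputs held at their base-case values. If the outcome difference has the
#' same sign at both bounds the result is returned as non-converged with the
#' boundary signs reported, not an error.
#'
#' @param parameter Input name; see [set_model_input()].
#' @param outcome `"incremental_QALY"` (discounted QALYs per 1000) or
#'   `"incremental_cost"` (discounted AUD per 1000).
#' @param bounds Length-2 numeric search interval.
#' @param tol Convergence tolerance on the absolute incremental outcome
#'   (per-1000 units); bisection also stops when the parameter interval
#'   shrinks below 1e-6.
#' @param params,costs,settings Base-case model objects.
#' @return An object of class `ax_threshold`: a list with `parameter`,
#'   `outcome`, `threshold` (NA if non-converged), `direction`
#'   (`"SLNB_preferred_below"` or `"SLNB_preferred_above"`), `bounds`,
#'   `f_bounds` (outcome at the bounds), `value_at_threshold`, `converged`,
#'   and `iterations`.
#' @export
#' @examples
#' \donttest{
#' p <- parameter_set(); cs <- cost_set()
#' one_way_threshold("p_slnb_fn", "incremental_QALY", c(0, 0.3),
#'                   params = p, costs = cs)
#' }
one_way_threshold <- function(parameter,
                              outcome = c("incremental_QALY", "incremental_cost"),
                              bounds, tol = 1e-3,
                              params = parameter_set(), costs = cost_set(),
                              settings = model_settings()) {
  outcome <- match.arg(outcome)
  f <- outcome_fn(parameter, outcome, params, costs, settings)
  lo <- min(bounds); hi <- max(bounds)
  f_lo <- f(lo); f_hi <- f(hi)
  res <- list(parameter = parameter, outcome = outcome, threshold = NA_real_,
              direction = NA_character_, bounds = c(lo, hi),
              f_bounds = c(f_lo, f_hi), value_at_threshold = NA_real_,
              converged = FALSE, iterations = 0L)
  class(res) <- "ax_threshold"
  if (is.na(f_lo) || is.na(f_hi) || sign(f_lo) == sign(f_hi)) return(res)
  # SLNB is preferred where the incremental QALY is positive / the
  # incremental cost is negative
  pref_sign <- if (outcome == "incremental_QALY") 1 else -1
  res$direction <- if (sign(f_lo) == pref_sign) "SLNB_preferred_below"
                   else "SLNB_preferred_above"
  it <- 0L
  f_mid <- NA_real_
  while (hi - lo > 1e-6 && it < 200L) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    it <- it + 1L
    if (abs(f_mid) < tol) break
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else { hi <- mid }
  }
  res$threshold <- (lo + hi) / 2
  if (!is.na(f_mid) && abs(f_mid) < tol) res$threshold <- mid
  res$value_at_threshold <- f(res$threshold)
  res$converged <- TRUE
  res$iterations <- it
  res
}

#' @export
print.ax_threshold <- function(x, ...) {
  cat("One-way threshold:", x$parameter, "vs", x$outcome, "\n")
  if (x$converged) {
    cat(sprintf("  threshold = %.6g (%s), outcome at threshold = %.3g\n",
                x$threshold, x$direction, x$value_at_threshold))
  } else {
    cat(sprintf("  not converged: outcome has the same sign at both bounds (%.3g, %.3g)\n",
                x$f_bounds[1], x$f_bounds[2]))
  }
  invisible(x)
}

#' Multiway sensitivity planes
#'
#' For a given population risk of nodal metastases, crosses levels of the
#' false-negative SLNB rate (panel columns) with levels of the 5-year
#' cumulative axillary-recurrence risk given a false-negative SLNB (panel
#' rows). Each panel is a grid over the probability of lymphoedema after ALND
#' (x) and the lymphoedema disutility (y); each cell records which strategy
#' yields more discounted QALYs over the horizon.
#'
#' Arm QALYs are exactly affine in the lymphoedema disutility (occupancy does
#' not depend on it), so each grid column is evaluated by full model
#' comparisons at the two ends of the disutility axis and interpolated
#' exactly in between.
#'
#' @param p_node_positive Scenario nodal-metastasis risk (0.27 or 0.50 in the
#'   standard analysis).
#' @param fn_levels Three false-negative rates (default: low, base, high of
#'   the sensitivity range).
#' @param recur5_levels Three 5-year cumulative axillary-recurrence risks
#'   given FN (default: low and base mapped from the annual range, and 0.30,
#'   the conservative upper estimate).
#' @param lymph_axis,disutility_axis Length-2 ranges for the grid axes.
#' @param grid_n Grid resolution per axis (default 41).
#' @param params,costs,settings Base-case model objects.
#' @param tie_tol Absolute discounted-QALY difference (per 1000) below which
#'   a cell is recorded as a tie.
#' @return A data.frame of class `ax_planes` in long format with columns
#'   `p_node_positive`, `fn_level`, `recur5_level`, `p_lymph_alnd`,
#'   `lymphoedema_disutility`, `d_qaly_disc`, `preferred`
#'   (`"SLNB"`/`"ALND"`/`"tie"`).
#' @export
multiway_plane <- function(p_node_positive = 0.27,
                           fn_levels = c(0.024, 0.055, 0.166),
                           recur5_levels = NULL,
                           lymph_axis = c(0.1312, 0.2112),
                           disutility_axis = c(0.01, 0.05),
                           grid_n = 41,
                           params = parameter_set(), costs = cost_set(),
                           settings = model_settings(), tie_tol = 1e-10) {
  if (is.null(recur5_levels)) {
    cum5 <- function(annual) 1 - (1 - annual)^5
    recur5_levels <- c(cum5(0.0102), cum5(0.0160), 0.30)
  }
  params$p_node_positive <- p_node_positive
  xs <- seq(lymph_axis[1], lymph_axis[2], length.out = grid_n)
  ds <- seq(disutility_axis[1], disutility_axis[2], length.out = grid_n)
  d0 <- disutility_axis[1]; d1 <- disutility_axis[2]
  out <- list()
  for (fn in fn_levels) for (r5 in recur5_levels) {
    p1 <- params
    p1$p_slnb_fn <- fn
    p1$p_axillary_recur_given_fn <- 1 - (1 - r5)^(1 / 5)
    for (x in xs) {
      p2 <- p1
      p2$p_lymph_alnd <- x
      p2$lymphoedema_disutility <- d0
      q0 <- incremental(p2, costs, settings)$d_qaly_disc
      p2$lymphoedema_disutility <- d1
      q1 <- incremental(p2, costs, settings)$d_qaly_disc
      dq <- if (d1 > d0) q0 + (q1 - q0) * (ds - d0) / (d1 - d0) else rep(q0, grid_n)
      out[[length(out) + 1L]] <- data.frame(
        p_node_positive = p_node_positive, fn_level = fn, recur5_level = r5,
        p_lymph_alnd = x, lymphoedema_disutility = ds, d_qaly_disc = dq,
        preferred = ifelse(abs(dq) < tie_tol, "tie",
                           ifelse(dq > 0, "SLNB", "ALND")),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("ax_planes", "data.frame")
  out
}

#' Plot multiway preference planes
#'
#' Renders the output of [multiway_plane()] as a 3x3 grid of shaded planes
#' (preferred strategy by colour). Requires ggplot2.
#'
#' @param planes An `ax_planes` data.frame.
#' @return A ggplot object.
#' @export
plot_preference_planes <- function(planes) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  planes$fn_label <- sprintf("FN rate %.1f%%", 100 * planes$fn_level)
  planes$r5_label <- sprintf("5y recurrence %.0f%%", 100 * planes$recur5_level)
  ggplot2::ggplot(planes,
                  ggplot2::aes(x = .data$p_lymph_alnd,
                               y = .data$lymphoedema_disutility,
                               fill = .data$preferred)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(r5_label ~ fn_label) +
    ggplot2::scale_fill_manual(values = c(SLNB = "#2c7fb8", ALND = "#a1dab4",
                                          tie = "grey80")) +
    ggplot2::labs(x = "Probability of lymphoedema after ALND",
                  y = "Lymphoedema disutility",
                  fill = "More QALYs with",
                  title = sprintf("Nodal metastasis risk %.0f%%",
                                  100 * planes$p_node_positive[1])) +
    ggplot2::theme_minimal()
}

#' Tornado summary of one-way parameter variation
#'
#' Varies each input over its sensitivity range (probabilities/utilities: the
#' tabulated low-high range; costs: +/-20%), holding all others at base case,
#' and records the incremental outcome at each end.
#'
#' @param parameters Character vector of input names; defaults to every
#'   ranged probability/utility and every cost item.
#' @param outcome `"incremental_QALY"` or `"incremental_cost"`.
#' @param params,costs,settings Base-case model objects.
#' @return A data.frame sorted by decreasing swing, with columns `parameter`,
#'   `low`, `high`, `outcome_at_low`, `outcome_at_high`, `outcome_at_base`,
#'   `swing`, and `classification_stable` (TRUE when the preferred strategy by
#'   that outcome is the same at both ends).
#' @export
tornado <- function(parameters = NULL,
                    outcome = c("incremental_QALY", "incremental_cost"),
                    params = parameter_set(), costs = cost_set(),
                    settings = model_settings()) {
  outcome <- match.arg(outcome)
  pr <- parameter_ranges()
  cost_fields <- names(unclass(costs))[!startsWith(names(unclass(costs)), "uptake_")]
  if (is.null(parameters)) parameters <- c(pr$name, cost_fields)
  base_val <- incremental(params, costs, settings)
  base_out <- if (outcome == "incremental_QALY") base_val$d_qaly_disc else base_val$d_cost_disc
  rows <- lapply(parameters, function(nm) {
    if (nm %in% pr$name) {
      lo <- pr$low[pr$name == nm]; hi <- pr$high[pr$name == nm]
    } else if (nm %in% cost_fields) {
      lo <- 0.8 * costs[[nm]]; hi <- 1.2 * costs[[nm]]
    } else stop("unknown model input: ", nm)
    f <- outcome_fn(nm, outcome, params, costs, settings)
    o_lo <- f(lo); o_hi <- f(hi)
    pref <- function(v) if (outcome == "incremental_QALY") v > 0 else v < 0
    data.frame(parameter = nm, low = lo, high = hi,
               outcome_at_low = o_lo, outcome_at_high = o_hi,
               outcome_at_base = base_out,
               swing = abs(o_hi - o_lo),
               classification_stable = pref(o_lo) == pref(o_hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  out
}
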