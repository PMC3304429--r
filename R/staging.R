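#' Arm-level adjuvant therapy cost per patient
#'
#' Sum of uptake x unit cost over radiotherapy, first-line chemotherapy,
#' 5-year endocrine therapy and 1-year trastuzumab. With
#' `differential = FALSE` (the default model behaviour) the ALND uptake
#' proportions are applied to both arms, so the staging strategy is assumed
#' not to change adjuvant therapy use; with `differential = TRUE` each arm
#' uses its own uptake proportions.
#'
#' @param costs An [cost_set()] object.
#' @param strategy `"SLNB"` or `"ALND"`.
#' @param differential Use arm-specific uptakes (default FALSE).
#' @return Adjuvant cost per patient (AUD), accrued before the first cycle.
#' @export
arm_adjuvant_cost <- function(costs, strategy = c("SLNB", "ALND"),
                              differential = FALSE) {
  strategy <- match.arg(strategy)
  slnb <- differential && strategy == "SLNB"
  rt <- if (slnb) costs$uptake_radiotherapy_slnb else costs$uptake_radiotherapy_alnd
  ch <- if (slnb) costs$uptake_chemo_slnb else costs$uptake_chemo_alnd
  rt * costs$c_radiotherapy + ch * costs$c_chemo_first_line +
    costs$uptake_endocrine * costs$c_endocrine_5yr +
    costs$uptake_herceptin * costs$c_herceptin_1yr
}

#' Lymphoedema probability for a staging procedure
#'
#' The trial-reported probability of moderate-severe arm lymphoedema
#' associated with each surgical procedure. Within the SLNB arm, patients
#' whose pathway converts to completion ALND (positive or failed SLNB) carry
#' the ALND-level risk; see [build_strata()].
#'
#' @param strategy `"SLNB"` or `"ALND"`.
#' @param params An [parameter_set()] object.
#' @return A probability.
#' @export
arm_lymphoedema_probability <- function(strategy = c("SLNB", "ALND"), params) {
  strategy <- match.arg(strategy)
  if (strategy == "ALND") params$p_lymph_alnd else params$p_lymph_slnb
}

#' Build the cohort strata for one staging strategy
#'
#' Encodes the upfront decision tree. The ALND arm splits into 2 strata by
#' nodal status. The SLNB arm splits into 5 strata by nodal status and
#' staging pathway, with weights (p = node-positive proportion, f = SLNB
#' failure rate, fn = false-negative rate among node-positive patients whose
#' mapping succeeded):
#' node-negative/fail `(1-p)f`, node-negative/true-negative `(1-p)(1-f)`,
#' node-positive/fail `pf`, node-positive/false-negative `p(1-f)fn`,
#' node-positive/detected `p(1-f)(1-fn)`.
#'
#' Each stratum carries its upfront surgical cost, the arm adjuvant cost, a
#' lymphoedema probability (ALND-level risk on pathways that undergo ALND,
#' including completion ALND after a positive or failed SLNB), and the
#' axillary-recurrence profile (`fn_elevated` on the false-negative pathway,
#' `baseline` elsewhere).
#'
#' @param strategy `"SLNB"` or `"ALND"`.
#' @param params An [parameter_set()] object.
#' @param costs An [cost_set()] object.
#' @param settings An [model_settings()] object (controls whether adjuvant
#'   uptake is arm-specific).
#' @return A data.frame of class `ax_strata`, one row per stratum, with
#'   columns `strategy`, `pathway`, `nodal_status`, `weight`, `upfront_cost`,
#'   `p_lymphoedema`, `profile`.
#' @export
#' @examples
#' s <- build_strata("SLNB", parameter_set(), cost_set())
#' sum(s$weight)
build_strata <- function(strategy = c("SLNB", "ALND"), params, costs,
                         settings = model_settings()) {
  strategy <- match.arg(strategy)
  adj <- arm_adjuvant_cost(costs, strategy,
                           differential = settings$differential_adjuvant_uptake)
  p <- params$p_node_positive
  if (strategy == "ALND") {
    out <- data.frame(
      strategy = "ALND",
      pathway = "ALND_direct",
      nodal_status = c("positive", "negative"),
      weight = c(p, 1 - p),
      surgical_cost = costs$c_alnd,
      p_lymphoedema = params$p_lymph_alnd,
      profile = "baseline",
      stringsAsFactors = FALSE
    )
  } else {
    f <- params$p_slnb_fail
    fn <- params$p_slnb_fn
    out <- data.frame(
      strategy = "SLNB",
      pathway = c("SLNB_true_negative", "SLNB_fail_to_ALND",
                  "SLNB_false_negative", "SLNB_positive_to_ALND",
                  "SLNB_fail_to_ALND"),
      nodal_status = c("negative", "negative", "positive", "positive", "positive"),
      weight = c((1 - p) * (1 - f), (1 - p) * f,
                 p * (1 - f) * fn, p * (1 - f) * (1 - fn), p * f),
      surgical_cost = c(costs$c_slnb_neg, costs$c_slnb_fail_then_alnd,
                        costs$c_slnb_neg, costs$c_slnb_pos_then_alnd,
                        costs$c_slnb_fail_then_alnd),
      p_lymphoedema = c(params$p_lymph_slnb, params$p_lymph_alnd,
                        params$p_lymph_slnb, params$p_lymph_alnd,
                        params$p_lymph_alnd),
      profile = c("baseline", "baseline", "fn_elevated", "baseline", "baseline"),
      stringsAsFactors = FALSE
    )
  }
  out$upfront_cost <- out$surgical_cost + adj
  if (abs(sum(out$weight) - 1) > 1e-12)
    stop("internal consistency error: stratum weights sum to ", sum(out$weight))
  if (any(out$profile == "fn_elevated" &
          (out$nodal_status != "positive" | out$strategy != "SLNB")))
    stop("fn_elevated profile outside the SLNB false-negative pathway")
  class(out) <- c("ax_strata", "data.frame")
  out
}
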