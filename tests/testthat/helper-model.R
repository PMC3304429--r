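# Shared fixtures, built in code.

base_params <- function(...) parameter_set(...)
base_costs <- function(...) cost_set(...)
base_settings <- function(...) model_settings(...)

# a mortality schedule with no other-cause deaths (isolates disease dynamics)
zero_mortality <- function() data.frame(age = 58:78, q = 0)

# parameters for the two-cycle toy model checked against a hand recursion
toy_params <- function() parameter_set(
  p_node_positive = 1,
  p_dm_first_node_pos = 0.1,
  p_local_recur_first = 0.05,
  p_axillary_recur_first = 0.02,
  p_dm_after_local_pos = 0.3,
  p_dm_after_axillary_pos = 0.4,
  p_death_after_dm = 0.5,
  u_disease_free = 0.9, u_recurrence = 0.8, u_dm = 0.6,
  lymphoedema_disutility = 0.1,
  p_lymph_alnd = 0.5,
  other_cause_mortality = zero_mortality()
)

toy_costs <- function() cost_set(
  c_alnd = 2000,
  uptake_radiotherapy_alnd = 0, uptake_radiotherapy_slnb = 0,
  uptake_chemo_alnd = 0, uptake_chemo_slnb = 0,
  uptake_endocrine = 0, uptake_herceptin = 0,
  c_followup_annual = 100, c_dm_annual = 1000, c_lymph_annual = 200,
  c_local_recur_event = 500, c_axillary_recur_event = 700,
  c_death_cancer = 900, c_death_other = 0
)

# a configuration under which the two arms are structurally identical
symmetric_inputs <- function() {
  params <- parameter_set(p_slnb_fail = 0, p_slnb_fn = 0,
                          p_lymph_slnb = 0.176)
  costs <- cost_set(c_slnb_neg = 5576.45, c_slnb_pos_then_alnd = 5576.45)
  list(params = params, costs = costs)
}

get_measure <- function(res, meas, h) {
  m <- if (inherits(res, "ax_arm_result")) res$measures else res
  col <- if ("value" %in% names(m)) "value" else "difference"
  m[[col]][m$measure == meas & m$horizon == h]
}

# dense-grid oracle for threshold location: returns the interval of the first
# sign change of the incremental outcome over an equally spaced grid
grid_scan_crossing <- function(parameter, outcome, bounds, n_grid = 201,
                               params = parameter_set(), costs = cost_set(),
                               settings = model_settings()) {
  xs <- seq(bounds[1], bounds[2], length.out = n_grid)
  vals <- vapply(xs, function(x) {
    mod <- set_model_input(params, costs, parameter, x)
    inc <- incremental(mod$params, mod$costs, settings)
    if (outcome == "incremental_QALY") inc$d_qaly_disc else inc$d_cost_disc
  }, numeric(1))
  s <- sign(vals)
  flip <- which(s[-1] != s[-n_grid])[1]
  if (is.na(flip)) return(NULL)
  c(lower = xs[flip], upper = xs[flip + 1], step = xs[2] - xs[1])
}
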