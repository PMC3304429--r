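test_that("bisection thresholds are roots and agree with a dense grid scan", {
  p <- base_params(); cs <- base_costs(); st <- base_settings()
  tol <- 1e-3
  for (spec in list(list("p_slnb_fn", c(0, 0.3)),
                    list("lymphoedema_disutility", c(0, 0.05)))) {
    th <- one_way_threshold(spec[[1]], "incremental_QALY", spec[[2]], tol = tol,
                            params = p, costs = cs, settings = st)
    expect_true(th$converged)
    # re-evaluating the model at the threshold gives |outcome| < 10 tol
    f <- axstage:::outcome_fn(spec[[1]], "incremental_QALY", p, cs, st)
    expect_lt(abs(f(th$threshold)), 10 * tol)
    # brute-force oracle: sign change located by a 201-point scan
    g <- grid_scan_crossing(spec[[1]], "incremental_QALY", spec[[2]], 201,
                            p, cs, st)
    expect_gte(th$threshold, g["lower"] - g["step"])
    expect_lte(th$threshold, g["upper"] + g["step"])
  }
})

test_that("a parameter with no effect on the outcome returns non-converged", {
  th <- one_way_threshold("c_followup_annual", "incremental_QALY",
                          c(100, 500), params = base_params(),
                          costs = base_costs(), settings = base_settings())
  expect_false(th$converged)
  expect_true(is.na(th$threshold))
  expect_equal(sign(th$f_bounds[1]), sign(th$f_bounds[2]))
})

test_that("threshold directions state where SLNB is preferred", {
  p <- base_params(); cs <- base_costs(); st <- base_settings()
  th_fn <- one_way_threshold("p_slnb_fn", "incremental_QALY", c(0, 0.3),
                             params = p, costs = cs, settings = st)
  expect_equal(th_fn$direction, "SLNB_preferred_below")
  th_ly <- one_way_threshold("p_lymph_alnd", "incremental_QALY", c(0.119, 0.25),
                             params = p, costs = cs, settings = st)
  expect_equal(th_ly$direction, "SLNB_preferred_above")
})

test_that("the 5-year recurrence risk maps to its annual probability", {
  p <- base_params(); cs <- base_costs()
  mod <- set_model_input(p, cs, "cum5_axillary_recur_given_fn", 0.30)
  expect_equal(mod$params$p_axillary_recur_given_fn, 1 - 0.7^(1 / 5))
  expect_equal(1 - (1 - mod$params$p_axillary_recur_given_fn)^5, 0.30)
  expect_error(set_model_input(p, cs, "no_such_input", 1), "unknown model input")
})

test_that("preference planes shade by the strategy generating more QALYs", {
  p <- base_params(); cs <- base_costs(); st <- base_settings()
  cum5 <- function(a) 1 - (1 - a)^5
  # FN rate and recurrence risk at the favourable end: SLNB preferred everywhere
  low <- multiway_plane(0.27, fn_levels = 0.024, recur5_levels = cum5(0.0102),
                        grid_n = 7, params = p, costs = cs, settings = st)
  # SLNB is preferred across the panel except, at most, the extreme corner
  # where the lymphoedema probabilities nearly coincide and the disutility is
  # at its floor
  expect_gte(mean(low$preferred == "SLNB"), 0.95)
  expect_true(all(low$preferred[low$lymphoedema_disutility >= 0.02] == "SLNB"))
  # at the unfavourable end ALND dominates most of the plane
  high <- multiway_plane(0.27, fn_levels = 0.166, recur5_levels = 0.30,
                         grid_n = 7, params = p, costs = cs, settings = st)
  expect_gt(mean(high$preferred == "ALND"), 0.5)
  # no lymphoedema benefit at all: SLNB can never be preferred
  p_eq <- parameter_set(p_lymph_slnb = 0.119)
  none <- multiway_plane(0.27, fn_levels = 0.055, recur5_levels = cum5(0.016),
                         lymph_axis = c(0.119, 0.119),
                         disutility_axis = c(0, 0), grid_n = 3,
                         params = p_eq, costs = cs, settings = st)
  expect_true(all(none$preferred != "SLNB"))
})

test_that("planes are monotone and coherent with the one-way threshold", {
  p <- base_params(); cs <- base_costs(); st <- base_settings()
  pl <- multiway_plane(0.269, fn_levels = 0.055,
                       recur5_levels = 1 - (1 - 0.016)^5,
                       lymph_axis = c(0.1312, 0.2112),
                       disutility_axis = c(0.01, 0.05),
                       grid_n = 9, params = p, costs = cs, settings = st)
  # within each row/column the preferred strategy switches at most once
  for (d in unique(pl$lymphoedema_disutility)) {
    row <- pl[pl$lymphoedema_disutility == d, ]
    row <- row[order(row$p_lymph_alnd), ]
    expect_lte(sum(diff(row$preferred == "SLNB") != 0), 1)
  }
  # the disutility axis interpolation is exact (QALYs are affine in it)
  cell <- pl[5, ]
  mod <- p
  mod$p_slnb_fn <- cell$fn_level
  mod$p_axillary_recur_given_fn <- 1 - (1 - cell$recur5_level)^(1 / 5)
  mod$p_lymph_alnd <- cell$p_lymph_alnd
  mod$lymphoedema_disutility <- cell$lymphoedema_disutility
  expect_equal(incremental(mod, cs, st)$d_qaly_disc, cell$d_qaly_disc,
               tolerance = 1e-9)
  # sign flip along the lymphoedema axis at the one-way threshold +/- one step
  th <- one_way_threshold("p_lymph_alnd", "incremental_QALY", c(0.119, 0.25),
                          params = p, costs = cs, settings = st)
  d_mid <- unique(pl$lymphoedema_disutility)[which.min(abs(
    unique(pl$lymphoedema_disutility) - 0.03))]
  row <- pl[pl$lymphoedema_disutility == d_mid, ]
  row <- row[order(row$p_lymph_alnd), ]
  flip <- which(diff(row$preferred == "SLNB") != 0)
  step <- diff(row$p_lymph_alnd[1:2])
  expect_length(flip, 1)
  expect_lt(abs(row$p_lymph_alnd[flip] - th$threshold), 2 * step)
})

test_that("tornado ranks swings and keeps dominance under cost variation", {
  p <- base_params(); cs <- base_costs(); st <- base_settings()
  cost_fields <- names(unclass(cs))[!startsWith(names(unclass(cs)), "uptake_")]
  tq <- tornado(cost_fields, "incremental_QALY", p, cs, st)
  expect_true(all(tq$swing < 1e-9))  # pure cost items cannot move QALYs
  tc <- tornado(cost_fields, "incremental_cost", p, cs, st)
  expect_true(all(diff(tc$swing) <= 1e-12))  # sorted by decreasing swing
  # +/-20% on any cost item other than the staging-procedure costs (which
  # have their own cost thresholds) leaves SLNB cost saving at both ends
  stable <- !(tc$parameter %in% c("c_alnd", "c_slnb_neg", "c_slnb_pos_then_alnd"))
  expect_true(all(tc$classification_stable[stable]))
  expect_true(all(tc$outcome_at_low[stable] < 0 & tc$outcome_at_high[stable] < 0))
  # a collapsed range produces zero swing
  t0 <- tornado("p_slnb_fn", "incremental_QALY",
                params = p, costs = cs, settings = st)
  pr <- parameter_ranges()
  expect_gt(t0$swing, 0)
  f <- axstage:::outcome_fn("p_slnb_fn", "incremental_QALY", p, cs, st)
  expect_equal(f(p$p_slnb_fn), t0$outcome_at_base, tolerance = 1e-9)
})
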