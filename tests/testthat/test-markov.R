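fn_stratum <- function() {
  data.frame(strategy = "SLNB", pathway = "SLNB_false_negative",
             nodal_status = "positive", weight = 1, surgical_cost = 0,
             p_lymphoedema = 0, profile = "fn_elevated", upfront_cost = 0,
             stringsAsFactors = FALSE)
}

test_that("transition schedules are proper and apply the halving rule", {
  p <- base_params(); st <- base_settings()
  for (prof in c("baseline", "fn_elevated")) {
    stratum <- list(nodal_status = "positive", profile = prof)
    P <- build_schedule(stratum, p, st)
    for (t in 1:20) {
      expect_equal(unname(rowSums(P[, , t])), rep(1, 11), tolerance = 1e-12)
      expect_true(all(P[, , t] >= 0))
    }
    # dead states are absorbing
    expect_equal(P["dead_cancer", "dead_cancer", 7], 1)
    expect_equal(P["dead_other", "dead_other", 13], 1)
    # cancer death is reachable only from distant metastases
    expect_true(all(P[setdiff(rownames(P[, , 1]), c("dm", "dead_cancer")),
                      "dead_cancer", ] == 0))
  }
  P <- build_schedule(list(nodal_status = "positive", profile = "baseline"), p, st)
  expect_equal(P["df_0", "lr_0", 3], 0.0055)
  expect_equal(P["df_0", "lr_0", 6], 0.00275)   # halves after year 5
  expect_equal(P["df_0", "lr_0", 11], 0.001375) # halves again after year 10
  expect_equal(P["df_0", "ar_1", 1], 0.0008)
  Pfn <- build_schedule(list(nodal_status = "positive", profile = "fn_elevated"), p, st)
  expect_equal(Pfn["df_0", "ar_1", 1], 0.016)
  # the elevation ends after the first axillary recurrence
  expect_equal(Pfn["df_ar", "ar_2", 1], 0.0008)
})

test_that("infeasible competing probabilities are rejected with context", {
  p <- parameter_set(p_dm_after_axillary_pos = 0.999, validate = FALSE)
  p$other_cause_mortality <- data.frame(age = 58:78, q = 0.05)
  expect_error(build_schedule(list(nodal_status = "positive", profile = "baseline"),
                              p, base_settings()),
               "competing probabilities sum to .* at cycle 1")
})

test_that("false-negative axillary recurrence accumulates to the 5-year figure", {
  # with competing risks switched off, 5-year cumulative axillary recurrence
  # after a false-negative SLNB is 1 - (1 - 0.016)^5 = 7.75%
  p <- parameter_set(p_local_recur_first = 0, p_dm_first_node_pos = 0,
                     other_cause_mortality = zero_mortality())
  res <- run_cohort(params = p, costs = base_costs(), settings = base_settings(),
                    strata = fn_stratum())
  expect_equal(get_measure(res, "cum_axillary_recurrence", 5) / 1000,
               1 - (1 - 0.016)^5, tolerance = 1e-12)
  expect_equal(1 - (1 - 0.016)^5, 0.0775, tolerance = 1e-3)
})

test_that("two-cycle cohort matches an independent hand recursion", {
  p <- toy_params(); cs <- toy_costs()
  st <- model_settings(horizon = 2, discount_rate = 0.05)
  res <- run_cohort("ALND", p, cs, st)

  # hand recursion over the public states (node-positive ALND stratum only;
  # the node-negative stratum has weight 0 because p_node_positive = 1)
  # cycle 1 flows out of disease free
  df0 <- 1
  dm1 <- 0.1; lr1 <- 0.05; ar1 <- 0.02; df1 <- df0 - dm1 - lr1 - ar1
  mid_df <- (df0 + df1) / 2; mid_lr <- lr1 / 2; mid_ar <- ar1 / 2; mid_dm <- dm1 / 2
  alive1 <- 1 # no deaths possible in cycle 1 (q = 0, no dm occupancy yet)
  q1 <- mid_df * 0.9 + (mid_lr + mid_ar) * 0.8 + mid_dm * 0.6 - 0.5 * 0.1 * alive1
  c1 <- (mid_df + mid_lr + mid_ar) * 100 + mid_dm * 1000 +
    0.5 * alive1 * 200 + lr1 * 500 + ar1 * 700
  # cycle 2
  dm_from_df <- df1 * 0.1; lr2 <- df1 * 0.05; ar2 <- df1 * 0.02
  df2 <- df1 - dm_from_df - lr2 - ar2 + lr1 * 0.7 + ar1 * 0.6
  dm2 <- dm1 * 0.5 + dm_from_df + lr1 * 0.3 + ar1 * 0.4
  dc2 <- dm1 * 0.5
  mid_df <- (df1 + df2) / 2; mid_lr <- (lr1 + lr2) / 2; mid_ar <- (ar1 + ar2) / 2
  mid_dm <- (dm1 + dm2) / 2
  alive2 <- (1 + (1 - dc2)) / 2
  q2 <- mid_df * 0.9 + (mid_lr + mid_ar) * 0.8 + mid_dm * 0.6 - 0.5 * 0.1 * alive2
  c2 <- (mid_df + mid_lr + mid_ar) * 100 + mid_dm * 1000 +
    0.5 * alive2 * 200 + lr2 * 500 + ar2 * 700 + dc2 * 900
  qaly_disc <- q1 / 1.05 + q2 / 1.05^2
  cost_disc <- 2000 + c1 / 1.05 + c2 / 1.05^2

  expect_equal(get_measure(res, "qaly_discounted", 2), 1000 * qaly_disc,
               tolerance = 1e-12)
  expect_equal(get_measure(res, "cost_discounted", 2), 1000 * cost_disc,
               tolerance = 1e-12)
  expect_equal(get_measure(res, "qaly_undiscounted", 2), 1000 * (q1 + q2),
               tolerance = 1e-12)
  expect_equal(get_measure(res, "total_life_years", 2), 1000 * (alive1 + alive2),
               tolerance = 1e-12)
})

test_that("cohort mass is conserved and counters are monotone", {
  set.seed(21)
  st <- base_settings()
  for (i in 1:5) {
    p <- parameter_set(p_node_positive = runif(1, 0.1, 0.6),
                       p_slnb_fn = runif(1, 0, 0.2),
                       p_axillary_recur_given_fn = runif(1, 0.001, 0.06))
    for (arm in c("SLNB", "ALND")) {
      res <- run_cohort(arm, p, base_costs(), st)
      occ <- stats::aggregate(occupancy ~ stratum + cycle, res$trace, sum)
      expect_equal(occ$occupancy, rep(1, nrow(occ)), tolerance = 1e-12)
      for (cnt in c("new_axillary", "new_local", "new_dm",
                    "new_death_cancer", "new_death_other")) {
        cum <- cumsum(res$cycles[[cnt]])
        expect_true(all(diff(cum) >= -1e-15))
        expect_lte(1000 * max(cum), 1000)
      }
    }
  }
})

test_that("zero discounting makes discounted and undiscounted outcomes equal", {
  st0 <- model_settings(discount_rate = 0)
  res <- run_cohort("SLNB", base_params(), base_costs(), st0)
  expect_equal(get_measure(res, "qaly_discounted", 20),
               get_measure(res, "qaly_undiscounted", 20), tolerance = 1e-12)
  expect_equal(get_measure(res, "cost_discounted", 20),
               get_measure(res, "cost_undiscounted", 20), tolerance = 1e-12)
  # and with discounting, discounted QALYs are strictly smaller
  res5 <- run_cohort("SLNB", base_params(), base_costs(), base_settings())
  expect_lt(get_measure(res5, "qaly_discounted", 20),
            get_measure(res5, "qaly_undiscounted", 20))
})

test_that("identical arms produce exactly zero differences", {
  sym <- symmetric_inputs()
  st <- base_settings()
  cmp <- compare(run_cohort("SLNB", sym$params, sym$costs, st),
                 run_cohort("ALND", sym$params, sym$costs, st))
  expect_true(all(abs(cmp$difference) < 1e-9))
  expect_true(all(attr(cmp, "classification") %in%
                    c("tie", "SLNB dominant", "ALND dominant")))
})

test_that("dominance classification covers all quadrants", {
  expect_equal(axstage:::classify_dominance(5, -100), "SLNB dominant")
  expect_equal(axstage:::classify_dominance(-5, 100), "ALND dominant")
  expect_equal(axstage:::classify_dominance(2, 100), "ICER = 50.00")
  expect_equal(axstage:::classify_dominance(0, 0), "tie")
})

test_that("incremental QALYs respond monotonically to the key drivers", {
  cs <- base_costs(); st <- base_settings()
  dq <- function(...) incremental(parameter_set(...), cs, st)$d_qaly_disc
  # more false negatives, worse recurrence after FN, more node positives:
  # SLNB advantage shrinks
  expect_true(all(diff(vapply(c(0.01, 0.055, 0.12, 0.2, 0.3),
                              function(x) dq(p_slnb_fn = x), numeric(1))) < 0))
  expect_true(all(diff(vapply(c(0.005, 0.016, 0.04, 0.0689),
                              function(x) dq(p_axillary_recur_given_fn = x),
                              numeric(1))) < 0))
  expect_true(all(diff(vapply(c(0.1, 0.269, 0.4, 0.6),
                              function(x) dq(p_node_positive = x), numeric(1))) < 0))
  # more lymphoedema after ALND, stronger aversion to it: SLNB advantage grows
  expect_true(all(diff(vapply(c(0.12, 0.176, 0.21, 0.25),
                              function(x) dq(p_lymph_alnd = x), numeric(1))) > 0))
  expect_true(all(diff(vapply(c(0, 0.01, 0.03, 0.05),
                              function(x) dq(lymphoedema_disutility = x),
                              numeric(1))) > 0))
})

test_that("comparing runs under different settings is refused", {
  p <- base_params(); cs <- base_costs()
  a <- run_cohort("SLNB", p, cs, base_settings())
  b <- run_cohort("ALND", p, cs, model_settings(discount_rate = 0))
  expect_error(compare(a, b), "different settings")
})
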