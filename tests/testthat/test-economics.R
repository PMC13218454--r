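test_that("targeted screening is the exact convex blend of the pure arms", {
  p <- base_params()
  none <- evaluate_strategy(p, "none")
  uni <- evaluate_strategy(p, "universal")

  for (f in c(0, 0.3, 1)) {
    pf <- p
    pf$settings$targeted_fraction <- f
    targ <- evaluate_strategy(pf, "targeted")
    expect_equal(targ$cost, f * uni$cost + (1 - f) * none$cost, tolerance = 1e-9)
    expect_equal(targ$qalys, f * uni$qalys + (1 - f) * none$qalys,
                 tolerance = 1e-9)
  }
})

test_that("strategy ordering holds under base parameters in both modes", {
  p <- base_params()
  for (mode in c("accumulated", "endpoint")) {
    fit <- ace_cua(p, mode = mode)
    q <- fit$table$qalys
    cost <- fit$table$cost
    names(q) <- names(cost) <- fit$table$strategy
    expect_lte(q[["none"]], q[["targeted"]])
    expect_lte(q[["targeted"]], q[["universal"]])
    expect_lte(cost[["none"]], cost[["targeted"]])
    expect_lte(cost[["targeted"]], cost[["universal"]])
    # QALY ceiling per accounting mode
    n <- p$settings$cohort_size
    ceiling <- if (mode == "accumulated") n * p$settings$horizon_years else n
    expect_true(all(q <= ceiling))
  }
})

test_that("per-cycle breakdowns reassemble the discounted totals", {
  p <- base_params()
  res <- evaluate_strategy(p, "universal")
  n <- p$settings$cohort_size
  pc <- res$breakdown$per_cycle
  expect_equal(nrow(pc), p$settings$horizon_years)
  expect_equal(n * sum(pc$discounted_qalys), res$qalys, tolerance = 1e-9)
  one_time <- res$breakdown$one_time_per_patient$total
  expect_equal(n * (one_time + sum(pc$discounted_cost)), res$cost,
               tolerance = 1e-9)
})

test_that("ICER handles identical strategies, dominance and mixed modes", {
  a <- strategy_result("none", 1000, 10)
  expect_true(is.na(icer(a, a)$icer))
  expect_equal(icer(a, a)$dominance, "neither")

  dominant <- icer(a, strategy_result("universal", 900, 11))
  expect_equal(dominant$dominance, "dominant")
  dominated <- icer(a, strategy_result("universal", 1100, 9))
  expect_equal(dominated$dominance, "dominated")
  ne <- icer(a, strategy_result("universal", 1100, 11))
  expect_equal(ne$dominance, "tradeoff_NE")
  expect_equal(ne$icer, 100)

  b <- strategy_result("universal", 2000, 12, mode = "endpoint")
  expect_error(icer(a, b), "accounting mode")
  c2 <- strategy_result("universal", 2000, 12, cohort_size = 1)
  expect_error(icer(a, c2), "cohort scale")
})

test_that("ICER is invariant to the cohort scale", {
  p <- base_params()
  fit_cohort <- ace_cua(p)
  p1 <- p
  p1$settings$cohort_size <- 1L
  fit_pp <- ace_cua(p1)
  expect_equal(fit_cohort$incrementals$universal$icer,
               fit_pp$incrementals$universal$icer, tolerance = 1e-9)
})

test_that("net monetary benefit is linear in the threshold and zero at the ICER", {
  inc <- icer(strategy_result("none", 0, 0), strategy_result("universal", 1173180, 4.11))
  expect_equal(net_monetary_benefit(inc, 160000), 160000 * 4.11 - 1173180)
  expect_equal(net_monetary_benefit(inc, 160000), -515580)
  expect_equal(net_monetary_benefit(inc, inc$icer), 0, tolerance = 1e-9)

  inc2 <- icer(strategy_result("none", 0, 0), strategy_result("targeted", 332700, 1.25))
  expect_equal(net_monetary_benefit(inc2, 266160), 0, tolerance = 1e-9)
  expect_error(net_monetary_benefit(inc, -1), "nonnegative")
})

test_that("willingness-to-pay verdicts cover band, bounds and dominance", {
  ref <- strategy_result("none", 10000, 10)
  make <- function(dc, dq) {
    icer(ref, strategy_result("universal", 10000 + dc, 10 + dq))
  }

  expect_equal(wtp_verdict(make(266160 * 1.25, 1.25), 160000, 200000),
               "not_cost_effective")
  expect_equal(wtp_verdict(make(150000, 1), 160000, 200000), "cost_effective")
  expect_equal(wtp_verdict(make(180000, 1), 160000, 200000), "borderline")
  expect_equal(wtp_verdict(make(-100, 1), 160000, 200000), "cost_effective")

  dominated <- icer(strategy_result("none", 100, 10),
                    strategy_result("universal", 200, 9))
  expect_equal(wtp_verdict(dominated, 160000, 200000), "not_cost_effective")
  # zero QALY difference at extra cost is weak dominance, not an error
  flat <- icer(strategy_result("none", 100, 10),
               strategy_result("universal", 200, 10))
  expect_equal(wtp_verdict(flat, 160000, 200000), "not_cost_effective")
  # identical strategies leave neither an ICER nor a dominance direction
  same <- icer(ref, ref)
  expect_error(wtp_verdict(same, 160000, 200000), "verdict")
  expect_error(wtp_verdict(make(100, 1), 200000, 160000), "exceeds")
})

test_that("the full comparison reports ICERs against the no-screening reference", {
  fit <- ace_cua(base_params())
  expect_equal(fit$reference, "none")
  expect_named(fit$incrementals, c("targeted", "universal"))
  expect_true(is.na(fit$table$icer_vs_reference[1]))
  expect_true(all(fit$table$icer_vs_reference[-1] > 0))
  df <- as.data.frame(fit)
  expect_equal(df$strategy, c("none", "targeted", "universal"))
  expect_output(summary(fit), "vs. 'none'")
})
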