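zero_transitions <- function() {
  list(background_mortality = 0, omg_to_generalized = 0, incident_omg = 0,
       incident_hypothyroid = 0, symptom_triggered_detection = 0)
}

test_that("transition matrix realizes the intended edge set", {
  m0 <- build_transition_matrix(zero_transitions())
  expect_equal(unname(m0), diag(7))

  tr <- zero_transitions()
  tr$background_mortality <- 1
  m1 <- build_transition_matrix(tr)
  for (s in setdiff(rownames(m1), "death")) expect_equal(m1[s, "death"], 1)

  tr <- zero_transitions()
  tr$background_mortality <- 0.01
  tr$omg_to_generalized <- 0.05
  m <- build_transition_matrix(tr)
  expect_equal(m["omg_early_dx", c("omg_early_dx", "generalized_mg", "death")],
               c(omg_early_dx = 0.94, generalized_mg = 0.05, death = 0.01))
  expect_equal(m["omg_delayed", c("omg_delayed", "generalized_mg", "death")],
               c(omg_delayed = 0.94, generalized_mg = 0.05, death = 0.01))
  expect_equal(unname(rowSums(m)), rep(1, 7), tolerance = 1e-12)
  expect_equal(unname(m["death", ]), c(0, 0, 0, 0, 0, 0, 1))  # absorbing

  tr$symptom_triggered_detection <- 0.99
  expect_error(build_transition_matrix(tr), "omg_delayed")
})

test_that("cohort projection conserves mass and matches closed forms", {
  p <- base_params()
  m <- build_transition_matrix(p$transitions)
  init <- acescreen:::initial_distribution(p, "universal")
  trace <- run_cohort(m, init, 10)
  expect_equal(unname(rowSums(trace)), rep(1, 11), tolerance = 1e-9)
  expect_true(all(trace >= 0))
  expect_true(all(diff(trace[, "death"]) >= -1e-15))  # absorption

  id <- run_cohort(diag(7), init, 5)
  for (k in 1:5) expect_equal(id[k + 1, ], id[1, ])

  # two-state toy with a closed form: alive -> death at 0.5/cycle
  toy <- matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE,
                dimnames = list(c("alive", "death"), c("alive", "death")))
  tt <- run_cohort(toy, c(alive = 1, death = 0), 2, cohort_size = 100)
  expect_equal(unname(tt[, "alive"]), c(100, 50, 25))
})

test_that("small chains match the exhaustive path-enumeration oracle", {
  set.seed(7)
  for (rep in 1:5) {
    raw <- matrix(runif(9), 3, 3)
    m <- raw / rowSums(raw)
    dimnames(m) <- list(letters[1:3], letters[1:3])
    init <- c(a = 0.5, b = 0.3, c = 0.2)
    trace <- run_cohort(m, init, 3)
    oracle <- enumerate_occupancy(m, init, 3)
    expect_equal(unclass(trace), oracle, tolerance = 1e-12)
  }
})

test_that("discount factors follow the annuity closed form", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(1, 0.03), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(0:20, 0), rep(1, 21))
  expect_equal(sum(discount_factor(1:10, 0.03)), (1 - 1.03^-10) / 0.03,
               tolerance = 1e-12)
  expect_equal(sum(discount_factor(1:10, 0.03)), 8.530203, tolerance = 1e-6)
  expect_error(discount_factor(1, -0.1), "nonnegative")
})

test_that("QALY accumulation hits the full-health ceilings in both modes", {
  full <- list(idiopathic_ace = 1, early_dx_omg = 1, delayed_dx_omg = 1,
               treated_hypothyroid = 1, missed_condition = 1,
               generalized_mg = 1, death = 0)
  m <- build_transition_matrix(zero_transitions())
  init <- stats::setNames(c(1, 0, 0, 0, 0, 0, 0), rownames(m))
  trace <- run_cohort(m, init, 10, cohort_size = 110)

  expect_equal(accumulate_qalys(trace, full, 0, "accumulated"), 1100)
  expect_equal(accumulate_qalys(trace, full, 0.03, "accumulated"),
               110 * 8.530203, tolerance = 1e-6)
  expect_equal(accumulate_qalys(trace, full, 0.03, "endpoint"), 110,
               tolerance = 1e-9)

  dark <- lapply(full, function(x) 0)
  expect_equal(accumulate_qalys(trace, dark, 0.03, "accumulated"), 0)

  colnames(trace)[1] <- "limbo"
  expect_error(accumulate_qalys(trace, full, 0.03), "limbo")
})

test_that("QALYs are monotone in utilities and in harmful transitions", {
  p <- base_params()
  res <- evaluate_strategy(p, "none")
  worse_u <- p
  worse_u$utilities$delayed_dx_omg <- p$utilities$delayed_dx_omg - 0.2
  worse_u$utilities$generalized_mg <- worse_u$utilities$delayed_dx_omg
  expect_lte(evaluate_strategy(worse_u, "none")$qalys, res$qalys)

  worse_t <- p
  worse_t$transitions$background_mortality <- 0.05  # more flow into death
  expect_lte(evaluate_strategy(worse_t, "none")$qalys, res$qalys)

  worse_g <- p
  worse_g$transitions$omg_to_generalized <- 0.2     # generalized u <= early u
  expect_lte(evaluate_strategy(worse_g, "universal")$qalys,
             evaluate_strategy(p, "universal")$qalys)
})

test_that("cost accumulation applies the follow-up window and discounting", {
  p <- base_params()
  m <- build_transition_matrix(zero_transitions())
  init <- stats::setNames(c(1, 0, 0, 0, 0, 0, 0), rownames(m))
  trace <- run_cohort(m, init, 10)

  # zero per-cycle costs: total is the one-time amount, undiscounted
  c0 <- p$costs
  c0$followup_visit <- 0
  expect_equal(accumulate_costs(trace, c0, 0.03, one_time = 1234), 1234)

  # six visits at 750 over the first three years, rate 0: 4,500 per patient
  expect_equal(accumulate_costs(trace, p$costs, 0, one_time = 0), 4500)

  # treatment costs follow the diagnosed-state occupancy
  ct <- p$costs
  ct$followup_visit <- 0
  ct$annual_treatment_mg <- 1000
  init_mg <- stats::setNames(c(0, 1, 0, 0, 0, 0, 0), rownames(m))
  tr_mg <- run_cohort(m, init_mg, 10)
  expect_equal(accumulate_costs(tr_mg, ct, 0, one_time = 0), 10000)

  bad <- p$costs
  bad$chest_ct <- -1
  expect_error(accumulate_costs(trace, bad, 0.03), "nonnegative")
})

test_that("MRI cost cancels exactly in the incremental comparison", {
  p <- base_params()
  inc1 <- icer(evaluate_strategy(p, "none"), evaluate_strategy(p, "universal"))
  p2 <- p
  p2$costs$mri_brain_orbit <- 0
  inc2 <- icer(evaluate_strategy(p2, "none"), evaluate_strategy(p2, "universal"))
  expect_equal(inc1$delta_cost, inc2$delta_cost, tolerance = 1e-9)
})
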