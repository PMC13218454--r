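test_that("outcome probabilities match hand arithmetic for both tests", {
  achr <- outcome_probabilities(0.027, 0.75, 0.98)
  expect_equal(as.numeric(achr), c(0.020250, 0.006750, 0.019460, 0.953540),
               tolerance = 1e-12, ignore_attr = TRUE)
  tft <- outcome_probabilities(0.009, 0.90, 0.92)
  expect_equal(as.numeric(tft), c(0.008100, 0.000900, 0.079280, 0.911720),
               tolerance = 1e-12, ignore_attr = TRUE)

  none <- outcome_probabilities(0, 0.75, 0.98)
  expect_equal(as.numeric(none), c(0, 0, 0.02, 0.98), ignore_attr = TRUE)
  perfect <- outcome_probabilities(0.027, 1, 1)
  expect_equal(as.numeric(perfect), c(0.027, 0, 0, 0.973), ignore_attr = TRUE)
})

test_that("outcome probabilities conserve mass and respect monotonicity", {
  set.seed(42)
  for (i in 1:200) {
    prev <- runif(1)
    se <- runif(1)
    sp <- runif(1)
    op <- outcome_probabilities(prev, se, sp)
    expect_lt(abs(sum(op) - 1), 1e-12)
    expect_equal(op[["tp"]] + op[["fn"]], prev, tolerance = 1e-12)
    expect_equal(op[["fp"]] + op[["tn"]], 1 - prev, tolerance = 1e-12)
    # tp nondecreasing in Se and prev; fp nonincreasing in Sp
    eps <- 0.01
    expect_gte(outcome_probabilities(prev, min(se + eps, 1), sp)[["tp"]], op[["tp"]])
    expect_gte(outcome_probabilities(min(prev + eps, 1), se, sp)[["tp"]], op[["tp"]])
    expect_lte(outcome_probabilities(prev, se, min(sp + eps, 1))[["fp"]], op[["fp"]])
  }
})

test_that("positive predictive value follows from the branch masses", {
  achr <- outcome_probabilities(0.027, 0.75, 0.98)
  expect_equal(positive_predictive_value(achr), 0.020250 / (0.020250 + 0.019460),
               tolerance = 1e-12)
  expect_equal(positive_predictive_value(outcome_probabilities(0.1, 0.8, 1)), 1.0)
  expect_error(positive_predictive_value(outcome_probabilities(0, 0.8, 1)),
               "undefined")
})

test_that("expected counts scale probabilities and match exhaustive enumeration", {
  achr <- outcome_probabilities(0.027, 0.75, 0.98)
  counts <- expected_pathway_counts(achr, 110)
  expect_equal(counts[["tp"]], 2.2275, tolerance = 1e-12)
  expect_equal(counts[["fp"]], 2.1406, tolerance = 1e-12)
  expect_equal(sum(counts), 110)
  expect_equal(sum(expected_pathway_counts(achr, 0)), 0)

  perfect <- outcome_probabilities(3 / 110, 1, 1)
  expect_equal(expected_pathway_counts(perfect, 110)[["tp"]], 3.0)

  # enumeration oracle: split an integer cohort into diseased/healthy and
  # enumerate the disease x result table directly
  n <- 110; cases <- 3; se <- 0.75; sp <- 0.98
  enum <- c(tp = cases * se, fn = cases * (1 - se),
            fp = (n - cases) * (1 - sp), tn = (n - cases) * sp)
  op <- outcome_probabilities(cases / n, se, sp)
  expect_equal(expected_pathway_counts(op, n), enum, tolerance = 1e-9)
})

test_that("screening costs assemble the published unit prices", {
  p <- base_params()
  uni <- screening_cost_per_patient(p, "universal")
  expect_equal(uni$tests, 1900 + 170 + 170 + 150)  # 2390 THB of assays
  expect_equal(uni$mri, 16000)
  none <- screening_cost_per_patient(p, "none")
  expect_equal(none$tests, 0)
  expect_equal(none$fp_workup, 0)
  expect_equal(none$mri, 16000)                     # MRI charged in every arm
  targ <- screening_cost_per_patient(p, "targeted")
  expect_equal(targ$tests, 0.3 * uni$tests)
  # follow-up block: six visits at 750 THB undiscounted
  expect_equal(p$costs$visits_per_patient * p$costs$followup_visit, 4500)
  expect_error(screening_cost_per_patient(p, "quarterly"))
})

test_that("pathway table conserves the cohort and assigns coherent states", {
  p <- base_params()
  tab <- pathway_table(p)
  for (strat in c("none", "targeted", "universal")) {
    for (tst in c("achr_ab", "tft")) {
      sub <- tab[tab$strategy == strat & tab$test == tst, ]
      expect_equal(sum(sub$expected_count), p$settings$cohort_size,
                   tolerance = 1e-9, info = paste(strat, tst))
      expect_equal(sum(sub$probability), 1, tolerance = 1e-12)
    }
  }
  uni <- tab[tab$strategy == "universal" & tab$test == "achr_ab", ]
  expect_equal(uni$initial_state[uni$outcome == "tp"], "omg_early_dx")
  expect_equal(uni$initial_state[uni$outcome == "fn"], "omg_delayed")
  expect_equal(uni$initial_state[uni$outcome == "fp"], "idiopathic_ace")
  expect_equal(uni$initial_state[uni$outcome == "tn"], "idiopathic_ace")
  # false positives carry the confirmatory workup on top of the assay price
  expect_equal(uni$one_time_cost[uni$outcome == "fp"] -
                 uni$one_time_cost[uni$outcome == "tn"],
               p$costs$chest_ct + 2 * p$costs$followup_visit)
  # no-screening arm: all diseased mass starts delayed/missed
  non <- tab[tab$strategy == "none" & tab$test == "achr_ab", ]
  expect_equal(non$probability[non$outcome == "fn"], p$prevalence$mg$value)
  expect_equal(non$probability[non$outcome == "tp"], 0)
})
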