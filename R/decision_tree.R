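# Decision-tree layer: diagnostic outcome probabilities per test, the
# initial Markov state each outcome feeds, and first-year pathway costs.

#' Diagnostic outcome probabilities
#'
#' Splits a screened population into true-positive, false-negative,
#' false-positive and true-negative mass from disease prevalence and test
#' sensitivity/specificity:
#' `tp = prev * Se`, `fn = prev * (1 - Se)`, `fp = (1 - prev) * (1 - Sp)`,
#' `tn = (1 - prev) * Sp`. The four probabilities always sum to 1.
#'
#' @param prev Disease prevalence in \[0, 1\].
#' @param sensitivity,specificity Test accuracy in \[0, 1\].
#' @return Named numeric vector `c(tp, fn, fp, tn)` of class
#'   `ace_outcome_probs`.
#' @export
#' @examples
#' outcome_probabilities(0.027, 0.75, 0.98)
outcome_probabilities <- function(prev, sensitivity, specificity) {
  prev <- as_probability(prev, "prev")
  se <- as_probability(sensitivity, "sensitivity")
  sp <- as_probability(specificity, "specificity")
  out <- c(tp = prev * se,
           fn = prev * (1 - se),
           fp = (1 - prev) * (1 - sp),
           tn = (1 - prev) * sp)
  stopifnot(abs(sum(out) - 1) < 1e-12)
  structure(out, class = c("ace_outcome_probs", "numeric"))
}

#' @export
print.ace_outcome_probs <- function(x, ...) {
  cat(sprintf("TP %.6f  FN %.6f  FP %.6f  TN %.6f\n", x["tp"], x["fn"], x["fp"], x["tn"]))
  invisible(x)
}

#' Positive predictive value
#'
#' @param op An `ace_outcome_probs` vector.
#' @return `tp / (tp + fp)`. Errors when no positive results are possible.
#' @export
positive_predictive_value <- function(op) {
  pos <- op[["tp"]] + op[["fp"]]
  if (pos <= 0) stop("positive predictive value undefined: tp + fp = 0", call. = FALSE)
  op[["tp"]] / pos
}

#' Expected diagnostic-outcome counts in a finite cohort
#'
#' @param op An `ace_outcome_probs` vector.
#' @param cohort_size Nonnegative cohort size.
#' @return Named numeric vector of expected counts; sums to `cohort_size`.
#' @export
expected_pathway_counts <- function(op, cohort_size) {
  check_nonneg(cohort_size, "cohort_size")
  counts <- as.numeric(op) * cohort_size
  names(counts) <- names(op)
  counts
}

# Shared screening-cost pieces -------------------------------------------

tft_panel_cost <- function(costs) costs$tsh + costs$ft3 + costs$ft4

# False positives resolve to idiopathic after a one-cycle confirmatory
# workup: chest CT plus two extra outpatient visits, no lasting disutility.
fp_workup_cost <- function(costs) costs$chest_ct + 2 * costs$followup_visit

#' Baseline screening cost per patient
#'
#' One-time year-0 diagnostic cost for a strategy. MRI of the brain and
#' orbit is performed for every esotropia patient regardless of strategy,
#' so it is charged in all arms (and cancels in incremental comparisons).
#' The universal arm adds the AChR-Ab assay and the full three-assay TFT
#' panel; the targeted arm applies the universal tests to the targeted
#' fraction of the cohort; the no-screening arm charges no test.
#' Expected false-positive confirmatory workup (chest CT + two visits) is
#' included in proportion to the false-positive mass of each test.
#'
#' @param params An `ace_parameters` object.
#' @param strategy One of `"none"`, `"targeted"`, `"universal"`.
#' @return A named list with components `tests`, `mri`, `fp_workup` and
#'   `total` (THB per patient, expected value).
#' @export
screening_cost_per_patient <- function(params, strategy) {
  strategy <- match.arg(strategy, ACE_STRATEGIES)
  costs <- params$costs
  f <- switch(strategy, none = 0, universal = 1, targeted = params$settings$targeted_fraction)
  tests <- f * (costs$achr_ab_test + tft_panel_cost(costs))
  op_achr <- outcome_probabilities(params$prevalence$mg$value,
                                   params$accuracy$achr_ab$sensitivity,
                                   params$accuracy$achr_ab$specificity)
  op_tft <- outcome_probabilities(params$prevalence$thyroid$value,
                                  params$accuracy$tft$sensitivity,
                                  params$accuracy$tft$specificity)
  fp_mass <- f * (op_achr[["fp"]] + op_tft[["fp"]])
  fp <- fp_mass * fp_workup_cost(costs)
  list(tests = tests, mri = costs$mri_brain_orbit, fp_workup = fp,
       total = tests + costs$mri_brain_orbit + fp)
}

#' Decision-tree pathway table
#'
#' One row per strategy x test x diagnostic outcome: branch probability,
#' expected patient count, one-time cost attached to the branch, and the
#' Markov state the branch feeds. True positives start in the treated
#' (early-diagnosis) state; false negatives in the delayed/missed state;
#' false positives resolve to idiopathic after the confirmatory workup;
#' true negatives are managed as idiopathic esotropia. In the no-screening
#' arm all diseased patients start delayed/missed.
#'
#' @param params An `ace_parameters` object.
#' @param strategies Character vector of strategy labels.
#' @return A data frame; expected counts within a strategy x test sum to
#'   the cohort size.
#' @export
pathway_table <- function(params, strategies = ACE_STRATEGIES) {
  params <- validate_parameters(params)
  n <- params$settings$cohort_size
  rows <- list()
  for (strat in strategies) {
    strat <- match.arg(strat, ACE_STRATEGIES)
    f <- switch(strat, none = 0, universal = 1, targeted = params$settings$targeted_fraction)
    for (test in c("achr_ab", "tft")) {
      prev <- if (test == "achr_ab") params$prevalence$mg$value else params$prevalence$thyroid$value
      acc <- params$accuracy[[test]]
      op_screen <- outcome_probabilities(prev, acc$sensitivity, acc$specificity)
      # unscreened patients: diseased -> missed, healthy -> idiopathic
      op_none <- c(tp = 0, fn = prev, fp = 0, tn = 1 - prev)
      op <- f * as.numeric(op_screen) + (1 - f) * op_none
      names(op) <- names(op_none)
      states <- if (test == "achr_ab") {
        c(tp = "omg_early_dx", fn = "omg_delayed", fp = "idiopathic_ace",
          tn = "idiopathic_ace")
      } else {
        c(tp = "hypothyroid_treated", fn = "hypothyroid_missed",
          fp = "idiopathic_ace", tn = "idiopathic_ace")
      }
      unit <- if (test == "achr_ab") params$costs$achr_ab_test else tft_panel_cost(params$costs)
      one_time <- c(tp = f * unit, fn = f * unit,
                    fp = f * unit + fp_workup_cost(params$costs), tn = f * unit)
      # fp row cost is conditional on being an fp among screened patients;
      # report expected per-branch cost on the branch's own mass
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strat, test = test, outcome = names(op),
        probability = unname(op),
        expected_count = unname(op) * n,
        one_time_cost = unname(one_time),
        initial_state = unname(states),
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Initial Markov distribution for a pure strategy, per patient.
# Diseases are mutually exclusive at the observed prevalences; the joint
# mass (~0.02%) is negligible and the tree has parallel branches.
initial_distribution <- function(params, strategy) {
  strategy <- match.arg(strategy, ACE_STRATEGIES)
  p_mg <- params$prevalence$mg$value
  p_thy <- params$prevalence$thyroid$value
  init <- stats::setNames(numeric(length(ACE_STATES)), ACE_STATES)
  if (strategy == "targeted") {
    f <- params$settings$targeted_fraction
    return(f * initial_distribution(params, "universal") +
             (1 - f) * initial_distribution(params, "none"))
  }
  if (strategy == "universal") {
    se_a <- params$accuracy$achr_ab$sensitivity
    se_t <- params$accuracy$tft$sensitivity
    init["omg_early_dx"] <- p_mg * se_a
    init["omg_delayed"] <- p_mg * (1 - se_a)
    init["hypothyroid_treated"] <- p_thy * se_t
    init["hypothyroid_missed"] <- p_thy * (1 - se_t)
  } else {
    init["omg_delayed"] <- p_mg
    init["hypothyroid_missed"] <- p_thy
  }
  init["idiopathic_ace"] <- 1 - p_mg - p_thy
  stopifnot(abs(sum(init) - 1) < 1e-12)
  init
}
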