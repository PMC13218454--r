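# Strategy evaluation and incremental economics: costs, QALYs, ICER, NMB,
# dominance, willingness-to-pay verdicts.

#' Construct a strategy result
#'
#' Container for the discounted totals of one strategy. Produced by
#' [evaluate_strategy()]; can also be built directly from published cohort
#' totals to feed [icer()].
#'
#' @param strategy Strategy label.
#' @param cost Total discounted cost (THB) for the cohort.
#' @param qalys Total discounted QALYs for the cohort.
#' @param mode Accounting mode label (`"accumulated"` or `"endpoint"`).
#' @param cohort_size Cohort the totals refer to.
#' @param trace Optional `ace_trace`.
#' @param breakdown Optional named list of cost/QALY components.
#' @return An `ace_strategy_result` object.
#' @export
strategy_result <- function(strategy, cost, qalys, mode = "accumulated",
                            cohort_size = 110, trace = NULL, breakdown = NULL) {
  check_nonneg(cost, "cost")
  check_nonneg(qalys, "qalys")
  structure(list(strategy = strategy, cost = cost, qalys = qalys, mode = mode,
                 cohort_size = cohort_size, trace = trace, breakdown = breakdown),
            class = "ace_strategy_result")
}

#' Evaluate one screening strategy
#'
#' Runs the decision tree (initial health-state assignment and one-time
#' costs) and the Markov cohort model (10-year annual cycles with
#' half-cycle correction and discounting in the base case) for one
#' strategy, returning discounted cohort totals.
#'
#' The targeted strategy is a proportional application of universal
#' screening: a fraction `settings$targeted_fraction` of the cohort follows
#' the universal pathway and the rest the no-screening pathway, so its
#' totals are exactly the convex blend of the two pure strategies.
#'
#' @param params An `ace_parameters` object.
#' @param strategy One of `"none"`, `"targeted"`, `"universal"`.
#' @param mode QALY accounting mode, see [accumulate_qalys()].
#' @return An `ace_strategy_result` with cohort-scale `cost` and `qalys`,
#'   the per-patient trace, and a cost breakdown.
#' @export
#' @examples
#' evaluate_strategy(default_parameters(), "universal")
evaluate_strategy <- function(params, strategy, mode = c("accumulated", "endpoint")) {
  mode <- match.arg(mode)
  strategy <- match.arg(strategy, ACE_STRATEGIES)
  params <- validate_parameters(params)
  evaluate_strategy_core(params, strategy, mode)
}

# Evaluation core without input validation; called repeatedly by the
# sensitivity suite where inputs are already validated/clipped.
evaluate_strategy_core <- function(params, strategy, mode) {
  n <- params$settings$cohort_size
  rate <- params$settings$discount_rate_annual
  horizon <- params$settings$horizon_years

  init <- initial_distribution(params, strategy)
  m <- build_transition_matrix(params$transitions)
  trace <- run_cohort(m, init, horizon)          # per-patient scale

  screen <- screening_cost_per_patient(params, strategy)
  cost_pp <- accumulate_costs(trace, params$costs, rate, one_time = screen$total)
  qaly_pp <- accumulate_qalys(trace, params$utilities, rate, mode)

  per_cycle <- data.frame(
    cycle = seq_len(horizon),
    discounted_qalys = qaly_cycle_vector(trace, params$utilities, rate),
    discounted_cost = cost_cycle_vector(trace, params$costs, rate)
  )
  strategy_result(
    strategy, cost = n * cost_pp, qalys = n * qaly_pp, mode = mode,
    cohort_size = n, trace = trace,
    breakdown = list(one_time_per_patient = screen,
                     cost_per_patient = cost_pp, qalys_per_patient = qaly_pp,
                     per_cycle = per_cycle)
  )
}

# (delta_cost, delta_qaly) of comparator vs reference on the cohort scale,
# minimal allocation; shared by DSA, PSA and the threshold grid.
incremental_pair_core <- function(params, mode, reference = "none",
                                  comparator = "universal") {
  ref <- evaluate_strategy_core(params, reference, mode)
  comp <- evaluate_strategy_core(params, comparator, mode)
  c(delta_cost = comp$cost - ref$cost, delta_qaly = comp$qalys - ref$qalys)
}

#' Incremental cost-effectiveness ratio
#'
#' Incremental comparison of a strategy against a reference:
#' `icer = (cost_comp - cost_ref) / (qalys_comp - qalys_ref)`, undefined
#' when the QALY difference is zero (dominance is then reported instead).
#' Dominance: `dominant` when the comparator costs no more and yields no
#' fewer QALYs (and differs), `dominated` for the reverse; otherwise a
#' `tradeoff_NE` (more costly, more effective) or `tradeoff_SW` quadrant
#' flag.
#'
#' @param ref Reference `ace_strategy_result` (conventionally no screening).
#' @param comp Comparator `ace_strategy_result`.
#' @return An `ace_incremental` object with `delta_cost`, `delta_qaly`,
#'   `icer`, `dominance`, and NMB evaluated at both configured WTP values
#'   when `wtp` is supplied.
#' @param wtp Optional numeric vector of willingness-to-pay thresholds at
#'   which to evaluate net monetary benefit.
#' @export
#' @examples
#' no_screen <- strategy_result("none", 1653500, 105.45)
#' targeted  <- strategy_result("targeted", 1986200, 106.70)
#' icer(no_screen, targeted)
icer <- function(ref, comp, wtp = NULL) {
  stopifnot(inherits(ref, "ace_strategy_result"), inherits(comp, "ace_strategy_result"))
  if (!identical(ref$mode, comp$mode)) {
    stop("cannot compare strategies evaluated under different accounting modes: ",
         ref$mode, " vs ", comp$mode, call. = FALSE)
  }
  if (!identical(ref$cohort_size, comp$cohort_size)) {
    stop("cannot compare strategies on different cohort scales", call. = FALSE)
  }
  dc <- comp$cost - ref$cost
  dq <- comp$qalys - ref$qalys
  dominance <- if (dc == 0 && dq == 0) "neither"
  else if (dc <= 0 && dq >= 0) "dominant"
  else if (dc >= 0 && dq <= 0) "dominated"
  else if (dc > 0) "tradeoff_NE" else "tradeoff_SW"
  ratio <- if (dq != 0) dc / dq else NA_real_
  out <- structure(list(reference = ref$strategy, comparator = comp$strategy,
                        delta_cost = dc, delta_qaly = dq, icer = ratio,
                        dominance = dominance, mode = ref$mode,
                        cohort_size = ref$cohort_size),
                   class = "ace_incremental")
  if (!is.null(wtp)) out$nmb <- stats::setNames(vapply(wtp, function(l)
    net_monetary_benefit(out, l), 0.0), format(wtp, scientific = FALSE, trim = TRUE))
  out
}

#' Net monetary benefit
#'
#' @param inc An `ace_incremental` object.
#' @param wtp Willingness-to-pay threshold (THB/QALY, >= 0).
#' @return `wtp * delta_qaly - delta_cost` (THB).
#' @export
net_monetary_benefit <- function(inc, wtp) {
  check_nonneg(wtp, "wtp")
  wtp * inc$delta_qaly - inc$delta_cost
}

#' Cost-effectiveness verdict against a willingness-to-pay band
#'
#' @param inc An `ace_incremental` object.
#' @param wtp_lower,wtp_upper Lower and upper thresholds (THB/QALY).
#' @return `"cost_effective"` (ICER below the band, or dominant),
#'   `"borderline"` (within the band), or `"not_cost_effective"` (above
#'   the band, or dominated).
#' @export
wtp_verdict <- function(inc, wtp_lower, wtp_upper) {
  if (wtp_lower > wtp_upper) stop("wtp_lower exceeds wtp_upper", call. = FALSE)
  if (inc$dominance == "dominant") return("cost_effective")
  if (inc$dominance == "dominated") return("not_cost_effective")
  if (is.na(inc$icer)) {
    stop("ICER undefined (zero QALY difference) and no dominance: no verdict",
         call. = FALSE)
  }
  # a southwest tradeoff (cheaper, less effective) is acceptable when the
  # savings per QALY forgone exceed the upper threshold
  if (inc$dominance == "tradeoff_SW") {
    return(if (inc$icer > wtp_upper) "cost_effective" else "not_cost_effective")
  }
  if (inc$icer < wtp_lower) "cost_effective"
  else if (inc$icer <= wtp_upper) "borderline"
  else "not_cost_effective"
}

#' Full cost-utility comparison of screening strategies
#'
#' The package's central evaluator: evaluates each requested strategy
#' through the decision tree and Markov engine, then forms incremental
#' comparisons of every active strategy against the no-screening reference
#' (the published comparator convention) with NMB at both configured WTP
#' thresholds and a verdict against the WTP band.
#'
#' @param params An `ace_parameters` object (default: the base case).
#' @param strategies Strategies to evaluate; the first is the reference.
#' @param mode QALY accounting mode, see [accumulate_qalys()].
#' @return An `ace_cua` object with components `results` (list of
#'   `ace_strategy_result`), `incrementals` (list of `ace_incremental`),
#'   `table` (summary data frame), `params`, `mode`.
#' @export
#' @examples
#' fit <- ace_cua(default_parameters())
#' summary(fit)
ace_cua <- function(params = default_parameters(),
                    strategies = c("none", "targeted", "universal"),
                    mode = c("accumulated", "endpoint")) {
  mode <- match.arg(mode)
  strategies <- match.arg(strategies, ACE_STRATEGIES, several.ok = TRUE)
  results <- lapply(strategies, function(s) evaluate_strategy(params, s, mode))
  names(results) <- strategies
  ref <- results[[1L]]
  wtp <- c(params$settings$wtp_lower, params$settings$wtp_upper)
  incrementals <- lapply(results[-1L], function(r) icer(ref, r, wtp = wtp))

  tab <- data.frame(
    strategy = strategies,
    qalys = vapply(results, function(r) r$qalys, 0.0),
    cost = vapply(results, function(r) r$cost, 0.0),
    icer_vs_reference = c(NA_real_,
                          vapply(incrementals, function(i) i$icer, 0.0)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(results = results, incrementals = incrementals, table = tab,
                 params = params, mode = mode, reference = strategies[1L]),
            class = "ace_cua")
}

#' @export
print.ace_strategy_result <- function(x, ...) {
  cat(sprintf("Strategy '%s' (%s mode, cohort %d): cost %s THB, %.4f QALYs\n",
              x$strategy, x$mode, x$cohort_size,
              fmt_thb(round(x$cost)), x$qalys))
  invisible(x)
}

#' @export
print.ace_incremental <- function(x, ...) {
  cat(sprintf("%s vs %s (%s mode):\n", x$comparator, x$reference, x$mode))
  cat(sprintf("  delta cost %s THB, delta QALYs %.4f\n",
              fmt_thb(round(x$delta_cost)), x$delta_qaly))
  if (is.na(x$icer)) cat("  ICER undefined; dominance:", x$dominance, "\n")
  else cat(sprintf("  ICER %s THB/QALY (%s)\n",
                   fmt_thb(round(x$icer)), x$dominance))
  if (!is.null(x$nmb)) {
    for (nm in names(x$nmb)) {
      cat(sprintf("  NMB at WTP %s: %s THB\n", nm,
                  fmt_thb(round(x$nmb[[nm]]))))
    }
  }
  invisible(x)
}

#' @export
print.ace_cua <- function(x, ...) {
  cat(sprintf("Cost-utility comparison (%s mode, %d-year horizon, %.0f%% discount)\n",
              x$mode, x$params$settings$horizon_years,
              100 * x$params$settings$discount_rate_annual))
  tab <- x$table
  tab$cost <- fmt_thb(round(tab$cost))
  tab$qalys <- sprintf("%.4f", tab$qalys)
  tab$icer_vs_reference <- ifelse(is.na(x$table$icer_vs_reference), "Reference",
                                  fmt_thb(round(x$table$icer_vs_reference)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ace_cua <- function(object, ...) {
  s <- object$params$settings
  cat(sprintf("Strategies vs. '%s' at WTP %s-%s THB/QALY:\n", object$reference,
              fmt_thb(s$wtp_lower), fmt_thb(s$wtp_upper)))
  print(object)
  for (inc in object$incrementals) {
    verdict <- wtp_verdict(inc, s$wtp_lower, s$wtp_upper)
    cat(sprintf("  %s: %s\n", inc$comparator, verdict))
  }
  invisible(object)
}

#' @export
as.data.frame.ace_cua <- function(x, ...) x$table

#' @export
plot.ace_cua <- function(x, ...) {
  tab <- x$table
  op <- graphics::par(mar = c(5, 4, 3, 4))
  on.exit(graphics::par(op))
  bp <- graphics::barplot(tab$qalys, names.arg = tab$strategy,
                          ylab = "Discounted QALYs (cohort)",
                          col = "steelblue",
                          ylim = c(0, max(tab$qalys) * 1.15),
                          main = "Cost and QALYs by strategy", ...)
  graphics::par(new = TRUE)
  graphics::plot(bp, tab$cost, type = "b", col = "firebrick", pch = 19,
                 axes = FALSE, xlab = "", ylab = "",
                 ylim = c(0, max(tab$cost) * 1.15))
  graphics::axis(4, col.axis = "firebrick")
  graphics::mtext("Total cost (THB)", side = 4, line = 2.5, col = "firebrick")
  invisible(x)
}
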