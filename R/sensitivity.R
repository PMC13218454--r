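# Sensitivity suite: one-way DSA with tornado ordering, probabilistic
# sensitivity analysis with beta/gamma draws, CEAC, and the two-way
# price-prevalence threshold grid.

clip01 <- function(x, name) {
  if (x < 0 || x > 1) {
    warning(sprintf("parameter '%s': value %.4f clipped to [0, 1]", name, x),
            call. = FALSE)
    x <- min(max(x, 0), 1)
  }
  x
}

# Prevalences perturbed away from their observed counts must drop the
# counts, otherwise validation would flag the value/count mismatch.
set_prevalence <- function(params, which, value) {
  params$prevalence[[which]] <- list(value = value, cases = NULL, cohort = NULL)
  params
}

# OMG utilities are carried as (early-diagnosis utility, delay decrement).
# Shifting the early utility moves both OMG states in lockstep (the
# decrement, not the absolute level, is the literature-anchored quantity);
# the decrement bar is the "utility loss from undiagnosed MG".
apply_u_omg_early <- function(params, value) {
  d <- mg_delay_decrement(params)
  e <- clip01(value, "u_omg_early")
  params$utilities$early_dx_omg <- e
  params$utilities$delayed_dx_omg <- clip01(e - d, "u_omg_delayed")
  params$utilities$generalized_mg <- params$utilities$delayed_dx_omg
  params
}

apply_mg_decrement <- function(params, value) {
  e <- params$utilities$early_dx_omg
  value <- min(max(value, 0), e)
  params$utilities$delayed_dx_omg <- e - value
  params$utilities$generalized_mg <- params$utilities$delayed_dx_omg
  params
}

# One-way DSA parameter registry: base value plus a setter producing a
# modified parameter set. The default `vary` list mirrors the bars of the
# published tornado (prevalences, unit costs, utilities); test accuracy is
# excluded by default because a +/-20% band around a 0.98 specificity is
# clinically implausible, but the accuracy entries can be requested
# explicitly through `vary`.
dsa_parameter_defs <- function(params) {
  u <- params$utilities
  c_ <- params$costs
  list(
    prevalence_mg = list(
      base = params$prevalence$mg$value,
      apply = function(p, v) set_prevalence(p, "mg", clip01(v, "prevalence_mg"))),
    prevalence_thyroid = list(
      base = params$prevalence$thyroid$value,
      apply = function(p, v) set_prevalence(p, "thyroid", clip01(v, "prevalence_thyroid"))),
    cost_achr_ab = list(
      base = c_$achr_ab_test,
      apply = function(p, v) { p$costs$achr_ab_test <- v; p }),
    cost_tft_panel = list(
      base = tft_panel_cost(c_),
      apply = function(p, v) {
        scale <- v / tft_panel_cost(p$costs)
        p$costs$tsh <- p$costs$tsh * scale
        p$costs$ft3 <- p$costs$ft3 * scale
        p$costs$ft4 <- p$costs$ft4 * scale
        p
      }),
    cost_chest_ct = list(
      base = c_$chest_ct,
      apply = function(p, v) { p$costs$chest_ct <- v; p }),
    cost_mri = list(
      base = c_$mri_brain_orbit,
      apply = function(p, v) { p$costs$mri_brain_orbit <- v; p }),
    cost_followup_visit = list(
      base = c_$followup_visit,
      apply = function(p, v) { p$costs$followup_visit <- v; p }),
    u_omg_early = list(base = u$early_dx_omg, apply = apply_u_omg_early),
    u_mg_delay_decrement = list(
      base = u$early_dx_omg - u$delayed_dx_omg, apply = apply_mg_decrement),
    u_hypothyroid = list(
      base = u$treated_hypothyroid,
      apply = function(p, v) {
        p$utilities$treated_hypothyroid <- clip01(v, "u_hypothyroid"); p
      }),
    u_idiopathic = list(
      base = u$idiopathic_ace,
      apply = function(p, v) {
        p$utilities$idiopathic_ace <- clip01(v, "u_idiopathic"); p
      }),
    sens_achr_ab = list(
      base = params$accuracy$achr_ab$sensitivity,
      apply = function(p, v) {
        p$accuracy$achr_ab$sensitivity <- clip01(v, "sens_achr_ab"); p
      }),
    spec_achr_ab = list(
      base = params$accuracy$achr_ab$specificity,
      apply = function(p, v) {
        p$accuracy$achr_ab$specificity <- clip01(v, "spec_achr_ab"); p
      }),
    sens_tft = list(
      base = params$accuracy$tft$sensitivity,
      apply = function(p, v) {
        p$accuracy$tft$sensitivity <- clip01(v, "sens_tft"); p
      }),
    spec_tft = list(
      base = params$accuracy$tft$specificity,
      apply = function(p, v) {
        p$accuracy$tft$specificity <- clip01(v, "spec_tft"); p
      })
  )
}

DSA_DEFAULT_VARY <- c("prevalence_mg", "prevalence_thyroid", "cost_achr_ab",
                      "cost_tft_panel", "cost_chest_ct", "cost_mri",
                      "cost_followup_visit", "u_omg_early",
                      "u_mg_delay_decrement", "u_hypothyroid", "u_idiopathic")

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Varies each parameter one at a time by +/- `settings$dsa_variation`
#' (20% in the base case) around its base value, re-evaluates the
#' comparator and reference strategies, and records the net monetary
#' benefit at the given willingness-to-pay threshold at both extremes.
#' Probabilities and utilities pushed outside \[0, 1\] are clipped with a
#' warning. Entries are returned sorted by descending swing
#' `|NMB_high - NMB_low|`, the tornado ordering.
#'
#' @param params An `ace_parameters` object.
#' @param vary Character vector of parameter names from the DSA registry
#'   (default: the published tornado set; see Details in the vignette).
#' @param wtp Willingness-to-pay threshold (default: `settings$wtp_lower`).
#' @param mode QALY accounting mode.
#' @param reference,comparator Strategy labels for the incremental pair.
#' @return An `ace_dsa` object: a data frame with columns `parameter`,
#'   `base`, `low`, `high`, `nmb_low`, `nmb_high`, `swing`, plus the
#'   base-case NMB as attribute `base_nmb`.
#' @export
#' @examples
#' dsa <- one_way_dsa(default_parameters())
#' head(dsa)
one_way_dsa <- function(params, vary = DSA_DEFAULT_VARY, wtp = NULL,
                        mode = c("accumulated", "endpoint"),
                        reference = "none", comparator = "universal") {
  mode <- match.arg(mode)
  params <- validate_parameters(params)
  if (is.null(wtp)) wtp <- params$settings$wtp_lower
  defs <- dsa_parameter_defs(params)
  unknown <- setdiff(vary, names(defs))
  if (length(unknown) > 0) {
    stop("unknown DSA parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  delta <- params$settings$dsa_variation
  nmb_at <- function(p) {
    inc <- incremental_pair_core(p, mode, reference, comparator)
    wtp * inc[["delta_qaly"]] - inc[["delta_cost"]]
  }
  base_nmb <- nmb_at(params)
  rows <- lapply(vary, function(nm) {
    def <- defs[[nm]]
    lo <- def$base * (1 - delta)
    hi <- def$base * (1 + delta)
    data.frame(parameter = nm, base = def$base, low = lo, high = hi,
               nmb_low = nmb_at(def$apply(params, lo)),
               nmb_high = nmb_at(def$apply(params, hi)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$swing <- abs(out$nmb_high - out$nmb_low)
  out <- out[order(-out$swing), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_nmb = base_nmb, wtp = wtp, mode = mode,
            class = c("ace_dsa", "data.frame"))
}

#' @export
plot.ace_dsa <- function(x, ...) {
  base_nmb <- attr(x, "base_nmb")
  n <- nrow(x)
  ord <- x[rev(seq_len(n)), ]          # widest bar on top
  op <- graphics::par(mar = c(5, 11, 3, 2))
  on.exit(graphics::par(op))
  xlim <- range(c(ord$nmb_low, ord$nmb_high, base_nmb))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = sprintf("Net monetary benefit at WTP %s (THB)",
                                fmt_thb(attr(x, "wtp"))),
                 ylab = "", main = "One-way sensitivity (tornado)", ...)
  graphics::axis(2, at = seq_len(n), labels = ord$parameter, las = 1, cex.axis = 0.8)
  for (i in seq_len(n)) {
    graphics::rect(min(ord$nmb_low[i], ord$nmb_high[i]), i - 0.35,
                   max(ord$nmb_low[i], ord$nmb_high[i]), i + 0.35,
                   col = "lightsteelblue", border = "grey30")
  }
  graphics::abline(v = base_nmb, lty = 2)
  invisible(x)
}

# Distribution parameterization -----------------------------------------

#' Beta distribution from a probability and effective sample size
#'
#' `alpha = p * n`, `beta = (1 - p) * n`: the mean is exactly `p` and `n`
#' acts as the weight of evidence behind the estimate (a sensitivity of
#' 0.75 with n = 100 gives alpha = 75, beta = 25).
#'
#' @param p Probability strictly inside (0, 1); the boundary values are
#'   degenerate and must be handled as point masses by the caller.
#' @param n Positive effective sample size.
#' @return List with `alpha` and `beta`.
#' @export
#' @examples
#' beta_from_pn(0.75, 100)
beta_from_pn <- function(p, n) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("p must lie strictly inside (0, 1); use a point mass for degenerate values",
         call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("n must be positive", call. = FALSE)
  }
  list(alpha = p * n, beta = (1 - p) * n)
}

#' Gamma distribution from a mean and standard deviation
#'
#' Shape `k = mu^2 / sigma^2`, scale `theta = sigma^2 / mu`, so the mean
#' `k * theta = mu` and variance `k * theta^2 = sigma^2` are recovered
#' exactly. The package default for cost parameters is `sigma = 0.2 * mu`
#' (20% coefficient of variation, consistent with the +/-20% DSA ranges).
#'
#' @param mu Positive mean (THB).
#' @param sigma Positive standard deviation (THB); default `0.2 * mu`.
#' @return List with `shape` and `scale`.
#' @export
#' @examples
#' gamma_from_mu_sigma(1900) # shape 25, scale 76
gamma_from_mu_sigma <- function(mu, sigma = 0.2 * mu) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) stop("mu must be positive", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  list(shape = mu^2 / sigma^2, scale = sigma^2 / mu)
}

# PSA stochastic-parameter registry. Probabilities and utilities are beta
# distributed (effective n = evidence cohort size where counts exist,
# otherwise 100); costs are gamma distributed with CV 20%. Parameters at a
# degenerate boundary (idiopathic utility 1.0, zero-valued treatment
# costs) stay fixed at their base value.
psa_parameter_defs <- function(params, beta_n = 100) {
  defs <- list()
  add_beta <- function(name, p, n, apply) {
    if (p <= 0 || p >= 1) return()      # point mass: not sampled
    spec <- beta_from_pn(p, n)
    defs[[name]] <<- list(type = "beta", alpha = spec$alpha, beta = spec$beta,
                          mean = p, sd = sqrt(spec$alpha * spec$beta /
                            ((n)^2 * (n + 1))), apply = apply)
  }
  add_gamma <- function(name, mu, apply) {
    if (mu <= 0) return()
    spec <- gamma_from_mu_sigma(mu)
    defs[[name]] <<- list(type = "gamma", shape = spec$shape, scale = spec$scale,
                          mean = mu, sd = 0.2 * mu, apply = apply)
  }
  pm <- params$prevalence$mg
  pt <- params$prevalence$thyroid
  add_beta("prevalence_mg", pm$value,
           if (!is.null(pm$cohort)) pm$cohort else beta_n,
           function(p, v) set_prevalence(p, "mg", v))
  add_beta("prevalence_thyroid", pt$value,
           if (!is.null(pt$cohort)) pt$cohort else beta_n,
           function(p, v) set_prevalence(p, "thyroid", v))
  add_beta("sens_achr_ab", params$accuracy$achr_ab$sensitivity, beta_n,
           function(p, v) { p$accuracy$achr_ab$sensitivity <- v; p })
  add_beta("spec_achr_ab", params$accuracy$achr_ab$specificity, beta_n,
           function(p, v) { p$accuracy$achr_ab$specificity <- v; p })
  add_beta("sens_tft", params$accuracy$tft$sensitivity, beta_n,
           function(p, v) { p$accuracy$tft$sensitivity <- v; p })
  add_beta("spec_tft", params$accuracy$tft$specificity, beta_n,
           function(p, v) { p$accuracy$tft$specificity <- v; p })
  add_beta("u_omg_early", params$utilities$early_dx_omg, beta_n, apply_u_omg_early)
  add_beta("u_mg_delay_decrement", mg_delay_decrement(params), beta_n,
           apply_mg_decrement)
  add_beta("u_hypothyroid", params$utilities$treated_hypothyroid, beta_n,
           function(p, v) { p$utilities$treated_hypothyroid <- v; p })
  add_beta("u_idiopathic", params$utilities$idiopathic_ace, beta_n,
           function(p, v) { p$utilities$idiopathic_ace <- v; p })
  add_gamma("cost_achr_ab", params$costs$achr_ab_test,
            function(p, v) { p$costs$achr_ab_test <- v; p })
  add_gamma("cost_tsh", params$costs$tsh, function(p, v) { p$costs$tsh <- v; p })
  add_gamma("cost_ft3", params$costs$ft3, function(p, v) { p$costs$ft3 <- v; p })
  add_gamma("cost_ft4", params$costs$ft4, function(p, v) { p$costs$ft4 <- v; p })
  add_gamma("cost_chest_ct", params$costs$chest_ct,
            function(p, v) { p$costs$chest_ct <- v; p })
  add_gamma("cost_mri", params$costs$mri_brain_orbit,
            function(p, v) { p$costs$mri_brain_orbit <- v; p })
  add_gamma("cost_followup_visit", params$costs$followup_visit,
            function(p, v) { p$costs$followup_visit <- v; p })
  defs
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of every stochastic model parameter:
#' probabilities and utilities from beta distributions parameterized as
#' `alpha = p n`, `beta = (1 - p) n`; costs from gamma distributions with
#' 20% coefficient of variation (see [beta_from_pn()],
#' [gamma_from_mu_sigma()]). Parameters are sampled independently (no
#' correlation structure is imposed). Each draw re-evaluates the
#' comparator and reference strategies and records the incremental cost
#' and QALY pair; results are fully reproducible from the seed.
#'
#' @param params An `ace_parameters` object.
#' @param draws Number of Monte-Carlo draws (default `settings$psa_draws`).
#' @param seed Integer RNG seed, recorded in the result.
#' @param mode QALY accounting mode.
#' @param reference,comparator Strategy labels for the incremental pair.
#' @return An `ace_psa` object: `draws` data frame (`delta_cost`,
#'   `delta_qaly`, `icer`), the parameter `samples` matrix, quadrant
#'   tallies, the base-case incremental, and the seed.
#' @export
#' @examples
#' psa <- run_psa(default_parameters(), draws = 200, seed = 1)
#' summary(psa)
run_psa <- function(params, draws = NULL, seed = 1,
                    mode = c("accumulated", "endpoint"),
                    reference = "none", comparator = "universal") {
  mode <- match.arg(mode)
  params <- validate_parameters(params)
  if (is.null(draws)) draws <- params$settings$psa_draws
  if (draws < 1) stop("draws must be >= 1", call. = FALSE)
  defs <- psa_parameter_defs(params)

  set.seed(seed)
  # one column of draws per parameter, sampled in registry order
  samples <- vapply(defs, function(d) {
    switch(d$type,
           beta = stats::rbeta(draws, d$alpha, d$beta),
           gamma = stats::rgamma(draws, shape = d$shape, scale = d$scale))
  }, numeric(draws))
  if (draws == 1L) samples <- matrix(samples, nrow = 1L,
                                     dimnames = list(NULL, names(defs)))

  dc <- numeric(draws)
  dq <- numeric(draws)
  for (i in seq_len(draws)) {
    p_i <- params
    for (j in seq_along(defs)) p_i <- defs[[j]]$apply(p_i, unname(samples[i, j]))
    inc <- incremental_pair_core(p_i, mode, reference, comparator)
    dc[i] <- inc[["delta_cost"]]
    dq[i] <- inc[["delta_qaly"]]
  }
  base_inc <- icer(evaluate_strategy_core(params, reference, mode),
                   evaluate_strategy_core(params, comparator, mode))
  draws_df <- data.frame(draw = seq_len(draws), delta_cost = dc, delta_qaly = dq,
                         icer = ifelse(dq != 0, dc / dq, NA_real_))
  quadrants <- c(
    NE = mean(dq > 0 & dc > 0), NW = mean(dq <= 0 & dc > 0),
    SE = mean(dq > 0 & dc <= 0), SW = mean(dq <= 0 & dc <= 0)
  )
  structure(list(draws = draws_df, samples = samples, seed = seed, mode = mode,
                 reference = reference, comparator = comparator,
                 base = base_inc, quadrants = quadrants,
                 wtp = c(params$settings$wtp_lower, params$settings$wtp_upper)),
            class = "ace_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with
#' positive net monetary benefit `wtp * delta_qaly - delta_cost > 0`.
#'
#' @param psa An `ace_psa` object.
#' @param lambda_grid Ascending vector of WTP values (THB/QALY); default
#'   0 to 500,000 in steps of 10,000.
#' @return Data frame with columns `wtp` and `probability`, of class
#'   `ace_ceac`.
#' @export
ceac <- function(psa, lambda_grid = seq(0, 500000, by = 10000)) {
  if (length(lambda_grid) == 0) stop("lambda_grid must be nonempty", call. = FALSE)
  prob <- vapply(lambda_grid, function(l) {
    mean(l * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
  }, 0.0)
  structure(data.frame(wtp = lambda_grid, probability = prob),
            class = c("ace_ceac", "data.frame"))
}

#' @export
print.ace_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d), %s vs %s, %s mode\n",
              nrow(x$draws), x$seed, x$comparator, x$reference, x$mode))
  cat(sprintf("  quadrants: NE %.1f%%, NW %.1f%%, SE %.1f%%, SW %.1f%%\n",
              100 * x$quadrants["NE"], 100 * x$quadrants["NW"],
              100 * x$quadrants["SE"], 100 * x$quadrants["SW"]))
  icers <- x$draws$icer[x$draws$delta_qaly > 0]
  if (length(icers) > 0) {
    cat(sprintf("  ICER (draws with QALY gain): mean %s, median %s THB/QALY\n",
                fmt_thb(round(mean(icers))),
                fmt_thb(round(stats::median(icers)))))
  }
  invisible(x)
}

#' @export
summary.ace_psa <- function(object, ...) {
  print(object)
  for (l in object$wtp) {
    p_ce <- mean(l * object$draws$delta_qaly - object$draws$delta_cost > 0)
    cat(sprintf("  P(cost-effective) at WTP %s: %.3f\n",
                fmt_thb(l), p_ce))
  }
  invisible(object)
}

#' @export
plot.ace_psa <- function(x, type = c("plane", "icer", "ceac"), ...) {
  type <- match.arg(type)
  d <- x$draws
  if (type == "plane") {
    graphics::plot(d$delta_qaly, d$delta_cost, pch = 16, cex = 0.4,
                   col = grDevices::adjustcolor("navy", 0.35),
                   xlab = "Incremental QALYs", ylab = "Incremental cost (THB)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey50")
    for (l in x$wtp) graphics::abline(0, l, lty = 2, col = "darkgreen")
  } else if (type == "icer") {
    icers <- d$icer[d$delta_qaly > 0]
    graphics::hist(icers, breaks = 50, col = "lightsteelblue",
                   xlab = "ICER (THB/QALY)", main = "ICER distribution", ...)
    graphics::abline(v = x$base$icer, lwd = 2, col = "navy")
    for (l in x$wtp) graphics::abline(v = l, lty = 2, col = "darkgreen")
  } else {
    cc <- ceac(x)
    graphics::plot(cc$wtp, cc$probability, type = "l", lwd = 2, ylim = c(0, 1),
                   xlab = "Willingness-to-pay (THB/QALY)",
                   ylab = "P(cost-effective)",
                   main = "Cost-effectiveness acceptability curve", ...)
    for (l in x$wtp) graphics::abline(v = l, lty = 2, col = "darkgreen")
  }
  invisible(x)
}

#' Two-way price-prevalence threshold analysis
#'
#' Recomputes the deterministic ICER of the comparator strategy against
#' the reference over a grid of AChR-Ab unit prices and MG prevalences,
#' and flags the cells where the ICER crosses the willingness-to-pay
#' threshold between grid neighbours (the cost-effectiveness frontier of
#' the contour plot).
#'
#' @param params An `ace_parameters` object.
#' @param price_grid Ascending AChR-Ab unit costs (THB); default 0-3,000
#'   by 100.
#' @param prev_grid Ascending MG prevalences; default 0.5%-10% by 0.25%.
#' @param wtp Willingness-to-pay threshold (default `settings$wtp_lower`).
#' @param mode QALY accounting mode.
#' @return An `ace_threshold` object: the ICER matrix (`price x prev`),
#'   the grids, a logical `cost_effective` matrix (`icer <= wtp`, or
#'   dominant), and the base-case cell.
#' @export
two_way_threshold <- function(params, price_grid = seq(0, 3000, by = 100),
                              prev_grid = seq(0.005, 0.10, by = 0.0025),
                              wtp = NULL, mode = c("accumulated", "endpoint")) {
  mode <- match.arg(mode)
  params <- validate_parameters(params)
  if (is.null(wtp)) wtp <- params$settings$wtp_lower
  if (length(price_grid) == 0 || length(prev_grid) == 0) {
    stop("grids must be nonempty", call. = FALSE)
  }
  if (is.unsorted(price_grid) || is.unsorted(prev_grid)) {
    stop("grids must be ascending", call. = FALSE)
  }
  icer_mat <- matrix(NA_real_, length(price_grid), length(prev_grid),
                     dimnames = list(price = price_grid, prevalence = prev_grid))
  ce_mat <- matrix(FALSE, length(price_grid), length(prev_grid),
                   dimnames = dimnames(icer_mat))
  for (j in seq_along(prev_grid)) {
    p_j <- set_prevalence(params, "mg", prev_grid[j])
    for (i in seq_along(price_grid)) {
      p_ij <- p_j
      p_ij$costs$achr_ab_test <- price_grid[i]
      inc <- incremental_pair_core(p_ij, mode)
      dq <- inc[["delta_qaly"]]
      dc <- inc[["delta_cost"]]
      icer_mat[i, j] <- if (dq != 0) dc / dq else NA_real_
      ce_mat[i, j] <- (dq > 0 && dc <= 0) || (dq > 0 && dc / dq <= wtp)
    }
  }
  boundary <- abs(diff(ce_mat)) > 0            # crossing along the price axis
  structure(list(icer = icer_mat, cost_effective = ce_mat,
                 price_grid = price_grid, prev_grid = prev_grid, wtp = wtp,
                 mode = mode, boundary = boundary,
                 base_cell = c(price = params$costs$achr_ab_test,
                               prevalence = params$prevalence$mg$value)),
            class = "ace_threshold")
}

#' @export
print.ace_threshold <- function(x, ...) {
  cat(sprintf("Two-way threshold grid: %d prices x %d prevalences, WTP %s THB/QALY\n",
              length(x$price_grid), length(x$prev_grid),
              fmt_thb(x$wtp)))
  cat(sprintf("  cost-effective cells: %.1f%%\n", 100 * mean(x$cost_effective)))
  base_ce <- x$cost_effective[
    which.min(abs(x$price_grid - x$base_cell["price"])),
    which.min(abs(x$prev_grid - x$base_cell["prevalence"]))]
  cat(sprintf("  base case (price %s, prevalence %.1f%%): %s\n",
              fmt_thb(x$base_cell[["price"]]),
              100 * x$base_cell[["prevalence"]],
              if (base_ce) "cost-effective" else "not cost-effective"))
  invisible(x)
}

#' @export
plot.ace_threshold <- function(x, ...) {
  graphics::image(x$price_grid, 100 * x$prev_grid, 1 - x$cost_effective,
                  col = c("darkseagreen2", "lightcoral"),
                  xlab = "AChR-Ab test price (THB)", ylab = "MG prevalence (%)",
                  main = "Price-prevalence threshold", ...)
  graphics::contour(x$price_grid, 100 * x$prev_grid, x$icer, levels = x$wtp,
                    add = TRUE, lty = 2, lwd = 2, drawlabels = FALSE)
  graphics::points(x$base_cell[["price"]], 100 * x$base_cell[["prevalence"]],
                   pch = 19, col = "blue", cex = 1.3)
  invisible(x)
}
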