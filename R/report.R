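# Report bundles: plain-text tables, delimited data files, figures, and a
# run manifest so every emitted number is traceable and reproducible.

run_manifest <- function(command, params_path = NULL, seed = NULL, mode = NULL) {
  list(
    command = command,
    parameter_digest = if (!is.null(params_path) && file.exists(params_path)) {
      unname(tools::md5sum(params_path))
    } else NA_character_,
    seed = seed,
    mode = mode,
    package_version = as.character(utils::packageVersion("acescreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

write_manifest <- function(manifest, out_dir) {
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Base-case report bundle
#'
#' Evaluates all three strategies under both QALY accounting modes, writes
#' the strategy table (discounted QALYs, total cost, ICER vs. the
#' no-screening reference), the decision-tree pathway table, and the
#' willingness-to-pay verdict lines, together with a run manifest.
#'
#' @param params An `ace_parameters` object.
#' @param out_dir Output directory (created if needed).
#' @param params_path Optional path of the parameter file used, for the
#'   manifest digest.
#' @return Invisibly, a list with both `ace_cua` fits and the manifest.
#' @export
run_base_case <- function(params = default_parameters(), out_dir,
                          params_path = NULL) {
  params <- validate_parameters(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- lapply(c(accumulated = "accumulated", endpoint = "endpoint"),
                 function(m) ace_cua(params, mode = m))
  s <- params$settings

  for (m in names(fits)) {
    tab <- fits[[m]]$table
    names(tab)[names(tab) == "icer_vs_reference"] <- "icer_vs_no_screening"
    write_tsv(tab, file.path(out_dir, sprintf("strategy_table_%s.tsv", m)))
  }
  write_tsv(pathway_table(params), file.path(out_dir, "pathway_table.tsv"))

  # per-patient occupancy trace per strategy with discounted per-cycle
  # cost/QALY columns (accumulated accounting; cycle 0 is the initial state)
  for (res in fits$accumulated$results) {
    trace_df <- data.frame(cycle = 0:(nrow(res$trace) - 1L),
                           unclass(res$trace), check.names = FALSE)
    pc <- res$breakdown$per_cycle
    trace_df$discounted_qalys <- c(NA, pc$discounted_qalys)
    trace_df$discounted_cost <- c(NA, pc$discounted_cost)
    write_tsv(trace_df, file.path(out_dir, sprintf("trace_%s.tsv", res$strategy)))
  }

  lines <- c(sprintf("Comparator convention: vs. no routine screening (WTP %s-%s THB/QALY)",
                     fmt_thb(s$wtp_lower),
                     fmt_thb(s$wtp_upper)))
  for (m in names(fits)) {
    for (inc in fits[[m]]$incrementals) {
      lines <- c(lines, sprintf(
        "[%s] %s: delta cost %s THB, delta QALYs %.4f, ICER %s THB/QALY -> %s",
        m, inc$comparator, fmt_thb(round(inc$delta_cost)),
        inc$delta_qaly,
        if (is.na(inc$icer)) "undefined" else fmt_thb(round(inc$icer)),
        wtp_verdict(inc, s$wtp_lower, s$wtp_upper)))
    }
  }
  writeLines(lines, file.path(out_dir, "verdicts.txt"))

  manifest <- run_manifest("run_base_case", params_path, mode = "both")
  write_manifest(manifest, out_dir)
  invisible(list(fits = fits, manifest = manifest))
}

#' Full analysis report bundle
#'
#' Base case plus the one-way tornado, the probabilistic sensitivity
#' analysis (cost-effectiveness plane, ICER histogram, CEAC) and the
#' two-way price-prevalence threshold grid. Numeric outputs are written as
#' delimited text, figures as PNG, and everything is stamped with a
#' manifest carrying the seed so a rerun reproduces the bundle exactly.
#'
#' @param params An `ace_parameters` object.
#' @param seed Integer seed for the PSA.
#' @param out_dir Output directory (created if needed).
#' @param psa_draws Number of PSA draws (default `settings$psa_draws`).
#' @param params_path Optional parameter-file path for the manifest digest.
#' @param mode QALY accounting mode for the sensitivity analyses.
#' @return Invisibly, a list with all result objects and the manifest.
#' @export
run_full_suite <- function(params = default_parameters(), seed = 1, out_dir,
                           psa_draws = NULL, params_path = NULL,
                           mode = "accumulated") {
  params <- validate_parameters(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- run_base_case(params, out_dir, params_path)

  dsa <- one_way_dsa(params, mode = mode)
  write_tsv(as.data.frame(dsa), file.path(out_dir, "tornado.tsv"))

  psa <- run_psa(params, draws = psa_draws, seed = seed, mode = mode)
  write_tsv(psa$draws, file.path(out_dir, "psa_draws.tsv"))
  cc <- ceac(psa)
  write_tsv(as.data.frame(cc), file.path(out_dir, "ceac.tsv"))

  thr <- two_way_threshold(params, mode = mode)
  thr_df <- data.frame(
    price = rep(thr$price_grid, times = length(thr$prev_grid)),
    prevalence = rep(thr$prev_grid, each = length(thr$price_grid)),
    icer = as.vector(thr$icer),
    cost_effective = as.vector(thr$cost_effective)
  )
  write_tsv(thr_df, file.path(out_dir, "threshold_grid.tsv"))

  s <- params$settings
  share_above <- vapply(c(s$wtp_lower, s$wtp_upper), function(l) {
    mean(psa$draws$icer > l & psa$draws$delta_qaly > 0, na.rm = TRUE)
  }, 0.0)
  writeLines(c(
    sprintf("PSA quadrant shares: NE %.3f, NW %.3f, SE %.3f, SW %.3f",
            psa$quadrants["NE"], psa$quadrants["NW"],
            psa$quadrants["SE"], psa$quadrants["SW"]),
    sprintf("Share of QALY-gaining draws with ICER above WTP %s: %.3f",
            fmt_thb(c(s$wtp_lower, s$wtp_upper)), share_above),
    sprintf("Threshold base-case cell: price %s THB, prevalence %.1f%%",
            fmt_thb(params$costs$achr_ab_test),
            100 * params$prevalence$mg$value)
  ), file.path(out_dir, "psa_summary.txt"))

  figures <- list(
    tornado = function() plot(dsa),
    ce_plane = function() plot(psa, type = "plane"),
    icer_hist = function() plot(psa, type = "icer"),
    ceac = function() plot(psa, type = "ceac"),
    threshold = function() plot(thr)
  )
  for (nm in names(figures)) {
    grDevices::png(file.path(out_dir, paste0(nm, ".png")), width = 900,
                   height = 650, res = 110)
    tryCatch(figures[[nm]](), finally = grDevices::dev.off())
  }

  manifest <- run_manifest("run_full_suite", params_path, seed = seed, mode = mode)
  write_manifest(manifest, out_dir)
  invisible(list(base = base, dsa = dsa, psa = psa, ceac = cc, threshold = thr,
                 manifest = manifest))
}
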