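# Command-line style driver: one call that reads the inputs, assesses, and
# optionally repairs, writing the assessment TSV, per-assay detail TSVs, the
# repaired libraries and summary plots. The exec/speclibqc script is a thin
# wrapper over run_qc().

#' Run configuration for the QC driver
#'
#' @param library_path Transition-list library file.
#' @param dialect Optional dialect override (auto-detected when NULL).
#' @param swath_path Optional SWATH definition file.
#' @param proteome_path Optional protein FASTA for completeness criteria.
#' @param mass_correct Rewrite fragment m/z to theoretical values.
#' @param filter_conflicts Segregate conflict assays (requires `swath_path`).
#' @param out_dir Output directory (created if absent).
#' @param tol_fragment,tol_precursor Mass-error tolerances (Da).
#' @param plots Render summary plots.
#' @return A `run_config` list.
#' @export
run_config <- function(library_path, dialect = NULL, swath_path = NULL,
                       proteome_path = NULL, mass_correct = FALSE,
                       filter_conflicts = FALSE, out_dir = ".",
                       tol_fragment = 0.01, tol_precursor = 0.01,
                       plots = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

.exit_codes <- c(success = 0L, usage = 2L, format = 3L, empty_input = 4L)

#' Assess (and optionally repair) a library end to end
#'
#' Always writes `assessment_report.tsv` (62 rows) and, when problem or
#' conflict assays exist, per-assay detail TSVs. With repair flags set it
#' writes `<stem>_mz_corrected.tsv`, `<stem>_clean.tsv` and
#' `<stem>_problem.tsv` in the input dialect, plus a line-oriented
#' `repair_log.tsv` so every edit and removal is auditable.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `status` (0 on success, 2 usage error,
#'   3 format error, 4 empty input), `report`, and `paths` of artifacts
#'   written.
#' @export
run_qc <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$filter_conflicts && is.null(cfg$swath_path)) {
    message("usage error: --filter-conflicts requires --swath")
    return(invisible(list(status = .exit_codes[["usage"]], paths = NULL)))
  }
  if (!file.exists(cfg$library_path)) {
    message("usage error: library file not found: ", cfg$library_path)
    return(invisible(list(status = .exit_codes[["usage"]], paths = NULL)))
  }
  lib <- tryCatch(read_library(cfg$library_path, cfg$dialect),
                  error = function(e) e)
  if (inherits(lib, "error")) {
    message("format error: ", conditionMessage(lib))
    code <- if (grepl("empty library", conditionMessage(lib)))
      "empty_input" else "format"
    return(invisible(list(status = .exit_codes[[code]], paths = NULL)))
  }
  scheme <- if (!is.null(cfg$swath_path)) read_swath_scheme(cfg$swath_path)
  proteome <- if (!is.null(cfg$proteome_path))
    build_proteome_index(cfg$proteome_path)
  params <- assess_params(tol_fragment = cfg$tol_fragment,
                          tol_precursor = cfg$tol_precursor)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  target <- lib
  stem <- sub("\\.(tsv|txt|csv)$", "", basename(cfg$library_path))
  log <- .empty_change_log()
  if (cfg$mass_correct) {
    target <- correct_masses(target, scope = "fragments", params = params)
    log <- rbind(log, attr(target, "change_log"))
    p <- file.path(cfg$out_dir, paste0(stem, "_mz_corrected.tsv"))
    write_library(target, p)
    paths <- c(paths, p)
  }
  if (cfg$filter_conflicts) {
    fc <- filter_conflicts(target, scheme)
    log <- rbind(log, fc$change_log)
    p1 <- file.path(cfg$out_dir, paste0(stem, "_clean.tsv"))
    p2 <- file.path(cfg$out_dir, paste0(stem, "_problem.tsv"))
    write_library(fc$clean_library, p1)
    if (nrow(fc$problem_library$assays) > 0) write_library(fc$problem_library, p2)
    else writeLines(character(0), p2)
    paths <- c(paths, p1, p2)
    target <- fc$clean_library
  }

  report <- assess(target, scheme = scheme, proteome = proteome,
                   params = params)
  rp <- file.path(cfg$out_dir, "assessment_report.tsv")
  write_report(report, rp)
  paths <- c(paths, rp)

  dm <- report$details$delta_mass
  problem_ids <- union(dm$mass_error_assay_ids, dm$unverifiable_assay_ids)
  if (length(problem_ids) > 0) {
    pp <- file.path(cfg$out_dir, "problem_assays.tsv")
    utils::write.table(
      target$assays[target$assays$assay_id %in% problem_ids,
                    c("assay_id", "modified_sequence", "precursor_charge")],
      pp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pp)
  }
  if (cfg$mass_correct || cfg$filter_conflicts) {
    lp <- file.path(cfg$out_dir, "repair_log.tsv")
    utils::write.table(log, lp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, lp)
  }
  if (cfg$plots) {
    paths <- c(paths, render_plots(report, cfg$out_dir))
  }
  invisible(list(status = .exit_codes[["success"]], report = report,
                 paths = paths))
}

#' Render graphical summary plots
#'
#' Writes up to four PNG files: precursor charge distribution, fragments per
#' precursor, fragment delta-mass histogram, and the 2+/3+ RT-fit scatter
#' (skipped when the RT fit was not evaluated).
#'
#' @param report An `assessment_report` from [assess()].
#' @param outdir Output directory.
#' @return Character vector of files written.
#' @export
render_plots <- function(report, outdir) {
  stopifnot(inherits(report, "assessment_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  crit <- report$criteria
  val <- function(id) crit$value[match(id, crit$id)]

  p <- file.path(outdir, "charge_distribution.png")
  grDevices::png(p, width = 600, height = 450)
  graphics::barplot(
    c(`1+` = val("pct_charge_1"), `2+` = val("pct_charge_2"),
      `3+` = val("pct_charge_3"), `4+` = val("pct_charge_4"),
      `>=5+` = val("pct_charge_ge5")),
    ylab = "% of assays", main = "Precursor charge distribution")
  grDevices::dev.off()
  written <- c(written, p)

  p <- file.path(outdir, "fragments_per_precursor.png")
  grDevices::png(p, width = 600, height = 450)
  graphics::barplot(
    c(min = val("fragments_per_precursor_min"),
      mean = val("fragments_per_precursor_mean"),
      max = val("fragments_per_precursor_max")),
    ylab = "fragments", main = "Fragments per precursor")
  grDevices::dev.off()
  written <- c(written, p)

  deltas <- report$details$delta_mass$fragment_deltas
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) > 0) {
    p <- file.path(outdir, "delta_mass_histogram.png")
    grDevices::png(p, width = 600, height = 450)
    graphics::hist(deltas, breaks = 50, xlab = "library - theoretical (Da)",
                   main = "Fragment delta mass")
    grDevices::dev.off()
    written <- c(written, p)
  }

  rt <- report$details$rt_fit
  if (isTRUE(rt$evaluated)) {
    p <- file.path(outdir, "rt_fit.png")
    grDevices::png(p, width = 600, height = 450)
    graphics::plot(rt$rt2, rt$rt3, xlab = "RT at 2+", ylab = "RT at 3+",
                   main = sprintf("RT fit: R-squared = %.4f", rt$r_squared))
    graphics::abline(rt$intercept, rt$slope, col = "red")
    grDevices::dev.off()
    written <- c(written, p)
  }
  written
}
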