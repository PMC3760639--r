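# End-to-end orchestration: simulate both study types, run both pipelines,
# write every output plus a manifest. With a fixed seed the run is
# bit-identical across invocations (no timestamps in any output).

#' Run the full simulate-analyze-summarize workflow
#'
#' Generates a ground-truth table, a two-channel slide set and a
#' single-channel expression study from `config`, writes the inputs, runs the
#' miRNA and mRNA pipelines, and writes all result files plus a JSON manifest
#' recording the parameter set and every written path.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param detect_multiplier,min_slides,lowess_span,lowess_iterations,fc_threshold,top_n
#'   passed to [run_mirna_pipeline()].
#' @param top_fraction,scale_target passed to [run_mrna_pipeline()].
#' @return (invisibly) a list: `manifest` (relative paths of every written
#'   file), `mirna`, `mrna`, `truth`.
#' @export
run_full <- function(config = sim_config(), out_dir,
                     detect_multiplier = 3, min_slides = NULL,
                     lowess_span = 0.3, lowess_iterations = 1L,
                     fc_threshold = 2, top_n = 10L,
                     top_fraction = 0.25, scale_target = 100) {
  stopifnot(inherits(config, "sim_config"))
  for (d in file.path(out_dir, c("input", "mirna", "mrna"))) {
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  }
  paths <- character()

  truth <- generate_truth(config)
  slides <- simulate_two_channel_slides(truth, config)
  study <- simulate_expression_study(truth, config)

  p <- file.path(out_dir, "input", "truth.tsv")
  write_truth_table(truth, p); paths <- c(paths, p)
  p <- file.path(out_dir, "input", "slides.tsv")
  write_slide_set(slides, p); paths <- c(paths, p)
  trio <- file.path(out_dir, "input",
                    c("signals.tsv", "calls.tsv", "groups.tsv"))
  write_expression_study(study, trio[1], trio[2], trio[3])
  paths <- c(paths, trio)

  mirna <- run_mirna_pipeline(
    slides, detect_multiplier = detect_multiplier, min_slides = min_slides,
    lowess_span = lowess_span, lowess_iterations = lowess_iterations,
    fc_threshold = fc_threshold, top_n = top_n
  )
  paths <- c(paths, write_results(
    file.path(out_dir, "mirna"),
    venn = mirna$venn,
    ratios = mirna$ratio_table,
    sets = list(detected_exosome = mirna$detected$exosome,
                detected_cell = mirna$detected$cell,
                top_enriched = mirna$top_enriched),
    summary = list(fc_threshold = fc_threshold,
                   detect_multiplier = detect_multiplier)
  ))

  mrna <- run_mrna_pipeline(study, top_fraction = top_fraction,
                            scale_target = scale_target)
  paths <- c(paths, write_results(
    file.path(out_dir, "mrna"),
    sets = list(detected_exosome = mrna$detected$exosome,
                detected_cell = mrna$detected$cell,
                unique_exosome = mrna$unique$exosome,
                unique_cell = mrna$unique$cell),
    summary = c(unclass(mrna$summary),
                list(top_fraction = top_fraction, scale_target = scale_target))
  ))

  root <- normalizePath(out_dir)
  rel <- sort(substring(normalizePath(paths), nchar(root) + 2L))
  manifest <- list(
    parameters = c(unclass(config),
                   list(detect_multiplier = detect_multiplier,
                        min_slides = min_slides,
                        lowess_span = lowess_span,
                        lowess_iterations = lowess_iterations,
                        fc_threshold = fc_threshold, top_n = top_n,
                        top_fraction = top_fraction,
                        scale_target = scale_target)),
    files = rel
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(manifest = c(rel, "manifest.json"), mirna = mirna,
                 mrna = mrna, truth = truth))
}
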