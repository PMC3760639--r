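# Packaged fixture of the profiled study's printed summary counts, and the
# desk-scale recomputation of its derived worked examples.

#' Reported summary counts of the profiled exosome study
#'
#' The printed totals of the HMC-1 exosome RNA-cargo profiling experiment the
#' pipelines emulate: miRNA Venn totals, mRNA detected counts, and the ranked
#' top-ten exosome-enriched miRNA identifiers. Each value carries a short
#' description of what was reported.
#'
#' @return named list; each element has `value` and `source`.
#' @export
reported_counts <- function() {
  path <- system.file("extdata", "reported_counts.json", package = "exocargo")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Recompute the study's derived worked examples from its printed totals
#'
#' Builds membership sets sized to the reported totals (exosome 116, cell 134,
#' overlap 89; mRNA 1,849 and 12,346), pushes them through [build_venn()] and
#' [detected_summary()], and compares every derived quantity with its reported
#' value: exosome-only and cell-only miRNA counts, the detected-set union, and
#' the exosomal percentage of the cellular mRNA content.
#'
#' @return data.frame with columns `quantity`, `recomputed`, `reported`,
#'   `match`.
#' @export
#' @examples
#' check_reported_counts()
check_reported_counts <- function() {
  rc <- reported_counts()
  shared_ids <- sprintf("shared_%03d", seq_len(rc$mirna_shared$value))
  exo_ids <- c(shared_ids,
               sprintf("exo_%03d",
                       seq_len(rc$mirna_exo_total$value - rc$mirna_shared$value)))
  cell_ids <- c(shared_ids,
                sprintf("cell_%03d",
                        seq_len(rc$mirna_cell_total$value - rc$mirna_shared$value)))
  venn <- build_venn(exo_ids, cell_ids)
  msum <- detected_summary(
    sprintf("mrna_e_%05d", seq_len(rc$mrna_exo_detected$value)),
    sprintf("mrna_c_%05d", seq_len(rc$mrna_cell_detected$value))
  )
  report <- data.frame(
    quantity = c("mirna_exo_only", "mirna_cell_only", "mirna_union",
                 "mrna_detected_percent"),
    recomputed = c(venn$exo_only, venn$cell_only, venn$union_size,
                   msum$detected_percent),
    reported = c(rc$mirna_exo_only$value, rc$mirna_cell_only$value,
                 rc$mirna_exo_total$value + rc$mirna_cell_total$value -
                   rc$mirna_shared$value,
                 rc$mrna_detected_percent$value),
    stringsAsFactors = FALSE
  )
  report$match <- report$recomputed == report$reported
  report
}
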