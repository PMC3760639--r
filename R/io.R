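# Readers and writers for the flat tabular formats the pipelines consume and
# produce. One on-disk dialect for inputs: tab-delimited text with a header
# row (the shape of ImaGene-style quantification exports and flat expression
# matrices). Result tables are comma-delimited; summaries are JSON.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read a quantified two-channel slide table
#'
#' @param path tab-delimited file with header columns `probe_id`, `slide`,
#'   `replicate`, `hy3_fg`, `hy3_bg`, `hy5_fg`, `hy5_bg`.
#' @return a `slide_set` data.frame; rejects (never silently drops) rows with
#'   missing columns, duplicate spot triples, or negative/non-numeric signals.
#' @export
read_slide_set <- function(path) {
  as_slide_set(read_tsv_checked(path))
}

#' Write a slide set as tab-delimited text
#' @param x a `slide_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_slide_set <- function(x, path) {
  x <- as_slide_set(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a ground-truth table
#' @param path tab-delimited file.
#' @return `read_truth_table`: the truth data.frame.
#' @export
read_truth_table <- function(path) {
  x <- read_tsv_checked(path)
  missing_cols <- setdiff(truth_columns, names(x))
  if (length(missing_cols) > 0L) {
    stop_parse("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(x$probe_id)) {
    stop_parse("duplicated probe_id in truth table: ",
               x$probe_id[duplicated(x$probe_id)][1])
  }
  x[truth_columns]
}

#' @rdname read_truth_table
#' @param x a truth table.
#' @export
write_truth_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single-channel expression study from its three files
#'
#' @param signals_path tab-delimited matrix of signals; first column
#'   `probe_id`, remaining columns one per sample.
#' @param calls_path matching matrix of P/M/A calls, same layout and labels.
#' @param groups_path two-column table `sample`, `group`.
#' @return an [expression_study()]. Label mismatches raise an alignment error
#'   listing the symmetric difference; call values outside P/M/A raise a
#'   parse error.
#' @export
read_expression_study <- function(signals_path, calls_path, groups_path) {
  sig <- read_tsv_checked(signals_path)
  cal <- read_tsv_checked(calls_path)
  grp <- read_tsv_checked(groups_path)
  for (nm in list(c("signals", signals_path), c("calls", calls_path))) {
    tab <- if (nm[1] == "signals") sig else cal
    if (names(tab)[1] != "probe_id") {
      stop_parse(nm[1], " file ", nm[2], " must have 'probe_id' as first column")
    }
  }
  row_diff <- c(setdiff(sig$probe_id, cal$probe_id),
                setdiff(cal$probe_id, sig$probe_id))
  if (length(row_diff) > 0L) {
    stop_parse("signal/call probe labels differ; symmetric difference: ",
               paste(unique(row_diff), collapse = ", "))
  }
  sm <- as.matrix(sig[-1])
  rownames(sm) <- sig$probe_id
  storage.mode(sm) <- "double"
  if (anyNA(sm)) stop_parse("non-numeric signal value in ", signals_path)
  cal <- cal[match(sig$probe_id, cal$probe_id), , drop = FALSE]
  cm <- as.matrix(cal[-1])
  rownames(cm) <- cal$probe_id
  cm <- cm[, colnames(sm), drop = FALSE]
  expression_study(sm, cm, grp)
}

#' Write an expression study to its three tab-delimited files
#' @param study an [expression_study()].
#' @inheritParams read_expression_study
#' @return the three paths, invisibly.
#' @export
write_expression_study <- function(study, signals_path, calls_path, groups_path) {
  stopifnot(inherits(study, "expression_study"))
  write_mat <- function(m, path) {
    df <- data.frame(probe_id = rownames(m) %||% character(0),
                     m, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(study$signals, signals_path)
  write_mat(study$calls, calls_path)
  utils::write.table(study$groups, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(signals_path, calls_path, groups_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pipeline results to a directory
#'
#' Emits a structured JSON summary (Venn counts plus any extra summary
#' fields), a comma-delimited classified ratio table sorted by descending
#' mean log2 ratio (ties broken by probe id, unclassified probes last), and
#' one plain-text probe-id list per named set.
#'
#' @param out_dir output directory, created if needed.
#' @param venn a [build_venn()] result, or `NULL`.
#' @param ratios a ratio table from [summarize_ratios()] /
#'   [run_mirna_pipeline()], or `NULL`.
#' @param sets named list of character vectors; each written as
#'   `set_<name>.txt`, one probe id per line.
#' @param summary named list of extra scalar fields merged into the summary.
#' @return character vector of written paths (the manifest), invisibly.
#' @export
write_results <- function(out_dir, venn = NULL, ratios = NULL,
                          sets = list(), summary = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  manifest <- character()

  summ <- summary
  if (!is.null(venn)) summ <- c(unclass(venn), summ)
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- c(manifest, summary_path)

  if (!is.null(ratios)) {
    rt <- as.data.frame(ratios)
    ord <- order(is.na(rt$mean_log2_ratio), -xtfrm(rt$mean_log2_ratio),
                 rt$probe_id)
    rt <- rt[ord, , drop = FALSE]
    ratio_path <- file.path(out_dir, "ratio_table.csv")
    utils::write.csv(rt, ratio_path, row.names = FALSE, quote = FALSE)
    manifest <- c(manifest, ratio_path)
  }

  for (nm in names(sets)) {
    p <- file.path(out_dir, paste0("set_", nm, ".txt"))
    writeLines(as.character(sets[[nm]]), p)
    manifest <- c(manifest, p)
  }
  invisible(manifest)
}
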