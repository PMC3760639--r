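# Validated in-memory containers for the two array formats.

slide_set_columns <- c("probe_id", "slide", "replicate",
                       "hy3_fg", "hy3_bg", "hy5_fg", "hy5_bg")

empty_slide_set <- function() {
  as_slide_set(data.frame(
    probe_id = character(), slide = integer(), replicate = integer(),
    hy3_fg = numeric(), hy3_bg = numeric(),
    hy5_fg = numeric(), hy5_bg = numeric(),
    stringsAsFactors = FALSE
  ))
}

#' Validate a quantified two-channel slide table
#'
#' Checks the column contract of a quantified slide set — one row per
#' (probe, slide, replicate spot) with per-channel foreground and spot
#' background — and enforces its invariants: unique spot triples and finite,
#' non-negative signals.
#'
#' @param x a data.frame with columns `probe_id`, `slide`, `replicate`,
#'   `hy3_fg`, `hy3_bg`, `hy5_fg`, `hy5_bg`.
#' @return `x` with class `slide_set` prepended.
#' @export
as_slide_set <- function(x) {
  missing_cols <- setdiff(slide_set_columns, names(x))
  if (length(missing_cols) > 0L) {
    stop_parse("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[slide_set_columns]
  x$probe_id <- as.character(x$probe_id)
  for (col in c("hy3_fg", "hy3_bg", "hy5_fg", "hy5_bg")) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_parse("non-numeric value in column '", col, "' at row ",
                 if (is.na(bad)) "?" else bad)
    }
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0L) {
      stop_parse("negative or non-finite value in column '", col,
                 "' at row ", bad[1])
    }
  }
  key <- paste(x$probe_id, x$slide, x$replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop_parse("duplicated (probe_id, slide, replicate) triple at row ",
               dup[1], ": (", x$probe_id[dup[1]], ", ", x$slide[dup[1]],
               ", ", x$replicate[dup[1]], ")")
  }
  class(x) <- c("slide_set", "data.frame")
  x
}

#' Construct a single-channel expression study
#'
#' Bundles a probe-by-sample signal matrix, the matching Present/Marginal/
#' Absent call matrix, and a sample-to-group map, enforcing that all three
#' agree on their labels and that calls use only the P/M/A vocabulary.
#'
#' @param signals numeric matrix, probes x samples, positive signals.
#' @param calls character matrix of identical dimnames with values in
#'   `c("P", "M", "A")`.
#' @param groups data.frame with columns `sample` and `group`
#'   (`"exosome"` or `"cell"`), one row per sample.
#' @return a list of class `expression_study`.
#' @export
expression_study <- function(signals, calls, groups) {
  signals <- as.matrix(signals)
  calls <- as.matrix(calls)
  if (!identical(dim(signals), dim(calls)) ||
      !identical(rownames(signals), rownames(calls)) ||
      !identical(colnames(signals), colnames(calls))) {
    sdiff <- c(setdiff(rownames(signals), rownames(calls)),
               setdiff(rownames(calls), rownames(signals)),
               setdiff(colnames(signals), colnames(calls)),
               setdiff(colnames(calls), colnames(signals)))
    stop_parse("signal and call matrices disagree on labels",
               if (length(sdiff) > 0L) {
                 paste0("; symmetric difference: ",
                        paste(unique(sdiff), collapse = ", "))
               } else "")
  }
  bad <- setdiff(unique(as.vector(calls)), c("P", "M", "A"))
  if (length(bad) > 0L) {
    stop_parse("call value(s) outside {P, M, A}: ", paste(bad, collapse = ", "))
  }
  if (!all(c("sample", "group") %in% names(groups))) {
    stop_parse("groups table must have columns 'sample' and 'group'")
  }
  groups <- data.frame(sample = as.character(groups$sample),
                       group = as.character(groups$group),
                       stringsAsFactors = FALSE)
  sdiff <- c(setdiff(groups$sample, colnames(signals)),
             setdiff(colnames(signals), groups$sample))
  if (length(sdiff) > 0L || anyDuplicated(groups$sample)) {
    stop_parse("group map and matrix columns disagree; symmetric difference: ",
               paste(unique(sdiff), collapse = ", "))
  }
  badg <- setdiff(unique(groups$group), c("exosome", "cell"))
  if (length(badg) > 0L) {
    stop_parse("group value(s) outside {exosome, cell}: ",
               paste(badg, collapse = ", "))
  }
  structure(list(signals = signals, calls = calls, groups = groups),
            class = "expression_study")
}

#' Sample names belonging to one group of an expression study
#' @param study an [expression_study()].
#' @param group `"exosome"` or `"cell"`.
#' @return character vector of sample names.
#' @export
group_samples <- function(study, group) {
  stopifnot(inherits(study, "expression_study"))
  study$groups$sample[study$groups$group == group]
}
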