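# Two-channel miRNA pipeline: slide background estimation, replicate-based
# detection status, cross-slide reliability aggregation, global lowess MA
# normalization, cross-slide log2-ratio summaries, fold-change classification,
# and Venn set algebra over the detected compartments.
#
# Channel orientation is fixed throughout: Hy3 carries the exosome sample and
# Hy5 the donor-cell sample; every ratio is exosome over cell.

#' Slide-wide channel background
#'
#' The detectability reference for each slide and channel: the median of all
#' foreground signals of that channel on the slide (every replicate spot of
#' every probe). A probe later counts as detectable on the slide only when its
#' summarized signal exceeds `detect_multiplier` times this value.
#'
#' @param slides a `slide_set`.
#' @return data.frame with one row per (slide, channel): columns `slide`,
#'   `channel` (`"Hy3"`/`"Hy5"`), `background`.
#' @export
estimate_slide_background <- function(slides) {
  slides <- as_slide_set(slides)
  if (nrow(slides) == 0L) stop("empty slide set: no spots to estimate from")
  dt <- data.table::as.data.table(slides)
  med <- dt[, .(Hy3 = stats::median(hy3_fg), Hy5 = stats::median(hy5_fg)),
            by = slide]
  out <- data.frame(
    slide = rep(med$slide, 2L),
    channel = rep(c("Hy3", "Hy5"), each = nrow(med)),
    background = c(med$Hy3, med$Hy5),
    stringsAsFactors = FALSE
  )
  out[order(out$slide, out$channel), , drop = FALSE]
}

#' Detection status of one probe on one slide (one channel)
#'
#' Three-valued call from the replicate spots:
#' * `absent` — the foreground is at or below its own spot background in at
#'   least half the replicates (ceiling; 2 or more of 4 in the default design);
#' * `detectable` — otherwise, if the summarized signal (median of the
#'   replicate foregrounds) exceeds `multiplier` times the slide-wide channel
#'   background;
#' * `below_limit` — otherwise.
#'
#' @param foregrounds numeric vector of replicate foreground signals.
#' @param spot_backgrounds matching vector of per-spot background signals.
#' @param slide_background the slide-wide channel background from
#'   [estimate_slide_background()].
#' @param multiplier detectability multiplier (default 3).
#' @return one of `"absent"`, `"below_limit"`, `"detectable"`.
#' @export
#' @examples
#' call_slide_status(c(5, 5, 90, 90), c(6, 6, 10, 10), 10)  # "absent"
call_slide_status <- function(foregrounds, spot_backgrounds, slide_background,
                              multiplier = 3) {
  k <- length(foregrounds)
  if (k == 0L || length(spot_backgrounds) != k) {
    stop("foregrounds and spot_backgrounds must be non-empty and equal length")
  }
  if (sum(foregrounds <= spot_backgrounds) >= ceiling(k / 2)) return("absent")
  if (stats::median(foregrounds) > multiplier * slide_background) {
    return("detectable")
  }
  "below_limit"
}

#' Aggregate per-slide statuses into a detected/undetected verdict
#'
#' A probe's channel is `detected` only when it was `detectable` on at least
#' `min_slides` slides; probes seen on fewer slides are treated as unreliable
#' and excluded from the detected set. The default demands all available
#' slides (3 of 3 in the triplicate design).
#'
#' @param statuses character vector of per-slide statuses for one probe and
#'   channel (values from [call_slide_status()]).
#' @param min_slides minimum number of `detectable` slides; defaults to
#'   `length(statuses)`.
#' @return `"detected"` or `"undetected"`.
#' @export
aggregate_detection <- function(statuses, min_slides = length(statuses)) {
  if (length(statuses) < 1L) stop("need at least one slide status")
  if (min_slides > length(statuses)) {
    stop_config("min_slides (", min_slides, ") exceeds the number of slides (",
                length(statuses), ")")
  }
  if (sum(statuses == "detectable") >= min_slides) "detected" else "undetected"
}

#' Per-probe detection across a whole slide set
#'
#' Applies [call_slide_status()] to every (probe, slide, channel) and
#' [aggregate_detection()] across slides.
#'
#' @param slides a `slide_set`.
#' @param multiplier detectability multiplier (default 3).
#' @param min_slides minimum detectable slides for a detected verdict;
#'   `NULL` (default) means all slides present in the data.
#' @return list with `per_slide` (probe_id, slide, channel, status) and
#'   `aggregated` (probe_id, channel, n_detectable, detected) data.frames.
#' @export
compute_detection <- function(slides, multiplier = 3, min_slides = NULL) {
  slides <- as_slide_set(slides)
  if (nrow(slides) == 0L) {
    return(list(
      per_slide = data.frame(probe_id = character(), slide = integer(),
                             channel = character(), status = character(),
                             stringsAsFactors = FALSE),
      aggregated = data.frame(probe_id = character(), channel = character(),
                              n_detectable = integer(), detected = logical(),
                              stringsAsFactors = FALSE)
    ))
  }
  bg <- estimate_slide_background(slides)
  n_slides <- length(unique(slides$slide))
  if (is.null(min_slides)) min_slides <- n_slides
  if (min_slides > n_slides) {
    stop_config("min_slides (", min_slides, ") exceeds the number of slides (",
                n_slides, ")")
  }
  dt <- data.table::as.data.table(slides)
  bg3 <- stats::setNames(bg$background[bg$channel == "Hy3"],
                         bg$slide[bg$channel == "Hy3"])
  bg5 <- stats::setNames(bg$background[bg$channel == "Hy5"],
                         bg$slide[bg$channel == "Hy5"])
  per <- dt[, .(
    hy3_status = call_slide_status(hy3_fg, hy3_bg, bg3[[as.character(slide[1])]],
                                   multiplier),
    hy5_status = call_slide_status(hy5_fg, hy5_bg, bg5[[as.character(slide[1])]],
                                   multiplier)
  ), by = .(probe_id, slide)]
  per_slide <- data.frame(
    probe_id = rep(per$probe_id, 2L),
    slide = rep(per$slide, 2L),
    channel = rep(c("Hy3", "Hy5"), each = nrow(per)),
    status = c(per$hy3_status, per$hy5_status),
    stringsAsFactors = FALSE
  )
  ps <- data.table::as.data.table(per_slide)
  agg <- ps[, .(n_detectable = sum(status == "detectable")),
            by = .(probe_id, channel)]
  agg[, detected := n_detectable >= min_slides]
  list(per_slide = per_slide, aggregated = as.data.frame(agg))
}

#' Probe ids detected on one channel
#' @param detection result of [compute_detection()].
#' @param channel `"Hy3"` (exosome) or `"Hy5"` (cell).
#' @return character vector of probe ids.
#' @export
detected_set <- function(detection, channel) {
  a <- detection$aggregated
  sort(a$probe_id[a$channel == channel & a$detected])
}

#' Global lowess (MA) normalization of one slide
#'
#' Summarizes each probe's replicate spots by their median per channel,
#' computes `M = log2(Hy3/Hy5)` and `A = (log2 Hy3 + log2 Hy5)/2`, fits a
#' lowess curve of M on A over all probes of the slide, and returns the
#' residual M. A smooth intensity-dependent dye bias is thereby removed; the
#' median residual is ~0 when the bias is smooth in A. Foregrounds are used
#' directly (no background subtraction); probes whose summarized signal is
#' not strictly positive on both channels are excluded from the fit and
#' reported with `excluded = TRUE` and `NA` ratios.
#'
#' @param slide_df the rows of a `slide_set` belonging to one slide.
#' @param span lowess span (fraction of points in each local window).
#' @param iterations robustness iterations of the lowess fit.
#' @return data.frame with columns `probe_id`, `A`, `M`, `normalized_m`,
#'   `excluded`.
#' @export
lowess_normalize_slide <- function(slide_df, span = 0.3, iterations = 1L) {
  if (length(unique(slide_df$slide)) > 1L) {
    stop("lowess_normalize_slide expects the spots of a single slide")
  }
  dt <- data.table::as.data.table(slide_df)
  summ <- dt[, .(hy3 = stats::median(hy3_fg), hy5 = stats::median(hy5_fg)),
             by = probe_id]
  ok <- summ$hy3 > 0 & summ$hy5 > 0
  m <- a <- norm <- rep(NA_real_, nrow(summ))
  m[ok] <- log2(summ$hy3[ok] / summ$hy5[ok])
  a[ok] <- 0.5 * log2(summ$hy3[ok] * summ$hy5[ok])
  if (sum(ok) >= 2L) {
    fit <- stats::lowess(a[ok], m[ok], f = span, iter = iterations)
    o <- order(a[ok])
    resid <- m[ok]
    resid[o] <- m[ok][o] - fit$y
    norm[ok] <- resid
  } else if (sum(ok) == 1L) {
    norm[ok] <- 0
  }
  data.frame(probe_id = summ$probe_id, A = a, M = m, normalized_m = norm,
             excluded = !ok, stringsAsFactors = FALSE)
}

#' Normalize every slide of a slide set
#' @inheritParams lowess_normalize_slide
#' @param slides a `slide_set`.
#' @return long data.frame: `probe_id`, `slide`, `A`, `M`, `normalized_m`,
#'   `excluded`.
#' @export
normalize_slide_set <- function(slides, span = 0.3, iterations = 1L) {
  slides <- as_slide_set(slides)
  pieces <- lapply(split(slides, slides$slide), function(sl) {
    res <- lowess_normalize_slide(sl, span = span, iterations = iterations)
    res$slide <- sl$slide[1]
    res
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(probe_id = character(), A = numeric(), M = numeric(),
                      normalized_m = numeric(), excluded = logical(),
                      slide = integer(), stringsAsFactors = FALSE)
  }
  out[c("probe_id", "slide", "A", "M", "normalized_m", "excluded")]
}

#' Summarize normalized log2 ratios across slides
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of each
#' probe's normalized log2(Hy3/Hy5) over the slides on which it was not
#' excluded. A probe excluded on every slide keeps an `NA` mean (missing, not
#' zero).
#'
#' @param normalized long data.frame from [normalize_slide_set()].
#' @return data.frame: `probe_id`, `mean_log2_ratio`, `sd_log2_ratio`,
#'   `n_slides_used`.
#' @export
summarize_ratios <- function(normalized) {
  dt <- data.table::as.data.table(normalized)
  out <- dt[, .(
    mean_log2_ratio = if (all(is.na(normalized_m))) NA_real_ else
      mean(normalized_m, na.rm = TRUE),
    sd_log2_ratio = if (sum(!is.na(normalized_m)) >= 2L)
      stats::sd(normalized_m[!is.na(normalized_m)]) else NA_real_,
    n_slides_used = sum(!is.na(normalized_m))
  ), by = probe_id]
  as.data.frame(out[order(probe_id)])
}

#' Classify fold change on the log2 scale
#'
#' Three-way classification of the mean log2(exosome/cell) ratio with both
#' boundaries inclusive to the elevated classes: `elevated_in_exosomes` when
#' mean >= threshold, `elevated_in_cells` when mean <= -threshold, `equal`
#' otherwise. The default threshold of 2 log2 units marks a 4-fold change.
#' Missing means stay `NA` (unclassified).
#'
#' @param mean_log2_ratio numeric vector of mean log2 ratios.
#' @param threshold positive log2 threshold (default 2).
#' @return character vector of classes.
#' @export
classify_fold_change <- function(mean_log2_ratio, threshold = 2) {
  if (threshold <= 0) stop_config("'threshold' must be positive")
  ifelse(is.na(mean_log2_ratio), NA_character_,
         ifelse(mean_log2_ratio >= threshold, "elevated_in_exosomes",
                ifelse(mean_log2_ratio <= -threshold, "elevated_in_cells",
                       "equal")))
}

#' Venn counts of two detected compartments
#'
#' Exact set algebra over the probe ids detected in exosomes and in cells.
#'
#' @param exo_detected,cell_detected character vectors of probe ids.
#' @return list of class `venn_counts`: `exo_total`, `cell_total`, `shared`,
#'   `exo_only`, `cell_only`, `union_size`.
#' @export
#' @examples
#' build_venn(c("a", "b", "c"), c("b", "c", "d"))
build_venn <- function(exo_detected, cell_detected) {
  e <- unique(as.character(exo_detected))
  c_ <- unique(as.character(cell_detected))
  shared <- length(intersect(e, c_))
  out <- list(
    exo_total = length(e),
    cell_total = length(c_),
    shared = shared,
    exo_only = length(e) - shared,
    cell_only = length(c_) - shared,
    union_size = length(union(e, c_))
  )
  class(out) <- "venn_counts"
  out
}

#' @export
print.venn_counts <- function(x, ...) {
  cat("Venn counts: exosomes", x$exo_total, "| cells", x$cell_total,
      "| shared", x$shared, "\n  exosome-only", x$exo_only,
      "| cell-only", x$cell_only, "| union", x$union_size, "\n")
  invisible(x)
}

#' Top compartment-enriched probes
#'
#' Ranks probes by mean log2(exosome/cell) ratio — descending for the exosome
#' direction, ascending for the cell direction — with ties broken
#' lexicographically by probe id; unclassified (NA-mean) probes are dropped.
#'
#' @param ratio_table result of [summarize_ratios()].
#' @param n number of probes to return.
#' @param direction `"exosome"` or `"cell"`.
#' @return character vector of up to `n` probe ids.
#' @export
rank_enriched <- function(ratio_table, n, direction = c("exosome", "cell")) {
  direction <- match.arg(direction)
  if (n < 0) stop_config("'n' must be non-negative")
  rt <- ratio_table[!is.na(ratio_table$mean_log2_ratio), , drop = FALSE]
  key <- if (direction == "exosome") -rt$mean_log2_ratio else rt$mean_log2_ratio
  ord <- order(key, rt$probe_id)
  utils::head(rt$probe_id[ord], n)
}

#' Run the complete two-channel miRNA pipeline
#'
#' Slide backgrounds, per-slide detection status, cross-slide aggregation,
#' global lowess normalization, log2-ratio summaries with fold-change classes,
#' Venn counts of the detected compartments, and the top enriched probes
#' (ranked among probes detected in exosomes).
#'
#' @param slides a `slide_set`.
#' @param detect_multiplier detectability multiplier (default 3).
#' @param min_slides minimum detectable slides; `NULL` = all slides.
#' @param lowess_span,lowess_iterations lowess parameters.
#' @param fc_threshold log2 fold-change classification threshold (default 2).
#' @param top_n number of top enriched probes to report.
#' @return list: `backgrounds`, `detection`, `ratio_table` (with `fc_class`),
#'   `detected` (list of exosome/cell probe-id sets), `venn`, `top_enriched`.
#' @export
run_mirna_pipeline <- function(slides, detect_multiplier = 3, min_slides = NULL,
                               lowess_span = 0.3, lowess_iterations = 1L,
                               fc_threshold = 2, top_n = 10L) {
  slides <- as_slide_set(slides)
  if (nrow(slides) == 0L) {
    rt <- data.frame(probe_id = character(), mean_log2_ratio = numeric(),
                     sd_log2_ratio = numeric(), n_slides_used = integer(),
                     fc_class = character(), stringsAsFactors = FALSE)
    return(list(backgrounds = NULL,
                detection = compute_detection(slides),
                ratio_table = rt,
                detected = list(exosome = character(), cell = character()),
                venn = build_venn(character(), character()),
                top_enriched = character()))
  }
  backgrounds <- estimate_slide_background(slides)
  detection <- compute_detection(slides, multiplier = detect_multiplier,
                                 min_slides = min_slides)
  normalized <- normalize_slide_set(slides, span = lowess_span,
                                    iterations = lowess_iterations)
  ratio_table <- summarize_ratios(normalized)
  ratio_table$fc_class <- classify_fold_change(ratio_table$mean_log2_ratio,
                                               threshold = fc_threshold)
  exo <- detected_set(detection, "Hy3")
  cell <- detected_set(detection, "Hy5")
  top <- rank_enriched(ratio_table[ratio_table$probe_id %in% exo, , drop = FALSE],
                       top_n, "exosome")
  list(backgrounds = backgrounds, detection = detection,
       ratio_table = ratio_table, detected = list(exosome = exo, cell = cell),
       venn = build_venn(exo, cell), top_enriched = top)
}
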