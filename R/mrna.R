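# Single-channel mRNA pipeline: per-array median scaling, group-wise
# top-quantile intensity filtering, Present/Marginal/Absent call filtering,
# compartment-unique sets, and the detected-fraction summary.

#' Scale each array to a target median intensity
#'
#' Multiplies every column by `target / median(column)` so all arrays share
#' the same median intensity and become comparable.
#'
#' @param signals numeric matrix, probes x samples, positive signals.
#' @param target target median (default 100).
#' @return the scaled matrix; every column median equals `target` to floating
#'   tolerance.
#' @export
#' @examples
#' scale_to_median(cbind(s1 = c(1, 2, 3)), target = 100)
scale_to_median <- function(signals, target = 100) {
  signals <- as.matrix(signals)
  if (target <= 0) stop_config("'target' must be positive")
  if (nrow(signals) == 0L) return(signals)
  med <- apply(signals, 2L, stats::median)
  bad <- which(!is.finite(med) | med <= 0)
  if (length(bad) > 0L) {
    stop("array '", (colnames(signals) %||% seq_len(ncol(signals)))[bad[1]],
         "' has a non-positive median; cannot scale")
  }
  sweep(signals, 2L, target / med, `*`)
}

#' Group-wise top-intensity filter
#'
#' Keeps a probe only if its signal on EVERY array of the group lies in the
#' top `top_fraction` of that array's intensity distribution. Cutoffs are the
#' `1 - top_fraction` quantile, linear-interpolation convention
#' ([stats::quantile()] type 7), and the comparison is boundary-inclusive
#' (`>=` the cutoff). With `pooled = TRUE` a single cutoff is computed from
#' the pooled group distribution instead of per array.
#'
#' @param signals numeric matrix, probes x samples (scaled).
#' @param samples sample names of the group (default: all columns).
#' @param top_fraction fraction of highest intensities retained (default 0.25).
#' @param pooled compute one cutoff from the pooled group values.
#' @return sorted character vector of passing probe ids.
#' @export
intensity_filter <- function(signals, samples = colnames(signals),
                             top_fraction = 0.25, pooled = FALSE) {
  if (!(top_fraction > 0 && top_fraction < 1)) {
    stop_config("'top_fraction' must be strictly between 0 and 1")
  }
  sub <- as.matrix(signals)[, samples, drop = FALSE]
  if (ncol(sub) == 0L) stop("empty group: no arrays to filter")
  if (nrow(sub) == 0L) return(character())
  if (pooled) {
    cutoff <- stats::quantile(as.vector(sub), probs = 1 - top_fraction,
                              names = FALSE, type = 7)
    pass <- rowSums(sub >= cutoff) == ncol(sub)
  } else {
    cutoffs <- apply(sub, 2L, stats::quantile, probs = 1 - top_fraction,
                     names = FALSE, type = 7)
    pass <- rowSums(sweep(sub, 2L, cutoffs, `>=`)) == ncol(sub)
  }
  sort(rownames(sub)[pass])
}

#' Presence filter: present on every array of the group
#'
#' A probe is present in a group only when its detection call is `P` on every
#' array of that group; a single `M` or `A` disqualifies it.
#'
#' @param calls character matrix of P/M/A calls, probes x samples.
#' @param samples sample names of the group (default: all columns).
#' @return sorted character vector of present probe ids.
#' @export
presence_filter <- function(calls, samples = colnames(calls)) {
  sub <- as.matrix(calls)[, samples, drop = FALSE]
  if (nrow(sub) == 0L) return(character())
  sort(rownames(sub)[rowSums(sub == "P") == ncol(sub)])
}

#' Compartment-unique probes
#'
#' A probe is unique to `own_samples`' group when it is called `P` on every
#' own-group array AND `A` on every array of the other group; a marginal call
#' anywhere in the other group disqualifies it.
#'
#' @param calls character matrix of P/M/A calls.
#' @param own_samples,other_samples disjoint non-empty sample name vectors.
#' @return sorted character vector of unique probe ids.
#' @export
unique_set <- function(calls, own_samples, other_samples) {
  if (length(own_samples) == 0L || length(other_samples) == 0L) {
    stop_config("both groups must be non-empty")
  }
  if (length(intersect(own_samples, other_samples)) > 0L) {
    stop_config("groups must be disjoint; overlap: ",
                paste(intersect(own_samples, other_samples), collapse = ", "))
  }
  m <- as.matrix(calls)
  own <- m[, own_samples, drop = FALSE]
  oth <- m[, other_samples, drop = FALSE]
  if (nrow(m) == 0L) return(character())
  keep <- rowSums(own == "P") == ncol(own) & rowSums(oth == "A") == ncol(oth)
  sort(rownames(m)[keep])
}

#' Detected-set summary across compartments
#'
#' Records both detected counts, the exosome/cell fraction, and the
#' percentage rounded half-up to the nearest integer for reporting.
#'
#' @param exo_detected,cell_detected character vectors of detected probe ids.
#' @return list of class `presence_summary`: `exo_detected_n`,
#'   `cell_detected_n`, `detected_fraction` (NA when the cell count is zero),
#'   `detected_percent`.
#' @export
#' @examples
#' s <- detected_summary(paste0("p", 1:1849), paste0("q", 1:12346))
#' s$detected_percent # 15
detected_summary <- function(exo_detected, cell_detected) {
  en <- length(unique(exo_detected))
  cn <- length(unique(cell_detected))
  fraction <- if (cn == 0L) NA_real_ else en / cn
  out <- list(
    exo_detected_n = en,
    cell_detected_n = cn,
    detected_fraction = fraction,
    detected_percent = if (is.na(fraction)) NA_real_ else
      round_half_up(100 * fraction)
  )
  class(out) <- "presence_summary"
  out
}

#' @export
print.presence_summary <- function(x, ...) {
  cat("Detected mRNAs: exosomes", x$exo_detected_n, "| cells",
      x$cell_detected_n, "| exosome fraction",
      if (is.na(x$detected_fraction)) "NA" else
        sprintf("%.3f (%d%%)", x$detected_fraction, x$detected_percent), "\n")
  invisible(x)
}

#' Run the complete single-channel mRNA pipeline
#'
#' Scales every array to the target median, then per group takes the
#' intersection of the intensity filter and the presence filter as the
#' detected set (the two filters are conjunctive, hence order-independent),
#' builds the compartment-unique sets from the calls, and summarizes the
#' detected fraction.
#'
#' @param study an [expression_study()].
#' @param top_fraction intensity-filter fraction (default 0.25).
#' @param scale_target target median intensity (default 100).
#' @param pooled use a pooled group cutoff in the intensity filter.
#' @return list: `scaled` (matrix), `detected` (list of exosome/cell sets),
#'   `unique` (list of exosome/cell unique sets), `summary`
#'   (a [detected_summary()]).
#' @export
run_mrna_pipeline <- function(study, top_fraction = 0.25, scale_target = 100,
                              pooled = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  exo_s <- group_samples(study, "exosome")
  cell_s <- group_samples(study, "cell")
  scaled <- scale_to_median(study$signals, target = scale_target)
  detected <- list(
    exosome = intersect(
      intensity_filter(scaled, exo_s, top_fraction, pooled = pooled),
      presence_filter(study$calls, exo_s)
    ),
    cell = intersect(
      intensity_filter(scaled, cell_s, top_fraction, pooled = pooled),
      presence_filter(study$calls, cell_s)
    )
  )
  uniq <- list(
    exosome = unique_set(study$calls, exo_s, cell_s),
    cell = unique_set(study$calls, cell_s, exo_s)
  )
  list(scaled = scaled, detected = detected, unique = uniq,
       summary = detected_summary(detected$exosome, detected$cell))
}
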