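# Shared builders for the test suite. Everything is generated in code;
# no binary fixtures.

noiseless_config <- function(...) {
  args <- list(...)
  defaults <- list(noise_cv = 0, dye_bias_amplitude = 0, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# A hand-built truth table (bypasses generate_truth) for targeted signal checks.
manual_truth <- function(probe_id, exo_abundance, cell_abundance) {
  data.frame(
    probe_id = probe_id,
    compartment_class = "shared",
    true_log2fc = log2(exo_abundance / cell_abundance),
    base_intensity = sqrt(exo_abundance * cell_abundance),
    exo_abundance = exo_abundance,
    cell_abundance = cell_abundance,
    stringsAsFactors = FALSE
  )
}

# Build a minimal slide_set directly from per-spot vectors.
manual_slides <- function(probe_id, slide, replicate, hy3_fg, hy5_fg,
                          hy3_bg = 0, hy5_bg = 0) {
  as_slide_set(data.frame(
    probe_id = probe_id, slide = slide, replicate = replicate,
    hy3_fg = hy3_fg, hy3_bg = hy3_bg, hy5_fg = hy5_fg, hy5_bg = hy5_bg,
    stringsAsFactors = FALSE
  ))
}

truth_present_sets <- function(truth) {
  list(
    exosome = sort(truth$probe_id[truth$compartment_class %in%
                                    c("exosome_only", "shared")]),
    cell = sort(truth$probe_id[truth$compartment_class %in%
                                 c("cell_only", "shared")])
  )
}

# One-slide set whose probes all share the log2 ratio `m_offset`, with A
# spread across a wide intensity range.
make_biased_slide <- function(n = 200, m_offset = 0, seed = 61) {
  set.seed(seed)
  a <- sort(runif(n, 4, 14))
  m <- rep(m_offset, n)
  manual_slides(sprintf("p%03d", 1:n), 1, 1,
                hy3_fg = 2^(a + m / 2), hy5_fg = 2^(a - m / 2))
}

# Independent mid-mean median oracle (sort-based), kept separate from
# stats::median on purpose.
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# Brute-force detection-status oracle: re-states the two-rule decision
# independently of call_slide_status's implementation.
status_oracle <- function(fg, bg, slide_bg, multiplier = 3) {
  below <- 0L
  for (i in seq_along(fg)) if (fg[i] <= bg[i]) below <- below + 1L
  if (below >= ceiling(length(fg) / 2)) return("absent")
  if (median_oracle(fg) > multiplier * slide_bg) "detectable" else "below_limit"
}
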