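test_that("slide background is the median foreground per channel, matching a sort oracle", {
  s <- manual_slides("p", 1, 1:3, hy3_fg = c(1, 2, 3), hy5_fg = c(1, 2, 3))
  bg <- estimate_slide_background(s)
  expect_equal(bg$background[bg$channel == "Hy3"], 2)
  s4 <- manual_slides("p", 1, 1:4, hy3_fg = c(1, 2, 3, 4), hy5_fg = 1:4)
  expect_equal(estimate_slide_background(s4)$background, c(2.5, 2.5))

  cfg <- sim_config(n_probes = 250, n_slides = 1, seed = 17)
  sim <- simulate_two_channel_slides(generate_truth(cfg), cfg)
  bg <- estimate_slide_background(sim)
  expect_identical(bg$background[bg$channel == "Hy3"], median_oracle(sim$hy3_fg))
  expect_identical(bg$background[bg$channel == "Hy5"], median_oracle(sim$hy5_fg))
  expect_error(estimate_slide_background(empty <- as_slide_set(sim[0, ])),
               "empty")
})

test_that("detection status follows the at-or-below and 3x-background rules", {
  # 2 of 4 replicates at/below their spot background: absent regardless of level
  expect_identical(call_slide_status(c(5, 5, 90, 90), c(6, 6, 10, 10), 1),
                   "absent")
  # 'equal to' counts as at-or-below
  expect_identical(call_slide_status(rep(0, 4), rep(0, 4), 10), "absent")
  # summarized signal must strictly exceed multiplier x slide background
  expect_identical(call_slide_status(c(30, 30, 30, 30), rep(1, 4), 10),
                   "below_limit")
  expect_identical(call_slide_status(c(31, 31, 31, 31), rep(1, 4), 10),
                   "detectable")
  expect_error(call_slide_status(c(1, 2), c(1, 2, 3), 1), "equal length")
})

test_that("status calls match the brute-force oracle over all replicate patterns and regimes", {
  slide_bg <- 10
  for (pattern in 0:15) {
    below <- as.logical(bitwAnd(pattern, 2^(0:3)))
    for (regime in c("le", "gt")) {
      # construct foregrounds realizing the at/below pattern with the
      # summarized signal in the requested regime
      level <- if (regime == "gt") 100 else 20 # vs 3 x 10 = 30
      fg <- ifelse(below, 5, level)
      bg <- rep(5, 4)
      expect_identical(
        call_slide_status(fg, bg, slide_bg),
        status_oracle(fg, bg, slide_bg),
        info = paste("pattern", pattern, regime)
      )
    }
  }
})

test_that("cross-slide aggregation requires min_slides detectable slides", {
  expect_identical(aggregate_detection(c("detectable", "detectable", "below_limit"),
                                       min_slides = 3), "undetected")
  expect_identical(aggregate_detection(rep("detectable", 3)), "detected")
  expect_error(aggregate_detection(rep("detectable", 2), min_slides = 3),
               "exceeds", class = "exocargo_config_error")

  # counting oracle over random status assignments
  set.seed(31)
  statuses <- c("absent", "below_limit", "detectable")
  for (i in 1:500) {
    st <- sample(statuses, 3, replace = TRUE)
    ms <- sample(1:3, 1)
    expect_identical(aggregate_detection(st, ms),
                     if (sum(st == "detectable") >= ms) "detected" else "undetected")
  }
})

test_that("detection is monotone in the multiplier and in min_slides", {
  cfg <- sim_config(n_probes = 200, seed = 23, noise_cv = 0.3)
  slides <- simulate_two_channel_slides(generate_truth(cfg), cfg)
  sets_by_mult <- lapply(c(2, 3, 4), function(m) {
    detected_set(compute_detection(slides, multiplier = m), "Hy3")
  })
  expect_true(all(sets_by_mult[[2]] %in% sets_by_mult[[1]]))
  expect_true(all(sets_by_mult[[3]] %in% sets_by_mult[[2]]))
  sets_by_min <- lapply(1:3, function(ms) {
    detected_set(compute_detection(slides, min_slides = ms), "Hy3")
  })
  expect_true(all(sets_by_min[[3]] %in% sets_by_min[[2]]))
  expect_true(all(sets_by_min[[2]] %in% sets_by_min[[1]]))
})

test_that("venn construction is exact set algebra and matches a brute-force oracle", {
  rc_sizes <- c(exo = 116L, cell = 134L, shared = 89L)
  shared <- sprintf("s%03d", 1:89)
  exo <- c(shared, sprintf("e%02d", 1:27))
  cell <- c(shared, sprintf("c%02d", 1:45))
  v <- build_venn(exo, cell)
  expect_identical(v$exo_only, 27L)
  expect_identical(v$cell_only, 45L)
  expect_identical(v$union_size, 161L)

  v2 <- build_venn(c("a", "b", "c"), c("x", "y", "z", "w", "v"))
  expect_identical(v2$shared, 0L)
  expect_identical(v2$union_size, 8L)

  set.seed(41)
  universe <- sprintf("m%03d", 1:60)
  for (i in 1:200) {
    e <- sample(universe, sample(0:40, 1))
    c_ <- sample(universe, sample(0:40, 1))
    v <- build_venn(e, c_)
    # brute-force membership enumeration over the union
    u <- unique(c(e, c_))
    in_e <- u %in% e
    in_c <- u %in% c_
    expect_identical(v$shared, sum(in_e & in_c))
    expect_identical(v$exo_only, sum(in_e & !in_c))
    expect_identical(v$cell_only, sum(!in_e & in_c))
    # conservation invariants
    expect_identical(v$exo_only + v$shared, v$exo_total)
    expect_identical(v$cell_only + v$shared, v$cell_total)
    expect_identical(v$union_size, v$exo_only + v$cell_only + v$shared)
  }
})

test_that("enrichment ranking sorts by mean ratio with lexicographic tie-breaks", {
  rt <- data.frame(probe_id = c("a", "b", "c"), mean_log2_ratio = c(3, 1, 2))
  expect_identical(rank_enriched(rt, 2, "exosome"), c("a", "c"))
  expect_identical(rank_enriched(rt, 10, "exosome"), c("a", "c", "b"))
  expect_identical(rank_enriched(rt, 2, "cell"), c("b", "c"))

  set.seed(51)
  rt <- data.frame(probe_id = sprintf("p%02d", 1:50),
                   mean_log2_ratio = sample(rep(round(rnorm(10), 1), 5)))
  got <- rank_enriched(rt, 50, "exosome")
  oracle <- rt$probe_id[order(-rt$mean_log2_ratio, rt$probe_id)]
  expect_identical(got, oracle)
})
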