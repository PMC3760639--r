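test_that("median scaling hits the target on every array and errors on degenerate arrays", {
  expect_equal(scale_to_median(cbind(a = c(50, 100, 150)), 100)[, 1],
               c(50, 100, 150))
  expect_equal(scale_to_median(cbind(a = c(1, 2, 3)), 100)[, 1],
               c(50, 100, 150))
  set.seed(111)
  m <- matrix(rlnorm(800, 5, 1), 100, 8,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:8)))
  sc <- scale_to_median(m, 100)
  expect_true(all(abs(apply(sc, 2, median) - 100) < 1e-9))
  m[, 3] <- 0
  expect_error(scale_to_median(m, 100), "s3")
})

test_that("intensity filter keeps the top quantile per array with inclusive boundaries", {
  m <- cbind(s1 = c(1, 2, 3, 4))
  rownames(m) <- c("a", "b", "c", "d")
  # type-7 cutoff at the 0.75 quantile of {1,2,3,4} is 3.25: only d passes
  expect_identical(intensity_filter(m, top_fraction = 0.25), "d")

  # constant matrix: every value ties the cutoff, >= keeps all probes
  cm <- matrix(7, 5, 3, dimnames = list(letters[1:5], paste0("s", 1:3)))
  expect_identical(intensity_filter(cm), letters[1:5])

  # conjunction over arrays: max on 3 arrays, min on the 4th -> fails
  m4 <- matrix(rep(c(10, 5, 4, 3, 2), 4), 5, 4,
               dimnames = list(letters[1:5], paste0("s", 1:4)))
  m4["a", 4] <- 1
  expect_false("a" %in% intensity_filter(m4, top_fraction = 0.25))

  # sort-and-count oracle on a random study
  set.seed(121)
  m <- matrix(rlnorm(300 * 4, 5, 1), 300, 4,
              dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:4)))
  got <- intensity_filter(m, top_fraction = 0.25)
  cutoffs <- apply(m, 2, function(x) quantile(x, 0.75, type = 7, names = FALSE))
  oracle <- rownames(m)[apply(m >= rep(cutoffs, each = nrow(m)), 1, all)]
  expect_identical(got, sort(oracle))
})

test_that("intensity filter is monotone in top_fraction and invariant to uniform rescaling", {
  set.seed(131)
  m <- matrix(rlnorm(200 * 4, 5, 1), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:4)))
  prev <- character()
  for (tf in c(0.1, 0.25, 0.5, 0.9)) {
    cur <- intensity_filter(m, top_fraction = tf)
    expect_true(all(prev %in% cur), info = paste("top_fraction", tf))
    prev <- cur
  }
  scaled <- sweep(m, 2, c(2, 0.5, 10, 1), `*`)
  expect_identical(intensity_filter(scaled), intensity_filter(m))
  expect_identical(intensity_filter(scale_to_median(m)), intensity_filter(m))
})

test_that("presence filter requires P on every array and matches a scan oracle", {
  calls <- rbind(a = c("P", "P", "P", "P"), b = c("P", "P", "M", "P"),
                 c = c("P", "A", "P", "P"))
  colnames(calls) <- paste0("s", 1:4)
  expect_identical(presence_filter(calls), "a")

  set.seed(141)
  calls <- matrix(sample(c("P", "M", "A"), 300 * 4, replace = TRUE,
                         prob = c(0.5, 0.2, 0.3)), 300, 4,
                  dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:4)))
  oracle <- rownames(calls)[vapply(seq_len(300),
                                   function(i) all(calls[i, ] == "P"),
                                   logical(1))]
  expect_identical(presence_filter(calls), sort(oracle))

  # adding an array never grows the presence set
  expect_true(all(presence_filter(calls, paste0("s", 1:4)) %in%
                    presence_filter(calls, paste0("s", 1:3))))
})

test_that("unique sets demand P everywhere in one group and A everywhere in the other", {
  calls <- rbind(u = c(rep("P", 4), rep("A", 4)),
                 m = c(rep("P", 4), "A", "A", "M", "A"),
                 p = rep("P", 8))
  colnames(calls) <- c(paste0("e", 1:4), paste0("c", 1:4))
  own <- paste0("e", 1:4); oth <- paste0("c", 1:4)
  expect_identical(unique_set(calls, own, oth), "u")
  expect_error(unique_set(calls, own, c(oth, "e1")), "disjoint",
               class = "exocargo_config_error")
  expect_error(unique_set(calls, character(), oth),
               class = "exocargo_config_error")
})

test_that("detected summary reports counts, fraction and half-up percentage", {
  s <- detected_summary(sprintf("e%04d", 1:1849), sprintf("c%05d", 1:12346))
  expect_identical(s$exo_detected_n, 1849L)
  expect_identical(s$detected_percent, 15)
  expect_identical(detected_summary(letters[1:5], letters[1:5])$detected_percent,
                   100)
  expect_identical(detected_summary("a", letters[1:3])$detected_percent, 33)
  # half-up convention: 0.5 rounds away from zero
  expect_identical(detected_summary(letters[1:1], letters[1:8])$detected_percent,
                   13)
  expect_true(is.na(detected_summary("a", character())$detected_fraction))
})

test_that("pipeline detected sets equal intensity AND presence filters, and truth is recovered", {
  cfg <- noiseless_config(n_probes = 500, seed = 151)
  truth <- generate_truth(cfg)
  study <- simulate_expression_study(truth, cfg)
  res <- run_mrna_pipeline(study)
  for (g in c("exosome", "cell")) {
    expect_identical(
      res$detected[[g]],
      intersect(intensity_filter(res$scaled, group_samples(study, g)),
                presence_filter(study$calls, group_samples(study, g)))
    )
  }
  tp <- truth_present_sets(truth)
  expect_identical(res$detected$exosome, tp$exosome)
  expect_identical(res$detected$cell, tp$cell)
  expect_identical(res$unique$exosome,
                   sort(truth$probe_id[truth$compartment_class == "exosome_only"]))
  expect_identical(res$unique$cell,
                   sort(truth$probe_id[truth$compartment_class == "cell_only"]))
})
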