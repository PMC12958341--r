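uhplc_yields <- tibble::tibble(
  compound = c("PS", "PG", "PSOH", "PGOH", "PES", "PEG", "ES", "EG",
               "PHBA", "MP"),
  yield_wt_pct = c(8.2, 5.26, 3.8, 2.9, 0.79, 0.22, 0.3, 0.2, 1.2, 0.63)
)

test_that("selectivity reproduces the published worked example", {
  expect_equal(sum(uhplc_yields$yield_wt_pct), 23.5)
  expect_equal(selectivity(uhplc_yields, c("PS", "PG")), 57, tolerance = 1 / 57)
  expect_equal(selectivity(uhplc_yields, c("PSOH", "PGOH")), 29,
               tolerance = 1 / 29)
  expect_equal(selectivity(uhplc_yields, uhplc_yields$compound), 100)
  expect_equal(selectivity(uhplc_yields, character(0)), 0)
  zero <- tibble::tibble(compound = "PS", yield_wt_pct = 0)
  expect_error(selectivity(zero, "PS"), "undefined")
})

test_that("selectivities over a disjoint exhaustive grouping sum to 100", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    groups <- split(uhplc_yields$compound,
                    sample(seq_len(k), nrow(uhplc_yields), replace = TRUE))
    total <- sum(vapply(groups, function(g) selectivity(uhplc_yields, g),
                        numeric(1)))
    expect_equal(total, 100, tolerance = 0.01 / 100)
  }
})

test_that("identical tables compare with R2 = 1 and zero deviations", {
  nmr <- tidyr::crossing(sample = paste0("s", 1:5),
                         compound = c("PS", "PG")) |>
    dplyr::mutate(yield_wt_pct = seq(1, 10, length.out = 10))
  cmp <- compare_to_reference(nmr, nmr)
  expect_equal(cmp$overall$mad, 0)
  expect_true(all(cmp$by_compound$r2_identity == 1))
  expect_true(all(cmp$by_compound$r2_fit == 1))
  expect_equal(nrow(cmp$unmatched), 0)
  expect_identical(tidy(cmp), cmp$by_compound)
  expect_identical(glance(cmp), cmp$overall)
})

test_that("a constant offset shows up as exactly that mean absolute deviation", {
  nmr <- tidyr::crossing(sample = paste0("s", 1:6), compound = "PS") |>
    dplyr::mutate(yield_wt_pct = 2 + seq_len(6))
  ref <- dplyr::mutate(nmr, yield_wt_pct = yield_wt_pct - 0.7)
  cmp <- compare_to_reference(nmr, ref)
  expect_equal(cmp$overall$mad, 0.7)
  expect_equal(cmp$by_compound$mad, 0.7)
})

test_that("comparison statistics equal a brute-force recomputation", {
  set.seed(21)
  base <- tidyr::crossing(sample = sprintf("s%02d", 1:20),
                          compound = c("PS", "PSOH", "PG")) |>
    dplyr::mutate(yield_wt_pct = runif(60, 1, 12))
  sigma <- 0.4
  nmr <- dplyr::mutate(base, yield_wt_pct = yield_wt_pct + rnorm(60, 0, sigma))
  cmp <- compare_to_reference(nmr, base)
  # brute-force oracle from the raw matched pairs
  d <- nmr$yield_wt_pct - base$yield_wt_pct
  expect_equal(cmp$overall$mad, mean(abs(d)))
  expect_equal(cmp$overall$mean_rel_dev_pct,
               mean(abs(100 * d / base$yield_wt_pct)))
  for (ab in c("PS", "PSOH", "PG")) {
    i <- base$compound == ab
    r2_or <- 1 - sum(d[i]^2) /
      sum((base$yield_wt_pct[i] - mean(base$yield_wt_pct[i]))^2)
    expect_equal(cmp$by_compound$r2_identity[cmp$by_compound$compound == ab],
                 r2_or)
  }
  # MAD of Gaussian noise concentrates near sigma * sqrt(2/pi)
  expect_equal(cmp$overall$mad, sigma * sqrt(2 / pi), tolerance = 0.25)
})

test_that("unmatched keys are reported and small groups drop R2 with a note", {
  nmr <- tibble::tibble(sample = c("a", "a", "b"),
                        compound = c("PS", "PG", "PS"),
                        yield_wt_pct = c(1, 2, 3))
  ref <- tibble::tibble(sample = c("a", "b", "c"),
                        compound = c("PS", "PS", "PS"),
                        yield_wt_pct = c(1, 3, 4))
  cmp <- compare_to_reference(nmr, ref)
  expect_equal(nrow(cmp$unmatched), 2)
  expect_setequal(cmp$unmatched$missing_from, c("reference", "nmr"))
  expect_true(is.na(cmp$by_compound$r2_identity))
  expect_match(cmp$by_compound$note, "fewer than 3")
})

test_that("the config-driven pipeline runs, is deterministic, and survives bad samples", {
  out_dir <- withr::local_tempdir()
  cfg <- list(
    samples = list(
      list(name = "a", scenario = "propyl_selective", seed = 11),
      list(name = "b", scenario = "oh_selective", seed = 12),
      list(name = "c", scenario = "mixed_50_50", seed = 13)
    ),
    options = list(noise_sigma = 0.05),
    out_dir = file.path(out_dir, "run1")
  )
  r1 <- run_pipeline(cfg)
  expect_equal(nrow(r1$errors), 0)
  expect_equal(length(unique(r1$results$sample)), 3)
  expect_true(file.exists(file.path(out_dir, "run1", "results.csv")))
  cfg$out_dir <- file.path(out_dir, "run2")
  r2 <- run_pipeline(cfg)
  f1 <- readBin(file.path(out_dir, "run1", "results.csv"), "raw", 1e6)
  f2 <- readBin(file.path(out_dir, "run2", "results.csv"), "raw", 1e6)
  expect_identical(f1, f2)
  # a missing spectrum file errors that sample only
  cfg_bad <- list(samples = list(
    list(name = "ok", scenario = "propyl_selective", seed = 11),
    list(name = "broken", spectrum = file.path(out_dir, "nope.jdx"))
  ))
  r3 <- run_pipeline(cfg_bad)
  expect_equal(r3$errors$sample, "broken")
  expect_setequal(unique(r3$results$sample), "ok")
})

test_that("pipeline results feed the comparison when a reference is given", {
  out_dir <- withr::local_tempdir()
  sim <- cached_oil("propyl_selective", seed = 11)
  ref <- true_yield_table(sim$truth) |>
    dplyr::transmute(sample = "a", compound, yield_wt_pct = true_yield)
  ref_path <- file.path(out_dir, "ref.csv")
  utils::write.csv(ref, ref_path, row.names = FALSE)
  cfg <- list(
    samples = list(list(name = "a", scenario = "propyl_selective", seed = 11)),
    reference = ref_path
  )
  r <- run_pipeline(cfg)
  expect_s3_class(r$comparison, "qnmr_comparison")
  expect_lt(r$comparison$overall$mad, 0.3)
})
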