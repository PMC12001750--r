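# brute-force threshold oracle: try every candidate control score and apply
# the exceedance-budget rule directly
threshold_oracle <- function(scores, specificity) {
  allowed <- ceiling(length(scores) * (1 - specificity) - 1e-9)
  cand <- sort(unique(scores))
  for (t in cand) if (sum(scores > t) <= allowed) return(t)
  max(cand)
}

test_that("threshold calibration matches the brute-force oracle", {
  ctrl <- seq(0.1, 0.9, by = 0.1)
  expect_equal(suppressWarnings(calibrate_threshold(ctrl, 0.9)), 0.8)
  expect_equal(suppressWarnings(calibrate_threshold(ctrl, 1.0)), 0.9)
  expect_equal(suppressWarnings(calibrate_threshold(rep(0.4, 7), 0.99)), 0.4)
  set.seed(91)
  for (i in 1:20) {
    sc <- round(runif(sample(10:400, 1)), 3)
    sp <- sample(c(0.9, 0.95, 0.99, 0.995), 1)
    expect_equal(suppressWarnings(calibrate_threshold(sc, sp)),
                 threshold_oracle(sc, sp))
  }
  expect_error(calibrate_threshold(numeric(0), 0.99), "no control")
})

test_that("Wilson intervals reproduce published values and a quadratic oracle", {
  expect_equal(round(unlist(wilson_ci(9, 40)[c("lo", "hi")]), 1),
               c(lo = 12.3, hi = 37.5))
  expect_equal(round(unlist(wilson_ci(32, 32)[c("lo", "hi")]), 1),
               c(lo = 89.3, hi = 100))
  expect_equal(round(unlist(wilson_ci(30, 32)[c("lo", "hi")]), 1),
               c(lo = 79.9, hi = 98.3))

  # oracle: roots of the score-test quadratic
  # (p-hat - p)^2 = z^2 p (1-p) / n, solved with polyroot
  z <- 1.959964
  for (n in c(1:20, 40, 77, 200)) {
    for (k in unique(round(seq(0, n, length.out = 7)))) {
      ph <- k / n
      roots <- sort(Re(polyroot(c(ph^2, -2 * ph - z^2 / n, 1 + z^2 / n))))
      ci <- wilson_ci(k, n)
      expect_equal(ci$lo, 100 * roots[1], tolerance = 1e-10)
      expect_equal(ci$hi, 100 * roots[2], tolerance = 1e-10)
    }
  }
  expect_error(wilson_ci(5, 0), "positive")
  expect_error(wilson_ci(6, 5), "k must")
})

test_that("classification modes apply thresholds as documented", {
  sc <- tibble::tibble(sample_id = c("a", "b", "c"),
                       signal_score = c(0.78, 0.781, 0.784),
                       gas_score = c(0.5, 0.5, 0.5),
                       protein17_score = c(0.96, 0.955, 0.97))
  strict <- classify_scores(sc, eval_config(mode = "raw_strict"))
  expect_equal(strict$signal_positive, c(FALSE, TRUE, TRUE))
  printed <- classify_scores(sc, eval_config(mode = "printed_rounded"))
  # two-decimal rounding: 0.78 and 0.784 -> 0.78 >= 0.78; 0.781 -> 0.78 too
  expect_equal(printed$signal_positive, c(TRUE, TRUE, TRUE))
  expect_equal(printed$protein17_positive, c(TRUE, TRUE, TRUE))
  expect_equal(strict$protein17_positive, c(FALSE, FALSE, TRUE))
})

test_that("any-positive combination is a logical OR with missing as negative", {
  calls <- tibble::tibble(signal_positive = c(TRUE, FALSE, NA),
                          gas_positive = c(FALSE, FALSE, TRUE))
  expect_warning(comb <- combine_calls(calls, c("signal", "gas")), "missing")
  expect_equal(comb, c(TRUE, FALSE, TRUE))
  expect_equal(combine_calls(calls[2, ], "signal"), FALSE)
  expect_error(combine_calls(calls, character(0)), "at least one")
  expect_error(combine_calls(calls, "protein17"), "missing call")
})

test_that("OR-combination is monotone in the assay set", {
  set.seed(92)
  for (i in 1:20) {
    calls <- tibble::tibble(signal_positive = runif(50) < 0.3,
                            gas_positive = runif(50) < 0.3,
                            protein17_positive = runif(50) < 0.3)
    a <- combine_calls(calls, "signal")
    ab <- combine_calls(calls, c("signal", "gas"))
    abc <- combine_calls(calls, c("signal", "gas", "protein17"))
    expect_true(all(ab >= a))
    expect_true(all(abc >= ab))
  }
})

test_that("severity subgroups partition the cases 8/19/13 with stated priorities", {
  cases <- subgroup_partition(study_cases())
  expect_equal(as.vector(table(cases$subgroup)), c(8L, 19L, 13L))
  # high-grade dysplasia wins over size
  expect_equal(as.character(cases$subgroup[cases$sample_id == "AA12"]), "HGD")
  # low dysplasia at 1.6 cm falls in the 1-2 cm group
  expect_equal(as.character(cases$subgroup[cases$sample_id == "AA04"]), "1-2cm")
  small <- as_cohort_table(tibble::tibble(
    sample_id = "x", group = "case", size_cm = 0.5, histology = "tubular",
    dysplasia = "low", location = "cecum"))
  expect_error(subgroup_partition(small), "unassignable")
})

test_that("literature comparator expectations match the published arithmetic", {
  fit <- literature_comparator(c(HGD = 8, `>=2cm` = 19, `1-2cm` = 13),
                               c(50, 42.1, 23.1))
  expect_equal(fit$detected, c(4, 8, 3, 15))
  expect_equal(fit$sensitivity[4], 37.5)
  msdna <- literature_comparator(c(8, 19, 13), c(75, 68.4, 38.5))
  expect_equal(msdna$detected[4], 24)
  expect_equal(msdna$sensitivity[4], 60)
  zero <- literature_comparator(c(8, 19, 13), c(0, 0, 0))
  expect_equal(zero$detected[4], 0)
  expect_error(literature_comparator(c(8, 19), c(1, 2, 3)), "lengths differ")
})

test_that("reproducibility summarizes paired scores on the log scale", {
  pairs <- tibble::tibble(score1 = c(0.1, 0.4, 0.8, 0.95),
                          score2 = c(0.1, 0.4, 0.8, 0.95))
  rr <- reproducibility(pairs)
  expect_equal(rr$r, 1)
  set.seed(93)
  null_pairs <- tibble::tibble(score1 = runif(1000, 0.01, 0.99),
                               score2 = runif(1000, 0.01, 0.99))
  expect_lt(abs(reproducibility(null_pairs)$r), 0.1)
  expect_error(reproducibility(pairs[1:2, ]), "at least 3")
  flat <- tibble::tibble(score1 = rep(0.5, 5), score2 = runif(5))
  expect_error(reproducibility(flat), "zero variance")
})

test_that("evaluation report invariants hold", {
  res <- reproduce_study()
  rep <- tibble::as_tibble(res$report)
  own <- rep[!rep$methodology %in% c("FIT", "mt-sDNA", "mt-sDNA next-gen"), ]
  expect_true(all(own$detected <= own$n))
  expect_true(all(own$sens_lo <= own$sensitivity & own$sensitivity <= own$sens_hi))
  expect_true(all(own$spec_lo <= own$specificity & own$specificity <= own$spec_hi))
  expect_true(all(own$sens_lo >= 0 & own$sens_hi <= 100))
})

test_that("plot helpers return ggplot objects", {
  cases <- study_cases()
  cases$group <- "case"
  p1 <- plot_sorted_scores(cases, "signal_score", 0.78)
  expect_s3_class(p1, "ggplot")
  calls <- classify_scores(cases, eval_config())
  p2 <- plot_combination_contributions(calls)
  expect_s3_class(p2, "ggplot")
  p3 <- autoplot(reproduce_study()$report)
  expect_s3_class(p3, "ggplot")
})
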