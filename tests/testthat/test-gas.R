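test_that("arm profiles are depth-invariant fractions with sane control z-scores", {
  p2 <- amplicon_panel(tibble::tibble(
    amplicon_id = paste0("a", 1:4), chrom = c("1", "1", "2", "2"),
    arm = c("1p", "1p", "2q", "2q"), start = 1:4, insert_length = 100L
  ), drop_acrocentric_p = FALSE)
  m <- matrix(c(10, 10, 10, 10), 1, dimnames = list("s", paste0("a", 1:4)))
  ap <- arm_profile(count_matrix(m), p2)
  expect_equal(ap$fraction, c(0.5, 0.5))
  ap10 <- arm_profile(count_matrix(m * 10), p2)
  expect_equal(ap10$fraction, ap$fraction)

  cfg <- tiny_config(n_controls = 60, n_cancers = 0)
  sim <- gen_cohort(cfg, seed = 51)
  frac <- adenoscreen:::arm_fraction_matrix(
    sim$counts, setNames(sim$panel$arm, sim$panel$amplicon_id))
  ref <- list(mean = colMeans(frac), sd = apply(frac, 2, sd))
  te <- gen_cohort(tiny_config(n_controls = 30, n_cancers = 0), seed = 52,
                   world = sim$world)
  ap2 <- arm_profile(te$counts, sim$panel, ref = ref)
  expect_true(mean(abs(ap2$z) < 3) > 0.95)
})

test_that("in-silico aneuploid construction matches the copy-number formula", {
  cfg <- sim_config(n_arms = 4, amplicons_per_arm = 200, n_controls = 6,
                    n_cancers = 0)
  sim <- gen_cohort(cfg, seed = 53)
  sid <- rownames(sim$counts$counts)[1]
  v0 <- sim$counts$counts[sid, ]
  arm_of <- setNames(sim$panel$arm, sim$panel$amplicon_id)

  # tumor_fraction = 1, single-copy gain: arm propensity x1.5 before renorm
  set.seed(54)
  v1 <- make_insilico_aneuploid(sim$counts, sid, sim$panel, "1p",
                                gain = TRUE, tumor_fraction = 1)
  expect_equal(sum(v1), sum(v0))  # resampled to original depth
  f0 <- sum(v0[arm_of == "1p"]) / sum(v0)
  f1 <- sum(v1[arm_of == "1p"]) / sum(v1)
  expect_equal(f1, 1.5 * f0 / (1.5 * f0 + (1 - f0)), tolerance = 0.02)

  # tumor_fraction = 0 leaves the sample statistically unchanged
  set.seed(55)
  v2 <- make_insilico_aneuploid(sim$counts, sid, sim$panel, "1p",
                                gain = TRUE, tumor_fraction = 0)
  expect_equal(sum(v2[arm_of == "1p"]) / sum(v2), f0, tolerance = 0.02)

  expect_error(make_insilico_aneuploid(sim$counts, sid, sim$panel, "99z",
                                       tumor_fraction = 0.1), "unknown arm")
  expect_error(make_insilico_aneuploid(sim$counts, sid, sim$panel, "1p",
                                       tumor_fraction = 1.2), "tumor_fraction")
})

test_that("altered-arm z-scores rise above unaltered arms at modest tumor fraction", {
  cfg <- sim_config(n_arms = 6, amplicons_per_arm = 240, n_controls = 80,
                    n_cancers = 0)
  sim <- gen_cohort(cfg, seed = 56)
  arm_of <- setNames(sim$panel$arm, sim$panel$amplicon_id)
  frac <- adenoscreen:::arm_fraction_matrix(
    sim$counts, arm_of[colnames(sim$counts$counts)])
  ref <- list(mean = colMeans(frac), sd = apply(frac, 2, sd))
  te <- gen_cohort(sim_config(n_arms = 6, amplicons_per_arm = 240,
                              n_controls = 40, n_cancers = 0),
                   seed = 57, world = sim$world)
  set.seed(58)
  hits <- vapply(seq_len(80), function(i) {
    a <- sample(unique(sim$panel$arm), 1)
    v <- make_insilico_aneuploid(te$counts, rownames(te$counts$counts)[(i - 1) %% 40 + 1],
                                 sim$panel, a, gain = TRUE, tumor_fraction = 0.15)
    z <- (v_to_frac(v, arm_of) - ref$mean) / ref$sd
    abs(z[a]) > quantile(abs(z[names(z) != a]), 0.95)
  }, logical(1))
  expect_gt(mean(hits), 0.7)
})

test_that("GAS training calibrates specificity and detects multi-arm gains", {
  cfg <- sim_config(n_arms = 6, amplicons_per_arm = 240, n_controls = 120,
                    n_cancers = 0)
  sim <- gen_cohort(cfg, seed = 61)
  ins <- make_insilico_set(sim$counts, sim$panel, n = 120, seed = 62)
  gm <- suppressWarnings(train_gas(sim$counts, ins$counts, sim$panel, seed = 63))
  expect_true(gm$threshold >= 0 && gm$threshold <= 1)

  te <- gen_cohort(sim_config(n_arms = 6, amplicons_per_arm = 240,
                              n_controls = 250, n_cancers = 0),
                   seed = 64, world = sim$world)
  sc <- score_gas(gm, te$counts, sim$panel)
  expect_true(all(sc$gas_score >= 0 & sc$gas_score <= 1))
  expect_lte(mean(sc$gas_positive), 0.005 + 1.96 * sqrt(0.005 * 0.995 / 250) + 2 / 250)

  set.seed(65)
  m3 <- t(vapply(1:40, function(i)
    make_insilico_aneuploid(te$counts, rownames(te$counts$counts)[i], sim$panel,
                            arms = sample(unique(sim$panel$arm), 3),
                            gain = TRUE, tumor_fraction = 0.2),
    numeric(ncol(te$counts$counts))))
  rownames(m3) <- paste0("G", 1:40)
  sc3 <- score_gas(gm, count_matrix(m3, batch = "b"), sim$panel)
  expect_gte(mean(sc3$gas_positive), 0.9)
})

test_that("mean GAS is non-decreasing in tumor fraction", {
  cfg <- sim_config(n_arms = 6, amplicons_per_arm = 240, n_controls = 100,
                    n_cancers = 0)
  sim <- gen_cohort(cfg, seed = 66)
  ins <- make_insilico_set(sim$counts, sim$panel, n = 100, seed = 67)
  gm <- suppressWarnings(train_gas(sim$counts, ins$counts, sim$panel, seed = 68))
  te <- gen_cohort(sim_config(n_arms = 6, amplicons_per_arm = 240,
                              n_controls = 30, n_cancers = 0),
                   seed = 69, world = sim$world)
  set.seed(70)
  mean_gas <- vapply(c(0.02, 0.05, 0.1, 0.2), function(tf) {
    m <- t(vapply(1:30, function(i)
      make_insilico_aneuploid(te$counts, rownames(te$counts$counts)[i],
                              sim$panel, arms = c("1p", "3p", "5p"),
                              gain = TRUE, tumor_fraction = tf),
      numeric(ncol(te$counts$counts))))
    rownames(m) <- paste0("s", 1:30)
    mean(score_gas(gm, count_matrix(m, batch = "b"), sim$panel)$gas_score)
  }, numeric(1))
  expect_true(all(diff(mean_gas) > -0.05))
  expect_gt(mean_gas[4], mean_gas[1])
})
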