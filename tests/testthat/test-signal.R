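test_that("per-arm normalization is compositional and depth-invariant", {
  fx <- tiny_counts_fixture()
  panel <- amplicon_panel(fx$panel, drop_acrocentric_p = FALSE)
  m <- matrix(c(2, 3, 5), 1, dimnames = list("s", c("a1", "a2", "a3")))
  p1 <- amplicon_panel(tibble::tibble(
    amplicon_id = c("a1", "a2", "a3"), chrom = "1", arm = "1p",
    start = 1:3, insert_length = 100L
  ), drop_acrocentric_p = FALSE)
  n1 <- normalize_by_arm(count_matrix(m), p1)
  expect_equal(unname(n1[["1p"]][1, ]), c(0.2, 0.3, 0.5))

  rd <- read_counts(fx$counts_path, fx$panel_path)
  n2 <- normalize_by_arm(rd$counts, panel)
  expect_equal(sort(names(n2)), c("1p", "2q"))
  expect_true(all(abs(rowSums(n2[["1p"]]) - 1) < 1e-12))
  expect_true(all(abs(rowSums(n2[["2q"]]) - 1) < 1e-12))
  # scaling one sample's counts by 10 leaves its compositions unchanged
  m10 <- rd$counts$counts; m10["s1", ] <- m10["s1", ] * 10
  n3 <- normalize_by_arm(count_matrix(m10, batch = rd$counts$batch), panel)
  expect_equal(n3[["1p"]]["s1", ], n2[["1p"]]["s1", ])
  # a zero arm total is an informative error
  m0 <- rd$counts$counts; m0["s1", c("ampC", "ampD")] <- 0
  expect_error(normalize_by_arm(count_matrix(m0), panel), "s1.*arm 2q")
})

test_that("non-negative factorization recovers exact low-rank structure", {
  set.seed(1)
  # rank-1: outer product of positive vectors, k = 1
  w <- runif(12, 0.5, 2); h <- runif(9, 0.5, 2)
  V <- outer(w, h)
  fit <- adenoscreen:::nmf_fit(V, 1, seed = 2)
  expect_lt(fit$residual, 1e-6)
  expect_equal(colSums(fit$W), 1, tolerance = 1e-9, ignore_attr = TRUE)

  # k = 2 with disjoint supports: recovered signatures split the supports
  # (multiplicative updates converge slowly, so give them room)
  w1 <- c(runif(6, 0.5, 2), rep(0, 6)); w2 <- c(rep(0, 6), runif(6, 0.5, 2))
  # mixing weights include pure samples of each profile, so the
  # factorization is identifiable up to column order
  h1 <- c(runif(3, 0.5, 2), rep(0, 3), runif(3, 0.5, 2))
  h2 <- c(rep(0, 3), runif(6, 0.5, 2))
  V2 <- outer(w1, h1) + outer(w2, h2)
  fit2 <- adenoscreen:::nmf_fit(V2, 2, max_iter = 3000, tol = 1e-10, seed = 3)
  expect_lt(fit2$residual / sqrt(sum(V2^2)), 0.01)
  # after column matching, each signature concentrates on one support block
  top_block <- apply(fit2$W, 2, function(col) mean(col[1:6]) > mean(col[7:12]))
  expect_equal(sort(top_block), c(FALSE, TRUE), ignore_attr = TRUE)
  expect_error(adenoscreen:::nmf_fit(V, 20, seed = 1), "out of range")
})

test_that("signature columns are probability distributions", {
  cfg <- tiny_config()
  sim <- gen_cohort(cfg, seed = 31)
  norm <- normalize_by_arm(sim$counts, sim$panel)
  sig <- extract_signatures(norm, k = 2, seed = 32)
  for (W in sig$W) {
    expect_true(all(W >= 0))
    expect_equal(unname(colSums(W)), rep(1, ncol(W)), tolerance = 1e-9)
  }
  expect_error(extract_signatures(norm, k = 1000, seed = 1), "too large")
})

test_that("exposures are an NNLS refit with indicator recovery", {
  cfg <- tiny_config()
  sim <- gen_cohort(cfg, seed = 33)
  norm <- normalize_by_arm(sim$counts, sim$panel)
  sig <- extract_signatures(norm, k = 2, seed = 34)
  # a sample exactly equal to signature j gets an indicator exposure
  arm <- sig$arms[1]
  W <- sig$W[[arm]]
  fake <- lapply(sig$arms, function(a) {
    out <- matrix(sig$W[[a]][, 1], 1, dimnames = list("fake", rownames(sig$W[[a]])))
    out
  })
  names(fake) <- sig$arms
  ex <- exposures(sig, fake)
  expect_equal(unname(ex[1, paste0(arm, ".s1")]), 1, tolerance = 1e-6)
  expect_equal(unname(ex[1, paste0(arm, ".s2")]), 0, tolerance = 1e-6)
  # training exposures approximately reproduce the factorization's H
  V <- t(norm[[arm]])
  fit <- adenoscreen:::nmf_fit(V, 2, seed = 34)
  refit <- t(vapply(seq_len(ncol(V)), function(j)
    pracma::lsqnonneg(fit$W, V[, j])$x, numeric(2)))
  recon_nmf <- sqrt(sum((V - fit$W %*% fit$H)^2))
  recon_nnls <- sqrt(sum((V - fit$W %*% t(refit))^2))
  expect_lte(recon_nnls, recon_nmf * 1.001)  # NNLS is the per-column optimum
  # panel mismatch and all-zero samples are errors
  expect_error(exposures(sig, fake[1]), "arm set")
  zero <- fake; zero[[1]][1, ] <- 0
  expect_error(exposures(sig, zero), "all-zero")
})

test_that("batch-sensitive and low-count amplicons are filtered", {
  cfg <- tiny_config(n_controls = 24, n_cancers = 0, n_batches = 2)
  sim <- gen_cohort(cfg, seed = 41)
  m <- sim$counts$counts
  # amplicon 3 tripled in batch 2 only; amplicon 5 zeroed everywhere
  b2 <- sim$truth$batch == "batch2"
  m[b2, 3] <- m[b2, 3] * 3
  m[, 5] <- 0
  rep <- filter_amplicons(count_matrix(m, batch = sim$truth$batch))
  expect_true(colnames(m)[3] %in% attr(rep, "dropped"))
  expect_true(colnames(m)[5] %in% attr(rep, "dropped"))
  expect_equal(sort(c(attr(rep, "kept"), attr(rep, "dropped"))),
               sort(colnames(m)))
  expect_error(filter_amplicons(count_matrix(m, batch = "one")), ">= 2 batches")
})

test_that("filter false-drop rate under exchangeable batches is near q_max", {
  cfg <- sim_config(n_arms = 5, amplicons_per_arm = 200, n_controls = 30,
                    n_cancers = 0, n_batches = 2, batch_sd = 0, subject_sd = 0.1)
  sim <- gen_cohort(cfg, seed = 43)
  rep <- filter_amplicons(sim$counts, q_max = 0.05)
  frac_batch <- mean(rep$reason == "batch_effect", na.rm = TRUE)
  # BH on null p-values drops about q_max of amplicons at most; allow
  # binomial slack around [0, q_max]
  expect_lt(sum(rep$reason == "batch_effect", na.rm = TRUE),
            0.05 * nrow(rep) + 3 * sqrt(0.05 * nrow(rep)))
})

test_that("fragmentation-consistent selection finds the tilt and respects the null", {
  w <- small_signal_world()
  sig <- w$fit$signatures
  sel <- w$fit$selection
  expect_gt(sum(sel$selected), 0)
  # at least one short-centroid signature selected with case-elevated exposure
  expect_true(any(sel$selected & sel$short & sel$delta > 0))

  # label permutation: expected selections stay within the false-positive budget
  norm <- normalize_by_arm(w$sim$counts, w$sim$panel)
  ex <- exposures(sig, norm)
  set.seed(44)
  n_sel_perm <- vapply(1:5, function(i) {
    perm <- sample(w$sim$cohort$group == "cancer")
    sum(select_fragmentation_features(sig, w$sim$panel, ex, perm)$selected)
  }, numeric(1))
  expect_lt(mean(n_sel_perm), 2)

  # a single signature with no class difference selects nothing
  ex1 <- matrix(rep(1, 20), 10, 2, dimnames = list(NULL, colnames(ex)[1:2]))
  sig1 <- sig; sig1$W <- sig$W[1]; sig1$arms <- sig$arms[1]
  sel1 <- select_fragmentation_features(sig1, w$sim$panel, ex1,
                                        rep(c(TRUE, FALSE), 5))
  expect_equal(sum(sel1$selected), 0)
})

test_that("fragmentation score separates classes, stays in [0,1], is seed-deterministic", {
  w <- small_signal_world()
  sc <- score_signal(w$fit, w$sim$counts, w$sim$panel)
  is_case <- w$sim$cohort$group == "cancer"
  expect_true(all(sc$signal_score >= 0 & sc$signal_score <= 1))
  expect_gt(mean(sc$signal_score[is_case]), mean(sc$signal_score[!is_case]))

  fit2 <- suppressWarnings(signal_fit(w$sim$counts, w$sim$panel, is_case,
                                      k = 2, seed = 422))
  sc2 <- score_signal(fit2, w$sim$counts, w$sim$panel)
  expect_equal(sc2$signal_score, sc$signal_score, tolerance = 1e-12)
})

test_that("cross-validated dimension choice follows the plateau rule", {
  cfg <- sim_config(n_arms = 4, amplicons_per_arm = 80, n_controls = 60,
                    n_cancers = 40)
  sim <- gen_cohort(cfg, seed = 21)
  labels <- sim$cohort$group == "cancer"
  k1 <- choose_dimension(sim$counts, sim$panel, labels, k_grid = 2)
  expect_equal(as.integer(k1), 2L)
  k <- suppressWarnings(choose_dimension(sim$counts, sim$panel, labels,
                                         k_grid = 1:3, folds = 3, seed = 22))
  cv <- attr(k, "cv")
  expect_equal(nrow(cv), 3L)
  # generator signal lives in a low-dimensional tilt; plateau at 2 +/- 1
  expect_true(as.integer(k) %in% 1:3)
  expect_gte(max(cv$sensitivity), cv$sensitivity[cv$k == as.integer(k)])
})
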