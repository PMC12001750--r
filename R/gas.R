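# Global aneuploidy score: chromosome-arm representation features, in-silico
# aneuploid training samples derived from controls, and a calibrated
# Gaussian-kernel SVM score in [0, 1].

#' Per-arm representation profile of each sample
#'
#' Each sample's counts are collapsed to the fraction of total reads on
#' every chromosome arm (so the profile is depth-invariant). If reference
#' statistics are supplied (or computable from `controls`), per-arm
#' z-scores relative to the control population are added.
#'
#' @param counts A [count_matrix()].
#' @param panel Companion [amplicon_panel()].
#' @param ref Optional list with `mean` and `sd` named per-arm vectors, as
#'   stored in a `gas_model`; when `NULL` no z-scores are computed.
#' @return Tibble with `sample_id`, `arm`, `fraction` and (with a
#'   reference) `z`.
#' @export
arm_profile <- function(counts, panel, ref = NULL) {
  arm_of <- setNames(panel$arm, panel$amplicon_id)[colnames(counts$counts)]
  if (anyNA(arm_of)) abort("count matrix contains amplicons absent from the panel")
  arms <- sort(unique(panel$arm))
  if (!all(arm_of %in% arms)) abort("arm absent from panel")
  frac <- arm_fraction_matrix(counts, arm_of, arms)
  out <- tibble::as_tibble(frac, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "arm", values_to = "fraction")
  if (!is.null(ref)) {
    z <- sweep(sweep(frac[, names(ref$mean), drop = FALSE], 2, ref$mean), 2, ref$sd, "/")
    zl <- tibble::as_tibble(z, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "arm", values_to = "z")
    out <- dplyr::left_join(out, zl, by = c("sample_id", "arm"))
  }
  out
}

arm_fraction_matrix <- function(counts, arm_of = NULL, arms = NULL) {
  m <- counts$counts
  if (is.null(arm_of)) abort("arm assignment required")
  arms <- arms %||% sort(unique(arm_of))
  tot <- rowSums(m)
  if (any(tot == 0)) abort("sample with zero total count")
  frac <- vapply(arms, function(a) {
    rowSums(m[, arm_of == a, drop = FALSE]) / tot
  }, numeric(nrow(m)))
  if (nrow(m) == 1) frac <- matrix(frac, nrow = 1, dimnames = list(rownames(m), arms))
  frac
}

#' Generate an in-silico aneuploid sample from a control
#'
#' Counts on the altered arms are multiplied by `1 + tumor_fraction/2` for
#' a single-copy gain or `1 - tumor_fraction/2` for a single-copy loss (a
#' fraction `t` of the DNA carrying 3 or 1 copies instead of 2), then the
#' whole sample is multinomially re-sampled to its original depth so the
#' result is again an integer count vector at the same coverage.
#'
#' @param counts A [count_matrix()] (one or more control samples).
#' @param sample_id Which sample to perturb.
#' @param panel Companion [amplicon_panel()].
#' @param arms Character vector of arms to alter.
#' @param gain `TRUE` for gain, `FALSE` for loss (recycled over `arms`).
#' @param tumor_fraction Fraction of tumor-derived DNA in (0, 1].
#' @return Integer count vector (named by amplicon) for the synthetic
#'   aneuploid sample.
#' @export
make_insilico_aneuploid <- function(counts, sample_id, panel, arms,
                                    gain = TRUE, tumor_fraction) {
  if (tumor_fraction < 0 || tumor_fraction > 1) {
    abort("tumor_fraction must be in [0, 1]")
  }
  bad <- setdiff(arms, panel$arm)
  if (length(bad) > 0) abort(paste0("unknown arm(s): ", paste(bad, collapse = ", ")))
  v <- counts$counts[sample_id, ]
  arm_of <- setNames(panel$arm, panel$amplicon_id)[names(v)]
  gain <- rep_len(gain, length(arms))
  mult <- rep(1, length(v))
  for (i in seq_along(arms)) {
    f <- if (gain[i]) 1 + tumor_fraction / 2 else 1 - tumor_fraction / 2
    if (f <= 0) abort("loss multiplier must stay positive")
    mult[arm_of == arms[i]] <- f
  }
  p <- v * mult
  out <- as.vector(rmultinom(1, size = sum(v), prob = p / sum(p)))
  names(out) <- names(v)
  out
}

#' Build an in-silico aneuploid training set from controls
#'
#' Applies [make_insilico_aneuploid()] over a grid of tumor fractions,
#' altered-arm counts and gain/loss states, cycling through the supplied
#' control samples, to produce the aneuploid class used to train the
#' aneuploidy score.
#'
#' @param counts [count_matrix()] of euploid control samples.
#' @param panel Companion [amplicon_panel()].
#' @param n Number of in-silico samples to generate.
#' @param tumor_fractions Grid of tumor fractions to cycle through.
#' @param n_arms_range Range of the number of altered arms.
#' @param seed Integer seed.
#' @return List with `counts` (a [count_matrix()] of the synthetic
#'   aneuploid samples) and `truth` (tibble of altered arms, direction,
#'   tumor fraction, source sample).
#' @export
make_insilico_set <- function(counts, panel, n = 100,
                              tumor_fractions = c(0.01, 0.02, 0.05, 0.1, 0.2),
                              n_arms_range = c(1, 5), seed = 1L) {
  set.seed(seed)
  arms <- unique(panel$arm)
  src <- rep_len(rownames(counts$counts), n)
  tf <- rep_len(tumor_fractions, n)
  n_alt <- sample(seq(n_arms_range[1], min(n_arms_range[2], length(arms))),
                  n, replace = TRUE)
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    alt <- sample(arms, n_alt[i])
    gain <- sample(c(TRUE, FALSE), n_alt[i], replace = TRUE)
    rows[[i]] <- make_insilico_aneuploid(counts, src[i], panel, alt,
                                         gain = gain, tumor_fraction = tf[i])
    truth[[i]] <- tibble::tibble(
      sample_id = sprintf("IS%03d", i), source = src[i], tumor_fraction = tf[i],
      altered_arms = paste(alt, collapse = ","),
      gains = paste(as.integer(gain), collapse = ",")
    )
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("IS%03d", seq_len(n))
  list(counts = count_matrix(m, batch = "insilico", panel = panel),
       truth = dplyr::bind_rows(truth))
}

#' Train the global aneuploidy score
#'
#' Features are per-arm z-scores of arm fractions relative to the euploid
#' training controls. The SVM is trained on controls versus the union of
#' cancer samples and in-silico aneuploid samples, with Platt probability
#' calibration, and the positivity threshold is set at the training-control
#' quantile for the target specificity.
#'
#' @param control_counts [count_matrix()] of presumably euploid controls.
#' @param case_counts [count_matrix()] of cancer and/or in-silico
#'   aneuploid samples.
#' @param panel Companion [amplicon_panel()].
#' @param gamma,cost SVM hyperparameters.
#' @param specificity Threshold calibration target. Default 0.995.
#' @param seed Seed for the probability-calibration folds.
#' @return A `gas_model` (control arm means/SDs, fitted scorer, threshold).
#' @export
train_gas <- function(control_counts, case_counts, panel, gamma = NULL,
                      cost = 1, specificity = 0.995, seed = 1L) {
  arm_of <- setNames(panel$arm, panel$amplicon_id)
  arms <- sort(unique(panel$arm))
  fc <- arm_fraction_matrix(control_counts, arm_of[colnames(control_counts$counts)], arms)
  fa <- arm_fraction_matrix(case_counts, arm_of[colnames(case_counts$counts)], arms)
  ref <- list(mean = colMeans(fc), sd = apply(fc, 2, sd))
  ref$sd[ref$sd == 0] <- 1e-12
  zc <- sweep(sweep(fc, 2, ref$mean), 2, ref$sd, "/")
  za <- sweep(sweep(fa, 2, ref$mean), 2, ref$sd, "/")
  x <- rbind(zc, za)
  labels <- c(rep(FALSE, nrow(zc)), rep(TRUE, nrow(za)))
  scorer <- fit_svm_scorer(x, labels, gamma = gamma, cost = cost,
                           specificity = specificity, seed = seed)
  structure(list(ref = ref, arms = arms, scorer = scorer,
                 threshold = scorer$threshold, specificity = specificity),
            class = "gas_model")
}

#' @export
print.gas_model <- function(x, ...) {
  cat(sprintf("<gas_model> %d arms, threshold %.3f\n",
              length(x$arms), x$threshold))
  invisible(x)
}

#' Score samples with a fitted aneuploidy model
#'
#' @param model A `gas_model` from [train_gas()].
#' @param counts A [count_matrix()] of samples to score.
#' @param panel Their [amplicon_panel()].
#' @return Tibble with `sample_id`, `gas_score` in \[0, 1\] and
#'   `gas_positive` (score strictly above the threshold).
#' @export
score_gas <- function(model, counts, panel) {
  arm_of <- setNames(panel$arm, panel$amplicon_id)[colnames(counts$counts)]
  frac <- arm_fraction_matrix(counts, arm_of, model$arms)
  z <- sweep(sweep(frac, 2, model$ref$mean), 2, model$ref$sd, "/")
  s <- score_svm_scorer(model$scorer, z)
  tibble::tibble(
    sample_id = rownames(counts$counts),
    gas_score = s,
    gas_positive = s > model$threshold
  )
}
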