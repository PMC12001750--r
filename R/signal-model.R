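# Stages 3-4 of the fragmentation classifier: selection of signatures whose
# behaviour is consistent with increased cfDNA fragmentation in disease, a
# Gaussian-kernel SVM on the selected exposures, and the cross-validated
# choice of the number of signatures per arm.

as_case_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  tolower(as.character(labels)) %in% c("case", "cancer", "positive", "aa", "tumor")
}

#' Length centroid of each fragmentation signature
#'
#' The centroid is the signature-mass-weighted mean expected insert length
#' of its amplicons: a signature concentrated on short-insert amplicons (low
#' centroid) captures amplifiability from highly fragmented DNA.
#'
#' @param model A `signature_model`.
#' @param panel The [amplicon_panel()] the model was built on.
#' @return Tibble with `signature`, `arm`, `centroid_bp`.
#' @export
signature_centroids <- function(model, panel) {
  len <- setNames(panel$insert_length, panel$amplicon_id)
  purrr::imap_dfr(model$W, function(W, arm) {
    tibble::tibble(
      signature = colnames(W),
      arm = arm,
      centroid_bp = as.numeric(crossprod(W, len[rownames(W)]))
    )
  })
}

#' Select signatures consistent with tumor cfDNA fragmentation
#'
#' Disease plasma carries more fragmented cfDNA, so informative signatures
#' should pair a short length centroid with *higher* exposure in cases, or a
#' long centroid with *lower* exposure in cases. Each signature is tested
#' with a one-sided Wilcoxon rank-sum test in the direction implied by its
#' centroid relative to the panel median insert length; selections are those
#' with Benjamini-Hochberg q below `q_max`.
#'
#' @param model A `signature_model`.
#' @param panel The matching [amplicon_panel()].
#' @param expo Exposure matrix from [exposures()] (training samples).
#' @param labels Case/control labels aligned with the rows of `expo`.
#' @param q_max Selection q-value cutoff. Default 0.1.
#' @return Tibble with one row per signature (`signature`, `centroid_bp`,
#'   `short`, `delta` mean case-minus-control exposure, `p_value`,
#'   `q_value`, `selected`). The selected signature names are in attribute
#'   `selected`; the set may be empty.
#' @export
select_fragmentation_features <- function(model, panel, expo, labels, q_max = 0.1) {
  is_case <- as_case_label(labels)
  if (nrow(expo) != length(is_case)) abort("exposures and labels are not aligned")
  cent <- signature_centroids(model, panel)
  med_len <- median(panel$insert_length[panel$amplicon_id %in% unlist(model$amplicons)])
  res <- purrr::map_dfr(cent$signature, function(sig) {
    v <- expo[, sig]
    short <- cent$centroid_bp[cent$signature == sig] < med_len
    alt <- if (short) "greater" else "less"  # case exposure vs control
    p <- if (length(unique(v)) == 1) 1 else
      suppressWarnings(wilcox.test(v[is_case], v[!is_case], alternative = alt)$p.value)
    tibble::tibble(
      signature = sig,
      centroid_bp = cent$centroid_bp[cent$signature == sig],
      short = short,
      delta = mean(v[is_case]) - mean(v[!is_case]),
      p_value = p
    )
  })
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$selected <- res$q_value < q_max &
    ((res$short & res$delta > 0) | (!res$short & res$delta < 0))
  structure(res, selected = res$signature[res$selected],
            median_insert_bp = med_len)
}

#' Train the Gaussian-kernel SVM stage of the fragmentation score
#'
#' Features are standardized with training statistics (stored in the model)
#' and fed to a radial-kernel SVM with Platt sigmoid probability
#' calibration, yielding a score in \[0, 1\]. The positivity threshold is
#' calibrated on the training controls' scores at `specificity` (see
#' [calibrate_threshold()]).
#'
#' @param expo Numeric matrix of (selected) exposures, samples in rows.
#' @param labels Case/control labels aligned with `expo` rows.
#' @param gamma Kernel bandwidth; default `1/ncol(expo)`.
#' @param cost SVM cost parameter. Default 1.
#' @param specificity Target training specificity for the threshold.
#'   Default 0.995.
#' @param seed Seed for the internal probability-calibration folds.
#' @return An `svm_scorer` object (standardization stats, fitted SVM,
#'   threshold, training score table).
#' @export
train_signal <- function(expo, labels, gamma = NULL, cost = 1,
                         specificity = 0.995, seed = 1L) {
  fit_svm_scorer(expo, labels, gamma = gamma, cost = cost,
                 specificity = specificity, seed = seed)
}

# shared supervised scorer: standardize -> RBF SVM -> Platt probability,
# threshold at the training-control quantile for the target specificity
fit_svm_scorer <- function(x, labels, gamma = NULL, cost = 1,
                           specificity = 0.995, seed = 1L) {
  x <- as.matrix(x)
  is_case <- as_case_label(labels)
  if (length(unique(is_case)) < 2) abort("both classes are required for training")
  if (min(table(is_case)) < 5) abort("need at least 5 samples per class")
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1
  xs <- scale(x, center = center, scale = scale)
  y <- factor(ifelse(is_case, "case", "control"), levels = c("control", "case"))
  gamma <- gamma %||% (1 / ncol(xs)^2)
  set.seed(seed)
  fit <- e1071::svm(xs, y, kernel = "radial", gamma = gamma, cost = cost,
                    probability = TRUE, scale = FALSE)
  obj <- structure(list(
    center = center, scale = scale, feature_names = colnames(x),
    gamma = gamma, cost = cost, svm = fit, seed = seed,
    specificity = specificity
  ), class = "svm_scorer")
  train_scores <- score_svm_scorer(obj, x)
  obj$threshold <- calibrate_threshold(train_scores[!is_case], specificity)
  obj$train_scores <- tibble::tibble(
    sample_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    label = y, score = train_scores
  )
  obj
}

score_svm_scorer <- function(obj, x) {
  x <- as.matrix(x)
  if (!is.null(obj$feature_names)) {
    if (is.null(colnames(x))) {
      if (ncol(x) != length(obj$feature_names)) abort("feature dimension mismatch")
      colnames(x) <- obj$feature_names
    } else {
      missing_f <- setdiff(obj$feature_names, colnames(x))
      if (length(missing_f) > 0) {
        abort(paste0("missing feature(s): ", paste(missing_f, collapse = ", ")))
      }
      x <- x[, obj$feature_names, drop = FALSE]
    }
  }
  xs <- scale(x, center = obj$center, scale = obj$scale)
  if (is.null(obj$svm)) return(score_svm_raw(obj, xs))
  pred <- predict(obj$svm, xs, probability = TRUE)
  unname(attr(pred, "probabilities")[, "case"])
}

#' Fit the full fragmentation-score pipeline
#'
#' Runs the four stages end to end on a training cohort: optional
#' batch-effect amplicon filtering (pass a [filter_amplicons()] report, or
#' `NULL` to skip with a single batch), per-arm normalization, signature
#' extraction at dimension `k`, NNLS exposures, fragmentation-consistent
#' feature selection, and the calibrated Gaussian-kernel SVM.
#'
#' @param counts Training [count_matrix()].
#' @param panel Companion [amplicon_panel()].
#' @param labels Case/control labels for the training samples (in row
#'   order).
#' @param k Signatures per arm.
#' @param filter Optional `filter_report`; its dropped amplicons are
#'   removed before normalization.
#' @param q_max_select Feature-selection q cutoff (see
#'   [select_fragmentation_features()]).
#' @param gamma,cost SVM hyperparameters.
#' @param specificity Threshold calibration target. Default 0.995.
#' @param seed Integer seed controlling NMF initialization and SVM
#'   probability folds.
#' @return A `signal_model` object.
#' @export
signal_fit <- function(counts, panel, labels, k = 2, filter = NULL,
                       q_max_select = 0.1, gamma = NULL, cost = 1,
                       specificity = 0.995, seed = 1L) {
  keep <- colnames(counts$counts)
  if (!is.null(filter)) keep <- intersect(keep, attr(filter, "kept"))
  cm <- count_matrix(counts$counts[, keep, drop = FALSE], batch = counts$batch)
  panel_used <- panel[panel$amplicon_id %in% keep, ]
  norm <- normalize_by_arm(cm, panel_used)
  sig <- extract_signatures(norm, k = k, seed = seed)
  expo <- exposures(sig, norm)
  sel <- select_fragmentation_features(sig, panel_used, expo, labels,
                                       q_max = q_max_select)
  selected <- attr(sel, "selected")
  if (length(selected) == 0) {
    warn("no fragmentation-consistent signature passed selection; using all signatures")
    selected <- colnames(expo)
  }
  scorer <- fit_svm_scorer(expo[, selected, drop = FALSE], labels,
                           gamma = gamma, cost = cost,
                           specificity = specificity, seed = seed)
  structure(list(
    filter = filter, signatures = sig, panel = panel_used,
    selection = sel, selected = selected, scorer = scorer,
    threshold = scorer$threshold, specificity = specificity, seed = seed
  ), class = "signal_model")
}

#' @export
print.signal_model <- function(x, ...) {
  cat(sprintf(
    "<signal_model> %d arms x %d signatures, %d selected features, threshold %.3f\n",
    length(x$signatures$arms), x$signatures$k, length(x$selected), x$threshold
  ))
  invisible(x)
}

#' Score samples with a fitted fragmentation model
#'
#' New samples are restricted to the model's amplicons, normalized per arm,
#' projected onto the signatures by NNLS, and scored by the calibrated SVM.
#'
#' @param model A `signal_model` from [signal_fit()].
#' @param counts A [count_matrix()] of samples to score.
#' @param panel Their [amplicon_panel()].
#' @return Tibble with `sample_id`, `signal_score` in \[0, 1\] and
#'   `signal_positive` (score strictly above the model threshold).
#' @export
score_signal <- function(model, counts, panel) {
  keep <- unlist(model$signatures$amplicons)
  missing_a <- setdiff(keep, colnames(counts$counts))
  if (length(missing_a) > 0) {
    abort(paste0("samples lack model amplicons, e.g. ", missing_a[1]))
  }
  cm <- count_matrix(counts$counts[, keep, drop = FALSE], batch = counts$batch)
  norm <- normalize_by_arm(cm, model$panel)
  expo <- exposures(model$signatures, norm)
  s <- score_svm_scorer(model$scorer, expo[, model$selected, drop = FALSE])
  tibble::tibble(
    sample_id = rownames(counts$counts),
    signal_score = s,
    signal_positive = s > model$threshold
  )
}

#' Choose the number of signatures per arm by cross-validation
#'
#' For each candidate `k`, the pipeline (signature extraction, feature
#' selection, SVM) is refit on stratified training folds and out-of-fold
#' scores are pooled; sensitivity is read off at the threshold giving the
#' target specificity on pooled out-of-fold control scores. The chosen
#' dimension is the smallest `k` whose sensitivity is within `eps` of the
#' maximum over the grid (the "plateau" rule).
#'
#' @param counts,panel,labels Training data as in [signal_fit()].
#' @param k_grid Candidate dimensions. Default `1:4`.
#' @param folds Number of stratified folds. Default 5.
#' @param specificity Specificity at which sensitivity is read. Default
#'   0.995.
#' @param eps Plateau tolerance on sensitivity. Default 0.01.
#' @param seed Seed for fold assignment and refits.
#' @return Integer `k`; the per-`k` pooled sensitivities are in attribute
#'   `cv`, a tibble.
#' @export
choose_dimension <- function(counts, panel, labels, k_grid = 1:4, folds = 5,
                             specificity = 0.995, eps = 0.01, seed = 1L) {
  is_case <- as_case_label(labels)
  if (length(unique(is_case)) < 2) abort("labels must contain both classes")
  n <- nrow(counts$counts)
  if (sum(!is_case) < folds || sum(is_case) < folds) {
    abort("too few samples per class to build stratified folds")
  }
  set.seed(seed)
  fold_id <- integer(n)
  fold_id[is_case] <- sample(rep_len(seq_len(folds), sum(is_case)))
  fold_id[!is_case] <- sample(rep_len(seq_len(folds), sum(!is_case)))
  if (length(k_grid) == 1) {
    return(structure(as.integer(k_grid),
                     cv = tibble::tibble(k = as.integer(k_grid), sensitivity = NA_real_)))
  }
  sens <- purrr::map_dbl(k_grid, function(k) {
    oof <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- suppressWarnings(signal_fit(
        count_matrix(counts$counts[tr, , drop = FALSE], batch = counts$batch[tr]),
        panel, labels = is_case[tr], k = k, specificity = specificity,
        seed = seed
      ))
      oof[!tr] <- suppressWarnings(score_signal(
        fit,
        count_matrix(counts$counts[!tr, , drop = FALSE], batch = counts$batch[!tr]),
        panel
      )$signal_score)
    }
    thr <- calibrate_threshold(oof[!is_case], specificity)
    mean(oof[is_case] > thr)
  })
  cv <- tibble::tibble(k = as.integer(k_grid), sensitivity = sens)
  best <- max(sens)
  k_star <- as.integer(k_grid[which(sens >= best - eps)[1]])
  structure(k_star, cv = cv)
}
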