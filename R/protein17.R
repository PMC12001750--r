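# Protein-17 score: supervised score on the plasma levels of 17
# cancer-associated proteins, thresholded at a target specificity.

protein_feature_matrix <- function(proteins) {
  x <- as.matrix(proteins[PROTEIN17_ANALYTES])
  if (anyNA(x)) {
    # median fill: a missing analyte takes the column median
    for (j in seq_len(ncol(x))) {
      x[is.na(x[, j]), j] <- median(x[, j], na.rm = TRUE)
    }
  }
  rownames(x) <- proteins$sample_id
  log10(x + 1)
}

#' Train the 17-protein plasma score
#'
#' Analyte concentrations are transformed as `log10(x + 1)`, standardized
#' per analyte with training statistics, and classified with a
#' Gaussian-kernel SVM under Platt probability calibration; the positivity
#' threshold is the training-control score quantile at `specificity`.
#' Analyte columns are matched by name against the canonical order
#' ([protein17_analytes()]), so column order never affects scores.
#'
#' @param proteins A `protein_table` (see [read_proteins()]).
#' @param labels Case/control labels aligned with the rows.
#' @param gamma,cost SVM hyperparameters.
#' @param specificity Threshold calibration target. Default 0.995.
#' @param seed Seed for the probability-calibration folds.
#' @return A `protein_model`.
#' @export
train_protein17 <- function(proteins, labels, gamma = NULL, cost = 1,
                            specificity = 0.995, seed = 1L) {
  proteins <- as_protein_table(proteins)
  x <- protein_feature_matrix(proteins)
  scorer <- fit_svm_scorer(x, labels, gamma = gamma, cost = cost,
                           specificity = specificity, seed = seed)
  structure(list(analytes = PROTEIN17_ANALYTES, scorer = scorer,
                 threshold = scorer$threshold, specificity = specificity),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> 17 analytes, threshold %.3f\n", x$threshold))
  invisible(x)
}

#' Score samples with a fitted protein model
#'
#' @param model A `protein_model` from [train_protein17()].
#' @param proteins A `protein_table` of samples to score.
#' @return Tibble with `sample_id`, `protein17_score` in \[0, 1\] and
#'   `protein17_positive` (score strictly above the threshold).
#' @export
score_protein17 <- function(model, proteins) {
  proteins <- as_protein_table(proteins)
  s <- score_svm_scorer(model$scorer, protein_feature_matrix(proteins))
  tibble::tibble(
    sample_id = proteins$sample_id,
    protein17_score = s,
    protein17_positive = s > model$threshold
  )
}
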