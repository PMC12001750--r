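# JSON serialization of fitted models. The SVM is stored as its support
# vectors, dual coefficients, rho and Platt sigmoid parameters, and scoring
# from the serialized form re-implements the radial-kernel decision
# function, so a written model scores identically after reloading.

scorer_to_list <- function(obj) {
  fit <- obj$svm
  list(
    center = as.list(obj$center), scale = as.list(obj$scale),
    feature_names = obj$feature_names,
    gamma = obj$gamma, cost = obj$cost,
    threshold = obj$threshold, specificity = obj$specificity,
    sv = unname(as.matrix(fit$SV)),
    coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    probA = as.numeric(fit$probA), probB = as.numeric(fit$probB),
    first_label = fit$levels[fit$labels[1]]
  )
}

scorer_from_list <- function(x) {
  structure(list(
    center = unlist(x$center), scale = unlist(x$scale),
    feature_names = as.character(unlist(x$feature_names)),
    gamma = x$gamma, cost = x$cost,
    threshold = x$threshold, specificity = x$specificity,
    svm = NULL,
    raw = list(sv = as.matrix(x$sv),
               coefs = as.numeric(x$coefs), rho = x$rho,
               probA = x$probA, probB = x$probB,
               first_label = x$first_label)
  ), class = "svm_scorer")
}

# radial-kernel decision + Platt sigmoid, used when scoring a deserialized
# model (obj$svm is NULL, obj$raw holds the SVM internals)
score_svm_raw <- function(obj, xs) {
  r <- obj$raw
  sv <- r$sv
  d2 <- outer(rowSums(xs^2), rowSums(sv^2), "+") - 2 * xs %*% t(sv)
  dec <- exp(-obj$gamma * d2) %*% r$coefs - r$rho
  p_first <- 1 / (1 + exp(r$probA * dec + r$probB))
  p_case <- if (identical(r$first_label, "case")) p_first else 1 - p_first
  as.numeric(p_case)
}

#' Write a fitted model to JSON
#'
#' Serializes a `signal_model`, `gas_model` or `protein_model` (SVM
#' support vectors, Platt parameters, standardization statistics,
#' signatures / reference statistics, threshold) so it can be reloaded
#' with [read_model_json()] and score identically.
#'
#' @param model The fitted model.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  body <- if (inherits(model, "signal_model")) {
    list(
      type = "signal_model",
      scorer = scorer_to_list(model$scorer),
      selected = model$selected,
      k = model$signatures$k,
      arms = model$signatures$arms,
      W = lapply(model$signatures$W, function(w)
        list(amplicons = rownames(w), signatures = colnames(w), values = unname(w))),
      panel = as.data.frame(model$panel),
      threshold = model$threshold, specificity = model$specificity,
      seed = model$seed
    )
  } else if (inherits(model, "gas_model")) {
    list(
      type = "gas_model",
      scorer = scorer_to_list(model$scorer),
      arms = model$arms,
      ref_mean = as.list(model$ref$mean), ref_sd = as.list(model$ref$sd),
      threshold = model$threshold, specificity = model$specificity
    )
  } else if (inherits(model, "protein_model")) {
    list(
      type = "protein_model",
      scorer = scorer_to_list(model$scorer),
      analytes = model$analytes,
      threshold = model$threshold, specificity = model$specificity
    )
  } else {
    abort("unsupported model class")
  }
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model_json()]
#'
#' @param path JSON path.
#' @return The model object; its scorer uses the package's own
#'   radial-kernel implementation and reproduces the original scores.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$type, "signal_model") && !identical(x$type, "gas_model") &&
      !identical(x$type, "protein_model")) {
    abort(paste0("unknown model type: ", x$type %||% "<missing>"))
  }
  scorer <- scorer_from_list(x$scorer)
  if (identical(x$type, "signal_model")) {
    W <- lapply(x$W, function(w) {
      m <- as.matrix(w$values)
      dimnames(m) <- list(w$amplicons, w$signatures)
      m
    })
    arms <- unlist(x$arms)
    names(W) <- arms
    panel_df <- tibble::as_tibble(x$panel)
    structure(list(
      filter = NULL,
      signatures = structure(list(W = W, k = x$k, arms = arms,
                                  amplicons = lapply(W, rownames),
                                  meta = list()), class = "signature_model"),
      panel = amplicon_panel(panel_df, drop_acrocentric_p = FALSE),
      selection = NULL, selected = unlist(x$selected), scorer = scorer,
      threshold = x$threshold, specificity = x$specificity, seed = x$seed
    ), class = "signal_model")
  } else if (identical(x$type, "gas_model")) {
    structure(list(
      ref = list(mean = unlist(x$ref_mean), sd = unlist(x$ref_sd)),
      arms = unlist(x$arms), scorer = scorer,
      threshold = x$threshold, specificity = x$specificity
    ), class = "gas_model")
  } else if (identical(x$type, "protein_model")) {
    structure(list(
      analytes = unlist(x$analytes), scorer = scorer,
      threshold = x$threshold, specificity = x$specificity
    ), class = "protein_model")
  } else {
    abort(paste0("unknown model type: ", x$type %||% "<missing>"))
  }
}
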