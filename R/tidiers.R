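# broom-style tidiers and ggplot2 visualisations for the fitted objects.

#' @exportS3Method generics::tidy
tidy.signal_model <- function(x, ...) {
  sel <- x$selection
  if (is.null(sel)) {
    return(tibble::tibble(signature = x$selected, selected = TRUE))
  }
  tibble::as_tibble(sel)
}

#' @exportS3Method generics::glance
glance.signal_model <- function(x, ...) {
  tibble::tibble(
    k = x$signatures$k,
    n_arms = length(x$signatures$arms),
    n_selected = length(x$selected),
    threshold = x$threshold,
    specificity = x$specificity
  )
}

#' @exportS3Method generics::tidy
tidy.gas_model <- function(x, ...) {
  tibble::tibble(arm = x$arms,
                 control_mean = unname(x$ref$mean[x$arms]),
                 control_sd = unname(x$ref$sd[x$arms]))
}

#' @exportS3Method generics::glance
glance.gas_model <- function(x, ...) {
  tibble::tibble(n_arms = length(x$arms), threshold = x$threshold,
                 specificity = x$specificity)
}

#' @exportS3Method generics::tidy
tidy.protein_model <- function(x, ...) {
  tibble::tibble(analyte = x$analytes,
                 log_center = unname(x$scorer$center),
                 log_scale = unname(x$scorer$scale))
}

#' @exportS3Method generics::glance
glance.protein_model <- function(x, ...) {
  tibble::tibble(n_analytes = length(x$analytes), threshold = x$threshold,
                 specificity = x$specificity)
}

#' @exportS3Method generics::tidy
tidy.mutation_call <- function(x, ...) tibble::as_tibble(x$mutations)

#' @exportS3Method generics::glance
glance.mutation_call <- function(x, ...) {
  tibble::tibble(n_mutations = nrow(x$mutations), aggregate = x$aggregate,
                 p_value = x$p_value, positive = x$positive, alpha = x$alpha)
}

#' Sorted score strip plot for one assay
#'
#' Cases and controls sorted by score within group, with the positivity
#' threshold as a hatched line: the standard presentation of a calibrated
#' biomarker on a case-control cohort.
#'
#' @param scores Data frame with `sample_id`, the score column and a
#'   `group` column (`case` vs anything else).
#' @param score_col Name of the score column, e.g. `"signal_score"`.
#' @param threshold Positivity threshold to draw.
#' @return A ggplot object.
#' @export
plot_sorted_scores <- function(scores, score_col, threshold) {
  df <- tibble::as_tibble(scores) |>
    dplyr::mutate(status = ifelse(.data$group == "case", "case", "control")) |>
    dplyr::arrange(.data$status, dplyr::desc(.data[[score_col]])) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data[[score_col]],
                                   fill = .data$status)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(case = "#c0392b", control = "#2c6fbb")) +
    ggplot2::labs(x = NULL, y = score_col, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Cumulative detection contributions of the combined assays
#'
#' For the assay order given, shows how many cases each additional assay
#' adds to the any-positive combination.
#'
#' @param case_calls Output of [classify_scores()] on case scores.
#' @param assays Assay order. Default fragmentation, protein, aneuploidy.
#' @return A ggplot object.
#' @export
plot_combination_contributions <- function(case_calls,
                                           assays = c("signal", "protein17", "gas")) {
  cum <- purrr::map_int(seq_along(assays), function(i)
    sum(combine_calls(case_calls, assays[seq_len(i)])))
  df <- tibble::tibble(
    assay = factor(assays, levels = assays),
    added = diff(c(0L, cum)),
    cumulative = cum
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$assay, y = .data$cumulative)) +
    ggplot2::geom_col(fill = "#2c6fbb") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("+", .data$added)),
                       vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "cases detected (cumulative)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, subgroup = "all", ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$subgroup == !!subgroup)
  df$methodology <- factor(df$methodology, levels = unique(df$methodology))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$methodology, y = .data$sensitivity)) +
    ggplot2::geom_col(fill = "#2c6fbb") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$sens_lo, ymax = .data$sens_hi),
                           width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = sprintf("sensitivity (%%), %s", subgroup)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
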