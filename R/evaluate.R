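# Evaluation layer: specificity-calibrated thresholds, per-assay calls,
# any-positive combination, Wilson intervals, subgroup analysis and
# literature comparators.

# round half away from zero, to match printed percentages
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Calibrate a positivity threshold at a target specificity
#'
#' Returns the smallest observed control score `t` such that the number of
#' controls scoring strictly above `t` does not exceed the allowed
#' exceedance budget `ceiling(n * (1 - specificity))`. With
#' `specificity = 1` this is the control maximum.
#'
#' @param control_scores Numeric scores of control samples.
#' @param specificity Target specificity in (0, 1]. Default 0.995.
#' @return The threshold (a value of `control_scores`).
#' @export
calibrate_threshold <- function(control_scores, specificity = 0.995) {
  control_scores <- control_scores[!is.na(control_scores)]
  n <- length(control_scores)
  if (n == 0) abort("no control scores supplied")
  if (n < 1 / (1 - specificity + .Machine$double.eps)) {
    warn(sprintf(
      "only %d controls: the %.1f%% specificity quantile is coarsely estimated",
      n, 100 * specificity
    ))
  }
  allowed <- ceiling(n * (1 - specificity) - 1e-9)
  s <- sort(unique(control_scores))
  exceed <- vapply(s, function(t) sum(control_scores > t), integer(1))
  s[which(exceed <= allowed)[1]]
}

#' Wilson score confidence interval for a proportion
#'
#' The score-test inversion interval, without continuity correction, at
#' `z = 1.959964` for the default 95% level. Bounds are returned in
#' percent.
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param level Confidence level. Default 0.95.
#' @return Tibble with `estimate`, `lo`, `hi` (percent).
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (any(n <= 0)) abort("n must be positive")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n")
  z <- if (identical(level, 0.95)) 1.959964 else stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  tibble::tibble(
    estimate = 100 * p,
    lo = 100 * (centre - half) / denom,
    hi = 100 * (centre + half) / denom
  )
}

#' Evaluation configuration
#'
#' Bundles the per-assay positivity thresholds, the target specificity they
#' were calibrated at, the score-comparison mode and the confidence level.
#' `mode = "raw_strict"` calls a sample positive when its raw score is
#' strictly above the threshold (the operational rule). With scores
#' published to two decimals, rounded ties must count as positive to
#' reproduce printed counts, so `mode = "printed_rounded"` calls positive
#' when the two-decimal score is greater than or equal to the threshold.
#'
#' @param thresholds Named list with `signal`, `gas`, `protein17` in
#'   \[0, 1\]. Defaults are the published study thresholds 0.78, 0.71,
#'   0.96.
#' @param target_specificity Specificity the thresholds correspond to.
#' @param mode `"printed_rounded"` or `"raw_strict"`.
#' @param level Confidence level for intervals.
#' @return An `eval_config` list.
#' @export
eval_config <- function(thresholds = list(signal = 0.78, gas = 0.71, protein17 = 0.96),
                        target_specificity = 0.995,
                        mode = c("printed_rounded", "raw_strict"),
                        level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(all(unlist(thresholds) >= 0), all(unlist(thresholds) <= 1))
  structure(list(thresholds = thresholds, target_specificity = target_specificity,
                 mode = mode, level = level), class = "eval_config")
}

#' Apply per-assay thresholds to a score table
#'
#' @param scores Data frame with `sample_id` and any of `signal_score`,
#'   `gas_score`, `protein17_score` (missing scores yield `NA` calls).
#' @param config An [eval_config()].
#' @return The input tibble with `signal_positive`, `gas_positive`,
#'   `protein17_positive` logical columns appended (where the score column
#'   exists).
#' @export
classify_scores <- function(scores, config = eval_config()) {
  scores <- tibble::as_tibble(scores)
  call_one <- function(s, thr) {
    if (config$mode == "printed_rounded") round_half_away(s, 2) >= thr else s > thr
  }
  for (assay in c("signal", "gas", "protein17")) {
    col <- paste0(assay, "_score")
    if (col %in% names(scores)) {
      scores[[paste0(assay, "_positive")]] <-
        call_one(scores[[col]], config$thresholds[[assay]])
    }
  }
  scores
}

#' Combine assay calls under the any-positive rule
#'
#' A sample is combination-positive when at least one selected assay calls
#' it positive. Missing calls are treated as negative (with a warning), so
#' a sample lacking one assay can still be called by the others.
#'
#' @param calls Data frame with `<assay>_positive` logical columns (as
#'   produced by [classify_scores()]).
#' @param assays Character vector of assay names to combine, e.g.
#'   `c("signal", "protein17")`.
#' @return Logical vector of combined calls, one per row of `calls`.
#' @export
combine_calls <- function(calls, assays) {
  if (length(assays) == 0) abort("select at least one assay")
  cols <- paste0(assays, "_positive")
  missing_cols <- setdiff(cols, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0("missing call column(s): ", paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(calls[cols])
  if (anyNA(m)) {
    warn("missing assay calls treated as negative in combination")
    m[is.na(m)] <- FALSE
  }
  rowSums(m) > 0
}

#' Partition cases into mutually exclusive severity subgroups
#'
#' Cases are assigned, in priority order, to: `"HGD"` (high-grade
#' dysplasia, any size), `">=2cm"` (remaining cases with maximum dimension
#' at least 2.0 cm) and `"1-2cm"` (remaining cases with dimension in
#' \[1.0, 2.0) cm). The groups are disjoint and exhaustive over cases.
#'
#' @param cohort A `cohort_table` (see [read_cohort()]).
#' @return The case rows with a `subgroup` factor column appended.
#' @export
subgroup_partition <- function(cohort) {
  cases <- dplyr::filter(cohort, .data$group == "case")
  sub <- dplyr::case_when(
    !is.na(cases$dysplasia) & cases$dysplasia == "high" ~ "HGD",
    cases$size_cm >= 2 ~ ">=2cm",
    cases$size_cm >= 1 ~ "1-2cm",
    TRUE ~ NA_character_
  )
  if (anyNA(sub)) {
    abort(paste0("unassignable case(s): ",
                 paste(cases$sample_id[is.na(sub)], collapse = ", ")))
  }
  cases$subgroup <- factor(sub, levels = c("HGD", ">=2cm", "1-2cm"))
  cases
}

#' Expected detection by a literature comparator test
#'
#' Applies published per-subgroup sensitivities to the study's subgroup
#' sizes: the expected detected count in each subgroup is the rounded
#' product (half away from zero), and the overall sensitivity is the summed
#' count over the summed size.
#'
#' @param n Integer vector of subgroup sizes.
#' @param sensitivity Per-subgroup sensitivities in percent, same length.
#' @return Tibble with per-subgroup expected counts plus attributes; the
#'   last row is the overall total.
#' @export
literature_comparator <- function(n, sensitivity) {
  if (length(n) != length(sensitivity)) abort("n and sensitivity lengths differ")
  if (any(sensitivity < 0 | sensitivity > 100)) abort("sensitivities must be in [0, 100]")
  detected <- round_half_away(n * sensitivity / 100)
  n_all <- c(unname(n), sum(n))
  det_all <- c(unname(detected), sum(detected))
  tibble::tibble(
    subgroup = c(names(n) %||% paste0("group", seq_along(n)), "overall"),
    n = n_all,
    detected = det_all,
    sensitivity = round_half_away(100 * det_all / n_all, 1)
  )
}

#' Score reproducibility between duplicate aliquots
#'
#' Pearson correlation of paired scores on the log scale, with the
#' concordance of positivity calls at a threshold.
#'
#' @param pairs Data frame with numeric columns `score1` and `score2`, one
#'   row per duplicate pair (scores in (0, 1\]).
#' @param threshold Positivity threshold for the concordance counts.
#' @param floor Scores are floored at this value before taking logs (a
#'   score printed as 0.01 is the natural floor at two-decimal precision).
#' @return A `glance`-style one-row tibble: `r`, `p_value`, `n_pairs`,
#'   `concordant_positive`, `concordant_negative`, `discordant`.
#' @export
reproducibility <- function(pairs, threshold = 0.78, floor = 1e-3) {
  if (nrow(pairs) < 3) abort("need at least 3 duplicate pairs")
  s1 <- pmax(pairs$score1, floor)
  s2 <- pmax(pairs$score2, floor)
  if (var(s1) == 0 || var(s2) == 0) abort("zero variance in one replicate set")
  ct <- cor.test(log(s1), log(s2), method = "pearson")
  p1 <- pairs$score1 > threshold
  p2 <- pairs$score2 > threshold
  tibble::tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n_pairs = nrow(pairs),
    concordant_positive = sum(p1 & p2),
    concordant_negative = sum(!p1 & !p2),
    discordant = sum(p1 != p2)
  )
}

# Published per-subgroup sensitivities (percent) of the stool comparators,
# in subgroup order HGD / >=2cm / 1-2cm, with their specificities.
STOOL_COMPARATORS <- list(
  FIT = list(sens = c(HGD = 50, ">=2cm" = 42.1, "1-2cm" = 23.1), spec = 96),
  `mt-sDNA` = list(sens = c(HGD = 75, ">=2cm" = 68.4, "1-2cm" = 38.5), spec = 90),
  `mt-sDNA next-gen` = list(sens = c(HGD = 75, ">=2cm" = 68.4, "1-2cm" = 38.5), spec = 92.7)
)

#' Evaluate single assays and combinations on a scored cohort
#'
#' Builds the full performance table: for each assay combination, the
#' number detected and sensitivity (with Wilson CI) overall and within the
#' mutually exclusive severity subgroups, and the specificity (with Wilson
#' CI) from the control calls. Optionally appends literature stool-test
#' comparator rows computed with [literature_comparator()].
#'
#' @param case_scores Data frame of case scores: `sample_id`,
#'   `signal_score`, `gas_score`, `protein17_score`.
#' @param control_scores Same layout for controls.
#' @param cohort A `cohort_table` providing `dysplasia` and `size_cm` for
#'   the cases.
#' @param config An [eval_config()].
#' @param combos List of assay-name vectors to evaluate. Defaults to the
#'   three single assays, the three pairs and the triple.
#' @param comparators Append the FIT / mt-sDNA comparator rows? Default
#'   `TRUE`.
#' @return An `eval_report`: tidy tibble with one row per (methodology,
#'   subgroup): `methodology`, `subgroup`, `n`, `detected`, `sensitivity`,
#'   `sens_lo`, `sens_hi`, `fp`, `n_controls`, `specificity`, `spec_lo`,
#'   `spec_hi`.
#' @export
evaluate_assays <- function(case_scores, control_scores, cohort,
                            config = eval_config(),
                            combos = NULL, comparators = TRUE) {
  combos <- combos %||% list(
    "signal", "protein17", "gas",
    c("signal", "protein17"), c("signal", "gas"), c("protein17", "gas"),
    c("signal", "protein17", "gas")
  )
  cases <- subgroup_partition(cohort)
  case_calls <- classify_scores(case_scores, config)
  ctrl_calls <- classify_scores(control_scores, config)
  case_calls <- dplyr::left_join(case_calls, cases[c("sample_id", "subgroup")],
                                 by = "sample_id")
  if (anyNA(case_calls$subgroup)) abort("case scores include samples absent from the cohort")
  subgroups <- list(
    "all" = rep(TRUE, nrow(case_calls)),
    "HGD" = case_calls$subgroup == "HGD",
    ">=2cm" = case_calls$subgroup == ">=2cm",
    "1-2cm" = case_calls$subgroup == "1-2cm"
  )
  rows <- purrr::map_dfr(combos, function(assays) {
    label <- paste(assays, collapse = " + ")
    pos_case <- combine_calls(case_calls, assays)
    pos_ctrl <- combine_calls(ctrl_calls, assays)
    fp <- sum(pos_ctrl)
    n_ctrl <- length(pos_ctrl)
    spec_ci <- wilson_ci(n_ctrl - fp, n_ctrl, config$level)
    purrr::imap_dfr(subgroups, function(in_sub, sub_name) {
      n <- sum(in_sub)
      k <- sum(pos_case & in_sub)
      ci <- wilson_ci(k, n, config$level)
      tibble::tibble(
        methodology = label, subgroup = sub_name, n = n, detected = k,
        sensitivity = round_half_away(100 * k / n, 1),
        sens_lo = round_half_away(ci$lo, 1), sens_hi = round_half_away(ci$hi, 1),
        fp = fp, n_controls = n_ctrl,
        specificity = round_half_away(100 * (n_ctrl - fp) / n_ctrl, 1),
        spec_lo = round_half_away(spec_ci$lo, 1),
        spec_hi = round_half_away(spec_ci$hi, 1)
      )
    })
  })
  if (comparators) {
    sizes <- c(HGD = sum(subgroups$HGD), ">=2cm" = sum(subgroups$`>=2cm`),
               "1-2cm" = sum(subgroups$`1-2cm`))
    comp_rows <- purrr::imap_dfr(STOOL_COMPARATORS, function(cmp, label) {
      lc <- literature_comparator(sizes, cmp$sens)
      tibble::tibble(
        methodology = label,
        subgroup = c(names(sizes), "all")[match(lc$subgroup, c(names(sizes), "overall"))],
        n = lc$n, detected = lc$detected, sensitivity = lc$sensitivity,
        sens_lo = NA_real_, sens_hi = NA_real_,
        fp = NA_integer_, n_controls = NA_integer_,
        specificity = cmp$spec, spec_lo = NA_real_, spec_hi = NA_real_
      )
    })
    rows <- dplyr::bind_rows(rows, comp_rows)
  }
  structure(rows, config = config,
            class = c("eval_report", class(rows)))
}
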