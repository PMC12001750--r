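# Stage 1 of the fragmentation classifier: drop amplicons whose
# depth-normalized representation shifts between sequencing batches, plus a
# low-count floor. Run on training controls only, so batch differences are
# not confounded with disease.

#' Filter batch-sensitive and low-count amplicons
#'
#' Counts are depth-normalized per sample (divided by the sample total), and
#' each amplicon is tested for a batch effect with a Kruskal-Wallis test
#' across batch labels; p-values are Benjamini-Hochberg corrected. An
#' amplicon is dropped when its q-value falls below `q_max` or when its
#' median normalized count is below `floor_frac` of the panel-wide median
#' (a floor that also removes all-zero amplicons).
#'
#' @param counts A [count_matrix()] of training control samples with at
#'   least two batches of three or more samples each.
#' @param q_max Benjamini-Hochberg q-value below which an amplicon is
#'   considered batch-sensitive. Default 0.05.
#' @param floor_frac Low-count floor as a fraction of the median per-amplicon
#'   median normalized count. Default 0.1.
#' @return A `filter_report`: tibble with one row per amplicon
#'   (`amplicon_id`, `statistic`, `p_value`, `q_value`, `median_norm`,
#'   `kept`, `reason`), with attributes `kept` and `dropped` holding the id
#'   vectors.
#' @export
filter_amplicons <- function(counts, q_max = 0.05, floor_frac = 0.1) {
  stopifnot(inherits(counts, "count_matrix"))
  batches <- counts$batch
  tab <- table(batches)
  if (length(tab) < 2) {
    abort(paste0(
      "amplicon filtering needs >= 2 batches; with a single batch, skip ",
      "filtering explicitly (pass the full amplicon set downstream)"
    ))
  }
  if (any(tab < 3)) abort("every batch needs >= 3 control samples")
  m <- counts$counts
  norm <- m / rowSums(m)
  g <- factor(batches)
  stats_p <- apply(norm, 2, function(v) {
    if (all(v == v[1])) return(c(NA_real_, 1))  # constant amplicon: no batch signal
    kt <- suppressWarnings(kruskal.test(v, g))
    c(unname(kt$statistic), kt$p.value)
  })
  p <- stats_p[2, ]
  q <- p.adjust(p, method = "BH")
  med_norm <- apply(norm, 2, median)
  floor_val <- floor_frac * median(med_norm)
  batch_fail <- !is.na(q) & q < q_max
  floor_fail <- med_norm < floor_val
  kept <- !(batch_fail | floor_fail)
  report <- tibble::tibble(
    amplicon_id = colnames(m),
    statistic = stats_p[1, ],
    p_value = p,
    q_value = q,
    median_norm = med_norm,
    kept = kept,
    reason = dplyr::case_when(
      batch_fail & floor_fail ~ "batch_effect+low_count",
      batch_fail ~ "batch_effect",
      floor_fail ~ "low_count",
      TRUE ~ NA_character_
    )
  )
  structure(report,
            kept = report$amplicon_id[kept],
            dropped = report$amplicon_id[!kept],
            q_max = q_max, floor_frac = floor_frac,
            class = c("filter_report", class(report)))
}
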