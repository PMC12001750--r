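# Multi-well mutation-detection statistic: per-well mutant allele
# frequencies, an empirical background-noise model pooled from non-target
# variants and a no-cancer control run, per-mutation tail scores, and a
# Monte-Carlo p-value for the aggregate score.

#' Per-well and pooled mutant allele frequencies
#'
#' Wells with fewer than `min_depth` total reads are excluded (and
#' reported); for qualifying wells the MAF is `mutant_reads /
#' total_reads`, and the pooled MAF of a mutation is total mutant reads
#' over total reads across its qualifying wells.
#'
#' @param wells A `well_table` (see [read_wells()]).
#' @param min_depth Minimum well depth. Default 100.
#' @return List with `wells` (per-well tibble with `maf` and `qualified`)
#'   and `pooled` (per-mutation tibble with `n_wells`, `mutant_reads`,
#'   `total_reads`, `pooled_maf`). A mutation with no qualifying well is an
#'   error.
#' @export
compute_mafs <- function(wells, min_depth = 100) {
  wells <- tibble::as_tibble(wells)
  wells$qualified <- wells$total_reads >= min_depth
  wells$maf <- ifelse(wells$qualified, wells$mutant_reads / wells$total_reads, NA_real_)
  pooled <- wells |>
    dplyr::filter(.data$qualified) |>
    dplyr::group_by(.data$sample_id, .data$mutation_id) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      mutant_reads = sum(.data$mutant_reads),
      total_reads = sum(.data$total_reads),
      pooled_maf = sum(.data$mutant_reads) / sum(.data$total_reads),
      .groups = "drop"
    )
  dropped <- dplyr::anti_join(
    dplyr::distinct(wells, .data$sample_id, .data$mutation_id),
    pooled, by = c("sample_id", "mutation_id")
  )
  if (nrow(dropped) > 0) {
    abort(paste0("no well with depth >= ", min_depth, " for mutation(s): ",
                 paste(paste(dropped$sample_id, dropped$mutation_id, sep = "/"),
                       collapse = ", ")))
  }
  list(wells = wells, pooled = pooled)
}

#' Fit the background-noise model for the multi-well assay
#'
#' Pools well-level MAFs from two sources: non-target variants observed in
#' the patient's own amplicons, and all variants (targets included) in a
#' matched no-cancer control run. The empirical pool is the null
#' distribution used for tail probabilities; a beta distribution is also
#' fitted by the method of moments after adding a pseudo-count of
#' `0.5 / mean(total_reads)` to each MAF, as a smooth summary.
#'
#' @param nontarget_wells `well_table` rows with `is_target = FALSE` from
#'   the patient run (target rows are ignored with a message).
#' @param control_wells Optional `well_table` from the no-cancer control
#'   run; all its rows enter the pool.
#' @param min_depth Minimum well depth. Default 100.
#' @param min_pool Minimum pool size. Default 50.
#' @return A `noise_model`: list with `pool` (sorted well-level MAFs),
#'   `beta` (shape1, shape2), `pseudo`, `n_pool`.
#' @export
fit_background <- function(nontarget_wells, control_wells = NULL,
                           min_depth = 100, min_pool = 50) {
  nt <- tibble::as_tibble(nontarget_wells)
  nt <- nt[!nt$is_target, ]
  pool_tab <- dplyr::bind_rows(nt, if (!is.null(control_wells))
    tibble::as_tibble(control_wells))
  pool_tab <- pool_tab[pool_tab$total_reads >= min_depth, ]
  if (nrow(pool_tab) < min_pool) {
    abort(sprintf(
      "background pool has %d well-level MAFs (< %d); supply more non-target variants or a control run",
      nrow(pool_tab), min_pool
    ))
  }
  mafs <- pool_tab$mutant_reads / pool_tab$total_reads
  pseudo <- 0.5 / mean(pool_tab$total_reads)
  m <- mean(mafs + pseudo)
  v <- var(mafs + pseudo)
  beta_par <- if (is.na(v) || v <= 0 || v >= m * (1 - m)) {
    c(shape1 = NA_real_, shape2 = NA_real_)
  } else {
    a <- m * (m * (1 - m) / v - 1)
    c(shape1 = a, shape2 = a * (1 - m) / m)
  }
  structure(list(pool = sort(mafs), n_pool = length(mafs),
                 pooled_rate = sum(pool_tab$mutant_reads) / sum(pool_tab$total_reads),
                 beta = beta_par, pseudo = pseudo, min_depth = min_depth),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> pool of %d well MAFs, mean %.2e\n",
              x$n_pool, mean(x$pool)))
  invisible(x)
}

# add-one empirical upper-tail probability of each x under the sorted pool:
# (1 + #{pool >= x}) / (n + 1); never 0, and 1/(n+1) above the pool maximum
tail_prob <- function(x, noise) {
  n <- noise$n_pool
  n_lt <- findInterval(x, noise$pool, left.open = TRUE)  # pool values < x
  (1 + (n - n_lt)) / (n + 1)
}

#' Score a mutation against the background noise
#'
#' The score is the negative log of the add-one empirical upper-tail
#' probability of the observed pooled MAF under the noise pool, so a MAF at
#' the noise median scores about `-log(0.5)` and a MAF above every pooled
#' value scores `-log(1 / (n_pool + 1))`.
#'
#' @param observed_maf Numeric vector of pooled MAFs.
#' @param noise A `noise_model` from [fit_background()].
#' @return Numeric score(s), non-negative, increasing in the observed MAF.
#' @export
score_mutation <- function(observed_maf, noise) {
  -log(tail_prob(observed_maf, noise))
}

#' Aggregate mutation score and Monte-Carlo p-value for one sample
#'
#' Each mutation's score is the sum over its qualifying wells of the
#' negative log add-one tail probability of that well's MAF under the
#' noise pool (the per-well form of [score_mutation()]; summing over wells
#' is what makes the partitioned assay sensitive, and it keeps the
#' statistic nearly continuous even though background MAFs are heavily
#' zero-inflated). The sample's aggregate statistic is the sum of
#' per-mutation scores. Its null distribution is built by Monte Carlo: in
#' each replicate every well of every mutation redraws its MAF from the
#' noise pool and is scored identically. The p-value uses the add-one rule
#' `(1 + #null >= observed) / (n_null + 1)`; the sample is called
#' circulating-mutation positive when `p < alpha`.
#'
#' @param target_wells `well_table` rows for the sample's target mutations
#'   (those identified in the adenoma tissue).
#' @param noise A `noise_model`.
#' @param n_null Number of null replicates; at least 1000. Default 1e5.
#' @param alpha Positivity level. Default 0.01.
#' @param min_depth Minimum well depth. Default 100.
#' @param seed Integer seed for the null draws.
#' @return A `mutation_call`: list with `mutations` (per-mutation tibble
#'   with pooled MAF, positive-well count and score), `aggregate`,
#'   `p_value`, `positive`, `alpha`, `n_null`.
#' @export
aggregate_pvalue <- function(target_wells, noise, n_null = 1e5, alpha = 0.01,
                             min_depth = 100, seed = 1L) {
  if (n_null < 1000) abort("n_null below 1000 gives unusably coarse p-values")
  mafs <- compute_mafs(target_wells, min_depth = min_depth)
  pooled <- mafs$pooled
  if (nrow(pooled) == 0) abort("no target mutations to score")
  pos_wells <- mafs$wells |>
    dplyr::filter(.data$qualified) |>
    dplyr::group_by(.data$sample_id, .data$mutation_id) |>
    dplyr::summarise(positive_wells = sum(.data$mutant_reads > 0), .groups = "drop")
  pooled <- dplyr::left_join(pooled, pos_wells, by = c("sample_id", "mutation_id"))
  qwells <- mafs$wells[mafs$wells$qualified, ]
  key_q <- paste(qwells$sample_id, qwells$mutation_id)
  key_p <- paste(pooled$sample_id, pooled$mutation_id)
  qwells$well_score <- score_mutation(qwells$maf, noise)
  pooled$score <- vapply(key_p, function(k)
    sum(qwells$well_score[key_q == k]), numeric(1))
  aggregate <- sum(pooled$score)
  set.seed(seed)
  # null: every qualifying well redraws its mutant reads binomially at the
  # pool's aggregate background rate and its own observed depth, and is
  # scored through the same empirical tail map as the data, so observed
  # and null wells are exchangeable when all MAFs are background noise
  W_total <- nrow(qwells)
  null_maf <- matrix(
    rbinom(n_null * W_total, size = rep(qwells$total_reads, each = n_null),
           prob = noise$pooled_rate),
    n_null, W_total
  ) / matrix(rep(qwells$total_reads, each = n_null), n_null, W_total)
  null_agg <- rowSums(matrix(score_mutation(as.vector(null_maf), noise),
                             n_null, W_total))
  p <- (1 + sum(null_agg >= aggregate)) / (n_null + 1)
  structure(list(
    mutations = pooled,
    aggregate = aggregate,
    p_value = p,
    positive = p < alpha,
    alpha = alpha, n_null = n_null, seed = seed
  ), class = "mutation_call")
}

#' @export
print.mutation_call <- function(x, ...) {
  cat(sprintf("<mutation_call> %d mutation(s), aggregate %.2f, p = %.4g (%s)\n",
              nrow(x$mutations), x$aggregate, x$p_value,
              if (x$positive) "positive" else "negative"))
  invisible(x)
}

#' Call circulating mutations for every sample in a well table
#'
#' Convenience wrapper: for each sample, fits the background-noise model
#' from that sample's non-target variants plus the shared control run, then
#' computes the aggregate score and Monte-Carlo p-value from its target
#' mutations.
#'
#' @param wells `well_table` for the patient runs (targets and non-target
#'   variants).
#' @param control_wells Optional shared control-run `well_table`.
#' @inheritParams aggregate_pvalue
#' @return Tibble with one row per sample: `sample_id`, `n_mutations`,
#'   `aggregate`, `p_value`, `mutation_positive`.
#' @export
call_mutations <- function(wells, control_wells = NULL, n_null = 1e5,
                           alpha = 0.01, min_depth = 100, seed = 1L) {
  wells <- tibble::as_tibble(wells)
  purrr::map_dfr(unique(wells$sample_id), function(id) {
    w <- wells[wells$sample_id == id, ]
    noise <- fit_background(w[!w$is_target, ], control_wells,
                            min_depth = min_depth)
    call <- aggregate_pvalue(w[w$is_target, ], noise, n_null = n_null,
                             alpha = alpha, min_depth = min_depth, seed = seed)
    tibble::tibble(
      sample_id = id,
      n_mutations = nrow(call$mutations),
      aggregate = call$aggregate,
      p_value = call$p_value,
      mutation_positive = call$positive
    )
  })
}
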