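# Stage 2 of the fragmentation classifier: per-arm normalization and
# non-negative factorization of the count matrices into fragmentation
# signatures (distributions over amplicons), plus non-negative projection of
# samples onto the signatures.

#' Normalize counts within each chromosome arm
#'
#' For every chromosome arm, each sample's amplicon counts are divided by
#' that sample's total count on the arm, so per-arm profiles are
#' compositions (rows sum to 1) and the result is invariant to sequencing
#' depth.
#'
#' @param counts A [count_matrix()].
#' @param panel The companion [amplicon_panel()]; every amplicon in
#'   `counts` must be assigned to an arm.
#' @return A named list (one element per arm, arms in sorted order) of
#'   samples-by-amplicons matrices of arm fractions.
#' @export
normalize_by_arm <- function(counts, panel) {
  stopifnot(inherits(counts, "count_matrix"))
  arm_of <- setNames(panel$arm, panel$amplicon_id)[colnames(counts$counts)]
  if (anyNA(arm_of)) abort("count matrix contains amplicons absent from the panel")
  arms <- sort(unique(arm_of))
  out <- lapply(arms, function(a) {
    sub <- counts$counts[, arm_of == a, drop = FALSE]
    tot <- rowSums(sub)
    if (any(tot == 0)) {
      bad <- rownames(sub)[which(tot == 0)[1]]
      abort(paste0("sample ", bad, " has zero total count on arm ", a))
    }
    sub / tot
  })
  names(out) <- arms
  out
}

# NNDSVD-style deterministic initialization for NMF: leading SVD factor
# pairs split into their positive parts; zeros filled with a small seeded
# uniform jitter so multiplicative updates can move them.
nmf_init <- function(V, k, seed) {
  sv <- svd(V, nu = k, nv = k)
  W <- matrix(0, nrow(V), k)
  H <- matrix(0, k, ncol(V))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_p <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      n_n <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (n_p >= n_n && n_p > 0) {
        W[, j] <- sqrt(sv$d[j] * n_p) * up / sqrt(sum(up^2))
        H[j, ] <- sqrt(sv$d[j] * n_p) * vp / sqrt(sum(vp^2))
      } else if (n_n > 0) {
        W[, j] <- sqrt(sv$d[j] * n_n) * un / sqrt(sum(un^2))
        H[j, ] <- sqrt(sv$d[j] * n_n) * vn / sqrt(sum(vn^2))
      }
    }
  }
  eps <- mean(V) * 1e-4
  withr_seed <- .Random.seed_exists()
  set.seed(seed)
  W[W <= 0] <- eps * runif(sum(W <= 0))
  H[H <= 0] <- eps * runif(sum(H <= 0))
  if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, envir = globalenv())
  list(W = W, H = H)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

# Frobenius-loss NMF by multiplicative updates. V (non-negative,
# features x samples) ~ W %*% H with W >= 0, H >= 0.
nmf_fit <- function(V, k, max_iter = 500, tol = 1e-6, seed = 1L) {
  if (k < 1 || k > min(dim(V))) {
    abort(sprintf("k = %d out of range for a %d x %d matrix", k, nrow(V), ncol(V)))
  }
  init <- nmf_init(V, k, seed)
  W <- init$W; H <- init$H
  eps <- .Machine$double.eps
  err_prev <- Inf
  iter_used <- max_iter
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(err_prev) && abs(err_prev - err) <= tol * max(err_prev, eps)) {
        iter_used <- it
        break
      }
      err_prev <- err
    }
  }
  # rescale so signature columns are probability distributions over features
  s <- colSums(W)
  s[s == 0] <- 1
  W <- sweep(W, 2, s, "/")
  H <- sweep(H, 1, s, "*")
  list(W = W, H = H, iterations = iter_used,
       residual = sqrt(sum((V - W %*% H)^2)))
}

#' Extract fragmentation signatures by per-arm non-negative factorization
#'
#' Each arm's normalized samples-by-amplicons matrix is factorized (amplicons
#' by samples orientation) into `k` non-negative signatures: columns of the
#' arm's factor matrix, rescaled to sum to 1 so each signature is a
#' distribution over the arm's amplicons. Factorization minimizes Frobenius
#' loss by multiplicative updates from a deterministic SVD-based
#' initialization, so results are reproducible given `seed`.
#'
#' @param norm_arms Output of [normalize_by_arm()].
#' @param k Number of signatures per arm (the same `k` is used on every
#'   arm; see [choose_dimension()]).
#' @param max_iter,tol Update iteration cap and relative convergence
#'   tolerance on the Frobenius residual.
#' @param seed Integer seed for the initialization jitter.
#' @return A `signature_model`: list with `W` (named list of
#'   amplicons-by-k matrices), `k`, `arms`, `amplicons` (per-arm id lists)
#'   and `meta` (iterations, residuals, tol, seed).
#' @export
extract_signatures <- function(norm_arms, k, max_iter = 500, tol = 1e-6, seed = 1L) {
  fits <- purrr::imap(norm_arms, function(mat, arm) {
    if (k > min(ncol(mat), nrow(mat))) {
      abort(sprintf("k = %d too large for arm %s (%d amplicons, %d samples)",
                    k, arm, ncol(mat), nrow(mat)))
    }
    fit <- nmf_fit(t(mat), k, max_iter = max_iter, tol = tol, seed = seed)
    rownames(fit$W) <- colnames(mat)
    colnames(fit$W) <- paste0(arm, ".s", seq_len(k))
    fit
  })
  structure(list(
    W = purrr::map(fits, "W"),
    k = k,
    arms = names(norm_arms),
    amplicons = purrr::map(norm_arms, colnames),
    meta = list(
      iterations = purrr::map_int(fits, "iterations"),
      residual = purrr::map_dbl(fits, "residual"),
      max_iter = max_iter, tol = tol, seed = seed
    )
  ), class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d arms x %d signatures/arm\n",
              length(x$arms), x$k))
  invisible(x)
}

#' Project samples onto fragmentation signatures
#'
#' Computes non-negative least-squares exposures of each sample's per-arm
#' composition onto the arm's signatures, concatenated over arms in the
#' model's fixed arm order. The same projection is used at train and score
#' time, so training exposures are an NNLS refit rather than the
#' factorization's own mixing matrix.
#'
#' @param model A `signature_model` from [extract_signatures()].
#' @param norm_arms Output of [normalize_by_arm()] on the same panel (same
#'   arms and amplicons).
#' @return A samples-by-(arms x k) matrix of non-negative exposures, columns
#'   named `<arm>.s<j>`.
#' @export
exposures <- function(model, norm_arms) {
  if (!setequal(names(norm_arms), model$arms)) {
    abort("arm set does not match the signature model (panel mismatch)")
  }
  blocks <- lapply(model$arms, function(arm) {
    W <- model$W[[arm]]
    mat <- norm_arms[[arm]]
    if (!identical(colnames(mat), rownames(W))) {
      if (!setequal(colnames(mat), rownames(W))) {
        abort(paste0("amplicon set mismatch on arm ", arm))
      }
      mat <- mat[, rownames(W), drop = FALSE]
    }
    if (any(rowSums(mat) == 0)) abort(paste0("all-zero sample profile on arm ", arm))
    res <- vapply(seq_len(nrow(mat)),
                  function(i) pracma::lsqnonneg(W, mat[i, ])$x,
                  numeric(ncol(W)))
    if (is.null(dim(res))) res <- matrix(res, nrow = 1)  # k = 1
    t(res)
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(model$arms, function(a) colnames(model$W[[a]])))
  rownames(out) <- rownames(norm_arms[[1]])
  out
}
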