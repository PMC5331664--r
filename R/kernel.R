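# Core string-kernel computations.
#
# The sequence kernel K3(S,T) sums, over k = 1..p with
# p = min(k_max, |S|, |T|), the k-mer kernel K3^k(S,T): the sum over all
# contiguous (gap-free) k-mer pairs of the product of per-position
# amino-acid kernel values K1. The correlation kernel normalises K3 by the
# geometric mean of the self-kernels, and D = sqrt(2 - 2*Khat) is a metric
# bounded by sqrt(2).

#' Kernel parameters
#'
#' Bundles the amino-acid kernel `K1`, the Hadamard exponent `beta` and the
#' k-mer truncation `k_max`. If `matrix` has not had a Hadamard power
#' applied yet (`beta_applied == "none"`), `beta` is applied here;
#' otherwise the matrix is used as-is and `beta` must be left at its
#' default.
#'
#' @param matrix Odds-ratio matrix (e.g. [default_ratio_matrix()],
#'   [identity_ratio_matrix()], [ones_ratio_matrix()] or the result of
#'   [from_log_odds()]).
#' @param beta Strictly positive Hadamard exponent; the recommended
#'   default is 0.2.
#' @param k_max Maximum k-mer length included in the sum; the recommended
#'   default is 10.
#' @return Object of class `seqkernel_params`.
#' @export
#' @examples
#' p <- kernel_params(default_ratio_matrix(), beta = 0.2, k_max = 10)
kernel_params <- function(matrix = default_ratio_matrix(), beta = 0.2,
                          k_max = 10L) {
  if (!is.numeric(k_max) || length(k_max) != 1L || k_max < 1 ||
      k_max != round(k_max)) {
    stop("k_max must be a positive integer", call. = FALSE)
  }
  applied <- attr(matrix, "beta_applied")
  if (identical(applied, "none")) {
    K1 <- hadamard_power(matrix, beta)
  } else {
    K1 <- matrix
    beta <- applied
  }
  structure(list(K1 = unclass(K1), beta = beta, k_max = as.integer(k_max),
                 alphabet = rownames(K1)),
            class = "seqkernel_params")
}

#' @export
print.seqkernel_params <- function(x, ...) {
  cat("seqkernel params: beta = ", format(x$beta), ", k_max = ", x$k_max,
      ", alphabet size ", length(x$alphabet), "\n", sep = "")
  invisible(x)
}

.as_indices <- function(s) {
  if (is.character(s) && length(s) == 1L) s <- encode_residues(s)
  s <- as.integer(s)
  if (length(s) < 1L) stop("sequence must be non-empty", call. = FALSE)
  s
}

#' k-mer kernel: product of per-position amino-acid kernel values
#'
#' For two k-mers `u`, `v` of equal length, returns
#' `prod(K1(u_i, v_i))`. Gap-free by construction.
#'
#' @param u,v Integer vectors of residue indices (or single residue
#'   strings), equal length.
#' @param params [kernel_params()] object.
#' @return Scalar kernel value.
#' @export
k2 <- function(u, v, params) {
  u <- .as_indices(u)
  v <- .as_indices(v)
  if (length(u) != length(v)) {
    stop("k-mers must have equal length", call. = FALSE)
  }
  prod(params$K1[cbind(u, v)])
}

#' Summed sequence kernel, brute-force reference implementation
#'
#' Enumerates, for each k up to `p = min(k_max, n, m)`, all
#' `(n-k+1)(m-k+1)` contiguous k-mer pairs and sums their [k2()] values.
#' Cost `O(n m k_max^2)`; retained as the independent oracle against which
#' the efficient recursion [k3_recursive()] is verified.
#'
#' @param S,T Integer vectors of residue indices (or residue strings).
#' @param params [kernel_params()] object.
#' @return List with `k3` (total) and `k3_by_k` (per-k breakdown).
#' @export
k3_naive <- function(S, T, params) {
  S <- .as_indices(S)
  T <- .as_indices(T)
  n <- length(S)
  m <- length(T)
  p <- min(params$k_max, n, m)
  K1 <- params$K1
  by_k <- numeric(p)
  for (k in seq_len(p)) {
    acc <- 0
    for (i in seq_len(n - k + 1L)) {
      u <- S[i:(i + k - 1L)]
      for (j in seq_len(m - k + 1L)) {
        v <- T[j:(j + k - 1L)]
        acc <- acc + prod(K1[cbind(u, v)])
      }
    }
    by_k[k] <- acc
  }
  list(k3 = sum(by_k), k3_by_k = by_k)
}

#' Summed sequence kernel via the layered recursion
#'
#' Uses the convolution identity
#' `K2^k(u, v) = K2^(k-1)(u', v') * K1(u_k, v_k)` to build, layer by
#' layer, the matrix `M_k(i, j)` of k-mer kernel values for k-mers starting
#' at positions i and j; each layer is an elementwise shift-multiply of the
#' previous one, so the total cost is `O(n m k_max)`. At most two layers
#' are held at once. Agrees with [k3_naive()] to relative 1e-9.
#'
#' @inheritParams k3_naive
#' @return List with `k3` (total) and `k3_by_k` (per-k breakdown).
#' @export
k3_recursive <- function(S, T, params) {
  S <- .as_indices(S)
  T <- .as_indices(T)
  n <- length(S)
  m <- length(T)
  p <- min(params$k_max, n, m)
  M1 <- params$K1[S, T, drop = FALSE]
  by_k <- numeric(p)
  Mk <- M1
  by_k[1L] <- sum(Mk)
  if (p >= 2L) {
    for (k in 2:p) {
      Mk <- Mk[seq_len(n - k + 1L), seq_len(m - k + 1L), drop = FALSE] *
        M1[k:n, k:m, drop = FALSE]
      by_k[k] <- sum(Mk)
    }
  }
  if (!all(is.finite(by_k))) {
    stop("kernel accumulation overflowed to a non-finite value; ",
         "use a smaller beta or k_max", call. = FALSE)
  }
  list(k3 = sum(by_k), k3_by_k = by_k)
}

#' Correlation kernel between two sequences
#'
#' `Khat(S,T) = K3(S,T) / sqrt(K3(S,S) K3(T,T))`, so that
#' `Khat(S,S) = 1` exactly. Round-off excursions in `(1, 1 + 1e-9]` are
#' clamped to 1; larger excursions indicate a broken kernel upstream and
#' raise an error. With the identity matrix and sequences sharing no
#' residues the value 0 is returned with attribute `zero_overlap = TRUE`.
#'
#' @inheritParams k3_naive
#' @return Scalar in `[0, 1]`.
#' @export
correlation_kernel <- function(S, T, params) {
  S <- .as_indices(S)
  T <- .as_indices(T)
  kss <- k3_recursive(S, S, params)$k3
  ktt <- k3_recursive(T, T, params)$k3
  if (kss <= 0 || ktt <= 0) {
    stop("zero self-kernel; the amino-acid matrix assigns no weight to ",
         "exact matches", call. = FALSE)
  }
  kst <- k3_recursive(S, T, params)$k3
  .normalize_khat(kst / sqrt(kss * ktt))
}

.normalize_khat <- function(khat) {
  if (khat > 1 + 1e-9) {
    stop("correlation kernel value ", format(khat),
         " exceeds 1 beyond round-off; upstream kernel is invalid",
         call. = FALSE)
  }
  if (khat > 1) khat <- 1
  if (khat == 0) attr(khat, "zero_overlap") <- TRUE
  khat
}

#' Kernel-induced distance
#'
#' `D = sqrt(2 - 2 Khat)`; a metric taking values in `[0, sqrt(2)]` for
#' non-negative correlation kernels, with `D(S,S) = 0`.
#'
#' @param khat Correlation kernel value(s) in `[-1, 1]`.
#' @return Distance value(s).
#' @export
kernel_distance <- function(khat) {
  khat <- as.numeric(khat)
  if (any(khat > 1 + 1e-9)) {
    stop("correlation kernel exceeds 1; broken kernel upstream",
         call. = FALSE)
  }
  khat <- pmin(khat, 1)
  sqrt(pmax(2 - 2 * khat, 0))
}

#' Closed-form semi-kernel for the all-ones matrix
#'
#' With the all-ones amino-acid matrix every k-mer kernel value is 1, so
#' the summed kernel depends only on the sequence lengths:
#' `sum_{k=1}^{min(k_max, n, m)} (n - k + 1)(m - k + 1)`. Used as the
#' analytic reference for the degenerate beta-to-zero regime, in which the
#' kernel captures only length differences.
#'
#' @param n,m Sequence lengths.
#' @param k_max Maximum k-mer length.
#' @return Scalar value.
#' @export
limit_semikernel <- function(n, m, k_max) {
  stopifnot(n >= 1, m >= 1, k_max >= 1)
  k <- seq_len(min(k_max, n, m))
  sum((n - k + 1) * (m - k + 1))
}

#' All-vs-all similarity or distance matrix
#'
#' Computes the correlation kernel (or its induced distance) for every
#' pair in a sequence set. Self-kernels are computed once per sequence and
#' reused.
#'
#' @param seqs [protein_seqs()] object (or named list of index vectors).
#' @param params [kernel_params()] object.
#' @param output `"similarity"` (correlation kernel, unit diagonal) or
#'   `"distance"` (kernel distance, zero diagonal).
#' @return Symmetric numeric matrix with sequence ids as dimnames and
#'   attribute `type` set to `output`.
#' @export
pairwise_matrix <- function(seqs, params = kernel_params(),
                            output = c("similarity", "distance")) {
  output <- match.arg(output)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequences must carry unique ids", call. = FALSE)
  }
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  seqs <- lapply(seqs, .as_indices)
  n <- length(seqs)
  selfs <- vapply(seqs, function(s) k3_recursive(s, s, params)$k3,
                  numeric(1))
  if (any(selfs <= 0)) {
    stop("zero self-kernel for sequence '", ids[which(selfs <= 0)[1L]],
         "'", call. = FALSE)
  }
  sim <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      kst <- k3_recursive(seqs[[i]], seqs[[j]], params)$k3
      sim[i, j] <- sim[j, i] <-
        as.numeric(.normalize_khat(kst / sqrt(selfs[i] * selfs[j])))
    }
  }
  dimnames(sim) <- list(ids, ids)
  out <- if (output == "similarity") sim else {
    d <- kernel_distance(sim)
    dim(d) <- dim(sim)
    dimnames(d) <- dimnames(sim)
    diag(d) <- 0
    d
  }
  attr(out, "type") <- output
  out
}
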