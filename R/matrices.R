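#' @importFrom stats runif rbinom
NULL

# ---- internal helpers -------------------------------------------------------

.check_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  invisible(m)
}

.matrix_alphabet <- function(m) {
  if (!is.null(rownames(m))) return(rownames(m))
  if (nrow(m) == 20L) return(aa_alphabet())
  LETTERS[seq_len(nrow(m))]
}

.check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  asym <- max(abs(m - t(m)))
  scale <- max(abs(m), 1)
  if (asym > tol * scale) {
    stop(what, " is not symmetric (max asymmetry ", format(asym), ")",
         call. = FALSE)
  }
  invisible(m)
}

.ratio_matrix <- function(values, alphabet, beta_applied = "none") {
  dimnames(values) <- list(alphabet, alphabet)
  structure(values, beta_applied = beta_applied)
}

# ---- operations -------------------------------------------------------------

#' Normalise a substitution count matrix into an odds-ratio matrix
#'
#' Converts raw substitution counts `SM(i,j)` into the odds-ratio matrix
#' `SM2(i,j) = SM(i,j) / (P(i) P(j))`, where `P(i)` is the i-th row sum.
#' `SM2` is the un-logged counterpart of a BLOSUM-style log-odds matrix and
#' is the input from which the amino-acid kernel is built (see
#' [hadamard_power()]).
#'
#' @param counts Square symmetric matrix of non-negative substitution
#'   counts, rows/columns in alphabet order (dimnames used if present).
#' @param tol Relative symmetry tolerance.
#' @return Odds-ratio matrix with attribute `beta_applied = "none"`.
#' @export
#' @examples
#' normalize_counts(matrix(c(2, 1, 1, 2), 2, 2,
#'                         dimnames = list(c("A", "C"), c("A", "C"))))
normalize_counts <- function(counts, tol = 1e-8) {
  .check_square(counts, "count matrix")
  .check_symmetric(counts, tol, "count matrix")
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  alphabet <- .matrix_alphabet(counts)
  P <- rowSums(counts)
  if (any(P <= 0)) {
    stop("zero row sum for residue '", alphabet[which(P <= 0)[1L]], "'",
         call. = FALSE)
  }
  .ratio_matrix(counts / outer(P, P), alphabet)
}

#' Entrywise (Hadamard) power of an odds-ratio matrix
#'
#' Raises every entry of the odds-ratio matrix to the power `beta`, giving
#' the amino-acid kernel `K1(i,j) = SM2(i,j)^beta`. `beta` must be strictly
#' positive for the result to remain a kernel.
#'
#' @param ratio Odds-ratio matrix from [normalize_counts()],
#'   [from_log_odds()], [identity_ratio_matrix()] or [ones_ratio_matrix()],
#'   with `beta_applied = "none"`.
#' @param beta Strictly positive exponent.
#' @return Matrix with attribute `beta_applied = beta`.
#' @export
hadamard_power <- function(ratio, beta) {
  .check_square(ratio, "ratio matrix")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0) {
    stop("beta must be strictly positive", call. = FALSE)
  }
  if (!identical(attr(ratio, "beta_applied"), "none")) {
    stop("a Hadamard power has already been applied (beta_applied = ",
         format(attr(ratio, "beta_applied")), ")", call. = FALSE)
  }
  if (any(ratio < 0)) stop("ratio matrix has negative entries", call. = FALSE)
  .ratio_matrix(unclass(ratio)^beta, .matrix_alphabet(ratio),
                beta_applied = beta)
}

#' Check positive definiteness of a symmetric matrix
#'
#' Diagnostic used to verify that a candidate amino-acid kernel matrix is a
#' valid Gram matrix. A matrix passes when its smallest eigenvalue exceeds
#' `tol` times its largest eigenvalue, so positive-semidefinite matrices
#' with a (numerically) zero eigenvalue — such as the all-ones matrix that
#' arises in the beta-to-zero limit — are reported as *not* definite.
#'
#' @param m Square symmetric matrix.
#' @param tol Relative eigenvalue tolerance.
#' @return List with elements `positive_definite` (logical),
#'   `min_eigenvalue`, `max_eigenvalue` and `tol`.
#' @export
check_positive_definite <- function(m, tol = 1e-8) {
  .check_square(m)
  .check_symmetric(m, what = "matrix")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev)
  hi <- max(ev)
  list(positive_definite = lo > tol * max(abs(hi), .Machine$double.eps),
       min_eigenvalue = lo, max_eigenvalue = hi, tol = tol)
}

#' Back-transform an integer log-odds matrix to an odds-ratio matrix
#'
#' NCBI-style matrices such as BLOSUM62 store `round(log2(SM2(i,j)))`; this
#' inverts the transform as `base^BL(i,j)`. Because the stored values were
#' rounded to integers, the result only approximates the original
#' odds-ratio matrix; a warning says so, and a positive-definiteness report
#' is attached as attribute `pd_report`.
#'
#' @param int_matrix Square symmetric matrix of integer log-odds scores.
#' @param base Logarithm base used by the matrix (2 for BLOSUM).
#' @return Odds-ratio matrix with `beta_applied = "none"` and attribute
#'   `pd_report` from [check_positive_definite()].
#' @export
from_log_odds <- function(int_matrix, base = 2) {
  .check_square(int_matrix, "log-odds matrix")
  .check_symmetric(int_matrix, what = "log-odds matrix")
  if (max(abs(int_matrix - round(int_matrix))) > 1e-8) {
    stop("log-odds matrix must be integer-valued", call. = FALSE)
  }
  warning("back-transformed log-odds scores were rounded to integers; ",
          "the result only approximates the original odds-ratio matrix",
          call. = FALSE)
  out <- .ratio_matrix(base^unclass(int_matrix), .matrix_alphabet(int_matrix))
  attr(out, "pd_report") <- check_positive_definite(out)
  out
}

#' Identity amino-acid matrix
#'
#' The identity matrix as a substitution kernel: exact residue matches
#' score 1, everything else 0. It is invariant under any Hadamard power,
#' and with it the summed sequence kernel counts exactly matching k-mer
#' pairs.
#'
#' @param alphabet Ordered alphabet letters.
#' @return Ratio matrix with `beta_applied = "none"`.
#' @export
identity_ratio_matrix <- function(alphabet = aa_alphabet()) {
  .ratio_matrix(diag(length(alphabet)), alphabet)
}

#' All-ones amino-acid matrix (degenerate beta-to-zero limit)
#'
#' As beta tends to zero every entry of the amino-acid kernel tends to 1.
#' The all-ones matrix is *not* positive definite (rank 1), so it is not a
#' kernel, but it is useful as a diagnostic: with it the summed sequence
#' kernel depends only on sequence lengths (see [limit_semikernel()]).
#'
#' @param alphabet Ordered alphabet letters.
#' @return Ratio matrix with `beta_applied = "none"`.
#' @export
ones_ratio_matrix <- function(alphabet = aa_alphabet()) {
  n <- length(alphabet)
  .ratio_matrix(matrix(1, n, n), alphabet)
}

# ---- packaged fixture -------------------------------------------------------

#' Synthetic substitution count matrix (packaged fixture)
#'
#' A deterministic, synthetic 20x20 BLOSUM-style raw-count matrix. It is
#' built as `round(crossprod(A)/50) + 3000 I` for a fixed positive integer
#' matrix `A`, so it is symmetric, strictly positive and positive definite
#' by construction (the diagonal boost dominates the rounding
#' perturbation); since the row-sum normalisation of [normalize_counts()]
#' is a congruence by a positive diagonal matrix, the resulting odds-ratio
#' matrix inherits positive definiteness. The diagonal boost is sized so
#' that the odds-ratio matrix is strongly diagonally dominant
#' (diagonal-to-off-diagonal odds around 50), the qualitative signature of
#' real BLOSUM odds-ratio matrices. The fixture stands in for unpublished
#' alignment-derived counts and is clearly synthetic: use
#' [from_log_odds()] with a real BLOSUM matrix for analyses of real
#' proteins.
#'
#' @return Integer count matrix with amino-acid dimnames.
#' @export
toy_count_matrix <- function() {
  a <- aa_alphabet()
  # fixed pseudo-random positive integers; no RNG so the fixture is stable
  v <- (seq_len(400) * 7919L) %% 23L + 1L
  A <- matrix(v, 20L, 20L)
  counts <- round(crossprod(A) / 50) + diag(3000L, 20L)
  dimnames(counts) <- list(a, a)
  storage.mode(counts) <- "integer"
  counts
}

#' Default packaged odds-ratio matrix
#'
#' Row-sum normalisation of [toy_count_matrix()]; the matrix used by
#' default throughout the package when no substitution matrix is supplied.
#'
#' @return Odds-ratio matrix with `beta_applied = "none"`.
#' @export
default_ratio_matrix <- function() {
  normalize_counts(toy_count_matrix())
}

# ---- matrix file I/O --------------------------------------------------------

#' Write an odds-ratio (or count) matrix as a plain table
#'
#' One header line with the alphabet letters, then one whitespace-separated
#' row per residue.
#'
#' @param m Square matrix with alphabet dimnames.
#' @param path Output file path.
#' @export
write_ratio_matrix <- function(m, path) {
  .check_square(m)
  alphabet <- .matrix_alphabet(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(alphabet, collapse = " "), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(format(m[i, ], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read a matrix written by [write_ratio_matrix()]
#'
#' @param path File path.
#' @return Ratio matrix with `beta_applied = "none"`.
#' @export
read_ratio_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  alphabet <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  n <- length(alphabet)
  if (length(lines) < n + 1L) {
    stop("matrix file has fewer rows than alphabet letters", call. = FALSE)
  }
  rows <- lapply(lines[2:(n + 1L)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  if (any(lengths(rows) != n)) {
    stop("matrix rows must have one value per alphabet letter", call. = FALSE)
  }
  m <- do.call(rbind, rows)
  .ratio_matrix(m, alphabet)
}

#' Read an NCBI-format substitution matrix file
#'
#' Parses the whitespace-separated format used to distribute BLOSUM/PAM
#' matrices: comment lines start with `#`, a header row lists the column
#' letters, and each following row starts with its residue letter. Columns
#' and rows for ambiguity codes (B, Z, X, J, U, O, `*`) are dropped with a
#' message. The returned matrix holds the integer log-odds scores,
#' reordered to the standard alphabet; pass it to [from_log_odds()] to
#' recover an approximate odds-ratio matrix.
#'
#' @param path File path.
#' @return Integer matrix with amino-acid dimnames.
#' @export
read_ncbi_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not an NCBI matrix file", call. = FALSE)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  row_letters <- vapply(rows, `[[`, "", 1L)
  vals <- lapply(rows, function(r) as.numeric(r[-1L]))
  if (any(lengths(vals) != length(header))) {
    stop("malformed NCBI matrix: row length does not match header",
         call. = FALSE)
  }
  m <- do.call(rbind, vals)
  dimnames(m) <- list(row_letters, header)
  extra <- setdiff(union(header, row_letters), aa_alphabet())
  if (length(extra)) {
    message("ignoring non-standard matrix columns/rows: ",
            paste(extra, collapse = ", "))
  }
  keep <- aa_alphabet()
  missing <- setdiff(keep, intersect(row_letters, header))
  if (length(missing)) {
    stop("matrix file lacks standard residues: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- m[keep, keep]
  storage.mode(out) <- "integer"
  out
}
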