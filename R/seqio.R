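# File input/output: FASTA sequences, group labels, pairwise matrices,
# PHYLIP square distance matrices, and externally computed pair scores.

#' Read protein sequences from a FASTA file
#'
#' Identifiers are taken from the header up to the first whitespace;
#' residues are uppercased before encoding.
#'
#' @param path FASTA file path.
#' @param policy Residue policy, see [encode_residues()].
#' @return [protein_seqs()] object.
#' @export
read_fasta <- function(path, policy = c("strict", "map")) {
  policy <- match.arg(policy)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    stop("FASTA file '", path, "' contains no sequences", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  x <- as.character(aa)
  names(x) <- ids
  protein_seqs(x, policy = policy)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs [protein_seqs()] object.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  alphabet <- attr(seqs, "alphabet")
  if (is.null(alphabet)) alphabet <- aa_alphabet()
  chr <- vapply(seqs, decode_residues, "", alphabet = alphabet)
  aa <- Biostrings::AAStringSet(chr)
  names(aa) <- names(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a two-column group-label table
#'
#' Tab- or whitespace-separated file with one `id label` pair per line;
#' lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Named character vector mapping id to group label.
#' @export
read_groups <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed group line ", bad[1L], " in '", path, "'",
         call. = FALSE)
  }
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate ids in group table", call. = FALSE)
  }
  stats::setNames(vapply(parts, `[[`, "", 2L), ids)
}

#' Write a group-label table
#'
#' @param groups Named character vector (id to label).
#' @param path Output path.
#' @export
write_groups <- function(groups, path) {
  writeLines(paste(names(groups), groups, sep = "\t"), path)
  invisible(path)
}

#' Write a pairwise matrix as a tab-separated table
#'
#' @param m Square matrix with id dimnames.
#' @param path Output path.
#' @export
write_pair_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pairwise matrix written by [write_pair_matrix()]
#'
#' @param path File path.
#' @return Square numeric matrix with id dimnames.
#' @export
read_pair_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Write a distance matrix in PHYLIP square format
#'
#' Classic dialect consumed by distance-based tree programs such as Fitch:
#' first line is the sequence count; each row is the name padded (or
#' truncated) to exactly 10 characters followed by the full row of
#' distances printed with 6 decimals.
#'
#' @param m Square distance matrix (zero diagonal) with id dimnames.
#' @param path Output path.
#' @export
write_phylip_distance <- function(m, path) {
  .check_square(m, "distance matrix")
  if (any(abs(diag(m)) > 1e-12)) {
    stop("PHYLIP export requires a distance matrix with zero diagonal",
         call. = FALSE)
  }
  ids <- rownames(m)
  if (is.null(ids)) stop("distance matrix must have id dimnames",
                         call. = FALSE)
  short <- substr(ids, 1L, 10L)
  if (anyDuplicated(short)) {
    stop("ids collide after truncation to 10 characters: ",
         paste(unique(short[duplicated(short)]), collapse = ", "),
         call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(formatC(short[i], width = -10L),
                      paste(sprintf("%.6f", m[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Reads the dialect written by [write_phylip_distance()] (one row per
#' line, 10-character name field).
#'
#' @param path File path.
#' @return Square numeric matrix with names as dimnames.
#' @export
read_phylip_distance <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L) {
    stop("not a PHYLIP square distance file", call. = FALSE)
  }
  ids <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- lines[i + 1L]
    ids[i] <- trimws(substr(row, 1L, 10L))
    vals <- as.numeric(strsplit(trimws(substring(row, 11L)), "\\s+")[[1]])
    if (length(vals) != n) {
      stop("row ", i, " has ", length(vals), " values, expected ", n,
           call. = FALSE)
    }
    m[i, ] <- vals
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Rescale a distance matrix to the unit interval
#'
#' Divides every off-diagonal entry by the maximum entry so that all
#' distances range between 0 and 1 — the preprocessing applied before
#' building trees from distance matrices of different scales. Idempotent.
#'
#' @param m Square distance matrix (zero diagonal).
#' @return Rescaled matrix with maximum entry exactly 1.
#' @export
rescale_distances <- function(m) {
  .check_square(m, "distance matrix")
  mx <- max(m)
  if (mx <= 0) stop("all distances are zero; nothing to rescale",
                    call. = FALSE)
  out <- m / mx
  diag(out) <- 0
  attr(out, "type") <- attr(m, "type")
  out
}

#' Read a three-column pair-score table
#'
#' Ingests externally computed per-pair scores (for example structural
#' alignment SAS values) as lines `idA idB score`. Pairs are unordered:
#' `(a,b)` and `(b,a)` refer to the same pair and must carry the same
#' score. A header line is skipped if its third field is not numeric.
#'
#' @param path File path.
#' @return Data frame with columns `id1`, `id2` (canonically ordered so
#'   `id1 <= id2`) and `score`, one row per unordered pair.
#' @export
read_score_table <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lnos <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  if (length(parts) && length(parts[[1]]) == 3L &&
      is.na(suppressWarnings(as.numeric(parts[[1]][3L])))) {
    parts <- parts[-1L]
    lnos <- lnos[-1L]
  }
  if (!length(parts)) stop("score table is empty", call. = FALSE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed score-table row at line ", lnos[bad[1L]],
         call. = FALSE)
  }
  id1 <- vapply(parts, `[[`, "", 1L)
  id2 <- vapply(parts, `[[`, "", 2L)
  score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(score)) {
    stop("non-numeric score at line ", lnos[which(is.na(score))[1L]],
         call. = FALSE)
  }
  swap <- id1 > id2
  tmp <- id1[swap]
  id1[swap] <- id2[swap]
  id2[swap] <- tmp
  key <- paste(id1, id2, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    s <- score[key == k]
    if (max(s) - min(s) > 1e-12) {
      stop("conflicting scores for pair (",
           sub("\r", ", ", k), ")", call. = FALSE)
    }
  }
  first <- !duplicated(key)
  data.frame(id1 = id1[first], id2 = id2[first], score = score[first],
             stringsAsFactors = FALSE)
}
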