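#' The standard amino-acid alphabet
#'
#' The twenty standard one-letter amino-acid codes in fixed alphabetical
#' order (`ACDEFGHIKLMNPQRSTVWY`). This ordering is used for every matrix
#' the package builds or writes, and is recorded in the header of matrix
#' files so that downstream readers can verify it.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Conservative fallbacks for ambiguity / rare codes under the "map" policy.
# X is never mapped: any numeric stand-in would silently bias the kernel.
.nonstandard_map <- c(B = "D", Z = "E", J = "L", U = "C", O = "K")

#' Encode a residue string as alphabet indices
#'
#' @param x Single character string of one-letter residue codes (any case).
#' @param id Sequence identifier, used in error messages.
#' @param policy `"strict"` errors on any residue outside the 20-letter
#'   alphabet; `"map"` first substitutes B>D, Z>E, J>L, U>C, O>K. `X` is
#'   always an error under both policies.
#' @param alphabet Ordered alphabet letters (default [aa_alphabet()]).
#' @return Integer vector of 1-based positions in `alphabet`.
#' @export
encode_residues <- function(x, id = "<sequence>",
                            policy = c("strict", "map"),
                            alphabet = aa_alphabet()) {
  policy <- match.arg(policy)
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  if (length(chars) < 1L) {
    stop("sequence '", id, "' is empty", call. = FALSE)
  }
  if (policy == "map") {
    hit <- chars %in% names(.nonstandard_map)
    chars[hit] <- .nonstandard_map[chars[hit]]
  }
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("sequence '", id, "' contains disallowed residue '",
         chars[bad], "' at position ", bad,
         if (policy == "strict") " (policy = \"strict\")" else "",
         call. = FALSE)
  }
  idx
}

#' Decode alphabet indices back to a residue string
#'
#' @param idx Integer vector of alphabet indices.
#' @param alphabet Ordered alphabet letters.
#' @return Single character string.
#' @export
decode_residues <- function(idx, alphabet = aa_alphabet()) {
  stopifnot(all(idx >= 1L), all(idx <= length(alphabet)))
  paste(alphabet[idx], collapse = "")
}

#' Build a protein sequence set
#'
#' A `protein_seqs` object is a named list of integer vectors (residue
#' indices into a fixed alphabet), the internal representation used by all
#' kernel computations.
#'
#' @param x Named character vector of residue strings, or a named list of
#'   integer index vectors (already encoded).
#' @param policy Residue policy passed to [encode_residues()].
#' @param alphabet Ordered alphabet letters.
#' @return Object of class `protein_seqs`.
#' @export
protein_seqs <- function(x, policy = c("strict", "map"),
                         alphabet = aa_alphabet()) {
  policy <- match.arg(policy)
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- if (is.character(x)) {
    lapply(seq_along(x), function(i) encode_residues(x[[i]], ids[i],
                                                     policy, alphabet))
  } else {
    lapply(x, function(s) {
      s <- as.integer(s)
      if (length(s) < 1L || any(s < 1L) || any(s > length(alphabet))) {
        stop("invalid residue indices", call. = FALSE)
      }
      s
    })
  }
  names(seqs) <- ids
  structure(seqs, alphabet = alphabet, class = "protein_seqs")
}

#' @export
print.protein_seqs <- function(x, ...) {
  cat("protein_seqs: ", length(x), " sequence(s), alphabet size ",
      length(attr(x, "alphabet")), "\n", sep = "")
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    cat("  ", names(x)[i], " (", length(x[[i]]), " aa)\n", sep = "")
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}
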