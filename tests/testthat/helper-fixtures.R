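# Shared fixtures built in code at test time.

# 2-letter toy kernel matrix [[4,1],[1,4]] with beta already applied,
# used for hand-checkable kernel values.
toy2_params <- function(k_max = 3L) {
  m <- matrix(c(4, 1, 1, 4), 2, 2, dimnames = list(c("A", "B"),
                                                   c("A", "B")))
  kernel_params(structure(m, beta_applied = 1), k_max = k_max)
}

default_params <- function(k_max = 10L, beta = 0.2) {
  kernel_params(default_ratio_matrix(), beta = beta, k_max = k_max)
}

rand_seq <- function(n, alphabet_size = 20L) {
  sample.int(alphabet_size, n, replace = TRUE)
}

# Perfectly separated toy distances: two groups of `n_per`, within-group
# distances drawn in [0, 0.1], between-group in [0.9, 1].
separated_distances <- function(n_per = 5L) {
  ids <- sprintf("s%02d", seq_len(2L * n_per))
  groups <- stats::setNames(rep(c("g1", "g2"), each = n_per), ids)
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      within <- groups[i] == groups[j]
      m[i, j] <- m[j, i] <- if (within) runif(1, 0, 0.1) else
        runif(1, 0.9, 1)
    }
  }
  list(distances = m, groups = groups)
}

write_toy_fasta <- function(path, records) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}
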