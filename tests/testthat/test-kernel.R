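test_that("k-mer kernel is the product of per-position matrix entries", {
  p <- toy2_params()
  # k = 1 reduces to a single K1 lookup
  expect_equal(k2(1L, 1L, p), 4)
  expect_equal(k2(1L, 2L, p), 1)
  # u = AB vs v = AA -> 4 * 1
  expect_equal(k2(c(1L, 2L), c(1L, 1L), p), 4)
  expect_error(k2(c(1L, 2L), 1L, p), "equal length")

  pid <- kernel_params(identity_ratio_matrix(), k_max = 3)
  u <- c(4L, 7L, 19L)
  expect_equal(k2(u, u, pid), 1)
  expect_equal(k2(u, c(4L, 7L, 18L), pid), 0)
})

test_that("naive kernel matches an in-test enumeration oracle", {
  # independent oracle: explicit k-mer extraction + k2 products
  oracle <- function(S, T, p) {
    total <- 0
    for (k in seq_len(min(p$k_max, length(S), length(T)))) {
      for (i in seq_len(length(S) - k + 1)) {
        for (j in seq_len(length(T) - k + 1)) {
          total <- total + k2(S[i:(i + k - 1)], T[j:(j + k - 1)], p)
        }
      }
    }
    total
  }
  set.seed(41)
  p4 <- kernel_params(
    normalize_counts(crossprod(matrix(runif(16, 1, 3), 4, 4))),
    beta = 0.5, k_max = 3)
  for (rep in 1:5) {
    S <- rand_seq(8, 4)
    T <- rand_seq(8, 4)
    expect_equal(k3_naive(S, T, p4)$k3, oracle(S, T, p4),
                 tolerance = 1e-12)
  }
})

test_that("single-residue sequences reduce to one K1 lookup", {
  p <- default_params()
  a <- 5L
  expect_equal(k3_naive(a, a, p)$k3, p$K1[5, 5])
  expect_equal(k3_recursive(a, a, p)$k3, p$K1[5, 5])
})

test_that("recursion agrees with the brute-force oracle on random cases", {
  set.seed(42)
  p_default <- default_params(k_max = 5)
  pid <- kernel_params(identity_ratio_matrix(), k_max = 5)
  for (rep in 1:30) {
    n <- sample(2:25, 1)
    m <- sample(2:25, 1)
    S <- rand_seq(n)
    T <- rand_seq(m)
    p <- if (rep %% 2) p_default else pid
    a <- k3_naive(S, T, p)
    b <- k3_recursive(S, T, p)
    expect_equal(b$k3, a$k3, tolerance = 1e-9)
    expect_equal(b$k3_by_k, a$k3_by_k, tolerance = 1e-9)
    # symmetry inherited from K1
    expect_equal(k3_recursive(T, S, p)$k3, b$k3, tolerance = 1e-12)
  }
})

test_that("k_max = 1 reduces both algorithms to the 1-mer sum", {
  set.seed(43)
  p1 <- default_params(k_max = 1)
  S <- rand_seq(15)
  T <- rand_seq(12)
  expect_equal(k3_recursive(S, T, p1)$k3, k3_naive(S, T, p1)$k3)
  expect_equal(k3_recursive(S, T, p1)$k3, sum(p1$K1[S, T]))
})

test_that("k3_by_k decomposition sums to the total and is non-negative", {
  set.seed(44)
  p <- default_params()
  S <- rand_seq(30)
  T <- rand_seq(40)
  kv <- k3_recursive(S, T, p)
  expect_equal(sum(kv$k3_by_k), kv$k3)
  expect_true(all(kv$k3_by_k >= 0))
  expect_length(kv$k3_by_k, 10)
})

test_that("kernel sum is monotone in the k-mer truncation", {
  set.seed(45)
  S <- rand_seq(25)
  T <- rand_seq(30)
  vals <- vapply(1:12, function(k) {
    k3_recursive(S, T, default_params(k_max = k))$k3
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("overflow raises an informative error instead of returning Inf", {
  huge <- structure(matrix(1e300, 2, 2), beta_applied = "none")
  p <- kernel_params(huge, beta = 2, k_max = 5)
  expect_error(k3_recursive(rep(1L, 10), rep(1L, 10), p),
               "smaller beta or k_max")
})

test_that("correlation kernel is exactly 1 on the diagonal", {
  set.seed(46)
  p <- default_params()
  for (len in c(1, 5, 40, 120)) {
    S <- rand_seq(len)
    expect_identical(as.numeric(correlation_kernel(S, S, p)), 1)
  }
})

test_that("all-ones matrix gives correlation 1 for equal-length pairs", {
  set.seed(47)
  p <- kernel_params(ones_ratio_matrix(), k_max = 10)
  for (rep in 1:5) {
    S <- rand_seq(60)
    T <- rand_seq(60)
    expect_identical(as.numeric(correlation_kernel(S, T, p)), 1)
  }
})

test_that("identity matrix with disjoint residues flags zero overlap", {
  p <- kernel_params(identity_ratio_matrix(), k_max = 5)
  S <- rep(1:5, 4)
  T <- rep(6:10, 4)
  kh <- correlation_kernel(S, T, p)
  expect_equal(as.numeric(kh), 0)
  expect_true(attr(kh, "zero_overlap"))
})

test_that("kernel distance follows the closed form and its bounds", {
  expect_equal(kernel_distance(1), 0)
  expect_equal(kernel_distance(0), sqrt(2))
  expect_equal(kernel_distance(0.5), 1)
  expect_equal(kernel_distance(1 + 1e-10), 0) # round-off clamp
  expect_error(kernel_distance(1.1), "exceeds 1")
})

test_that("length-only closed form matches direct summation and the kernel", {
  expect_equal(limit_semikernel(1, 1, 10), 1)
  expect_equal(limit_semikernel(5, 5, 5), 55) # 25+16+9+4+1
  set.seed(48)
  p <- kernel_params(ones_ratio_matrix(), k_max = 7)
  for (rep in 1:10) {
    n <- sample(1:40, 1)
    m <- sample(1:40, 1)
    expect_identical(k3_naive(rand_seq(n), rand_seq(m), p)$k3,
                     limit_semikernel(n, m, 7))
  }
})

test_that("small-beta regime reproduces the length-capture limit", {
  # as beta -> 0 all K1 entries -> 1, so equal-length pairs approach
  # correlation 1 regardless of residue content
  set.seed(49)
  p <- default_params(beta = 1e-6, k_max = 10)
  for (rep in 1:5) {
    S <- rand_seq(80)
    T <- rand_seq(80)
    expect_equal(as.numeric(correlation_kernel(S, T, p)), 1,
                 tolerance = 1e-3)
  }
})

test_that("pairwise matrix matches per-pair recomputation and is symmetric", {
  set.seed(50)
  seqs <- protein_seqs(lapply(stats::setNames(1:5, paste0("s", 1:5)),
                              function(i) rand_seq(sample(20:40, 1))))
  p <- default_params(k_max = 6)
  sim <- pairwise_matrix(seqs, p, "similarity")
  expect_lt(max(abs(sim - t(sim))), 1e-12)
  expect_identical(diag(sim), stats::setNames(rep(1, 5), names(seqs)))
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(sim[i, j],
                   as.numeric(correlation_kernel(seqs[[i]], seqs[[j]], p)),
                   tolerance = 1e-12)
    }
  }
  d <- pairwise_matrix(seqs, p, "distance")
  expect_identical(diag(d), stats::setNames(rep(0, 5), names(seqs)))
  expect_equal(unclass(d)[1, 2], kernel_distance(sim[1, 2]))
})

test_that("identical sequences give an all-ones similarity matrix", {
  s <- rand_seq(30)
  seqs <- protein_seqs(list(a = s, b = s, c = s))
  sim <- pairwise_matrix(seqs, default_params(k_max = 5), "similarity")
  expect_equal(max(abs(sim - 1)), 0)
})

test_that("pairwise matrix rejects duplicate ids", {
  seqs <- list(a = rand_seq(10), a = rand_seq(10))
  expect_error(pairwise_matrix(seqs, default_params()), "unique ids")
})

test_that("kernel distances satisfy the triangle inequality", {
  set.seed(51)
  seqs <- protein_seqs(lapply(stats::setNames(1:12, paste0("s", 1:12)),
                              function(i) rand_seq(sample(30:60, 1))))
  d <- pairwise_matrix(seqs, default_params(k_max = 8), "distance")
  for (rep in 1:100) {
    t3 <- sample(12, 3)
    expect_lte(d[t3[1], t3[2]],
               d[t3[1], t3[3]] + d[t3[3], t3[2]] + 1e-12)
  }
  expect_lte(max(d), sqrt(2) + 1e-12)
})

test_that("recursion cost grows about linearly in k_max", {
  set.seed(52)
  S <- rand_seq(300)
  T <- rand_seq(300)
  p10 <- default_params(k_max = 10)
  p20 <- default_params(k_max = 20)
  time_of <- function(p) {
    reps <- 10
    t0 <- proc.time()[["elapsed"]]
    for (r in seq_len(reps)) k3_recursive(S, T, p)
    (proc.time()[["elapsed"]] - t0) / reps
  }
  time_of(p10) # warm up
  r <- time_of(p20) / max(time_of(p10), 1e-6)
  expect_lt(r, 3) # coarse guard: doubling k_max must not quadruple cost
})
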