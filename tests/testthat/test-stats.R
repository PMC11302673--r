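mk_cent <- function(v, kind = "PC") {
  structure(v / sum(v), names = paste0("R", seq_along(v)), kind = kind,
            class = "centrality")
}

test_that("delta of unit-sum centralities sums to zero", {
  rest <- mk_cent(c(1, 2, 3, 4))
  task <- mk_cent(c(4, 3, 2, 1))
  d <- delta(task, rest)
  expect_equal(sum(d), 0, tolerance = 1e-10)
  expect_equal(as.numeric(delta(rest, rest)), rep(0, 4))
  expect_equal(as.numeric(d), as.numeric(task) - as.numeric(rest))
  expect_error(delta(task, mk_cent(c(1, 1, 1, 1), kind = "DC")), "kinds differ")
})

test_that("cosine similarity and angular difference basics", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(angular_difference(c(1, 2), c(1, 2)), 0, tolerance = 1e-6)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(angular_difference(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(cosine_similarity(c(2, -1), c(-2, 1)), -1)
  expect_equal(angular_difference(c(2, -1), c(-2, 1)), pi)
  expect_error(cosine_similarity(c(0, 0), c(1, 2)), "zero vector")
})

test_that("complementary angles: angle(u, v) + angle(u, -v) = pi", {
  set.seed(12)
  for (q in 1:25) {
    u <- rnorm(8); v <- rnorm(8)
    expect_equal(angular_difference(u, v) + angular_difference(u, -v), pi,
                 tolerance = 1e-12)
  }
})

# independent oracle: concordant/discordant pair counting with tie correction
tau_brute <- function(u, v) {
  n <- length(u)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(u[i] - u[j]); b <- sign(v[i] - v[j])
    if (a == 0 && b == 0) next
    if (a == 0) tx <- tx + 1
    else if (b == 0) ty <- ty + 1
    else if (a == b) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

test_that("kendall tau equals brute-force pair counting", {
  expect_equal(kendall_tau(1:6, c(2, 4, 6, 8, 10, 12))$tau, 1)
  expect_equal(kendall_tau(1:6, 6:1)$tau, -1)
  u <- c(1, 2, 2, 3, 5)
  v <- c(2, 1, 4, 3, 5)
  expect_equal(kendall_tau(u, v)$tau, tau_brute(u, v), tolerance = 1e-12)
  set.seed(77)
  for (q in 1:30) {
    n <- sample(4:8, 1)
    u <- sample(1:5, n, replace = TRUE) + runif(n, 0, 0.01)
    v <- sample(1:5, n, replace = TRUE)
    if (sd(v) == 0) next
    expect_equal(kendall_tau(u, v)$tau, tau_brute(u, v), tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

# oracle: exhaustive relabeling with midranks
mwu_brute <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(n + m, n)
  Us <- apply(combos, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  p <- mean(abs(Us - n * m / 2) >= abs(U_obs - n * m / 2) - 1e-9)
  list(U = U_obs, p = p)
}

test_that("Mann-Whitney U: separation, identity, symmetry, oracle agreement", {
  res <- mann_whitney_u(c(7, 8, 9), c(1, 2, 3))
  expect_equal(res$U, 9)
  expect_equal(res$p, 0.1)
  # identical samples with exact midrank enumeration
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # swap symmetry
  x <- c(1.2, 3.4, 2.2, 5); y <- c(0.5, 2.9, 4.4)
  a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
  expect_equal(a$U, length(x) * length(y) - b$U)
  expect_equal(a$p, b$p)
  # oracle agreement for n*m <= 36 including ties
  set.seed(13)
  for (q in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, m, replace = TRUE)
    got <- mann_whitney_u(x, y)
    want <- mwu_brute(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("cluster test: no clusters when conditions are identical", {
  a <- matrix(rnorm(8 * 16), 8, 16)
  res <- cluster_permutation_paired_t(a, a)
  expect_equal(nrow(res$clusters), 0L)
  expect_true(res$exact)
  expect_equal(res$n_permutations, 256L)
})

test_that("exact sign-flip p-values are multiples of 1/2^n with minimum 2/2^n", {
  set.seed(2)
  n <- 8
  d_effect <- matrix(rnorm(n * 20, mean = 0, sd = 0.1), n, 20)
  d_effect[, 8:12] <- d_effect[, 8:12] + 2      # strong planted cluster
  a <- d_effect; b <- matrix(0, n, 20)
  res <- cluster_permutation_paired_t(a, b)
  expect_true(res$exact)
  expect_true(nrow(res$clusters) >= 1L)
  expect_true(all(abs(res$clusters$p * 256 - round(res$clusters$p * 256)) < 1e-9))
  expect_equal(min(res$clusters$p), 2 / 256)
  expect_equal(min(res$clusters$p), 0.0078125)
})

test_that("planted contiguous effects are localised correctly", {
  # the significant cluster must cover the planted band range and stray by at
  # most one band on either side (adjacent bands can cross the threshold by
  # chance and merge into the run)
  hits <- 0L
  for (seed in 1:60) {
    set.seed(seed)
    d <- matrix(rnorm(8 * 32, 0, 0.2), 8, 32)
    d[, 10:17] <- d[, 10:17] + 1
    res <- cluster_permutation_paired_t(d, matrix(0, 8, 32))
    sig <- res$clusters[res$clusters$p <= 0.05 & res$clusters$mass > 0, ]
    ok <- nrow(sig) >= 1L &&
      any(sig$from <= 10L & sig$to >= 17L & sig$from >= 9L & sig$to <= 18L)
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 57L)   # >= 95%
})

test_that("Monte Carlo branch is seeded and includes the observed flip", {
  set.seed(3)
  d <- matrix(rnorm(14 * 10, 0.5, 1), 14, 10)
  r1 <- cluster_permutation_paired_t(d, matrix(0, 14, 10), n_perm = 500, seed = 4)
  r2 <- cluster_permutation_paired_t(d, matrix(0, 14, 10), n_perm = 500, seed = 4)
  expect_false(r1$exact)
  expect_identical(r1$clusters, r2$clusters)
  expect_true(all(r1$clusters$p > 0))
})

test_that("cluster test input contracts", {
  expect_error(cluster_permutation_paired_t(matrix(1, 1, 4), matrix(0, 1, 4)),
               "2 paired conditions")
  expect_error(cluster_permutation_paired_t(matrix(1, 3, 4), matrix(0, 3, 5)),
               "identical shape")
})

test_that("compare_modalities assembles cosines and refuses the cluster test
           for a single condition", {
  set.seed(9)
  nb <- 6; nr <- 10
  bands <- log_spaced_bands(2, 90, nb)
  mk_bpr <- function() {
    structure(matrix(runif(nr * nb, 0.1, 0.3), nr, nb,
                     dimnames = list(paste0("R", 1:nr), rownames(bands))),
              band_edges = bands, component = "aperiodic",
              denominator = "total_fullband", class = "band_power_ratios")
  }
  pc_rest <- mk_cent(runif(nr) + 0.1); dc_rest <- mk_cent(runif(nr) + 0.1, "DC")
  rep1 <- compare_modalities(pc_rest,
                             list(t1 = mk_cent(runif(nr) + 0.1)),
                             dc_rest,
                             list(t1 = mk_cent(runif(nr) + 0.1, "DC")),
                             mk_bpr(), list(t1 = mk_bpr()))
  expect_null(rep1$cluster_test)
  expect_equal(dim(rep1$cos_pc), c(1L, nb))
  expect_true(all(abs(rep1$cos_pc) <= 1))
  expect_equal(nrow(rep1$tau_rest_vs_dpc), 1L)
  # angle summaries: no within-kind pairs for one condition, cross angle valid
  expect_length(rep1$angles_within_dpc, 0L)
  expect_gte(rep1$min_angle_dpc_vs_ddc, 0)
  expect_lte(rep1$min_angle_dpc_vs_ddc, pi)

  rep2 <- compare_modalities(pc_rest,
                             list(t1 = mk_cent(runif(nr) + 0.1),
                                  t2 = mk_cent(runif(nr) + 0.1)),
                             dc_rest,
                             list(t1 = mk_cent(runif(nr) + 0.1, "DC"),
                                  t2 = mk_cent(runif(nr) + 0.1, "DC")),
                             mk_bpr(), list(t1 = mk_bpr(), t2 = mk_bpr()))
  expect_length(rep2$angles_within_dpc, 1L)   # one condition pair
  expect_true(all(rep2$angles_within_ddc >= 0 & rep2$angles_within_ddc <= pi))
})
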