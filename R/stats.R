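#' Task-minus-rest difference vectors
#'
#' Elementwise `task - rest` for matching centrality vectors or band power
#' ratio matrices.  Differences of two unit-sum centrality vectors sum to
#' zero.
#'
#' @param task,rest Two objects of the same kind: `centrality` vectors with
#'   the same kind tag and regions, or `band_power_ratios` with the same
#'   bands and regions.
#' @param condition Optional condition label carried on the result.
#' @return For centralities, a named numeric `delta_vector` (attributes
#'   `kind`, `condition`); for band ratios, a region x band matrix of the same
#'   class layout.
#' @export
delta <- function(task, rest, condition = NA_character_) UseMethod("delta")

#' @export
delta.centrality <- function(task, rest, condition = NA_character_) {
  stopifnot(inherits(rest, "centrality"))
  stop_if(!identical(attr(task, "kind"), attr(rest, "kind")),
          "centrality kinds differ")
  stop_if(!identical(names(task), names(rest)), "region labels differ")
  structure(as.numeric(task) - as.numeric(rest), names = names(task),
            kind = paste0("d", attr(task, "kind")), condition = condition,
            class = "delta_vector")
}

#' @export
delta.band_power_ratios <- function(task, rest, condition = NA_character_) {
  stopifnot(inherits(rest, "band_power_ratios"))
  stop_if(!isTRUE(all.equal(attr(task, "band_edges"), attr(rest, "band_edges"))),
          "band definitions differ")
  stop_if(!identical(dimnames(task), dimnames(rest)), "region/band labels differ")
  structure(unclass(task) - unclass(rest),
            band_edges = attr(task, "band_edges"),
            kind = "dBPR", condition = condition, class = "delta_bpr")
}

#' Cosine similarity and angular difference
#'
#' `cosine_similarity` is u.v / (|u| |v|); `angular_difference` is its
#' arccosine in radians (0 = aligned, pi/2 = orthogonal, pi = antipodal).
#'
#' @param u,v Numeric vectors of equal length, neither all-zero.
#' @return A number in `[-1, 1]` (cosine) or `[0, pi]` (angle).
#' @export
cosine_similarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  stop_if(nu == 0 || nv == 0, "cosine similarity undefined for a zero vector")
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

#' @rdname cosine_similarity
#' @export
angular_difference <- function(u, v) acos(cosine_similarity(u, v))

#' Kendall rank correlation
#'
#' Tie-corrected tau-b with p-value from [stats::cor.test()] (exact for small
#' untied samples, tie-corrected normal approximation otherwise).
#'
#' @param u,v Numeric vectors, length >= 3, neither constant.
#' @return List with `tau` and `p`.
#' @export
kendall_tau <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  stopifnot(length(u) == length(v), length(u) >= 3L)
  stop_if(sd(u) == 0 || sd(v) == 0, "Kendall tau undefined for constant vector")
  ct <- suppressWarnings(cor.test(u, v, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test.  Without ties and for n*m <= 400 the exact
#' Wilcoxon distribution is used; with ties, all C(n+m, n) labelings are
#' enumerated exactly (midranks) when that count is at most 2e5, otherwise a
#' tie-corrected normal approximation applies.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `U` (number of (x, y) pairs with x > y, ties counted
#'   half) and `p`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n * m <= 400) {
    p <- suppressWarnings(wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value)
  } else if (ties && choose(n + m, n) <= 2e5) {
    combos <- combn(n + m, n)
    Us <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(Us - n * m / 2) >= abs(U - n * m / 2) - 1e-9)
  } else {
    nt <- table(c(x, y))
    sig2 <- n * m / 12 * ((n + m + 1) - sum(nt^3 - nt) / ((n + m) * (n + m - 1)))
    z <- (U - n * m / 2) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Cluster-based sign-flip permutation paired t-test across frequency bands
#'
#' For paired condition x band matrices `a` and `b`, computes the per-band
#' paired t statistic of d = a - b, forms clusters as maximal contiguous runs
#' of bands where |t| exceeds the two-sided t threshold at `threshold_p`, and
#' tests each cluster's mass (sum of t within the run) against the
#' permutation null of the maximal |cluster mass| under sign flips of the
#' condition-level difference vectors.  All 2^n flips are enumerated exactly
#' when n <= 12; otherwise `n_perm` random flips are drawn (seeded).
#' Familywise error is controlled by the max-mass null.
#'
#' @param a,b Condition x band matrices of identical shape, bands in
#'   frequency order, at least 2 conditions.
#' @param threshold_p Two-sided cluster-forming p threshold on the per-band t.
#' @param n_perm Monte Carlo flips when exact enumeration is infeasible.
#' @param seed Seed for the Monte Carlo branch.
#' @return A `cluster_test_result`: data.frame `clusters` (band range `from`,
#'   `to`, `mass`, `p`), per-band `t`, `threshold_t`, `n_permutations`,
#'   `exact`.
#' @export
cluster_permutation_paired_t <- function(a, b, threshold_p = 0.05,
                                         n_perm = 4096L, seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  stop_if(!identical(dim(a), dim(b)), "a and b must have identical shape")
  n <- nrow(a); nb <- ncol(a)
  stop_if(n < 2L, "need at least 2 paired conditions")
  d <- a - b
  thr <- qt(1 - threshold_p / 2, df = n - 1L)

  tstat_rows <- function(S) {
    # S: flips x conditions in {-1, +1}; returns flips x band t matrix
    mu <- (S %*% d) / n
    ssq <- matrix(colSums(d^2), nrow(S), nb, byrow = TRUE)
    s2 <- (ssq - n * mu^2) / (n - 1L)
    tt <- mu / sqrt(s2 / n)
    tt[!is.finite(tt)] <- 0
    tt
  }
  find_clusters <- function(tv) {
    supra <- abs(tv) > thr
    if (!any(supra)) return(NULL)
    rl <- rle(supra)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    data.frame(from = starts[keep], to = ends[keep],
               mass = vapply(which(keep),
                             function(q) sum(tv[starts[q]:ends[q]]), numeric(1)))
  }

  t_obs <- tstat_rows(matrix(1, 1L, n))[1L, ]
  cl <- find_clusters(t_obs)

  exact <- n <= 12L
  S <- if (exact) {
    as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  }
  tt <- tstat_rows(S)
  null_max <- apply(tt, 1L, function(tv) {
    cc <- find_clusters(tv)
    if (is.null(cc)) 0 else max(abs(cc$mass))
  })
  if (!exact) null_max <- c(null_max, if (is.null(cl)) 0 else max(abs(cl$mass)))

  if (!is.null(cl)) {
    cl$p <- vapply(cl$mass, function(ms) {
      tol <- max(1e-12, 1e-9 * abs(ms))    # observed flip must always count
      mean(null_max >= abs(ms) - tol)
    }, numeric(1))
  } else {
    cl <- data.frame(from = integer(0), to = integer(0), mass = numeric(0),
                     p = numeric(0))
  }
  structure(list(clusters = cl, t = t_obs, threshold_t = thr,
                 n_permutations = length(null_max), exact = exact),
            class = "cluster_test_result")
}

#' Compare topological and spectral condition changes
#'
#' Assembles Delta PC, Delta DC and Delta BPR for every task condition,
#' computes per-band cosine similarities of Delta BPR with each centrality
#' change, averages their absolute values across conditions, runs the
#' cluster-based sign-flip permutation test between the two |cosine| curves
#' (PC vs DC), and reports the Kendall rank association of resting PC with
#' each Delta PC.
#'
#' @param pc_rest,dc_rest Resting `centrality` vectors.
#' @param pc_tasks,dc_tasks Named lists of task `centrality` vectors.
#' @param bpr_rest Resting `band_power_ratios` (region x band).
#' @param bpr_tasks Named list of task `band_power_ratios`.
#' @param band_edges Band definition matrix (defaults to the one carried by
#'   `bpr_rest`).
#' @param threshold_p Cluster-forming threshold, see
#'   `cluster_permutation_paired_t()`.
#' @param seed Seed for any Monte Carlo permutation branch.
#' @return A `modality_report`: list with `cos_pc`, `cos_dc` (condition x
#'   band signed cosines), `abs_cos_pc`, `abs_cos_dc` (band-wise means),
#'   `cluster_test` (NULL for a single task condition), `tau_rest_vs_dpc`
#'   (per condition), `angles_within_dpc` / `angles_within_ddc` (pairwise
#'   angular differences between conditions' change vectors, radians;
#'   smaller = more consistent across tasks), `min_angle_dpc_vs_ddc` (the
#'   minimum angle between any Delta PC and any Delta DC vector; values near
#'   pi/2 mean the two kinds of change are at best orthogonal),
#'   `band_edges`, `conditions`.
#' @export
compare_modalities <- function(pc_rest, pc_tasks, dc_rest, dc_tasks,
                               bpr_rest, bpr_tasks, band_edges = NULL,
                               threshold_p = 0.05, seed = 1L) {
  conds <- names(pc_tasks)
  stopifnot(length(conds) >= 1L, identical(names(dc_tasks), conds),
            identical(names(bpr_tasks), conds))
  if (is.null(band_edges)) band_edges <- attr(bpr_rest, "band_edges")
  nb <- nrow(band_edges)
  cos_pc <- cos_dc <- matrix(NA_real_, length(conds), nb,
                             dimnames = list(conds, rownames(band_edges)))
  taus <- data.frame(condition = conds, tau = NA_real_, p = NA_real_)
  dpcs <- ddcs <- vector("list", length(conds))
  for (q in seq_along(conds)) {
    dpc <- dpcs[[q]] <- delta(pc_tasks[[q]], pc_rest, conds[q])
    ddc <- ddcs[[q]] <- delta(dc_tasks[[q]], dc_rest, conds[q])
    dbpr <- delta(bpr_tasks[[q]], bpr_rest, conds[q])
    for (bnd in seq_len(nb)) {
      u <- dbpr[, bnd]
      if (all(u == 0)) next
      cos_pc[q, bnd] <- cosine_similarity(u, dpc)
      cos_dc[q, bnd] <- cosine_similarity(u, ddc)
    }
    kt <- kendall_tau(pc_rest, dpc)
    taus$tau[q] <- kt$tau; taus$p[q] <- kt$p
  }
  cos_pc[is.na(cos_pc)] <- 0
  cos_dc[is.na(cos_dc)] <- 0
  ct <- if (length(conds) >= 2L) {
    cluster_permutation_paired_t(abs(cos_pc), abs(cos_dc),
                                 threshold_p = threshold_p, seed = seed)
  } else NULL
  # consistency of change vectors across conditions, and the closest
  # approach between the two kinds of change
  pair_angles <- function(vs) {
    if (length(vs) < 2L) return(numeric(0))
    idx <- combn(length(vs), 2L)
    vapply(seq_len(ncol(idx)), function(i)
      angular_difference(vs[[idx[1L, i]]], vs[[idx[2L, i]]]), numeric(1))
  }
  cross <- vapply(dpcs, function(u)
    vapply(ddcs, function(v) angular_difference(u, v), numeric(1)),
    numeric(length(ddcs)))
  structure(list(cos_pc = cos_pc, cos_dc = cos_dc,
                 abs_cos_pc = colMeans(abs(cos_pc)),
                 abs_cos_dc = colMeans(abs(cos_dc)),
                 cluster_test = ct, tau_rest_vs_dpc = taus,
                 angles_within_dpc = pair_angles(dpcs),
                 angles_within_ddc = pair_angles(ddcs),
                 min_angle_dpc_vs_ddc = min(cross),
                 band_edges = band_edges, conditions = conds),
            class = "modality_report")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat("cluster sign-flip permutation test:", x$n_permutations, "flips",
      if (x$exact) "(exact)" else "(Monte Carlo)", "\n")
  if (nrow(x$clusters)) print(x$clusters) else cat("no supra-threshold clusters\n")
  invisible(x)
}

#' @export
print.modality_report <- function(x, ...) {
  cat("modality comparison over", length(x$conditions), "task conditions,",
      nrow(x$band_edges), "bands\n")
  if (!is.null(x$cluster_test)) print(x$cluster_test)
  invisible(x)
}
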