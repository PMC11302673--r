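#' Volume-optimal persistent cycle for a barcode interval
#'
#' For a finite interval [b, d) paired as (birth edge, death triangle), finds
#' a 2-chain tau of triangles in the death-time complex that contains the
#' death triangle, whose mod-2 boundary lies in the birth-time complex, and
#' whose triangle count (volume) is minimal.  The persistent cycle is the
#' boundary of tau: the tightest wrapper of the hole the interval records.
#'
#' The search first restricts to triangles carrying at least one constrained
#' edge and to the death triangle's connected component of the constrained
#' incidence graph, applies unit propagation, and then solves the residual
#' GF(2) affine system exactly by kernel enumeration.  For the rare instances
#' whose kernel is too large to enumerate, the real-valued l1 relaxation
#' (an LP) is solved and accepted only when it certifies an integral optimum;
#' otherwise enumeration is retried at a higher cap.
#'
#' @param F A `flag_filtration`.
#' @param interval One row of an `h1_barcode` (or a list with `birth_edge`,
#'   `death_triangle`); must be a finite interval.
#' @param barcode The barcode the interval came from (supplies the reduction
#'   representative used as warm start; optional).
#' @return A `persistent_feature`: list with `interval`, `cycle_edges`
#'   (data.frame `i`, `j`, `edge`), `bounding_triangles` (data.frame `i`, `j`,
#'   `k`, `tri`), and `volume`.
#' @seealso `brute_force_optimal_cycle()` for the exhaustive oracle.
#' @export
volume_optimal_cycle <- function(F, interval, barcode = NULL) {
  stop_if(!is.finite(interval$death), "infinite interval has no bounding chain")
  rep_chain <- NULL
  if (!is.null(barcode)) {
    hit <- which(barcode$birth_edge == interval$birth_edge &
                 barcode$death_triangle %in% interval$death_triangle)
    if (length(hit)) rep_chain <- attr(barcode, "rep_chains")[[hit[1L]]]
  }
  res <- solve_optimal_cycles(F, data.frame(birth_edge = interval$birth_edge,
                                            death_triangle = interval$death_triangle),
                              list(rep_chain))[[1L]]
  make_feature(F, interval, res$tris, res$cycle_edges)
}

#' Volume-optimal cycles for every finite interval of a barcode
#'
#' Batch version of `volume_optimal_cycle()`; this is what the pipeline uses.
#'
#' @param F A `flag_filtration`.
#' @param barcode An `h1_barcode` from `compute_h1_barcode()`.
#' @return List of `persistent_feature`, one per finite interval (barcode
#'   row order); infinite intervals are skipped.
#' @export
volume_optimal_cycles <- function(F, barcode) {
  stopifnot(inherits(barcode, "h1_barcode"))
  fin <- which(is.finite(barcode$death))
  if (!length(fin)) return(list())
  res <- solve_optimal_cycles(F, barcode[fin, , drop = FALSE],
                              attr(barcode, "rep_chains")[fin])
  lapply(seq_along(fin), function(q) {
    make_feature(F, barcode[fin[q], , drop = FALSE],
                 res[[q]]$tris, res[[q]]$cycle_edges)
  })
}

# core dispatcher: exact C++ search, LP fallback, high-cap retry
solve_optimal_cycles <- function(F, rows, rep_chains, cap_k = 25L) {
  res <- optimal_cycles_cpp(F$tri_edges, as.integer(rows$birth_edge),
                            as.integer(rows$death_triangle), rep_chains,
                            nrow(F$edges), cap_k)
  for (q in seq_along(res)) {
    st <- res[[q]]$status
    if (st == 0L) next
    stop_if(st == 2L, "optimal cycle system infeasible for interval with birth edge ",
            rows$birth_edge[q], " - invalid persistence pair")
    sol <- solve_one_lp(F, rows$birth_edge[q], rows$death_triangle[q])
    if (is.null(sol)) {
      sol <- optimal_cycles_cpp(F$tri_edges, as.integer(rows$birth_edge[q]),
                                as.integer(rows$death_triangle[q]),
                                rep_chains[q], nrow(F$edges), 30L, 1e9, 5e8)[[1L]]
      stop_if(sol$status != 0L,
              "optimal cycle search exceeded enumeration capacity (kernel dim ",
              sol$k, ")")
      res[[q]] <- sol
    } else {
      res[[q]] <- sol
    }
  }
  res
}

# l1 relaxation over the reals; returns NULL unless it certifies an integral
# optimum whose support is feasible over GF(2)
solve_one_lp <- function(F, be, dt) {
  te <- F$tri_edges
  cand <- which(seq_len(nrow(te)) <= dt &
                (te[, 1L] > be | te[, 2L] > be | te[, 3L] > be))
  cedges <- sort(unique(as.vector(te[cand, , drop = FALSE])))
  cedges <- cedges[cedges > be]
  # oriented boundary: triangle (i<j<k) -> +(i,j) - (i,k) + (j,k)
  sgn <- c(1, -1, 1)
  nr <- length(cedges)
  erow <- match(seq_len(nrow(F$edges)), cedges)
  build_col <- function(t) {
    v <- numeric(nr)
    for (s in 1:3) {
      r <- erow[te[t, s]]
      if (!is.na(r)) v[r] <- v[r] + sgn[s]
    }
    v
  }
  others <- setdiff(cand, dt)
  if (!length(others)) return(NULL)
  Adeath <- build_col(dt)
  A <- vapply(others, build_col, numeric(nr))
  nv <- length(others)
  # variables p, q >= 0 with z = p - q; minimise sum(p + q).  Drop linearly
  # dependent constraint rows first (the simplex cannot handle them).
  beq <- -Adeath
  qrA <- qr(t(A), LAPACK = TRUE)
  keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  A <- A[keep, , drop = FALSE]
  beq <- beq[keep]
  Aeq <- cbind(A, -A)
  fit <- tryCatch(
    pracma::linprog(cc = rep(1, 2L * nv), A = NULL, b = NULL,
                    Aeq = Aeq, beq = beq, maxiter = 400L + 20L * nv),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$x)) return(NULL)
  z <- fit$x[seq_len(nv)] - fit$x[nv + seq_len(nv)]
  if (any(abs(z - round(z)) > 1e-6)) return(NULL)
  supp <- others[abs(round(z)) %% 2 == 1]
  tris <- sort(c(supp, dt))
  # GF(2) feasibility of the rounded support
  par <- tabulate(as.vector(te[tris, , drop = FALSE]), nbins = nrow(F$edges)) %% 2L
  if (any(par[cedges] != 0L)) return(NULL)
  if (length(tris) != round(sum(abs(z))) + 1L) return(NULL)
  cyc <- which(par == 1L)
  list(status = 0L, tris = tris, cycle_edges = cyc, volume = length(tris))
}

#' Exhaustive minimum-volume bounding chain (test oracle)
#'
#' Enumerates every admissible 2-chain (subsets of the triangles present at
#' the death time that contain the death triangle and whose boundary lies in
#' the birth-time complex) and returns one of minimal volume.  Refuses when
#' more than 20 candidate triangles would have to be enumerated.
#'
#' @inheritParams volume_optimal_cycle
#' @return A `persistent_feature`, same contract as `volume_optimal_cycle()`.
#' @export
brute_force_optimal_cycle <- function(F, interval) {
  stop_if(!is.finite(interval$death), "infinite interval has no bounding chain")
  be <- interval$birth_edge; dt <- interval$death_triangle
  stop_if(dt > 20L, "more than 20 candidate triangles: enumeration refused")
  m <- nrow(F$edges)
  te <- F$tri_edges
  constrained <- function(e) e > be
  par <- integer(m)
  viol <- 0L
  flip <- function(t) {
    for (e in te[t, ]) {
      par[e] <<- 1L - par[e]
      if (e > be) viol <<- viol + (if (par[e] == 1L) 1L else -1L)
    }
  }
  flip(dt)
  others <- setdiff(seq_len(dt), dt)
  k <- length(others)
  sel <- logical(k)
  best <- NULL; bestw <- Inf
  if (viol == 0L) { best <- dt; bestw <- 1L }
  if (k > 0L) {
    for (ii in seq_len(2^k - 1L)) {
      j <- round(log2(bitwAnd(ii, -ii))) + 1L
      flip(others[j])
      sel[j] <- !sel[j]
      w <- sum(sel) + 1L
      if (viol == 0L && w < bestw) { bestw <- w; best <- c(others[sel], dt) }
    }
  }
  stop_if(is.null(best), "no admissible bounding chain found - invalid pair")
  par2 <- tabulate(as.vector(te[best, , drop = FALSE]), nbins = m) %% 2L
  make_feature(F, interval, sort(best), which(par2 == 1L))
}

# assemble + invariant-check a persistent feature
make_feature <- function(F, interval, tris, cycle_edge_ids) {
  e <- F$edges; tr <- F$triangles
  stopifnot(length(tris) >= 1L, length(cycle_edge_ids) >= 1L)
  # boundary(tris) == cycle over Z/2
  par <- tabulate(as.vector(F$tri_edges[tris, , drop = FALSE]),
                  nbins = nrow(e)) %% 2L
  stopifnot(identical(sort(which(par == 1L)), sort(as.integer(cycle_edge_ids))))
  stopifnot(all(cycle_edge_ids <= interval$birth_edge),
            all(tris <= interval$death_triangle),
            interval$death_triangle %in% tris)
  structure(list(
    interval = list(birth = interval$birth, death = interval$death,
                    birth_edge = interval$birth_edge,
                    death_triangle = interval$death_triangle,
                    persistence = interval$death - interval$birth),
    cycle_edges = data.frame(i = e$i[cycle_edge_ids], j = e$j[cycle_edge_ids],
                             edge = as.integer(cycle_edge_ids)),
    bounding_triangles = data.frame(i = tr$i[tris], j = tr$j[tris],
                                    k = tr$k[tris], tri = as.integer(tris)),
    volume = length(tris)), class = "persistent_feature")
}

#' @export
print.persistent_feature <- function(x, ...) {
  cat(sprintf("persistent feature [%.4g, %.4g): cycle length %d, volume %d\n",
              x$interval$birth, x$interval$death, nrow(x$cycle_edges), x$volume))
  invisible(x)
}
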