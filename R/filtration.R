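#' Vietoris-Rips flag filtration of a pseudo-distance matrix
#'
#' Builds the 2-skeleton of the flag (clique) filtration: all vertices at
#' birth 0, every retained edge at birth omega, and every triangle whose three
#' edges are retained, born at the maximum of its edge births.  Simplices are
#' ordered by (birth, dimension, lexicographic index), which is a valid
#' filtration order: every face precedes its cofaces.
#'
#' @param D A `pseudo_distance`.
#' @return A `flag_filtration`: list with `n_vertices`, `labels`, `edges`
#'   (data.frame `i`, `j`, `birth` in filtration order), `triangles`
#'   (data.frame `i`, `j`, `k`, `birth`), and `tri_edges` (triangle x 3 matrix
#'   of edge indices).
#' @export
build_flag_filtration <- function(D) {
  stopifnot(inherits(D, "pseudo_distance"))
  n <- nrow(D$omega)
  mask <- D$mask
  ut <- which(upper.tri(mask) & mask, arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1L], j = ut[, 2L],
                      birth = D$omega[ut])
  ord <- order(edges$birth, edges$i, edges$j)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  m <- nrow(edges)

  # edge index lookup
  eidx <- matrix(0L, n, n)
  if (m > 0L) {
    eidx[cbind(edges$i, edges$j)] <- seq_len(m)
    eidx[cbind(edges$j, edges$i)] <- seq_len(m)
  }

  # triangles: for each edge (i, j), common retained neighbours k > j
  ti <- tj <- tk <- integer(0)
  if (m > 0L && n >= 3L) {
    li <- vector("list", m)
    for (e in seq_len(m)) {
      i <- edges$i[e]; j <- edges$j[e]
      ks <- which(mask[i, ] & mask[j, ])
      ks <- ks[ks > j]
      if (length(ks)) li[[e]] <- cbind(i, j, ks)
    }
    tri <- do.call(rbind, li)
    if (!is.null(tri) && nrow(tri)) { ti <- tri[, 1L]; tj <- tri[, 2L]; tk <- tri[, 3L] }
  }
  if (length(ti)) {
    b1 <- edges$birth[eidx[cbind(ti, tj)]]
    b2 <- edges$birth[eidx[cbind(ti, tk)]]
    b3 <- edges$birth[eidx[cbind(tj, tk)]]
    tb <- pmax(b1, b2, b3)
    ordt <- order(tb, ti, tj, tk)
    triangles <- data.frame(i = ti[ordt], j = tj[ordt], k = tk[ordt], birth = tb[ordt])
    rownames(triangles) <- NULL
    tri_edges <- cbind(eidx[cbind(triangles$i, triangles$j)],
                       eidx[cbind(triangles$i, triangles$k)],
                       eidx[cbind(triangles$j, triangles$k)])
  } else {
    triangles <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                            birth = numeric(0))
    tri_edges <- matrix(integer(0), 0L, 3L)
  }

  structure(list(n_vertices = n, labels = D$labels, edges = edges,
                 triangles = triangles, tri_edges = tri_edges),
            class = "flag_filtration")
}

# filtration-order sanity used by the reduction entry point
assert_valid_filtration <- function(F) {
  stopifnot(inherits(F, "flag_filtration"))
  e <- F$edges; tr <- F$triangles
  stop_if(nrow(e) > 1L && is.unsorted(e$birth), "edges not in filtration order")
  stop_if(nrow(tr) > 1L && is.unsorted(tr$birth), "triangles not in filtration order")
  if (nrow(tr)) {
    eb <- matrix(e$birth[F$tri_edges], ncol = 3L)
    stop_if(any(abs(apply(eb, 1L, max) - tr$birth) > 1e-12),
            "triangle births violate the flag property")
  }
  invisible(TRUE)
}

#' @export
print.flag_filtration <- function(x, ...) {
  cat("flag filtration:", x$n_vertices, "vertices,", nrow(x$edges), "edges,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}
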