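#' H1 persistence barcode of a flag filtration
#'
#' Computes first-homology persistence pairs over Z/2 by column reduction of
#' the triangle boundary matrix (compressed to creator edges).  Each finite
#' pair gives an interval [b, d) with b the birth edge's pseudo-distance and
#' d the death triangle's.  Zero-persistence pairs (b = d, ubiquitous in flag
#' filtrations through "apparent" edge-triangle pairs) are discarded; creator
#' edges that are never killed are reported as infinite intervals and are
#' excluded from scaffold construction downstream.
#'
#' @param F A `flag_filtration`.
#' @return An `h1_barcode` data.frame with columns `birth`, `death`,
#'   `birth_edge`, `death_triangle`, `persistence`, sorted by (birth, death);
#'   infinite intervals have `death = Inf` and `death_triangle = NA`.
#'   Attributes: `rep_chains` (reduction bounding chains per finite row, used
#'   to seed the optimal-cycle search), `n_zero_discarded`, `n_infinite`.
#' @export
compute_h1_barcode <- function(F) {
  assert_valid_filtration(F)
  m <- nrow(F$edges)
  if (m == 0L) return(empty_barcode())
  red <- ph_reduce_cpp(cbind(F$edges$i, F$edges$j), F$tri_edges, F$n_vertices)
  be <- red$birth_edge; dt <- red$death_tri
  birth <- F$edges$birth[be]
  death <- F$triangles$birth[dt]
  keep <- death > birth
  n_zero <- sum(!keep)
  bc <- data.frame(birth = birth[keep], death = death[keep],
                   birth_edge = be[keep], death_triangle = dt[keep],
                   persistence = death[keep] - birth[keep])
  chains <- red$rep_chain[keep]
  inf_e <- red$infinite_edges
  if (length(inf_e)) {
    bc <- rbind(bc, data.frame(birth = F$edges$birth[inf_e], death = Inf,
                               birth_edge = inf_e, death_triangle = NA_integer_,
                               persistence = Inf))
    chains <- c(chains, vector("list", length(inf_e)))
  }
  ord <- order(bc$birth, bc$death)
  bc <- bc[ord, , drop = FALSE]
  rownames(bc) <- NULL
  structure(bc, rep_chains = chains[ord], n_zero_discarded = n_zero,
            n_infinite = length(inf_e), dimension = 1L,
            class = c("h1_barcode", "data.frame"))
}

empty_barcode <- function() {
  structure(data.frame(birth = numeric(0), death = numeric(0),
                       birth_edge = integer(0), death_triangle = integer(0),
                       persistence = numeric(0)),
            rep_chains = list(), n_zero_discarded = 0L, n_infinite = 0L,
            dimension = 1L, class = c("h1_barcode", "data.frame"))
}

#' First Betti number at a threshold
#'
#' Number of barcode intervals alive at filtration value `t`, i.e. with
#' `birth <= t < death`.
#'
#' @param barcode An `h1_barcode`.
#' @param t Threshold (pseudo-distance value).
#' @return Integer count.
#' @export
betti1_at <- function(barcode, t) {
  stopifnot(inherits(barcode, "h1_barcode"))
  sum(barcode$birth <= t & t < barcode$death)
}

#' First Betti number by direct rank-nullity (independent oracle)
#'
#' Computes beta_1 of the flag complex at threshold `t` from scratch as
#' dim ker(d1) - rank(d2) = (E - rank d1) - rank d2, with ranks over GF(2)
#' obtained by plain Gaussian elimination.  Shares no code path with the
#' persistence pairing and is used to validate `compute_h1_barcode()`.
#'
#' @param D A `pseudo_distance`.
#' @param t Threshold.
#' @return Integer beta_1.
#' @export
betti1_rank_nullity <- function(D, t) {
  stopifnot(inherits(D, "pseudo_distance"))
  n <- nrow(D$omega)
  mask <- D$mask & !is.na(D$omega) & D$omega <= t
  ut <- which(upper.tri(mask) & mask, arr.ind = TRUE)
  E <- nrow(ut)
  if (E == 0L) return(0L)
  # rank of the vertex-edge boundary over GF(2)
  r1 <- gf2_rank_cpp(c(ut[, 1L], ut[, 2L]), rep(seq_len(E), 2L), n, E)
  # triangles present at t
  eid <- matrix(0L, n, n)
  eid[ut] <- seq_len(E); eid[ut[, c(2L, 1L), drop = FALSE]] <- seq_len(E)
  rows <- integer(0); cols <- integer(0); Tn <- 0L
  for (i in seq_len(n - 2L)) for (j in seq(i + 1L, n - 1L)) {
    if (!mask[i, j]) next
    for (k in seq(j + 1L, n)) {
      if (mask[i, k] && mask[j, k]) {
        Tn <- Tn + 1L
        rows <- c(rows, eid[i, j], eid[i, k], eid[j, k])
        cols <- c(cols, Tn, Tn, Tn)
      }
    }
  }
  r2 <- if (Tn) gf2_rank_cpp(rows, cols, E, Tn) else 0L
  (E - r1) - r2
}

#' @export
print.h1_barcode <- function(x, ...) {
  cat("H1 barcode:", sum(is.finite(x$death)), "finite +",
      sum(!is.finite(x$death)), "infinite intervals (",
      attr(x, "n_zero_discarded"), "zero-persistence pairs discarded )\n")
  print(as.data.frame(x))
  invisible(x)
}
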