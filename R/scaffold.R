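#' Persistence homological scaffold from persistent features
#'
#' Aggregates volume-optimal persistent cycles into a region x region network:
#' the weight of edge (i, j) is the sum of the persistences of every cycle
#' that passes through it.  Edges in no cycle get weight zero.
#'
#' @param features List of `persistent_feature` (one subject-condition).
#' @param n_regions Number of regions.
#' @param labels Optional region labels.
#' @param condition Optional condition label stored as provenance.
#' @return A `scaffold_network`: list with symmetric nonnegative matrix `w`,
#'   `labels`, `provenance` ("subject-level") and `condition`.
#' @export
build_scaffold <- function(features, n_regions, labels = NULL, condition = NA_character_) {
  if (is.null(labels)) labels <- paste0("R", seq_len(n_regions))
  w <- matrix(0, n_regions, n_regions, dimnames = list(labels, labels))
  for (f in features) {
    stopifnot(inherits(f, "persistent_feature"))
    ce <- f$cycle_edges
    stop_if(any(ce$i > n_regions | ce$j > n_regions | ce$i < 1L | ce$j < 1L),
            "cycle edge index out of range")
    pi_t <- f$interval$persistence
    idx <- cbind(ce$i, ce$j)
    w[idx] <- w[idx] + pi_t
    w[idx[, 2:1, drop = FALSE]] <- w[idx[, 2:1, drop = FALSE]] + pi_t
  }
  scaffold_network(w, labels, provenance = "subject-level", condition = condition)
}

scaffold_network <- function(w, labels, provenance, condition = NA_character_) {
  stopifnot(isTRUE(all.equal(w, t(w))), all(w >= 0), all(diag(w) == 0))
  dimnames(w) <- list(labels, labels)
  structure(list(w = w, labels = labels, provenance = provenance,
                 condition = condition), class = "scaffold_network")
}

#' Group-averaged scaffold
#'
#' Entrywise arithmetic mean of subject-level scaffolds sharing the same
#' region set (and, typically, condition).
#'
#' @param scaffolds List of `scaffold_network`.
#' @return A `scaffold_network` with provenance "group-averaged".
#' @export
group_average <- function(scaffolds) {
  stopifnot(length(scaffolds) >= 1L)
  labs <- scaffolds[[1L]]$labels
  for (s in scaffolds) {
    stopifnot(inherits(s, "scaffold_network"))
    stop_if(!identical(s$labels, labs), "scaffolds have mismatched region labels")
  }
  w <- Reduce(`+`, lapply(scaffolds, `[[`, "w")) / length(scaffolds)
  scaffold_network(w, labs, provenance = "group-averaged",
                   condition = scaffolds[[1L]]$condition)
}

#' Persistence centrality
#'
#' PC(i) = sum_j w_ij / sum_{j,k} w_jk over ordered pairs, so the vector sums
#' to one: each region's share of total scaffold weight, i.e. of summed cycle
#' persistence passing through it.
#'
#' @param S A `scaffold_network`.
#' @return A `centrality` vector (kind "PC").
#' @export
persistence_centrality <- function(S) {
  stopifnot(inherits(S, "scaffold_network"))
  rs <- rowSums(S$w)
  denom <- sum(rs)
  stop_if(denom <= 0, "persistence centrality undefined for an all-zero scaffold")
  centrality(rs / denom, S$labels, kind = "PC")
}

#' @export
print.scaffold_network <- function(x, ...) {
  cat("scaffold network (", x$provenance, "):", length(x$labels), "regions,",
      sum(x$w[upper.tri(x$w)] > 0), "weighted edges, total mass",
      format(sum(x$w) / 2), "\n")
  invisible(x)
}
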