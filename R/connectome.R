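#' Functional connectome from regional time series
#'
#' Computes the sample Pearson correlation between every pair of regional
#' time series of one subject under one condition, yielding a symmetric
#' functional connectome with unit diagonal.
#'
#' @param ts A `regional_ts_set` as produced by `generate_bold_like()` or
#'   `generate_meg_like()`, or a plain numeric matrix (time x region).
#' @param subject Subject index (ignored when `ts` is a matrix).
#' @param condition Condition label (ignored when `ts` is a matrix).
#' @return A `functional_connectome`: list with `r` (region x region Pearson
#'   matrix) and `labels`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' G <- compute_fc(x)
#' stopifnot(isSymmetric(G$r), all(diag(G$r) == 1))
#' @export
compute_fc <- function(ts, subject = 1L, condition = NULL) {
  x <- as_region_matrix(ts, subject, condition)
  stop_if(nrow(x) < 3L, "need at least 3 timepoints to estimate correlations")
  stop_if(anyNA(x) || any(!is.finite(x)), "time series contain NA/non-finite values")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    stop("constant time series for region(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r <- cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  functional_connectome(r, colnames(x))
}

#' @rdname compute_fc
#' @param r Symmetric correlation matrix with unit diagonal.
#' @param labels Region labels (defaults to rownames or R1..Rn).
#' @export
functional_connectome <- function(r, labels = NULL) {
  r <- as.matrix(r)
  stop_if(nrow(r) != ncol(r), "correlation matrix must be square")
  stop_if(max(abs(r - t(r))) > 1e-8, "correlation matrix must be symmetric")
  stop_if(any(abs(diag(r)) - 1 > 1e-8), "diagonal must be 1")
  stop_if(any(r < -1 - 1e-8 | r > 1 + 1e-8), "correlations must lie in [-1, 1]")
  if (is.null(labels)) labels <- rownames(r)
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(r)))
  dimnames(r) <- list(labels, labels)
  structure(list(r = r, labels = labels), class = "functional_connectome")
}

# Extract a time x region matrix from a regional_ts_set or pass a matrix through.
as_region_matrix <- function(ts, subject = 1L, condition = NULL) {
  if (is.matrix(ts)) {
    if (is.null(colnames(ts))) colnames(ts) <- paste0("R", seq_len(ncol(ts)))
    return(ts)
  }
  stopifnot(inherits(ts, "regional_ts_set"))
  ci <- if (is.null(condition)) 1L else match(condition, ts$conditions)
  stop_if(is.na(ci), "unknown condition: ", condition)
  x <- t(ts$data[subject, ci, , ])      # region x time -> time x region
  colnames(x) <- ts$regions
  x
}

#' Pseudo-distance matrix from a functional connectome
#'
#' Converts each retained correlation r into the pseudo-distance omega = 1 - r.
#' Pairs with non-positive correlation are excluded outright: they are absent
#' from every complex of the downstream filtration rather than being assigned
#' a large distance.
#'
#' @param G A `functional_connectome`.
#' @return A `pseudo_distance`: list with `omega` (NA where excluded), logical
#'   `mask` of retained pairs, and `labels`.
#' @export
to_pseudo_distance <- function(G) {
  stopifnot(inherits(G, "functional_connectome"))
  r <- G$r
  mask <- r > 0
  diag(mask) <- FALSE
  omega <- 1 - r
  omega[!mask] <- NA_real_
  diag(omega) <- NA_real_
  structure(list(omega = omega, mask = mask, labels = G$labels),
            class = "pseudo_distance")
}

#' Degree centrality of a functional connectome
#'
#' DC(i) = sum_j r_ij / sum_{j,k} r_jk with both sums over ordered off-diagonal
#' pairs, so that the centralities sum to one.  By default only positive
#' correlations enter both sums, matching the edge set that is analysed
#' topologically; set `include_negative = TRUE` to sum raw signed weights.
#'
#' @param G A `functional_connectome`.
#' @param include_negative Keep negative correlations in the sums?
#' @return A `centrality` vector (named, unit sum, kind "DC").
#' @export
degree_centrality <- function(G, include_negative = FALSE) {
  stopifnot(inherits(G, "functional_connectome"))
  w <- G$r
  diag(w) <- 0
  if (!include_negative) w[w <= 0] <- 0
  rs <- rowSums(w)
  denom <- sum(rs)
  stop_if(denom <= 0, "degree centrality undefined: no positive total weight")
  centrality(rs / denom, G$labels, kind = "DC")
}

centrality <- function(values, labels, kind) {
  v <- as.numeric(values)
  names(v) <- labels
  structure(v, kind = kind, class = "centrality")
}

#' @export
print.functional_connectome <- function(x, ...) {
  cat("functional connectome:", length(x$labels), "regions,",
      sum(x$r[upper.tri(x$r)] > 0), "positive pairs\n")
  invisible(x)
}

#' @export
print.centrality <- function(x, ...) {
  cat(attr(x, "kind"), "centrality over", length(x), "regions (sum =",
      format(sum(x)), ")\n")
  print(utils::head(unclass(x)))
  invisible(x)
}
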