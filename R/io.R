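#' Read and write labelled matrices as TSV
#'
#' Plain-text interchange for connectomes, scaffolds, centrality tables and
#' band power ratios: a header row of column labels, a leading label column
#' for rows.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `read_matrix_tsv` returns a numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Barcode I/O as TSV
#'
#' Columns: dim, birth, death, birth_edge_i, birth_edge_j, death_triangle.
#'
#' @param barcode An `h1_barcode`.
#' @param F The `flag_filtration` it came from (for edge endpoints).
#' @param path File path.
#' @export
write_barcode_tsv <- function(barcode, F, path) {
  df <- data.frame(dim = 1L, birth = barcode$birth, death = barcode$death,
                   birth_edge_i = F$edges$i[barcode$birth_edge],
                   birth_edge_j = F$edges$j[barcode$birth_edge],
                   death_triangle = barcode$death_triangle)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a study configuration as YAML
#'
#' @param config A `synthetic_study_config`.
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(synthetic_study_config,
          x[intersect(names(x), names(formals(synthetic_study_config)))])
}
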