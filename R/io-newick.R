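#' Serialise a tree as Newick text
#'
#' Thin validated wrapper over `ape`'s writer: requires named leaves and
#' branch lengths, returns a single `;`-terminated Newick string. Alphanumeric
#' taxon names are written unquoted, so the output loads directly in standard
#' tree software.
#'
#' @param tree an `ape::phylo` object with tip labels and edge lengths.
#' @param path optional file; when given the string is also written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)) ||
      anyNA(tree$tip.label))
    stop("every leaf must be named")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#'
#' @param text_or_path Newick string or path to a file containing one.
#' @return an `ape::phylo`.
#' @export
read_newick <- function(text_or_path) {
  if (file.exists(text_or_path)) ape::read.tree(text_or_path)
  else ape::read.tree(text = text_or_path)
}

#' Write a tibble as CSV (comma separator, "." decimal, header row)
#'
#' Fixed dialect so outputs do not drift with locale.
#' @param x data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Read a CSV written by this package
#' @param path file path.
#' @return a tibble.
#' @export
read_result_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a pairwise matrix as CSV with an id header row and column
#' @param m a [pairwise_matrix()] or plain named square matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- tibble::as_tibble(unclass(m), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(id = rownames(m)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a pairwise matrix CSV (id column + square numeric block)
#' @param path file path.
#' @param kind kind tag for [pairwise_matrix()].
#' @return a [pairwise_matrix()].
#' @export
read_matrix_csv <- function(path, kind = "geographic") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  colnames(m) <- names(df)[-1]
  pairwise_matrix(m, kind)
}
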