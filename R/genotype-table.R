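#' Diploid multi-allelic genotype table
#'
#' Container for individuals-by-loci diploid allele calls (microsatellite
#' style: small positive integer allele codes). Internally two aligned integer
#' matrices, one per allele copy, with `NA` marking a missing genotype; a
#' genotype is either fully typed or fully missing at a locus (half-missing
#' calls are rejected, matching the Genepop convention where `0000`/`000000`
#' codes the whole genotype as absent).
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele codes;
#'   `NA` = missing. Must have identical dimensions and missingness pattern.
#' @param ids character vector of individual ids (unique).
#' @param loci character vector of locus names.
#' @param pop optional per-individual population/unit label.
#' @return an object of class `genotype_table`.
#' @examples
#' g <- genotype_table(matrix(c(1L, 1L), 2, 1), matrix(c(1L, 2L), 2, 1),
#'                     ids = c("b1", "b2"), loci = "L1")
#' allele_frequencies(g)
#' @export
genotype_table <- function(a1, a2, ids, loci, pop = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2))) stop("allele matrices differ in shape")
  if (length(ids) != nrow(a1)) stop("ids do not match row count")
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (length(loci) != ncol(a1)) stop("locus names do not match column count")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype: individual ", ids[w[1]], ", locus ", loci[w[2]])
  }
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele codes must be positive integers (missing is NA)")
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  if (!is.null(pop) && length(pop) != length(ids))
    stop("pop labels do not match individual count")
  structure(list(a1 = a1, a2 = a2, ids = as.character(ids),
                 loci = as.character(loci),
                 pop = if (is.null(pop)) NULL else as.character(pop)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("<genotype_table>", length(x$ids), "individuals x",
      length(x$loci), "loci\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.2f%%", 100 * miss))
  if (!is.null(x$pop)) cat(" | populations:", paste(unique(x$pop), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(length(x$ids), length(x$loci))

#' Tidy a genotype table into long form
#'
#' @param x a `genotype_table`.
#' @param ... unused.
#' @return a tibble with columns `id`, `locus`, `allele1`, `allele2`
#'   (and `pop` when present); one row per individual-locus genotype.
#' @export
tidy.genotype_table <- function(x, ...) {
  out <- tibble::tibble(
    id = rep(x$ids, times = length(x$loci)),
    locus = rep(x$loci, each = length(x$ids)),
    allele1 = as.vector(x$a1),
    allele2 = as.vector(x$a2)
  )
  if (!is.null(x$pop)) out$pop <- rep(x$pop, times = length(x$loci))
  dplyr::arrange(out, match(.data$id, x$ids), match(.data$locus, x$loci))
}

#' Build a genotype table from a long tibble
#'
#' Inverse of [tidy.genotype_table()]: expects columns `id`, `locus`,
#' `allele1`, `allele2` and optionally `pop`.
#'
#' @param tbl long-format tibble of genotypes.
#' @return a `genotype_table`.
#' @export
as_genotype_table <- function(tbl) {
  stopifnot(all(c("id", "locus", "allele1", "allele2") %in% names(tbl)))
  ids <- unique(tbl$id); loci <- unique(tbl$locus)
  a1 <- matrix(NA_integer_, length(ids), length(loci), dimnames = list(ids, loci))
  a2 <- a1
  i <- match(tbl$id, ids); j <- match(tbl$locus, loci)
  a1[cbind(i, j)] <- as.integer(tbl$allele1)
  a2[cbind(i, j)] <- as.integer(tbl$allele2)
  pop <- NULL
  if ("pop" %in% names(tbl))
    pop <- tbl$pop[match(ids, tbl$id)]
  genotype_table(a1, a2, ids, loci, pop)
}

# Subset individuals (used by complete-case paths and tests).
subset_individuals <- function(g, keep) {
  idx <- if (is.character(keep)) match(keep, g$ids) else keep
  genotype_table(g$a1[idx, , drop = FALSE], g$a2[idx, , drop = FALSE],
                 g$ids[idx], g$loci,
                 if (is.null(g$pop)) NULL else g$pop[idx])
}
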