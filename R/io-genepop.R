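#' Read a Genepop genotype file
#'
#' Parses the classic Genepop layout: one title line, locus names (one per
#' line or comma-separated on one line), then one or more `Pop` blocks
#' (case-insensitive) of `id , gggg gggg ...` rows. Both 2-digit and 3-digit
#' allele encodings are accepted; the width is auto-detected per file and
#' must be consistent (mixed widths are rejected). `00`/`000` per allele
#' (i.e. `0000`/`000000` per genotype) codes a missing genotype.
#'
#' @param path path to a Genepop file.
#' @return a [genotype_table()] with the Pop block index as `pop` label.
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a Genepop file: too few lines")
  body <- lines[-1]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no Pop block found")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- unlist(strsplit(locus_lines, "\\s*,\\s*"))
  loci <- trimws(loci[nzchar(trimws(loci))])
  if (!length(loci)) stop("no locus names before first Pop")
  L <- length(loci)

  ids <- character(); pop <- character()
  rows <- list()
  block <- 0L
  for (k in seq_along(body)) {
    if (k %in% pop_idx) { block <- block + 1L; next }
    if (block == 0L) next
    ln <- body[k]
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop("parse error at line ", k + 1, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    geno <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(geno) != L)
      stop("parse error at line ", k + 1, ": ", length(geno),
           " genotypes for ", L, " loci")
    ids <- c(ids, id); pop <- c(pop, paste0("pop", block))
    rows[[length(rows) + 1L]] <- geno
  }
  if (!length(rows)) stop("no individuals found")
  gm <- do.call(rbind, rows)
  widths <- unique(as.vector(nchar(gm)))
  if (length(widths) != 1 || !(widths %in% c(4L, 6L)))
    stop("inconsistent or unsupported allele code width (need all 2- or all 3-digit)")
  w <- widths / 2
  a1 <- matrix(as.integer(substr(gm, 1, w)), nrow(gm), L)
  a2 <- matrix(as.integer(substr(gm, w + 1, 2 * w)), nrow(gm), L)
  half <- xor(a1 == 0L, a2 == 0L)
  if (any(half)) {
    wpos <- which(half, arr.ind = TRUE)[1, ]
    stop("half-missing genotype for individual ", ids[wpos[1]],
         " at locus ", loci[wpos[2]])
  }
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  genotype_table(a1, a2, ids, loci, pop)
}

#' Write a genotype table as Genepop
#'
#' One title line, one locus name per line, individuals grouped into `Pop`
#' blocks by their `pop` label (a single block when absent), 3-digit allele
#' codes, missing genotypes as `000000`, `id ,` separator.
#'
#' @param g a [genotype_table()].
#' @param path output file.
#' @param title title line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, path, title = "ecogenlink export") {
  a1 <- g$a1; a2 <- g$a2
  if (any(a1 > 999, na.rm = TRUE) || any(a2 > 999, na.rm = TRUE))
    stop("allele codes exceed 3 digits")
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  gm <- matrix(sprintf("%03d%03d", a1, a2), nrow(a1), ncol(a1))
  pop <- g$pop %||% rep("pop1", length(g$ids))
  out <- c(title, g$loci)
  for (p in unique(pop)) {
    out <- c(out, "Pop")
    rows <- which(pop == p)
    out <- c(out, paste(g$ids[rows], ",", apply(gm[rows, , drop = FALSE], 1,
                                                paste, collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
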