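#' Habitat-use proportions from GPS fixes
#'
#' Per individual, the fraction of fixes falling in each of the seven
#' land-cover classes (count in class / total fixes).
#'
#' @param fixes tibble with columns `id` and `class` (one row per fix);
#'   classes must come from [habitat_classes].
#' @return tibble `id`, one column per class, `n_fixes`.
#' @export
use_proportions <- function(fixes) {
  stopifnot(all(c("id", "class") %in% names(fixes)))
  bad <- setdiff(unique(fixes$class), habitat_classes)
  if (length(bad)) stop("unknown land-cover class(es): ", paste(bad, collapse = ", "))
  counts <- fixes |>
    dplyr::count(.data$id, class = factor(.data$class, levels = habitat_classes),
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)
  tot <- rowSums(counts[habitat_classes])
  if (any(tot == 0))
    stop("individual(s) with zero fixes: ",
         paste(counts$id[tot == 0], collapse = ", "))
  out <- counts
  out[habitat_classes] <- counts[habitat_classes] / tot
  out$n_fixes <- as.integer(tot)
  out
}

#' Arcsine-square-root transform of proportions
#'
#' Element-wise asin(sqrt(p)), the classical variance-stabilising transform
#' for proportions; maps \[0, 1\] onto \[0, pi/2\].
#'
#' @param u habitat-use tibble (`id` + class columns) or a bare numeric
#'   matrix/vector of proportions.
#' @return same shape as the input with class columns transformed.
#' @export
arcsine_sqrt <- function(u) {
  tf <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("proportions must lie in [0, 1]")
    asin(sqrt(p))
  }
  if (is.data.frame(u)) {
    cls <- intersect(habitat_classes, names(u))
    if (!length(cls)) stop("no land-cover class columns found")
    u[cls] <- lapply(u[cls], tf)
    u
  } else tf(u)
}

#' Covariance PCA of (transformed) habitat use
#'
#' Same engine and conventions as [genotype_pca()], applied to the 7-column
#' arcsine-square-root-transformed use matrix.
#'
#' @param u transformed habitat-use tibble (`id` + class columns) or matrix.
#' @param n_axes number of axes.
#' @return an `eco_pca` object.
#' @export
habitat_pca <- function(u, n_axes = 3) {
  if (is.data.frame(u)) {
    ids <- u$id %||% as.character(seq_len(nrow(u)))
    X <- as.matrix(u[intersect(habitat_classes, names(u))])
  } else {
    X <- as.matrix(u); ids <- rownames(u) %||% as.character(seq_len(nrow(u)))
  }
  res <- pca_core(X, n_axes)
  sc <- tibble::as_tibble(res$scores, .name_repair = "minimal")
  names(sc) <- paste0("PC", seq_len(ncol(sc)))
  structure(list(scores = dplyr::bind_cols(tibble::tibble(id = ids), sc),
                 percent_variance = res$percent_variance,
                 percent_all = res$percent_all,
                 loadings = res$loadings, source = "habitat"),
            class = "eco_pca")
}

#' Habitat availability per management unit from random points
#'
#' Emulates scoring random points within multi-annual home ranges: per unit,
#' the class proportions over its sampled points.
#'
#' @param points tibble with columns `unit` and `class`.
#' @return tibble `unit`, one column per class, `n_points`.
#' @export
availability_from_points <- function(points) {
  stopifnot(all(c("unit", "class") %in% names(points)))
  bad <- setdiff(unique(points$class), habitat_classes)
  if (length(bad)) stop("unknown land-cover class(es): ", paste(bad, collapse = ", "))
  counts <- points |>
    dplyr::count(.data$unit, class = factor(.data$class, levels = habitat_classes),
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n", values_fill = 0L)
  tot <- rowSums(counts[habitat_classes])
  if (any(tot == 0))
    stop("unit(s) with zero sampled points: ",
         paste(counts$unit[tot == 0], collapse = ", "))
  out <- counts
  out[habitat_classes] <- counts[habitat_classes] / tot
  out$n_points <- as.integer(tot)
  out
}

#' Chi-squared heterogeneity test of availability across units
#'
#' Pearson chi-squared on the units x classes count table (counts
#' reconstructed as proportions x sampled point count; the test is
#' meaningless on proportions alone). df = (U - 1)(C - 1).
#'
#' @param a availability tibble from [availability_from_points()] (class
#'   columns + `n_points`).
#' @return tibble `statistic`, `df`, `p_value`.
#' @export
availability_chi2 <- function(a) {
  stopifnot("n_points" %in% names(a))
  counts <- round(as.matrix(a[habitat_classes]) * a$n_points)
  keep <- colSums(counts) > 0
  counts <- counts[, keep, drop = FALSE]
  exp_counts <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(exp_counts == 0))
    stop("expected count of zero; pool sparse habitat classes before testing")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' L1 habitat-availability distance between management units
#'
#' d(u, v) = sum over classes of |avail_u - avail_v| (the "absolute
#' difference" distance; `mean` variant switchable).
#'
#' @param a availability tibble (`unit` + class columns).
#' @param method `"sum"` (default) or `"mean"` of absolute differences.
#' @return symmetric unit x unit distance matrix.
#' @export
availability_distance <- function(a, method = c("sum", "mean")) {
  method <- match.arg(method)
  m <- as.matrix(a[habitat_classes])
  rownames(m) <- a$unit
  u <- nrow(m)
  d <- matrix(0, u, u, dimnames = list(a$unit, a$unit))
  for (i in seq_len(u)) for (j in seq_len(u)) {
    d[i, j] <- sum(abs(m[i, ] - m[j, ]))
  }
  if (method == "mean") d <- d / ncol(m)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`) on a symmetric zero-diagonal
#' distance matrix; recovers the generating topology and branch lengths
#' exactly on additive matrices. Negative limb lengths are retained by
#' default (set `clamp = TRUE` to floor them at 0).
#'
#' @param d symmetric distance matrix with row/column names, >= 3 taxa.
#' @param clamp floor negative branch lengths at zero.
#' @return an `ape::phylo`.
#' @export
neighbor_joining <- function(d, clamp = FALSE) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (is.null(rownames(d))) stop("taxa must be named")
  tr <- ape::nj(d)
  if (clamp) tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Summarise a translocation event table
#'
#' Counts and percentages of cross-unit events and, among those, northward
#' events, plus a source x destination flow matrix. `unit_order` is the
#' strict south-to-north ordering of units; a destination later in the order
#' than the source is a northward move.
#'
#' @param t translocation tibble (`source`, `dest`, optionally `year`).
#' @param unit_order character vector, southernmost first, covering every
#'   unit present in `t`.
#' @return list of class `transloc_summary`: `n_total`, `n_cross`,
#'   `pct_cross`, `n_north`, `pct_north` (percent of cross-unit events),
#'   rounded displays and the flow matrix.
#' @export
translocation_summary <- function(t, unit_order) {
  missing_units <- setdiff(unique(c(t$source, t$dest)), unit_order)
  if (length(missing_units))
    stop("unit(s) absent from unit_order: ", paste(missing_units, collapse = ", "))
  n_total <- nrow(t)
  flow <- matrix(0L, length(unit_order), length(unit_order),
                 dimnames = list(source = unit_order, dest = unit_order))
  if (n_total > 0) {
    tab <- table(factor(t$source, unit_order), factor(t$dest, unit_order))
    flow[] <- as.integer(tab)
  }
  src_rank <- match(t$source, unit_order)
  dst_rank <- match(t$dest, unit_order)
  cross <- dst_rank != src_rank
  n_cross <- sum(cross)
  n_north <- sum(dst_rank[cross] > src_rank[cross])
  structure(list(
    n_total = n_total, n_cross = n_cross,
    pct_cross = if (n_total > 0) 100 * n_cross / n_total else NA_real_,
    n_north = n_north,
    pct_north = if (n_cross > 0) 100 * n_north / n_cross else NA_real_,
    pct_cross_rounded = if (n_total > 0) round(100 * n_cross / n_total) else NA_real_,
    pct_north_rounded10 = if (n_cross > 0) 10 * round(10 * n_north / n_cross) else NA_real_,
    flow = flow), class = "transloc_summary")
}

#' @export
print.transloc_summary <- function(x, ...) {
  cat("<transloc_summary>", x$n_total, "events;",
      x$n_cross, sprintf("(%s%%)", format(round(x$pct_cross))), "cross-unit;",
      x$n_north, sprintf("(~%s%%)", format(x$pct_north_rounded10)),
      "of cross-unit moves northward\n")
  invisible(x)
}

#' @export
tidy.transloc_summary <- function(x, ...) {
  tibble::tibble(
    measure = c("total", "cross_unit", "northward_of_cross"),
    count = c(x$n_total, x$n_cross, x$n_north),
    percent = c(100, x$pct_cross, x$pct_north))
}
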