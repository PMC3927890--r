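#' Per-locus allele frequencies
#'
#' Relative frequencies over the 2 x (non-missing individuals) gene copies at
#' each locus; only observed alleles appear.
#'
#' @param g a [genotype_table()].
#' @return a tibble `locus`, `allele`, `count`, `freq`.
#' @export
allele_frequencies <- function(g) {
  purrr::map_dfr(seq_along(g$loci), function(l) {
    copies <- c(g$a1[, l], g$a2[, l])
    copies <- copies[!is.na(copies)]
    if (!length(copies)) stop("locus ", g$loci[l], " is fully missing")
    tab <- table(copies)
    tibble::tibble(locus = g$loci[l],
                   allele = as.integer(names(tab)),
                   count = as.integer(tab),
                   freq = as.numeric(tab) / length(copies))
  })
}

# loci x allele-code lookup matrix of frequencies (0 where unobserved)
freq_matrix <- function(g, af = allele_frequencies(g)) {
  amax <- max(af$allele)
  fm <- matrix(0, length(g$loci), amax,
               dimnames = list(g$loci, seq_len(amax)))
  fm[cbind(match(af$locus, g$loci), af$allele)] <- af$freq
  fm
}

#' Observed and expected heterozygosity
#'
#' Ho is the fraction of non-missing individuals heterozygous at the locus;
#' He = 1 - sum(p^2) from the sample allele frequencies, with the unbiased
#' small-sample variant He * 2n/(2n - 1) reported alongside.
#'
#' @param g a [genotype_table()].
#' @return tibble `locus`, `n_typed`, `ho`, `he`, `he_unbiased`, plus an
#'   attached `means` attribute with the across-locus means.
#' @export
heterozygosities <- function(g) {
  af <- allele_frequencies(g)
  out <- purrr::map_dfr(seq_along(g$loci), function(l) {
    a1 <- g$a1[, l]; a2 <- g$a2[, l]
    typed <- !is.na(a1)
    ho <- mean(a1[typed] != a2[typed])
    p <- af$freq[af$locus == g$loci[l]]
    he <- 1 - sum(p^2)
    n2 <- 2 * sum(typed)
    tibble::tibble(locus = g$loci[l], n_typed = sum(typed), ho = ho, he = he,
                   he_unbiased = if (n2 > 1) he * n2 / (n2 - 1) else NA_real_)
  })
  attr(out, "means") <- c(ho = mean(out$ho), he = mean(out$he),
                          he_unbiased = mean(out$he_unbiased))
  out
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium at one locus
#'
#' The observed heterozygote count is compared against its null distribution
#' obtained by permuting the 2n gene copies and re-pairing them at random
#' (`n_perm` tables). Two-sided by deviation from the null mean of the
#' heterozygote count, with the add-one correction
#' p = (#\{as or more extreme\} + 1) / (B + 1).
#'
#' @param g a [genotype_table()].
#' @param locus locus name or index.
#' @param n_perm number of permuted tables (default 10000).
#' @param seed integer seed.
#' @return tibble `locus`, `n_het`, `n_typed`, `p_value`, `n_perm`.
#' @export
hwe_test <- function(g, locus, n_perm = 10000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  l <- if (is.character(locus)) match(locus, g$loci) else locus
  if (is.na(l)) stop("unknown locus: ", locus)
  a1 <- g$a1[, l]; a2 <- g$a2[, l]
  typed <- !is.na(a1)
  copies <- c(a1[typed], a2[typed])
  if (length(unique(copies)) < 2)
    stop("locus ", g$loci[l], " is monomorphic: HWE test undefined")
  n <- sum(typed)
  h_obs <- sum(a1[typed] != a2[typed])
  with_seed(seed, {
    h_null <- vapply(seq_len(n_perm), function(b) {
      perm <- sample(copies)
      sum(perm[seq_len(n)] != perm[n + seq_len(n)])
    }, numeric(1))
  })
  mu <- mean(h_null)
  p <- (sum(abs(h_null - mu) >= abs(h_obs - mu)) + 1) / (n_perm + 1)
  tibble::tibble(locus = g$loci[l], n_het = h_obs, n_typed = n,
                 p_value = p, n_perm = n_perm)
}

#' Homozygosity by loci (HL)
#'
#' Per-individual index weighting each locus by its expected heterozygosity:
#' HL = sum(E_h over homozygous loci) /
#'      (sum(E_h over homozygous) + sum(E_j over heterozygous)),
#' where E_l is the locus's expected heterozygosity in the full sample.
#' Missing loci are excluded from both sums. 0 = fully heterozygous,
#' 1 = fully homozygous.
#'
#' @param g a [genotype_table()].
#' @param unbiased use the unbiased He variant as locus weights
#'   (default `FALSE`: plain sample He).
#' @return tibble `id`, `hl`, `n_typed`.
#' @export
homozygosity_by_loci <- function(g, unbiased = FALSE) {
  het <- heterozygosities(g)
  e <- if (unbiased) het$he_unbiased else het$he
  hom <- g$a1 == g$a2                    # n x L, NA where missing
  n_typed <- rowSums(!is.na(hom))
  if (any(n_typed == 0))
    stop("individual(s) with all loci missing: ",
         paste(g$ids[n_typed == 0], collapse = ", "))
  ew <- matrix(e, nrow(hom), ncol(hom), byrow = TRUE)
  ew[is.na(hom)] <- 0
  num <- rowSums(ew * ifelse(is.na(hom), 0, hom))
  den <- rowSums(ew)
  tibble::tibble(id = g$ids, hl = unname(num / den),
                 n_typed = unname(n_typed))
}

#' Per-individual, per-locus homozygosity indicators
#'
#' 1 = homozygous, 0 = heterozygous, NA = untyped. Input to the
#' single-locus-effect F-test.
#'
#' @param g a [genotype_table()].
#' @return numeric matrix individuals x loci with dimnames.
#' @export
single_locus_homozygosities <- function(g) {
  m <- (g$a1 == g$a2) * 1
  dimnames(m) <- list(g$ids, g$loci)
  m
}

#' Queller-Goodnight pairwise relatedness
#'
#' For focal x with alleles (a, b) and partner y with (c, d), each locus
#' contributes numerator 0.5(d_ac + d_ad + d_bc + d_bd) - p_a - p_b and
#' denominator 1 + d_ab - p_a - p_b (d = identity indicator, p = sample
#' allele frequency). The estimate is the ratio of locus-summed numerator to
#' locus-summed denominator, and the reported value is the mean of the two
#' ordered estimates (x focal, y focal). Loci missing in either member of a
#' pair are excluded pairwise; pairs sharing no typed locus are NA.
#' Frequencies come from the full sample (no leave-two-out). Values can fall
#' slightly outside \[-1, 1\] with rare alleles; they are reported raw.
#'
#' @param g a [genotype_table()].
#' @return a [pairwise_matrix()] of kind `"relatedness"` (diagonal = self
#'   estimate).
#' @export
qg_relatedness <- function(g) {
  if (length(g$ids) < 2) stop("need >= 2 individuals")
  fm <- freq_matrix(g)
  n <- length(g$ids); L <- length(g$loci)
  num <- matrix(0, n, n); den_acc <- matrix(0, n, n)
  for (l in seq_len(L)) {
    a1 <- g$a1[, l]; a2 <- g$a2[, l]
    typed <- !is.na(a1)
    if (sum(typed) < 1) next
    # allele-sharing count S_xy = d(a,c)+d(a,d)+d(b,c)+d(b,d)
    s <- outer(a1, a1, "==") + outer(a1, a2, "==") +
         outer(a2, a1, "==") + outer(a2, a2, "==")
    s[is.na(s)] <- 0
    pa <- fm[l, ifelse(typed, a1, 1)]; pb <- fm[l, ifelse(typed, a2, 1)]
    numl <- 0.5 * s - matrix(pa + pb, n, n)          # row x focal
    denl <- 1 + (a1 == a2) - pa - pb                 # depends on focal only
    mask <- outer(typed, typed, "&")
    numl[!mask] <- 0
    num <- num + numl
    den_acc <- den_acc + matrix(ifelse(typed, denl, 0), n, n) * mask
  }
  r_ord <- num / den_acc                              # [x, y] = x focal
  r_ord[!is.finite(r_ord)] <- NA_real_
  r <- (r_ord + t(r_ord)) / 2
  dimnames(r) <- list(g$ids, g$ids)
  pairwise_matrix(r, "relatedness")
}

#' Molecular coancestry (allele sharing)
#'
#' Malecot-style similarity: f_xy = mean over shared typed loci of
#' (d_ac + d_ad + d_bc + d_bd) / 4. Identical homozygous genotypes give 1,
#' no shared alleles give 0. Substitutes a direct allele-sharing estimator
#' for pedigree-reconstruction coancestry; downstream matrix tests only need
#' a similarity matrix.
#'
#' @param g a [genotype_table()].
#' @return a [pairwise_matrix()] of kind `"coancestry"`.
#' @export
molecular_coancestry <- function(g) {
  if (length(g$ids) < 2) stop("need >= 2 individuals")
  n <- length(g$ids)
  acc <- matrix(0, n, n); nl <- matrix(0, n, n)
  for (l in seq_along(g$loci)) {
    a1 <- g$a1[, l]; a2 <- g$a2[, l]
    typed <- !is.na(a1)
    s <- outer(a1, a1, "==") + outer(a1, a2, "==") +
         outer(a2, a1, "==") + outer(a2, a2, "==")
    s[is.na(s)] <- 0
    mask <- outer(typed, typed, "&")
    acc <- acc + (s / 4) * mask
    nl <- nl + mask
  }
  f <- acc / nl
  f[nl == 0] <- NA_real_
  dimnames(f) <- list(g$ids, g$ids)
  pairwise_matrix(f, "coancestry")
}

# individuals x allele-indicator count matrix (0/1/2), mean-imputed missing
allele_count_matrix <- function(g) {
  af <- allele_frequencies(g)
  cols <- paste(af$locus, af$allele, sep = ".")
  n <- length(g$ids)
  X <- matrix(NA_real_, n, nrow(af), dimnames = list(g$ids, cols))
  for (j in seq_len(nrow(af))) {
    l <- match(af$locus[j], g$loci); a <- af$allele[j]
    X[, j] <- (g$a1[, l] == a) + (g$a2[, l] == a)
  }
  for (j in seq_len(ncol(X))) {
    mis <- is.na(X[, j])
    if (any(mis)) X[mis, j] <- mean(X[!mis, j])
  }
  X
}

# Shared covariance-PCA core with the sign convention: on each axis the
# element with the largest absolute loading is made positive.
pca_core <- function(X, n_axes) {
  if (nrow(X) < 3) stop("PCA needs >= 3 individuals")
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(p$sdev > 1e-12)
  if (n_axes > rank) stop("n_axes (", n_axes, ") exceeds rank (", rank, ")")
  flip <- vapply(seq_len(n_axes), function(a) {
    v <- p$rotation[, a]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(p$x[, seq_len(n_axes), drop = FALSE], 2, flip, "*")
  loadings <- sweep(p$rotation[, seq_len(n_axes), drop = FALSE], 2, flip, "*")
  pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = loadings,
       percent_variance = pct[seq_len(n_axes)], percent_all = pct)
}

#' Covariance PCA of genotypes
#'
#' PCA of the individuals x allele-indicator matrix (per-allele counts
#' 0/1/2, missing genotypes mean-imputed, columns centered, unscaled
#' covariance). Axes are ordered by decreasing eigenvalue; each axis's sign
#' is fixed so its largest-|loading| element is positive.
#'
#' @param g a [genotype_table()].
#' @param n_axes number of axes to return.
#' @return list of class `eco_pca`: `scores` tibble (`id`, `PC1`, ...),
#'   `percent_variance`, `loadings`.
#' @export
genotype_pca <- function(g, n_axes = 3) {
  res <- pca_core(allele_count_matrix(g), n_axes)
  sc <- tibble::as_tibble(res$scores, .name_repair = "minimal")
  names(sc) <- paste0("PC", seq_len(ncol(sc)))
  structure(list(scores = dplyr::bind_cols(tibble::tibble(id = g$ids), sc),
                 percent_variance = res$percent_variance,
                 percent_all = res$percent_all,
                 loadings = res$loadings, source = "genotype"),
            class = "eco_pca")
}

#' @export
print.eco_pca <- function(x, ...) {
  cat("<eco_pca>", x$source, "PCA:",
      paste0(sprintf("%.1f%%", x$percent_variance), collapse = ", "),
      "variance on returned axes\n")
  invisible(x)
}

#' @export
tidy.eco_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"id", names_to = "axis", values_to = "score")
}

#' @export
glance.eco_pca <- function(x, ...) {
  tibble::tibble(axis = paste0("PC", seq_along(x$percent_variance)),
                 percent_variance = x$percent_variance)
}
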