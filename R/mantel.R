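#' Euclidean geographic distance matrix from capture coordinates
#'
#' @param coords tibble with columns `id`, `x`, `y` (planar coordinates).
#' @return a [pairwise_matrix()] of kind `"geographic"` (zero diagonal).
#' @export
geographic_distance <- function(coords) {
  stopifnot(all(c("id", "x", "y") %in% names(coords)))
  bad <- coords$id[!is.finite(coords$x) | !is.finite(coords$y)]
  if (length(bad)) stop("missing coordinates for: ", paste(bad, collapse = ", "))
  d <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
  dimnames(d) <- list(coords$id, coords$id)
  pairwise_matrix(d, "geographic")
}

#' Pairwise sex-combination matrix
#'
#' female/female = 0, female/male = 0.5, male/male = 1.
#'
#' @param sexes tibble with columns `id` and `sex` (values `"F"`/`"M"`), or a
#'   named character vector.
#' @return a [pairwise_matrix()] of kind `"sex"`.
#' @export
sex_matrix <- function(sexes) {
  if (is.data.frame(sexes)) {
    v <- sexes$sex; ids <- sexes$id
  } else {
    v <- unname(sexes); ids <- names(sexes)
  }
  if (!all(v %in% c("F", "M")))
    stop("unknown sex code(s): ", paste(setdiff(v, c("F", "M")), collapse = ", "))
  z <- as.numeric(v == "M")
  s <- (outer(z, z, "+")) / 2
  dimnames(s) <- list(ids, ids)
  pairwise_matrix(s, "sex")
}

#' Ecological distance on one habitat-use PC axis
#'
#' e_ij = |score_i - score_j| on the chosen axis.
#'
#' @param pca an `eco_pca` from [habitat_pca()] (or its `scores` tibble).
#' @param axis axis number (1-based; must be among the returned axes).
#' @return a [pairwise_matrix()] of kind `"ecological"`.
#' @export
ecological_distance <- function(pca, axis = 1) {
  scores <- if (inherits(pca, "eco_pca")) pca$scores else pca
  col <- paste0("PC", axis)
  if (!col %in% names(scores))
    stop("axis ", axis, " not available (have: ",
         paste(setdiff(names(scores), "id"), collapse = ", "), ")")
  v <- scores[[col]]
  e <- abs(outer(v, v, "-"))
  dimnames(e) <- list(scores$id, scores$id)
  pairwise_matrix(e, "ecological")
}

#' Mantel permutation test
#'
#' r is the Pearson correlation of the strictly-lower-triangle vectors. The
#' null is generated by simultaneously permuting rows and columns of the
#' second matrix; the default p-value is one-sided in the direction of the
#' observed r (matching signed one-sided reporting), with the add-one
#' correction so p is never 0. The 95% CI is by default a percentile
#' bootstrap over individuals (resampled submatrix correlation); a
#' permutation-quantile mode (`ci_method = "permutation"`, the null-centred
#' interval) is provided for fidelity with analyses that report it.
#'
#' @param a,b [pairwise_matrix()] or plain symmetric matrices over the same
#'   individuals in the same order.
#' @param n_perm permutations (published analyses used 10000).
#' @param seed integer seed.
#' @param alternative `"auto"` (one-sided toward the sign of observed r),
#'   `"greater"`, `"less"`, or `"two.sided"`.
#' @param ci_method `"bootstrap"` (default) or `"permutation"`.
#' @param n_boot bootstrap resamples for the CI.
#' @return a `mantel_result` tibble row: `r`, `p_value`, `alternative`,
#'   `n_perm`, `ci_lower`, `ci_upper`, `controls`.
#' @export
mantel_test <- function(a, b, n_perm = 999, seed = 1L,
                        alternative = c("auto", "greater", "less", "two.sided"),
                        ci_method = c("bootstrap", "permutation"),
                        n_boot = 500) {
  alternative <- match.arg(alternative)
  ci_method <- match.arg(ci_method)
  if (n_perm < 1) stop("n_perm must be >= 1")
  check_same_ids(a, b)
  n <- nrow(a)
  va <- lower_vec(a); vb <- lower_vec(b)
  if (sd(va) == 0 || sd(vb) == 0)
    stop("zero variance in a triangle vector: Mantel test undefined")
  r_obs <- cor(va, vb)
  dir <- if (alternative == "auto") {
    if (r_obs >= 0) "greater" else "less"
  } else alternative
  lt <- which(lower.tri(a), arr.ind = TRUE)
  ii <- lt[, 1]; jj <- lt[, 2]
  ma <- mean(va); sa <- sd(va); mb <- mean(vb); sb <- sd(vb)
  ac <- (va - ma) / sa
  np <- length(va)
  with_seed(seed, {
    r_null <- vapply(seq_len(n_perm), function(p) {
      pm <- sample.int(n)
      vbp <- b[cbind(pm[ii], pm[jj])]
      # row/col permutation preserves the off-diagonal multiset, so the
      # permuted triangle keeps b's mean and sd
      sum(ac * (vbp - mb)) / (sb * (np - 1))
    }, numeric(1))
    p <- switch(dir,
      greater = (sum(r_null >= r_obs) + 1) / (n_perm + 1),
      less = (sum(r_null <= r_obs) + 1) / (n_perm + 1),
      two.sided = (sum(abs(r_null) >= abs(r_obs)) + 1) / (n_perm + 1))
    ci <- mantel_ci(a, b, r_obs, r_null, ci_method, n_boot)
  })
  structure(tibble::tibble(r = r_obs, p_value = p, alternative = dir,
                           n_perm = n_perm, ci_lower = ci[1], ci_upper = ci[2],
                           controls = ""),
            class = c("mantel_result", "tbl_df", "tbl", "data.frame"))
}

mantel_ci <- function(a, b, r_obs, r_null, ci_method, n_boot) {
  n <- nrow(a)
  if (ci_method == "permutation") {
    # null-quantile interval re-centred on the estimate
    q <- quantile(r_null - mean(r_null), c(0.025, 0.975), names = FALSE)
    return(r_obs + q)
  }
  rs <- vapply(seq_len(n_boot), function(s) {
    idx <- sample.int(n, replace = TRUE)
    va <- lower_vec(a[idx, idx]); vb <- lower_vec(b[idx, idx])
    keep <- is.finite(va) & is.finite(vb)
    if (sd(va[keep]) == 0 || sd(vb[keep]) == 0) return(NA_real_)
    cor(va[keep], vb[keep])
  }, numeric(1))
  ci <- quantile(rs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  c(min(ci[1], r_obs), max(ci[2], r_obs))
}

#' Partial Mantel test
#'
#' Triangle vectors of `a` and `b` are each residualised by OLS (with
#' intercept) on the control matrices' triangle vectors; r is the correlation
#' of the residual vectors. The permutation null follows the
#' residual-permutation method: the residuals of `a` are reconstituted into a
#' symmetric matrix whose rows/columns are permuted before re-vectorising.
#'
#' @inheritParams mantel_test
#' @param controls a single matrix or list of 1-2 control matrices.
#' @return a `mantel_result` row.
#' @export
partial_mantel <- function(a, b, controls, n_perm = 999, seed = 1L,
                           alternative = c("auto", "greater", "less", "two.sided"),
                           ci_method = c("bootstrap", "permutation"),
                           n_boot = 500) {
  alternative <- match.arg(alternative)
  ci_method <- match.arg(ci_method)
  if (is.matrix(controls)) controls <- list(controls)
  if (length(controls) < 1 || length(controls) > 2)
    stop("need 1 or 2 control matrices")
  check_same_ids(a, b)
  for (cm in controls) check_same_ids(a, cm)
  n <- nrow(a)
  C <- do.call(cbind, lapply(controls, lower_vec))
  Xc <- cbind(1, C)
  if (kappa(crossprod(Xc)) > 1e10) stop("collinear control matrices")
  resid_of <- function(v) resid(stats::lm.fit(Xc, v))
  ra <- resid_of(lower_vec(a))
  rb <- resid_of(lower_vec(b))
  if (sd(ra) < 1e-14 || sd(rb) < 1e-14)
    stop("a matrix is fully explained by the controls: partial test undefined")
  r_obs <- cor(ra, rb)
  dir <- if (alternative == "auto") {
    if (r_obs >= 0) "greater" else "less"
  } else alternative
  # reconstitute residual-a matrix for row/column permutation
  ram <- matrix(0, n, n, dimnames = dimnames(unclass(a)))
  ram[lower.tri(ram)] <- ra
  ram <- ram + t(ram)
  lt <- which(lower.tri(ram), arr.ind = TRUE)
  ii <- lt[, 1]; jj <- lt[, 2]
  mb2 <- mean(rb); sb2 <- sd(rb)
  with_seed(seed, {
    r_null <- vapply(seq_len(n_perm), function(p) {
      pm <- sample.int(n)
      rap <- ram[cbind(pm[ii], pm[jj])]
      cor(rap, rb)
    }, numeric(1))
    p <- switch(dir,
      greater = (sum(r_null >= r_obs) + 1) / (n_perm + 1),
      less = (sum(r_null <= r_obs) + 1) / (n_perm + 1),
      two.sided = (sum(abs(r_null) >= abs(r_obs)) + 1) / (n_perm + 1))
    ci <- partial_ci(a, b, controls, r_obs, r_null, ci_method, n_boot)
  })
  structure(tibble::tibble(r = r_obs, p_value = p, alternative = dir,
                           n_perm = n_perm, ci_lower = ci[1], ci_upper = ci[2],
                           controls = paste(vapply(controls, function(m)
                             attr(m, "kind") %||% "control", character(1)),
                             collapse = "+")),
            class = c("mantel_result", "tbl_df", "tbl", "data.frame"))
}

partial_ci <- function(a, b, controls, r_obs, r_null, ci_method, n_boot) {
  n <- nrow(a)
  if (ci_method == "permutation") {
    q <- quantile(r_null - mean(r_null), c(0.025, 0.975), names = FALSE)
    return(r_obs + q)
  }
  rs <- vapply(seq_len(n_boot), function(s) {
    idx <- sample.int(n, replace = TRUE)
    C <- do.call(cbind, lapply(controls, function(m) lower_vec(m[idx, idx])))
    Xc <- cbind(1, C)
    va <- lower_vec(a[idx, idx]); vb <- lower_vec(b[idx, idx])
    fit <- tryCatch({
      ra <- resid(stats::lm.fit(Xc, va)); rb <- resid(stats::lm.fit(Xc, vb))
      if (sd(ra) < 1e-14 || sd(rb) < 1e-14) NA_real_ else cor(ra, rb)
    }, error = function(e) NA_real_)
    fit
  }, numeric(1))
  ci <- quantile(rs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  c(min(ci[1], r_obs), max(ci[2], r_obs))
}

#' Full individual-based isolation-by-ecology test battery
#'
#' Runs the standard layout: null models (S ~ E per axis, E ~ D per axis),
#' then per genetic metric G ~ D, G ~ S, G ~ E per axis, and the two partial
#' models G ~ D | E + S and G ~ E | D + S. The E axis used inside the partial
#' models is, per metric, the axis with the strongest simple |r| against that
#' metric (configurable via `partial_axis`).
#'
#' @param G named list of genetic similarity matrices (e.g.
#'   `list(qg = ..., coancestry = ...)`).
#' @param D geographic distance matrix.
#' @param S sex matrix.
#' @param E list of ecological distance matrices, one per PC axis.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param partial_axis axis index forced into the partial models, or `NULL`
#'   (strongest simple |r| per metric).
#' @return tibble of class `ibe_suite`: one row per test with `test`,
#'   `metric`, `r`, `p_value`, `ci_lower`, `ci_upper`, `controls`,
#'   `significant` (one-sided p <= 0.05).
#' @export
ibe_suite <- function(G, D, S, E, n_perm = 999, seed = 1L, partial_axis = NULL) {
  if (is.matrix(G)) G <- list(G = G)
  if (is.matrix(E)) E <- list(E)
  if (is.null(names(G))) names(G) <- paste0("G", seq_along(G))
  seeds <- substream_seeds(seed, 1000)
  si <- 0
  nxt <- function() { si <<- si + 1; seeds[si] }
  rows <- list()
  add <- function(test, metric, res) {
    rows[[length(rows) + 1L]] <<- dplyr::mutate(res, test = test,
                                                metric = metric, .before = 1)
  }
  for (ax in seq_along(E)) {
    add(paste0("S ~ E^PC", ax), "null", mantel_test(S, E[[ax]], n_perm, nxt()))
    add(paste0("E^PC", ax, " ~ D"), "null", mantel_test(E[[ax]], D, n_perm, nxt()))
  }
  for (mname in names(G)) {
    g <- G[[mname]]
    ge_r <- numeric(length(E))
    add("G ~ D", mname, mantel_test(g, D, n_perm, nxt()))
    add("G ~ S", mname, mantel_test(g, S, n_perm, nxt()))
    for (ax in seq_along(E)) {
      res <- mantel_test(g, E[[ax]], n_perm, nxt())
      ge_r[ax] <- res$r
      add(paste0("G ~ E^PC", ax), mname, res)
    }
    ax_pm <- partial_axis %||% which.max(abs(ge_r))
    add("G ~ D | E + S", mname,
        partial_mantel(g, D, list(E[[ax_pm]], S), n_perm, nxt()))
    add(paste0("G ~ E^PC", ax_pm, " | D + S"), mname,
        partial_mantel(g, E[[ax_pm]], list(D, S), n_perm, nxt()))
  }
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p_value <= 0.05
  class(out) <- c("ibe_suite", class(out))
  out
}
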