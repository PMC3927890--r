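#' Simulated-annealing K-means on habitat-use profiles
#'
#' Minimises the total within-group squared Euclidean deviation from group
#' centroids (squaring the absolute per-class difference in proportion of use
#' makes squared Euclidean the exact pairwise objective). Proposal: move one
#' random individual to a random other group; accept if the SSE does not
#' increase, else with probability exp(-dSSE / T) under geometric cooling
#' from T0 = 1% of the initial SSE down to 1e-6 T0. The best assignment seen
#' over all restarts is returned. Deterministic for a given seed and
#' invariant to input row order (rows are keyed by id internally).
#'
#' @param x numeric matrix (individuals x variables) with row ids, or a
#'   tibble with an `id` column and numeric columns (e.g. transformed
#'   habitat use).
#' @param k number of groups.
#' @param steps annealing steps per restart (desk-scale default 20000; the
#'   full-scale published setting of 5e6 is reachable here).
#' @param restarts independent restarts (full-scale: 100).
#' @param seed integer seed.
#' @return a `cluster_solution`: `k`, `assignment` tibble (`id`, `cluster`),
#'   `sse`, `bic`, `pseudo_f`, `restarts`.
#' @export
sa_kmeans <- function(x, k, steps = 20000, restarts = 10, seed = 1L) {
  X <- as_numeric_matrix(x)
  n <- nrow(X)
  if (k > n) stop("k (", k, ") exceeds number of individuals (", n, ")")
  if (k < 1 || steps < 1) stop("k and steps must be >= 1")
  ord <- order(rownames(X))
  X <- X[ord, , drop = FALSE]
  best <- with_seed(seed, sa_kmeans_engine(X, k, steps, restarts))
  assign_tbl <- tibble::tibble(id = rownames(X), cluster = best$assignment)
  assign_tbl <- assign_tbl[match(rownames(as_numeric_matrix(x)), assign_tbl$id), ]
  sol <- structure(list(k = k, assignment = assign_tbl, sse = best$sse,
                        restarts = restarts, steps = steps),
                   class = "cluster_solution")
  sol$bic <- kmeans_bic(sol, x)
  sol$pseudo_f <- pseudo_f(sol, x)
  sol
}

as_numeric_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- if ("id" %in% names(x)) as.character(x$id) else as.character(seq_len(nrow(x)))
    X <- as.matrix(x[vapply(x, is.numeric, logical(1)) & names(x) != "id"])
    rownames(X) <- ids
    X
  } else {
    X <- as.matrix(x)
    if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
    X
  }
}

sa_kmeans_engine <- function(X, k, steps, restarts) {
  n <- nrow(X); d <- ncol(X)
  xsq <- rowSums(X^2); total_sq <- sum(xsq)
  best_sse <- Inf; best_assign <- NULL
  for (r in seq_len(restarts)) {
    assign <- sample.int(k, n, replace = TRUE)
    assign[sample.int(n, min(k, n))] <- seq_len(min(k, n))  # no empty start
    S <- rowsum(X, assign, reorder = FALSE)
    grp <- as.integer(rownames(S))
    sums <- matrix(0, k, d); sums[grp, ] <- S
    counts <- tabulate(assign, k)
    contrib <- ifelse(counts > 0, rowSums(sums^2) / pmax(counts, 1), 0)
    sse <- total_sq - sum(contrib)
    if (sse < best_sse) { best_sse <- sse; best_assign <- assign }
    if (k == 1) next
    t0 <- max(0.01 * sse, 1e-12)
    cool <- (1e-6)^(1 / steps)
    temp <- t0
    for (s in seq_len(steps)) {
      i <- sample.int(n, 1)
      g <- assign[i]
      h <- sample.int(k - 1, 1); if (h >= g) h <- h + 1L
      xi <- X[i, ]
      ng <- counts[g]; nh <- counts[h]
      old_g <- contrib[g]; old_h <- contrib[h]
      new_sg <- sums[g, ] - xi; new_sh <- sums[h, ] + xi
      new_g <- if (ng > 1) sum(new_sg^2) / (ng - 1) else 0
      new_h <- sum(new_sh^2) / (nh + 1)
      dsse <- (old_g + old_h) - (new_g + new_h)
      if (dsse <= 0 || runif(1) < exp(-dsse / temp)) {
        assign[i] <- h
        sums[g, ] <- new_sg; sums[h, ] <- new_sh
        counts[g] <- ng - 1L; counts[h] <- nh + 1L
        contrib[g] <- new_g; contrib[h] <- new_h
        sse <- sse + dsse
        if (sse < best_sse - 1e-12) { best_sse <- sse; best_assign <- assign }
      }
      temp <- temp * cool
    }
  }
  list(sse = max(best_sse, 0), assignment = best_assign)
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k =", x$k, " SSE =", signif(x$sse, 6),
      " BIC =", signif(x$bic, 6),
      " pseudo-F =", if (is.finite(x$pseudo_f)) signif(x$pseudo_f, 6) else x$pseudo_f,
      "\n")
  invisible(x)
}

#' @export
tidy.cluster_solution <- function(x, ...) x$assignment

#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(k = x$k, sse = x$sse, bic = x$bic, pseudo_f = x$pseudo_f,
                 restarts = x$restarts, steps = x$steps)
}

solution_groups <- function(solution, X) {
  asg <- solution$assignment
  cl <- asg$cluster[match(rownames(X), asg$id)]
  if (anyNA(cl)) stop("assignment does not cover all rows of x")
  cl
}

#' Calinski-Harabasz pseudo-F of a clustering
#'
#' (SSB / (k - 1)) / (SSW / (n - k)) with SSB from group centroids vs the
#' grand centroid. Undefined (NA) at k = 1 or k = n; +Inf when SSW = 0 with
#' separation present.
#'
#' @param solution a `cluster_solution`.
#' @param x the data it was fit on.
#' @return scalar pseudo-F.
#' @export
pseudo_f <- function(solution, x) {
  X <- as_numeric_matrix(x)
  n <- nrow(X); k <- solution$k
  if (k <= 1 || k >= n) return(NA_real_)
  cl <- solution_groups(solution, X)
  grand <- colMeans(X)
  ssw <- 0; ssb <- 0
  for (g in unique(cl)) {
    rows <- X[cl == g, , drop = FALSE]
    cen <- colMeans(rows)
    ssw <- ssw + sum(sweep(rows, 2, cen)^2)
    ssb <- ssb + nrow(rows) * sum((cen - grand)^2)
  }
  if (ssw == 0) return(if (ssb > 0) Inf else 0)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Spherical-Gaussian BIC of a clustering
#'
#' n d ln(SSE / (n d)) + k d ln(n), with d the column count; the selected k
#' is the argmin over the profiled range. -Inf when SSE = 0.
#'
#' @param solution a `cluster_solution`.
#' @param x the data it was fit on.
#' @return scalar BIC.
#' @export
kmeans_bic <- function(solution, x) {
  X <- as_numeric_matrix(x)
  n <- nrow(X); d <- ncol(X); k <- solution$k
  cl <- solution_groups(solution, X)
  sse <- 0
  for (g in unique(cl)) {
    rows <- X[cl == g, , drop = FALSE]
    sse <- sse + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  if (sse == 0) return(-Inf)
  n * d * log(sse / (n * d)) + k * d * log(n)
}

#' Profile SA K-means over a range of k
#'
#' Runs [sa_kmeans()] for each k and collects the selection statistics; the
#' published analysis profiled k = 1..20 with pseudo-F and BIC.
#'
#' @inheritParams sa_kmeans
#' @param k_range integer vector of k values.
#' @return list of class `kmeans_profile`: `stats` tibble (one row per k),
#'   `solutions` (list of `cluster_solution`), `best_bic`, `best_pseudo_f`.
#' @export
sa_kmeans_profile <- function(x, k_range = 1:6, steps = 20000, restarts = 10,
                              seed = 1L) {
  seeds <- substream_seeds(seed, length(k_range))
  sols <- purrr::map2(k_range, seeds,
                      function(k, s) sa_kmeans(x, k, steps, restarts, seed = s))
  stats <- purrr::map_dfr(sols, glance)
  structure(list(stats = stats, solutions = setNames(sols, paste0("k", k_range)),
                 best_bic = k_range[which.min(stats$bic)],
                 best_pseudo_f = k_range[which.max(replace(stats$pseudo_f,
                                                           !is.finite(stats$pseudo_f) &
                                                             !is.na(stats$pseudo_f), Inf))]),
            class = "kmeans_profile")
}

#' @export
print.kmeans_profile <- function(x, ...) {
  cat("<kmeans_profile> k selected:", x$best_pseudo_f, "(pseudo-F),",
      x$best_bic, "(BIC)\n")
  print(x$stats)
  invisible(x)
}

#' Admixture-model Gibbs sampler for genetic clustering
#'
#' Standard admixture model with uncorrelated cluster allele frequencies:
#' each gene copy carries a latent cluster origin z sampled from
#' q_i(k) p_k(allele); cluster allele frequencies get a conjugate
#' Dirichlet(1 + counts) update; individual admixture proportions q_i a
#' conjugate Dirichlet(alpha + counts) update. Q is the posterior mean of
#' q_i over retained sweeps, the hard assignment its argmax, and each
#' replicate's mean observed-data log-likelihood (marginal over z given the
#' current q, p) feeds the Evanno delta-K criterion.
#'
#' @param g a [genotype_table()].
#' @param k number of clusters.
#' @param iterations total sweeps per replicate (desk-scale default 2000;
#'   the full-scale published setting was 1e6).
#' @param burn_in_fraction fraction of sweeps discarded (published: 0.2).
#' @param replicates independent replicate runs (published: 3).
#' @param alpha Dirichlet prior parameter on admixture proportions.
#' @param seed integer seed.
#' @return an `admixture_fit`: `k`, `Q` tibble (`id`, `Q1..Qk`, `cluster`)
#'   from the first replicate (replicate Qs in `replicate_Q`),
#'   `mean_loglik` per replicate, `loglik_trace`, final-state `p` and `q`.
#' @export
admixture_gibbs <- function(g, k, iterations = 2000, burn_in_fraction = 0.2,
                            replicates = 1, alpha = 1, seed = 1L) {
  if (k < 1) stop("k must be >= 1")
  n_retain <- iterations - floor(iterations * burn_in_fraction)
  if (n_retain < 100) stop("need >= 100 retained sweeps after burn-in")
  ord <- order(g$ids)
  g <- subset_individuals(g, ord)
  n <- length(g$ids); L <- length(g$loci)
  # flatten non-missing gene copies
  ind <- rep(seq_len(n), 2 * L)
  loc <- rep(rep(seq_len(L), each = n), 2)
  allele <- c(as.vector(g$a1), as.vector(g$a2))
  keep <- !is.na(allele)
  ind <- ind[keep]; loc <- loc[keep]; allele <- allele[keep]
  amax <- max(allele)
  obs_per_locus <- lapply(seq_len(L), function(l) sort(unique(allele[loc == l])))
  m <- length(allele)
  pa_idx <- (loc - 1L) * amax + allele          # index into L x amax freq slab
  burn <- iterations - n_retain
  seeds <- substream_seeds(seed, replicates, "rep")
  reps <- purrr::map(seq_len(replicates), function(r) {
    with_seed(seeds[r], {
      z <- sample.int(k, m, replace = TRUE)
      qsum <- matrix(0, n, k)
      p_cur <- NULL; q_cur <- NULL
      trace <- numeric(iterations)
      for (it in seq_len(iterations)) {
        # p | z: Dirichlet(1 + counts) per (cluster, locus)
        cnt_idx <- (z - 1L) * (L * amax) + pa_idx
        cnt <- array(tabulate(cnt_idx, k * L * amax), dim = c(amax, L, k))
        p <- array(0, dim = c(amax, L, k))
        for (kk in seq_len(k)) for (l in seq_len(L)) {
          al <- obs_per_locus[[l]]
          gsamp <- rgamma(length(al), shape = 1 + cnt[al, l, kk], rate = 1)
          gsamp[gsamp == 0] <- .Machine$double.xmin
          p[al, l, kk] <- gsamp / sum(gsamp)
        }
        # q | z: Dirichlet(alpha + counts) per individual
        zc <- matrix(tabulate((z - 1L) * n + ind, k * n), n, k)
        q <- rdirichlet_mat(alpha + zc)
        # z | q, p
        w <- matrix(0, m, k)
        for (kk in seq_len(k)) w[, kk] <- q[ind, kk] * p[pa_idx + (kk - 1L) * (L * amax)]
        rs <- rowSums(w)
        trace[it] <- sum(log(rs))
        u <- runif(m) * rs
        z <- rep(1L, m)
        acc <- w[, 1]
        if (k > 1) for (kk in 2:k) {
          z[u > acc] <- kk
          acc <- acc + w[, kk]
        }
        # note: the loop above assigns kk wherever u exceeds the cumulative
        # weight through kk-1; final z is the sampled category
        if (it > burn) qsum <- qsum + q
        if (it == iterations) { p_cur <- p; q_cur <- q }
      }
      list(Q = qsum / n_retain, trace = trace,
           mean_loglik = mean(trace[(burn + 1):iterations]),
           p_final = p_cur, q_final = q_cur)
    })
  })
  qtbl <- function(Q) {
    colnames(Q) <- paste0("Q", seq_len(k))
    tb <- dplyr::bind_cols(tibble::tibble(id = g$ids),
                           tibble::as_tibble(Q, .name_repair = "minimal"))
    tb$cluster <- max.col(Q, ties.method = "first")
    tb
  }
  structure(list(k = k, Q = qtbl(reps[[1]]$Q),
                 replicate_Q = purrr::map(reps, function(r) qtbl(r$Q)),
                 mean_loglik = purrr::map_dbl(reps, "mean_loglik"),
                 loglik_trace = purrr::map(reps, "trace"),
                 p_final = reps[[1]]$p_final, q_final = reps[[1]]$q_final,
                 iterations = iterations, burn_in_fraction = burn_in_fraction,
                 data = list(ind = ind, loc = loc, allele = allele,
                             amax = amax, L = L)),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("<admixture_fit> k =", x$k, ";", length(x$mean_loglik), "replicate(s);",
      "mean log-likelihood:", paste(signif(x$mean_loglik, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.admixture_fit <- function(x, ...) {
  tidyr::pivot_longer(x$Q, dplyr::starts_with("Q"),
                      names_to = "component", values_to = "q")
}

#' @export
glance.admixture_fit <- function(x, ...) {
  tibble::tibble(k = x$k, replicate = seq_along(x$mean_loglik),
                 mean_loglik = x$mean_loglik)
}

# observed-data log-likelihood given q and p (used by tests)
admixture_loglik <- function(fit, q = fit$q_final, p = fit$p_final) {
  d <- fit$data
  w <- 0
  rs <- numeric(length(d$allele))
  for (kk in seq_len(fit$k)) {
    rs <- rs + q[d$ind, kk] * p[d$allele + (d$loc - 1L) * d$amax +
                                  (kk - 1L) * (d$L * d$amax)]
  }
  sum(log(rs))
}

#' Profile the admixture sampler over k and select by Evanno delta-K
#'
#' @inheritParams admixture_gibbs
#' @param k_range consecutive k values (>= 3 of them for delta-K).
#' @return list of class `admixture_profile`: `fits`, `loglik` tibble,
#'   `delta_k` tibble, `best_k`.
#' @export
admixture_profile <- function(g, k_range = 1:5, iterations = 2000,
                              burn_in_fraction = 0.2, replicates = 3,
                              alpha = 1, seed = 1L) {
  seeds <- substream_seeds(seed, length(k_range))
  fits <- purrr::map2(k_range, seeds, function(k, s)
    admixture_gibbs(g, k, iterations, burn_in_fraction, replicates, alpha, s))
  ll <- purrr::map_dfr(fits, glance)
  dk <- evanno_delta_k(ll)
  structure(list(fits = setNames(fits, paste0("k", k_range)), loglik = ll,
                 delta_k = dk, best_k = attr(dk, "best_k")),
            class = "admixture_profile")
}

#' @export
print.admixture_profile <- function(x, ...) {
  cat("<admixture_profile> delta-K selects k =", x$best_k, "\n")
  print(x$delta_k)
  invisible(x)
}

#' Evanno delta-K criterion
#'
#' delta-K(k) = mean over replicates of |L(k+1) - 2 L(k) + L(k-1)| divided by
#' the across-replicate sd of L(k); defined only for interior k. The selected
#' k is the argmax. A zero sd yields Inf with a warning.
#'
#' @param loglik tibble `k`, `replicate`, `mean_loglik` covering >= 3
#'   consecutive k with >= 2 replicates each.
#' @return tibble `k`, `mean_l`, `sd_l`, `delta_k` (interior k only), with
#'   the selected k in attribute `best_k`.
#' @export
evanno_delta_k <- function(loglik) {
  ks <- sort(unique(loglik$k))
  if (length(ks) < 3) stop("delta-K needs >= 3 consecutive k values")
  if (any(diff(ks) != 1)) stop("k values must be consecutive")
  by_k <- loglik |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_l = mean(.data$mean_loglik),
                     sd_l = sd(.data$mean_loglik), n_rep = dplyr::n(),
                     .groups = "drop")
  if (any(by_k$n_rep < 2)) stop("delta-K needs >= 2 replicates per k")
  ml <- by_k$mean_l
  dk <- rep(NA_real_, length(ks))
  for (i in seq(2, length(ks) - 1)) {
    second_diff <- abs(ml[i + 1] - 2 * ml[i] + ml[i - 1])
    if (by_k$sd_l[i] == 0) {
      warn(paste0("zero across-replicate sd at k = ", ks[i], "; delta-K is Inf"))
      dk[i] <- Inf
    } else dk[i] <- second_diff / by_k$sd_l[i]
  }
  out <- dplyr::mutate(by_k, delta_k = dk)
  attr(out, "best_k") <- ks[which.max(dk)]
  out
}

#' Pearson correlation between ecotype and genotype cluster assignments
#'
#' Correlates the two integer label vectors directly (as published), with a
#' two-sided t-based p-value. Because the correlation of categorical labels
#' depends on how labels are numbered, a relabeling-sensitivity report (the
#' max and min r over all permutations of the smaller label set) is attached
#' rather than silently re-aligning labels.
#'
#' @param eco,gen integer assignment vectors of equal length (>= 3).
#' @return tibble `r`, `p_value`, `n`, `r_max_relabel`, `r_min_relabel`.
#' @export
assignment_correlation <- function(eco, gen) {
  if (length(eco) != length(gen)) stop("assignment vectors differ in length")
  n <- length(eco)
  if (n < 3) stop("need >= 3 individuals")
  if (sd(eco) == 0 || sd(gen) == 0)
    stop("constant assignment vector: correlation undefined")
  r <- cor(eco, gen)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tt), df = n - 2)
  ke <- length(unique(eco)); kg <- length(unique(gen))
  small_is_eco <- ke <= kg
  labs <- sort(unique(if (small_is_eco) eco else gen))
  perms <- perms_of(labs)
  rs <- vapply(perms, function(pm) {
    rel <- pm[match(if (small_is_eco) eco else gen, labs)]
    if (small_is_eco) cor(rel, gen) else cor(eco, rel)
  }, numeric(1))
  tibble::tibble(r = r, p_value = p, n = n,
                 r_max_relabel = max(rs), r_min_relabel = min(rs))
}

perms_of <- function(v) {
  if (length(v) > 6) stop("too many labels for exhaustive relabeling report")
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- perms_of(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}
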