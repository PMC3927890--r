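#' Body condition index
#'
#' Standardised residual of the OLS regression of ln(mass) on ln(straight-line
#' length): residual divided by the sample sd of the residuals, so the index
#' has mean 0 and sd 1 by construction.
#'
#' @param phenotypes tibble with columns `id`, `mass`, `sll` (positive;
#'   rows with either missing are returned as NA).
#' @return the input with a `bci` column appended.
#' @export
compute_bci <- function(phenotypes) {
  stopifnot(all(c("mass", "sll") %in% names(phenotypes)))
  ok <- !is.na(phenotypes$mass) & !is.na(phenotypes$sll)
  if (any((phenotypes$mass[ok] <= 0) | (phenotypes$sll[ok] <= 0)))
    stop("mass and straight-line length must be positive")
  if (sum(ok) < 3) stop("need >= 3 individuals with both measures")
  fit <- lm(log(mass) ~ log(sll), data = phenotypes[ok, ])
  r <- resid(fit)
  out <- phenotypes
  out$bci <- NA_real_
  out$bci[ok] <- r / sd(r)
  out
}

#' Build design matrices for the phenotype model suite
#'
#' Assembles the response and fixed-effect design for one model of the suite
#' \{M1 base, M2 base + HL, M3 M2 + cluster assignments, M4 M2 + PC scores\},
#' with optional HL-by-sex interaction. Base covariates: sex (male = 1), age,
#' northing, spring and summer dummies (fall is the season reference).
#' Genetic clusters with 3 levels become 2 dummies relative to the third
#' cluster; habitat clusters with 2 levels one dummy relative to the second.
#' Continuous covariates are standardised (mean 0, sd 1) when
#' `standardize = TRUE` (the reporting scale of the model tables); rows with
#' any missing value in the used columns are dropped with a message
#' (complete-case analysis).
#'
#' @param records phenotype tibble (`id`, `sex`, `age`, `season`, `y`
#'   northing, `unit`, `mass`, `sll`, optionally `bci`).
#' @param response one of `"log_mass"`, `"log_sll"`, `"bci"`.
#' @param model `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param hl tibble `id`, `hl` (required for M2-M4).
#' @param clusters list with `genetic` and/or `habitat` assignment tibbles
#'   (`id`, `cluster`) — required for M3.
#' @param pc_scores list with `genetic` and/or `habitat` score tibbles
#'   (`id`, `PC1`, `PC2`) — required for M4.
#' @param hl_by_sex add the HL x sex interaction column (model variant "x").
#' @param standardize standardise continuous covariates.
#' @return list: `y`, `X` (no intercept column; the overall intercept is the
#'   mean of the unit intercepts), `groups` (unit factor), `hl` (per-row HL
#'   on the design scale, for unit-varying slopes), `ids`, `n_dropped`.
#' @export
build_design <- function(records, response = c("log_mass", "log_sll", "bci"),
                         model = c("M1", "M2", "M3", "M4"),
                         hl = NULL, clusters = NULL, pc_scores = NULL,
                         hl_by_sex = FALSE, standardize = TRUE) {
  response <- match.arg(response)
  model <- match.arg(model)
  df <- tibble::as_tibble(records)
  stopifnot(all(c("id", "sex", "age", "season", "y", "unit") %in% names(df)))
  if (!all(df$season %in% c("spring", "summer", "fall")))
    stop("season must be spring/summer/fall")
  yv <- switch(response,
               log_mass = log(df$mass), log_sll = log(df$sll),
               bci = { if (!"bci" %in% names(df)) stop("bci column missing; run compute_bci()"); df$bci })
  X <- cbind(sex = as.numeric(df$sex == "M"),
             age = df$age, northing = df$y,
             spring = as.numeric(df$season == "spring"),
             summer = as.numeric(df$season == "summer"))
  hlv <- NULL
  if (model != "M1" || hl_by_sex) {
    if (is.null(hl)) stop("hl required for models beyond M1")
    hlv <- hl$hl[match(df$id, hl$id)]
    X <- cbind(X, hl = hlv)
    if (hl_by_sex) X <- cbind(X, hl_sex = hlv * as.numeric(df$sex == "M"))
  }
  if (model == "M3") {
    if (is.null(clusters)) stop("cluster assignments required for M3")
    for (side in names(clusters)) {
      cl <- clusters[[side]]$cluster[match(df$id, clusters[[side]]$id)]
      lev <- sort(unique(cl[!is.na(cl)]))
      if (length(lev) < 2) stop(side, " clustering has a single level")
      ref <- lev[length(lev)]   # dummies relative to the last (e.g. third) cluster
      for (l in setdiff(lev, ref))
        X <- cbind(X, stats::setNames(data.frame(as.numeric(cl == l)),
                                      paste0(side, "_k", l))[[1]])
      colnames(X)[(ncol(X) - length(lev) + 2):ncol(X)] <-
        paste0(substr(side, 1, 3), "_k", setdiff(lev, ref))
    }
  }
  if (model == "M4") {
    if (is.null(pc_scores)) stop("PC scores required for M4")
    for (side in names(pc_scores)) {
      sc <- pc_scores[[side]]
      for (ax in c("PC1", "PC2")) {
        if (!ax %in% names(sc)) stop(side, " scores lack ", ax)
        X <- cbind(X, stats::setNames(data.frame(sc[[ax]][match(df$id, sc$id)]),
                                      paste0(side, "_", ax))[[1]])
        colnames(X)[ncol(X)] <- paste0(substr(side, 1, 3), "_", ax)
      }
    }
  }
  keep <- stats::complete.cases(cbind(yv, X)) & !is.na(df$unit)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("dropping ", n_dropped, " incomplete case(s); n = ", sum(keep))
  X <- X[keep, , drop = FALSE]; yv <- yv[keep]
  if (!is.null(hlv)) hlv <- hlv[keep]
  dummy_cols <- colnames(X) %in% c("spring", "summer", "sex") |
    grepl("_k", colnames(X))
  zero_dummy <- dummy_cols & apply(X, 2, function(v) all(v == v[1]))
  if (any(zero_dummy))
    message("constant dummy column(s) dropped: ",
            paste(colnames(X)[zero_dummy], collapse = ", "))
  X <- X[, !zero_dummy, drop = FALSE]
  if (standardize) {
    cont <- !(colnames(X) %in% c("sex", "spring", "summer")) &
      !grepl("_k", colnames(X))
    for (j in which(cont)) {
      s <- sd(X[, j])
      if (s > 0) X[, j] <- (X[, j] - mean(X[, j])) / s
    }
    if (!is.null(hlv) && "hl" %in% colnames(X)) hlv <- X[, "hl"]
  }
  list(y = yv, X = X, groups = factor(df$unit[keep]), hl = hlv,
       ids = df$id[keep], n_dropped = n_dropped,
       response = response, model = model)
}

#' Fit a Bayesian hierarchical linear model by Gibbs sampling
#'
#' y = X beta + alpha_unit (+ gamma_unit * hl) + eps, with conjugate
#' updates throughout: beta ~ N(0, 100^2 I); unit intercepts
#' alpha_u ~ N(mu_alpha, sigma_alpha^2) with mu_alpha ~ N(0, 100^2) and
#' sigma_alpha^2 ~ IG(0.001, 0.001); optional unit-varying homozygosity
#' slopes gamma_u ~ N(mu_gamma, sigma_gamma^2) likewise; residual variance
#' IG(0.001, 0.001). There is no global intercept column: mu_alpha is the
#' overall intercept. DIC uses the conditional (given unit effects) Gaussian
#' likelihood. Chains start from overdispersed points; retained draws feed
#' posterior means, 95% credible intervals and the Gelman-Rubin diagnostic
#' (converged when all R-hat < 1.1 — flagged, never an error).
#'
#' @param y numeric response.
#' @param X fixed-effect design matrix (no intercept column).
#' @param groups factor of management units (>= 2 levels).
#' @param hl per-row homozygosity values; required when
#'   `unit_varying_hl = TRUE` (hl must then NOT also be a column of X).
#' @param unit_varying_hl add unit-varying HL slopes (model variant "y").
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iterations sweeps per chain.
#' @param burn_in fraction discarded.
#' @param seed integer seed.
#' @return an `hfc_fit` object: `draws` (list of retained draw matrices, one
#'   per chain), `summary` tibble (posterior mean, 95% CI, R-hat per
#'   parameter), `dic`, `dbar`, `pd`, `converged`, bookkeeping fields.
#' @export
fit_hierarchical <- function(y, X, groups, hl = NULL, unit_varying_hl = FALSE,
                             chains = 2, iterations = 2000, burn_in = 0.5,
                             seed = 1L) {
  groups <- droplevels(as.factor(groups))
  U <- nlevels(groups)
  if (U < 2) stop("need >= 2 management units")
  if (chains < 2) stop("need >= 2 chains")
  n <- length(y); p <- ncol(X)
  if (unit_varying_hl) {
    if (is.null(hl)) stop("unit-varying HL slopes need hl values")
    if ("hl" %in% colnames(X))
      X <- X[, colnames(X) != "hl", drop = FALSE]
    p <- ncol(X)
  }
  gi <- as.integer(groups)
  XtX <- crossprod(X)
  tau_fix <- 100^2
  a0 <- 0.001; b0 <- 0.001
  n_burn <- floor(iterations * burn_in)
  n_keep <- iterations - n_burn
  if (n_keep < 10) stop("too few retained draws")
  par_names <- c(colnames(X), "mu_alpha", "sigma_alpha",
                 if (unit_varying_hl) c("mu_gamma", "sigma_gamma"),
                 "sigma_resid", "deviance")
  chain_seeds <- substream_seeds(seed, chains, "chain")
  run_chain <- function(cs) {
    with_seed(cs, {
      beta <- rnorm(p, 0, 0.5)
      alpha <- rnorm(U, 0, 0.5); mu_a <- rnorm(1, 0, 0.5); s2_a <- runif(1, 0.05, 1)
      gam <- rep(0, U); mu_g <- 0; s2_g <- 1
      if (unit_varying_hl) { gam <- rnorm(U, 0, 0.5); mu_g <- rnorm(1, 0, 0.5) }
      s2 <- var(y)
      draws <- matrix(NA_real_, n_keep, length(par_names),
                      dimnames = list(NULL, par_names))
      sum_beta <- numeric(p); sum_alpha <- numeric(U); sum_gam <- numeric(U)
      sum_s2 <- 0
      for (it in seq_len(iterations)) {
        re <- alpha[gi] + if (unit_varying_hl) gam[gi] * hl else 0
        # beta (skipped for an intercept-only model)
        if (p > 0) {
          V <- chol2inv(chol(XtX / s2 + diag(1 / tau_fix, p)))
          mb <- V %*% crossprod(X, y - re) / s2
          beta <- as.numeric(mb + t(chol(V)) %*% rnorm(p))
          xb <- as.numeric(X %*% beta)
        } else xb <- numeric(n)
        # alpha_u
        r1 <- y - xb - (if (unit_varying_hl) gam[gi] * hl else 0)
        sums <- tapply(r1, gi, sum); ns <- tabulate(gi, U)
        v <- 1 / (ns / s2 + 1 / s2_a)
        alpha <- rnorm(U, v * (sums / s2 + mu_a / s2_a), sqrt(v))
        # mu_alpha, sigma_alpha^2
        vv <- 1 / (U / s2_a + 1 / tau_fix)
        mu_a <- rnorm(1, vv * sum(alpha) / s2_a, sqrt(vv))
        s2_a <- 1 / rgamma(1, a0 + U / 2, b0 + sum((alpha - mu_a)^2) / 2)
        if (unit_varying_hl) {
          r2 <- y - xb - alpha[gi]
          sh <- tapply(r2 * hl, gi, sum); shh <- tapply(hl^2, gi, sum)
          vg <- 1 / (shh / s2 + 1 / s2_g)
          gam <- rnorm(U, vg * (sh / s2 + mu_g / s2_g), sqrt(vg))
          vv2 <- 1 / (U / s2_g + 1 / tau_fix)
          mu_g <- rnorm(1, vv2 * sum(gam) / s2_g, sqrt(vv2))
          s2_g <- 1 / rgamma(1, a0 + U / 2, b0 + sum((gam - mu_g)^2) / 2)
        }
        # sigma^2
        fitted <- xb + alpha[gi] + (if (unit_varying_hl) gam[gi] * hl else 0)
        rss <- sum((y - fitted)^2)
        s2 <- 1 / rgamma(1, a0 + n / 2, b0 + rss / 2)
        if (s2 <= 0 || !is.finite(s2)) stop("degenerate residual variance update")
        if (it > n_burn) {
          j <- it - n_burn
          dev <- n * log(2 * pi * s2) + rss / s2
          draws[j, ] <- c(beta, mu_a, sqrt(s2_a),
                          if (unit_varying_hl) c(mu_g, sqrt(s2_g)),
                          sqrt(s2), dev)
          sum_beta <- sum_beta + beta; sum_alpha <- sum_alpha + alpha
          sum_gam <- sum_gam + gam; sum_s2 <- sum_s2 + s2
        }
      }
      list(draws = draws, mean_beta = sum_beta / n_keep,
           mean_alpha = sum_alpha / n_keep, mean_gam = sum_gam / n_keep,
           mean_s2 = sum_s2 / n_keep)
    })
  }
  res <- purrr::map(chain_seeds, run_chain)
  draws <- purrr::map(res, "draws")
  all_draws <- do.call(rbind, draws)
  est_names <- setdiff(par_names, "deviance")
  rhat <- gelman_rubin(purrr::map(draws, function(d) d[, est_names, drop = FALSE]))
  qs <- apply(all_draws[, est_names, drop = FALSE], 2, quantile,
              probs = c(0.025, 0.975))
  summary <- tibble::tibble(
    term = est_names,
    estimate = colMeans(all_draws[, est_names, drop = FALSE]),
    ci_lower = qs[1, ], ci_upper = qs[2, ],
    rhat = rhat$rhat[match(est_names, rhat$term)])
  summary$significant <- summary$ci_lower > 0 | summary$ci_upper < 0
  # plug-in deviance at posterior means (pooled over chains)
  mean_beta <- Reduce(`+`, purrr::map(res, "mean_beta")) / chains
  mean_alpha <- Reduce(`+`, purrr::map(res, "mean_alpha")) / chains
  mean_gam <- Reduce(`+`, purrr::map(res, "mean_gam")) / chains
  mean_s2 <- mean(purrr::map_dbl(res, "mean_s2"))
  fit_hat <- as.numeric(X %*% mean_beta) + mean_alpha[gi] +
    (if (unit_varying_hl) mean_gam[gi] * hl else 0)
  d_hat <- n * log(2 * pi * mean_s2) + sum((y - fit_hat)^2) / mean_s2
  dbar <- mean(all_draws[, "deviance"])
  pd <- dbar - d_hat
  structure(list(draws = draws, summary = summary,
                 dic = dbar + pd, dbar = dbar, pd = pd,
                 converged = all(summary$rhat < 1.1, na.rm = TRUE),
                 n = n, chains = chains, n_keep = n_keep,
                 unit_varying_hl = unit_varying_hl,
                 unit_levels = levels(groups)),
            class = "hfc_fit")
}

#' @export
print.hfc_fit <- function(x, ...) {
  cat("<hfc_fit> n =", x$n, "|", x$chains, "chains x", x$n_keep,
      "retained draws | DIC =", round(x$dic, 2),
      "(pD =", round(x$pd, 2), ")\n")
  cat("  converged (all R-hat < 1.1):", x$converged, "\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.hfc_fit <- function(x, ...) x$summary

#' @export
glance.hfc_fit <- function(x, ...) {
  tibble::tibble(dic = x$dic, dbar = x$dbar, pd = x$pd,
                 converged = x$converged, n = x$n,
                 chains = x$chains, retained = x$chains * x$n_keep)
}

#' Deviance information criterion of a fitted model
#'
#' DIC = Dbar + pD with Dbar the posterior mean deviance and
#' pD = Dbar - D(posterior means). Errors below 100 retained draws.
#'
#' @param fit an `hfc_fit`.
#' @return tibble `dic`, `dbar`, `pd`.
#' @export
dic <- function(fit) {
  if (fit$chains * fit$n_keep < 100)
    stop("fewer than 100 retained draws: DIC unreliable")
  tibble::tibble(dic = fit$dic, dbar = fit$dbar, pd = fit$pd)
}

#' Gelman-Rubin potential scale reduction
#'
#' R-hat = sqrt(((n - 1)/n W + B/n) / W) with B = n var(chain means) and W
#' the mean within-chain variance; values below 1.1 are read as convergence.
#'
#' @param chains list of draw matrices (equal-length chains, columns =
#'   parameters) or a plain matrix/list of numeric vectors for one parameter.
#' @return tibble `term`, `rhat`.
#' @export
gelman_rubin <- function(chains) {
  if (is.numeric(chains[[1]]) && is.null(dim(chains[[1]])))
    chains <- purrr::map(chains, function(v) matrix(v, ncol = 1,
                                                    dimnames = list(NULL, "par")))
  if (length(chains) < 2) stop("need >= 2 chains")
  lens <- purrr::map_int(chains, nrow)
  if (length(unique(lens)) != 1) stop("chains must have equal retained length")
  n <- lens[1]
  if (n < 10) stop("retained length must be >= 10")
  terms <- colnames(chains[[1]])
  rhat <- vapply(terms, function(tm) {
    cm <- vapply(chains, function(d) mean(d[, tm]), numeric(1))
    cv <- vapply(chains, function(d) var(d[, tm]), numeric(1))
    W <- mean(cv); B <- n * var(cm)
    if (W == 0) return(Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  tibble::tibble(term = terms, rhat = unname(rhat))
}

#' Fit and rank the phenotype model suite
#'
#' Fits M1-M4 for each response, ranks by DIC, then refits the best model
#' with the HL-by-sex interaction ("x") and with unit-varying HL slopes
#' ("y"). Coefficients whose 95% credible interval excludes 0 are flagged.
#'
#' @param records phenotype tibble (with `bci` for the BCI response).
#' @param hl tibble `id`, `hl`.
#' @param clusters list of assignment tibbles (`genetic`, `habitat`).
#' @param pc_scores list of score tibbles (`genetic`, `habitat`).
#' @param responses responses to model.
#' @param chains,iterations,burn_in MCMC settings.
#' @param standardize passed to [build_design()].
#' @param seed integer seed.
#' @return list of class `hfc_suite`: `table` (response x model DIC ranking),
#'   `coefficients` (tidy coefficient table), `fits` (named list).
#' @export
run_model_suite <- function(records, hl, clusters = NULL, pc_scores = NULL,
                            responses = c("log_mass", "log_sll", "bci"),
                            chains = 2, iterations = 2000, burn_in = 0.5,
                            standardize = TRUE, seed = 1L) {
  models <- c("M1", "M2", if (!is.null(clusters)) "M3",
              if (!is.null(pc_scores)) "M4")
  seeds <- substream_seeds(seed, length(responses) * (length(models) + 2))
  si <- 0
  fits <- list(); rows <- list(); coefs <- list()
  for (resp in responses) {
    resp_fits <- list()
    for (m in models) {
      si <- si + 1
      des <- build_design(records, resp, m, hl, clusters, pc_scores,
                          standardize = standardize)
      f <- fit_hierarchical(des$y, des$X, des$groups, hl = des$hl,
                            chains = chains, iterations = iterations,
                            burn_in = burn_in, seed = seeds[si])
      key <- paste(resp, m, sep = ".")
      fits[[key]] <- f; resp_fits[[m]] <- f
      rows[[key]] <- dplyr::mutate(glance(f), response = resp, model = m,
                                   .before = 1)
      coefs[[key]] <- dplyr::mutate(tidy(f), response = resp, model = m,
                                    .before = 1)
    }
    best <- models[which.min(purrr::map_dbl(resp_fits, "dic"))]
    for (variant in c("x", "y")) {
      si <- si + 1
      # both variants act on the homozygosity term, so the base must carry HL
      base_model <- if (best == "M1") "M2" else best
      des <- build_design(records, resp, base_model, hl, clusters, pc_scores,
                          hl_by_sex = (variant == "x"),
                          standardize = standardize)
      f <- fit_hierarchical(des$y, des$X, des$groups, hl = des$hl,
                            unit_varying_hl = (variant == "y"),
                            chains = chains, iterations = iterations,
                            burn_in = burn_in, seed = seeds[si])
      key <- paste(resp, paste0(best, variant), sep = ".")
      fits[[key]] <- f
      rows[[key]] <- dplyr::mutate(glance(f), response = resp,
                                   model = paste0(best, variant), .before = 1)
      coefs[[key]] <- dplyr::mutate(tidy(f), response = resp,
                                    model = paste0(best, variant), .before = 1)
    }
  }
  table <- dplyr::arrange(dplyr::bind_rows(rows), .data$response, .data$dic)
  structure(list(table = table, coefficients = dplyr::bind_rows(coefs),
                 fits = fits), class = "hfc_suite")
}

#' @export
print.hfc_suite <- function(x, ...) {
  cat("<hfc_suite>", length(x$fits), "fitted models\n")
  print(x$table)
  invisible(x)
}

#' Single-locus-effect F-test for a homozygosity association
#'
#' Tests whether a multilocus homozygosity association is driven by one locus:
#' the restricted OLS model carries the base covariates plus the single
#' combined homozygosity predictor; the full model replaces it with the L
#' per-locus homozygosity indicators. F = ((RSS_r - RSS_f)/(L - 1)) /
#' (RSS_f/(n - p_f)), df1 = L - 1 (14 for a 15-locus panel). Collinear
#' indicator columns are dropped with a warning and the dfs adjusted.
#'
#' @param y response vector.
#' @param base_X base covariate matrix (no intercept column; one is added).
#' @param hl combined per-individual homozygosity.
#' @param locus_hom individuals x loci 0/1 homozygosity indicator matrix
#'   ([single_locus_homozygosities()]).
#' @return tibble `f`, `df1`, `df2`, `p_value`, `loci_used`.
#' @export
single_locus_ftest <- function(y, base_X, hl, locus_hom) {
  n <- length(y)
  L0 <- ncol(locus_hom)
  keep <- rep(TRUE, L0)
  M <- cbind(1, base_X, locus_hom)
  qr_full <- qr(M)
  if (qr_full$rank < ncol(M)) {
    dropped <- colnames(M)[qr_full$pivot[-seq_len(qr_full$rank)]]
    dropped <- intersect(dropped, colnames(locus_hom))
    if (length(dropped)) {
      warn(paste("dropping collinear locus column(s):",
                 paste(dropped, collapse = ", ")))
      keep <- !(colnames(locus_hom) %in% dropped)
    }
  }
  Lh <- locus_hom[, keep, drop = FALSE]
  L <- ncol(Lh)
  fit_r <- lm(y ~ ., data = data.frame(base_X, hl = hl))
  fit_f <- lm(y ~ ., data = data.frame(base_X, Lh))
  rss_r <- sum(resid(fit_r)^2); rss_f <- sum(resid(fit_f)^2)
  p_f <- length(coef(fit_f))
  df1 <- L - 1; df2 <- n - p_f
  if (n <= p_f) stop("too few individuals for the full per-locus model")
  f <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  tibble::tibble(f = f, df1 = df1, df2 = df2,
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 loci_used = L)
}
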