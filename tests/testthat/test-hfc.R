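test_that("body condition index is the standardised log-log residual", {
  # points exactly on a log-log line -> BCI all 0 (and sd-normalisation skipped)
  on_line <- tibble::tibble(id = 1:5, sll = c(100, 120, 140, 160, 180))
  on_line$mass <- exp(-5 + 2 * log(on_line$sll))
  jit <- on_line
  jit$mass[1] <- jit$mass[1] * 1.01   # avoid exact-zero residual sd
  b <- compute_bci(jit)
  expect_equal(mean(b$bci), 0, tolerance = 1e-10)
  expect_equal(sd(b$bci), 1, tolerance = 1e-10)

  # closed-form OLS oracle on a 5-point toy
  set.seed(50)
  toy <- tibble::tibble(id = 1:5, sll = runif(5, 100, 200),
                        mass = exp(rnorm(5, 4, 0.3)))
  lx <- log(toy$sll); ly <- log(toy$mass)
  beta <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  res <- ly - (mean(ly) - beta * mean(lx)) - beta * lx
  expect_equal(compute_bci(toy)$bci, res / sd(res), tolerance = 1e-10)

  expect_error(compute_bci(tibble::tibble(id = 1:3, mass = c(-1, 2, 3),
                                          sll = c(1, 2, 3))), "positive")
})

test_that("build_design assembles the model suite's columns", {
  d <- sim_m2_data(n = 120, seed = 51)
  hl <- dplyr::select(d, id, hl)
  des1 <- build_design(d, "log_mass", "M1")
  expect_setequal(colnames(des1$X), c("sex", "age", "northing", "spring", "summer"))
  des2 <- build_design(d, "log_mass", "M2", hl = hl)
  expect_true("hl" %in% colnames(des2$X))
  # standardisation: continuous columns mean 0 sd 1
  for (cn in c("age", "northing", "hl"))
    expect_equal(c(mean(des2$X[, cn]), sd(des2$X[, cn])), c(0, 1),
                 tolerance = 1e-10)

  # genetic k = 3 -> exactly two dummies, relative to the third cluster
  cl <- list(genetic = tibble::tibble(id = d$id,
                                      cluster = sample(1:3, 120, TRUE)),
             habitat = tibble::tibble(id = d$id,
                                      cluster = sample(1:2, 120, TRUE)))
  des3 <- build_design(d, "log_mass", "M3", hl = hl, clusters = cl)
  expect_equal(sum(grepl("gen_k", colnames(des3$X))), 2)
  expect_equal(sum(grepl("hab_k", colnames(des3$X))), 1)

  # all-fall captures: season dummies dropped with a message
  dfall <- dplyr::mutate(d, season = "fall")
  expect_message(des4 <- build_design(dfall, "log_mass", "M1"), "constant dummy")
  expect_false(any(c("spring", "summer") %in% colnames(des4$X)))

  # complete-case handling drops and counts
  dmiss <- d; dmiss$mass[1:7] <- NA
  expect_message(des5 <- build_design(dmiss, "log_mass", "M1"), "7 incomplete")
  expect_equal(length(des5$y), 113)
})

test_that("the Gibbs sampler is deterministic and agrees with lmer", {
  d <- sim_m2_data(n = 400, seed = 52)
  des <- build_design(d, "log_mass", "M2",
                      hl = dplyr::select(d, id, hl), standardize = FALSE)
  f1 <- fit_hierarchical(des$y, des$X, des$groups, chains = 2,
                         iterations = 800, seed = 9)
  f2 <- fit_hierarchical(des$y, des$X, des$groups, chains = 2,
                         iterations = 800, seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(c("hl", "mu_alpha", "sigma_resid") %in% f1$summary$term))

  skip_if_not_installed("lme4")
  lf <- lme4::lmer(y ~ sex + age + northing + spring + summer + hl + (1 | g),
                   data = data.frame(des$X, y = des$y, g = des$groups),
                   REML = FALSE)
  fe <- lme4::fixef(lf)
  post <- f1$summary
  for (cn in c("sex", "age", "hl")) {
    expect_lt(abs(post$estimate[post$term == cn] - fe[[cn]]), 0.05)
  }
  expect_lt(abs(post$estimate[post$term == "sigma_resid"] -
                stats::sigma(lf)), 0.02)
})

test_that("zero-variance unit structure shrinks the intercept sd posterior", {
  # sigma_unit = 0 truth; sigma_resid at unit scale so the 0.1-relative
  # criterion is not swamped by the IG(0.001, 0.001) prior floor
  d <- sim_m2_data(n = 1200, sigma_unit = 0, sigma_resid = 1, seed = 53)
  des <- build_design(d, "log_mass", "M2", hl = dplyr::select(d, id, hl))
  f <- fit_hierarchical(des$y, des$X, des$groups, chains = 2,
                        iterations = 1200, seed = 10)
  draws <- do.call(rbind, f$draws)
  expect_lt(stats::median(draws[, "sigma_alpha"]),
            0.1 * stats::median(draws[, "sigma_resid"]))
})

test_that("unit-varying homozygosity slopes are sampled and centred on truth", {
  # strong per-unit signal: gamma_u ~ N(0.65, 0.1^2)
  set.seed(54)
  n <- 500; U <- 6
  unit <- sample.int(U, n, TRUE)
  hl <- rbeta(n, 2, 4)
  gam <- rnorm(U, 0.65, 0.1)
  y <- 1 + gam[unit] * hl + rnorm(n, 0, 0.1)
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "noise"))
  f <- fit_hierarchical(y, X, factor(unit), hl = hl, unit_varying_hl = TRUE,
                        chains = 2, iterations = 1000, seed = 11)
  mu_g <- f$summary$estimate[f$summary$term == "mu_gamma"]
  expect_lt(abs(mu_g - 0.65), 0.2)
  expect_true(f$summary$significant[f$summary$term == "mu_gamma"])
})

test_that("gelman_rubin matches its formula and flags divergence", {
  set.seed(55)
  iid <- list(rnorm(500), rnorm(500))
  expect_lt(gelman_rubin(iid)$rhat, 1.1)
  apart <- list(rnorm(500, 0), rnorm(500, 10))
  expect_gt(gelman_rubin(apart)$rhat, 5)

  # hand computation, 2 chains x 10 draws
  c1 <- c(1.2, 0.8, 1.1, 0.9, 1.0, 1.3, 0.7, 1.05, 0.95, 1.0)
  c2 <- c(0.6, 1.4, 1.0, 1.1, 0.9, 0.8, 1.2, 1.0, 1.05, 0.95)
  n <- 10
  W <- mean(c(var(c1), var(c2)))
  B <- n * var(c(mean(c1), mean(c2)))
  expect_equal(gelman_rubin(list(c1, c2))$rhat,
               sqrt(((n - 1) / n * W + B / n) / W), tolerance = 1e-12)
  expect_error(gelman_rubin(list(c1)), ">= 2")
  expect_error(gelman_rubin(list(c1[1:5], c2[1:5])), ">= 10")
})

test_that("DIC bookkeeping: dic = dbar + pd, positive pd, draw-count guard", {
  d <- sim_m2_data(n = 150, seed = 56)
  des <- build_design(d, "log_mass", "M2", hl = dplyr::select(d, id, hl))
  f <- fit_hierarchical(des$y, des$X, des$groups, chains = 2,
                        iterations = 600, seed = 12)
  res <- dic(f)
  expect_equal(res$dic, res$dbar + res$pd, tolerance = 1e-9)
  expect_gt(res$pd, 0)
  # effective parameter count should be near the true dimension (8 fe + 6 re)
  expect_lt(abs(res$pd - 12), 8)
  fshort <- f; fshort$n_keep <- 10
  expect_error(dic(fshort), "100 retained")
})

test_that("run_model_suite ranks models and flags coefficients", {
  d <- sim_m2_data(n = 200, hl_coef = 0.65, seed = 57)
  suite <- suppressMessages(run_model_suite(
    d, dplyr::select(d, id, hl), responses = "log_mass",
    chains = 2, iterations = 600, seed = 13))
  expect_setequal(unique(suite$table$model), c("M1", "M2", "M2x", "M2y"))
  tab <- suite$table
  expect_lt(tab$dic[tab$model == "M2"], tab$dic[tab$model == "M1"])
  co <- suite$coefficients
  hl_row <- co[co$model == "M2" & co$term == "hl", ]
  expect_true(hl_row$significant)
  expect_true(hl_row$estimate > 0)
  # one row per (response, model) pair in the ranking table
  expect_equal(nrow(tab), 4)
})

test_that("single-locus F-test has df1 = L - 1 and detects a planted locus", {
  set.seed(58)
  n <- 200; L <- 15
  hom <- matrix(rbinom(n * L, 1, 0.3), n, L,
                dimnames = list(NULL, sprintf("L%02d", 1:L)))
  hl <- rowMeans(hom)
  base_X <- cbind(sex = rbinom(n, 1, 0.5), age = rnorm(n))
  # pure general effect
  y <- 0.5 * hl + 0.2 * base_X[, "sex"] + rnorm(n, 0, 0.3)
  res <- single_locus_ftest(y, base_X, hl, hom)
  expect_equal(res$df1, 14)
  expect_equal(res$loci_used, 15)

  # planted strong single-locus effect is detected
  y2 <- 0.8 * hom[, 3] + rnorm(n, 0, 0.3)
  res2 <- single_locus_ftest(y2, base_X, rowMeans(hom), hom)
  expect_lt(res2$p_value, 0.05)

  # collinear locus column dropped with a warning, df adjusted
  hom_dup <- cbind(hom, L16 = hom[, 1])
  expect_warning(res3 <- single_locus_ftest(y, base_X, hl, hom_dup),
                 "collinear")
  expect_equal(res3$df1, 14)
})
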