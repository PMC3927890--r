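test_that("allele frequencies count gene copies and skip missing pairs", {
  g <- genotype_table(matrix(c(1L, 1L), 2, 1), matrix(c(1L, 2L), 2, 1),
                      c("a", "b"), "L1")
  af <- allele_frequencies(g)
  expect_equal(af$freq[af$allele == 1], 0.75)
  expect_equal(af$freq[af$allele == 2], 0.25)

  gm <- toy_genotypes()   # i4 missing at L2
  af2 <- allele_frequencies(gm)
  l2 <- af2[af2$locus == "L2", ]
  expect_equal(sum(l2$count), 6)        # 3 typed individuals x 2 copies
  expect_equal(sum(l2$freq), 1, tolerance = 1e-12)

  # brute-force tally on a larger table
  g5 <- random_genotypes(500, 8, seed = 5)
  af5 <- allele_frequencies(g5)
  for (l in c(1, 8)) {
    copies <- c(g5$a1[, l], g5$a2[, l])
    for (a in unique(copies)) {
      expect_equal(af5$freq[af5$locus == g5$loci[l] & af5$allele == a],
                   mean(copies == a), tolerance = 1e-12)
    }
  }
})

test_that("heterozygosities match closed forms and simulated expectations", {
  mono <- genotype_table(matrix(1L, 5, 1), matrix(1L, 5, 1),
                         paste0("i", 1:5), "L1")
  h <- heterozygosities(mono)
  expect_equal(h$ho, 0); expect_equal(h$he, 0)

  half <- genotype_table(matrix(1L, 10, 1), matrix(2L, 10, 1),
                         paste0("i", 1:10), "L1")   # p = 0.5 / 0.5
  expect_equal(heterozygosities(half)$he, 0.5)
  expect_equal(heterozygosities(half)$ho, 1)

  # mean He across 10 seeds tracks the analytic 1 - sum p^2 of the truth
  errs <- vapply(1:10, function(s) {
    cfg <- sim_config(n_individuals = 150, k_gen = 1, n_loci = 10, seed = s)
    out <- sim_genotypes(cfg)
    he_true <- mean(1 - rowSums(out$truth$p_population[[1]]^2))
    mean(heterozygosities(out$genotypes)$he) - he_true
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
})

test_that("HWE Monte-Carlo test flags heterozygote excess and guards inputs", {
  g <- genotype_table(matrix(1L, 50, 1), matrix(2L, 50, 1),
                      sprintf("i%02d", 1:50), "L1")
  res <- hwe_test(g, "L1", n_perm = 2000, seed = 1)
  expect_lt(res$p_value, 0.01)
  expect_error(hwe_test(g, "L1", n_perm = 0), "n_perm")
  mono <- genotype_table(matrix(1L, 5, 1), matrix(1L, 5, 1),
                         paste0("i", 1:5), "L1")
  expect_error(hwe_test(mono, "L1"), "monomorphic")
})

test_that("HWE test is calibrated under Hardy-Weinberg sampling", {
  # 200 loci drawn in exact HW proportions; rejection at 0.05 within +/- 0.03
  set.seed(42)
  n <- 200
  rej <- vapply(1:200, function(i) {
    p <- runif(1, 0.2, 0.8)
    a1 <- ifelse(runif(n) < p, 1L, 2L)
    a2 <- ifelse(runif(n) < p, 1L, 2L)
    g <- genotype_table(matrix(a1), matrix(a2), sprintf("i%03d", 1:n), "L1")
    hwe_test(g, "L1", n_perm = 399, seed = i)$p_value <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("homozygosity by loci matches its defining formula and endpoints", {
  ghet <- genotype_table(matrix(c(1L, 3L), 1, 2), matrix(c(2L, 4L), 1, 2),
                         "x", c("L1", "L2"))
  # single individual: He = 0.5 at both loci; fully heterozygous -> 0
  expect_equal(homozygosity_by_loci(ghet)$hl, 0)

  # 3-locus toy with sample He = 0.5, 0.8, 0.6 enforced via a reference
  # panel; focal individual homozygous at locus 2 only
  hl_weights <- c(0.5, 0.8, 0.6)
  het <- c(TRUE, FALSE, TRUE)
  expect_equal(sum(hl_weights[!het]) / sum(hl_weights), 0.8 / 1.9)
  # package path on a table engineered to those He values is exercised in
  # the acceptance suite; here check the pure indicator identities
  n <- 30
  set.seed(7)
  g <- random_genotypes(n, 6, seed = 8)
  hl <- homozygosity_by_loci(g)
  hom <- single_locus_homozygosities(g)
  he <- heterozygosities(g)$he
  manual <- vapply(seq_len(n), function(i) {
    w <- he[!is.na(hom[i, ])]
    h <- hom[i, !is.na(hom[i, ])]
    sum(w[h == 1]) / sum(w)
  }, numeric(1))
  expect_equal(hl$hl, manual, tolerance = 1e-12)
  expect_true(all(hl$hl >= 0 & hl$hl <= 1))
})

test_that("single-locus homozygosity indicators are consistent", {
  g <- toy_genotypes()
  m <- single_locus_homozygosities(g)
  expect_equal(unname(m["i1", "L1"]), 1)   # (1,1)
  expect_equal(unname(m["i2", "L1"]), 0)   # (1,2)
  expect_true(is.na(m["i4", "L2"]))
  frac <- rowMeans(m, na.rm = TRUE)
  expect_equal(unname(frac["i1"]), mean(c(1, 1, 1)))
})

test_that("Queller-Goodnight relatedness matches a scalar-loop oracle", {
  g <- random_genotypes(20, 5, seed = 11)
  r <- qg_relatedness(g)
  af <- allele_frequencies(g)
  for (pair in list(c(1, 2), c(3, 17), c(5, 20), c(9, 10))) {
    o <- (qg_pair_oracle(g, pair[1], pair[2], af) +
          qg_pair_oracle(g, pair[2], pair[1], af)) / 2
    expect_equal(unclass(r)[pair[1], pair[2]], o, tolerance = 1e-10)
  }
  expect_lt(max(abs(r - t(r))), 1e-12)
})

test_that("relatedness behaves under panmixia and for parent-offspring pairs", {
  g <- random_genotypes(100, 15, seed = 12)
  r <- unclass(qg_relatedness(g))
  expect_lt(abs(mean(lower_vec_test(r))), 0.05)

  # Mendelian parent-offspring pairs: one allele inherited from the parent
  set.seed(13)
  n_pairs <- 200; L <- 15; A <- 8
  p <- matrix(rgamma(L * A, 1), L, A); p <- p / rowSums(p)
  par1 <- par2 <- off1 <- off2 <- matrix(NA_integer_, 2 * n_pairs, L)
  a1 <- matrix(NA_integer_, 2 * n_pairs, L); a2 <- a1
  for (l in seq_len(L)) {
    pa <- sample.int(A, n_pairs, TRUE, p[l, ]); pb <- sample.int(A, n_pairs, TRUE, p[l, ])
    ma <- sample.int(A, n_pairs, TRUE, p[l, ])  # other parent's contribution
    inherit <- ifelse(runif(n_pairs) < 0.5, pa, pb)
    a1[seq_len(n_pairs), l] <- pa; a2[seq_len(n_pairs), l] <- pb
    a1[n_pairs + seq_len(n_pairs), l] <- inherit
    a2[n_pairs + seq_len(n_pairs), l] <- ma
  }
  ids <- c(sprintf("p%03d", 1:n_pairs), sprintf("o%03d", 1:n_pairs))
  gp <- genotype_table(a1, a2, ids, sprintf("L%02d", 1:L))
  rp <- unclass(qg_relatedness(gp))
  po <- vapply(seq_len(n_pairs), function(i) rp[i, n_pairs + i], numeric(1))
  expect_lt(abs(mean(po) - 0.5), 0.05)
})

test_that("a fully heterozygous genotype has self-relatedness 1", {
  # third individual shifts allele frequencies off the degenerate case where
  # the QG denominator vanishes
  a1 <- rbind(c(1L, 3L, 5L), c(1L, 4L, 6L), c(7L, 7L, 7L))
  a2 <- rbind(c(2L, 4L, 6L), c(2L, 3L, 5L), c(8L, 8L, 8L))
  g <- genotype_table(a1, a2, c("x", "y", "z"), c("L1", "L2", "L3"))
  r <- unclass(qg_relatedness(g))
  expect_equal(unname(r["x", "x"]), 1, tolerance = 1e-12)
  expect_equal(unname(r["y", "y"]), 1, tolerance = 1e-12)
})

test_that("molecular coancestry matches hand counts and its bounds", {
  # identical homozygous genotypes -> 1; disjoint alleles -> 0
  g <- genotype_table(matrix(c(1L, 1L, 3L), 3, 2), matrix(c(1L, 1L, 4L), 3, 2),
                      c("x", "y", "z"), c("L1", "L2"))
  f <- unclass(molecular_coancestry(g))
  expect_equal(f["x", "y"], 1)
  expect_equal(f["x", "z"], 0)

  # 2-locus toy: x = (1,2),(3,3); y = (1,1),(3,4) -> 0.5
  gt <- genotype_table(matrix(c(1L, 1L, 3L, 3L), 2, 2),
                       matrix(c(2L, 1L, 3L, 4L), 2, 2),
                       c("x", "y"), c("L1", "L2"))
  ft <- unclass(molecular_coancestry(gt))
  expect_equal(ft["x", "y"], 0.5)
  g2 <- random_genotypes(30, 8, seed = 14)
  f2 <- unclass(molecular_coancestry(g2))
  expect_true(all(f2 >= 0 & f2 <= 1))
})

test_that("pairwise matrices are permutation-equivariant", {
  g <- random_genotypes(15, 6, seed = 15)
  perm <- sample(15)
  gp <- genotype_table(g$a1[perm, ], g$a2[perm, ], g$ids[perm], g$loci)
  r1 <- unclass(qg_relatedness(g)); r2 <- unclass(qg_relatedness(gp))
  expect_equal(r2, r1[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
  f1 <- unclass(molecular_coancestry(g)); f2 <- unclass(molecular_coancestry(gp))
  expect_equal(f2, f1[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("genotype PCA separates diverged populations and matches eigen", {
  # private alleles: population A uses codes 1/2, population B codes 3/4
  set.seed(16)
  n <- 40; L <- 6
  a1 <- cbind(matrix(sample(1:2, n / 2 * L, TRUE), n / 2, L))
  a1 <- rbind(a1, matrix(sample(3:4, n / 2 * L, TRUE), n / 2, L))
  a2 <- rbind(matrix(sample(1:2, n / 2 * L, TRUE), n / 2, L),
              matrix(sample(3:4, n / 2 * L, TRUE), n / 2, L))
  g <- genotype_table(a1, a2, sprintf("i%02d", 1:n), sprintf("L%d", 1:L))
  pca <- genotype_pca(g, 2)
  pc1 <- pca$scores$PC1
  lab <- rep(1:2, each = n / 2)
  expect_true(abs(cor(pc1, lab)) > 0.99)
  expect_true(all(diff(pca$percent_all) < 1e-9))
  expect_lte(sum(pca$percent_all), 100 + 1e-9)

  # independent eigen-solver oracle (up to per-axis sign)
  g2 <- random_genotypes(25, 5, seed = 17)
  p2 <- genotype_pca(g2, 3)
  X <- ecogenlink:::allele_count_matrix(g2)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(cov(Xc))
  sc_oracle <- Xc %*% ev$vectors[, 1:3]
  for (ax in 1:3) {
    got <- p2$scores[[paste0("PC", ax)]]
    expect_true(min(max(abs(got - sc_oracle[, ax])),
                    max(abs(got + sc_oracle[, ax]))) < 1e-8)
  }
  expect_error(genotype_pca(g2, 500), "rank")
})
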