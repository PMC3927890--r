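# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (scalar loops, closed forms) and share no code with the package paths
# they check.

toy_genotypes <- function() {
  # 4 individuals x 3 loci, one missing genotype
  a1 <- matrix(c(1L, 1L, 2L, 1L,
                 3L, 3L, 3L, NA,
                 1L, 2L, 1L, 2L), 4, 3)
  a2 <- matrix(c(1L, 2L, 2L, 2L,
                 3L, 4L, 3L, NA,
                 1L, 2L, 2L, 2L), 4, 3)
  genotype_table(a1, a2, c("i1", "i2", "i3", "i4"), c("L1", "L2", "L3"))
}

random_genotypes <- function(n, L, A = 6, seed = 1) {
  set.seed(seed)
  p <- matrix(rgamma(L * A, 1), L, A)
  p <- p / rowSums(p)
  draw <- function() {
    m <- matrix(NA_integer_, n, L)
    for (l in seq_len(L)) m[, l] <- sample.int(A, n, TRUE, prob = p[l, ])
    m
  }
  genotype_table(draw(), draw(), sprintf("i%03d", seq_len(n)),
                 sprintf("L%02d", seq_len(L)))
}

# scalar-loop Queller-Goodnight for one ordered pair (x focal)
qg_pair_oracle <- function(g, x, y, freqs) {
  num <- 0; den <- 0
  for (l in seq_along(g$loci)) {
    a <- g$a1[x, l]; b <- g$a2[x, l]
    c_ <- g$a1[y, l]; d_ <- g$a2[y, l]
    if (anyNA(c(a, b, c_, d_))) next
    fl <- freqs[freqs$locus == g$loci[l], ]
    pa <- fl$freq[fl$allele == a]; pb <- fl$freq[fl$allele == b]
    num <- num + 0.5 * ((a == c_) + (a == d_) + (b == c_) + (b == d_)) - pa - pb
    den <- den + 1 + (a == b) - pa - pb
  }
  num / den
}

# restricted-growth-string enumeration of all partitions into <= k blocks
best_partition_sse <- function(X, k) {
  n <- nrow(X)
  best <- Inf
  rec <- function(i, labels, maxlab) {
    if (i > n) {
      sse <- 0
      for (g in unique(labels)) {
        rows <- X[labels == g, , drop = FALSE]
        sse <- sse + sum(sweep(rows, 2, colMeans(rows))^2)
      }
      best <<- min(best, sse)
      return(invisible())
    }
    for (lab in seq_len(min(maxlab + 1, k))) {
      rec(i + 1, c(labels, lab), max(maxlab, lab))
    }
  }
  rec(2, c(1L), 1L)
  best
}

lower_vec_test <- function(m) m[lower.tri(m)]

rand_index <- function(a, b) {
  n <- length(a)
  s <- 0; tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
    tot <- tot + 1
  }
  s / tot
}

# direct tree-distance recomputation (independent of ape::cophenetic)
tree_path_lengths <- function(tr) {
  nt <- length(tr$tip.label)
  nn <- nt + tr$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]; w <- tr$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(0, nt, nt, dimnames = list(tr$tip.label, tr$tip.label))
  for (s in seq_len(nt)) {
    dist <- rep(NA_real_, nn); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]; w <- adj[[v]][r, 2]
        if (is.na(dist[u])) { dist[u] <- dist[v] + w; queue <- c(queue, u) }
      }
    }
    d[s, ] <- dist[seq_len(nt)]
  }
  d
}

# M2-style phenotype generator on natural covariate scales
sim_m2_data <- function(n = 300, hl_coef = 0.65, sigma_unit = 0.1,
                        sigma_resid = 0.15, n_units = 6, seed = 1) {
  set.seed(seed)
  ui <- sample.int(n_units, n, TRUE)
  sex <- ifelse(runif(n) < 0.5, "F", "M")
  age <- 2L + rpois(n, 6)
  yco <- 100 * (ui - 1) + runif(n, 0, 80)
  hl <- rbeta(n, 2, 4)
  alpha <- rnorm(n_units, 0, sigma_unit)
  tibble::tibble(
    id = sprintf("b%03d", 1:n), sex = sex, age = age,
    season = sample(c("spring", "summer", "fall"), n, TRUE),
    x = runif(n, 0, 300), y = yco, unit = paste0("unit", ui), hl = hl,
    mass = exp(3.9 + 0.55 * (sex == "M") + 0.03 * age + 0.0002 * yco +
                 hl_coef * hl + alpha[ui] + rnorm(n, 0, sigma_resid)),
    sll = exp(4.9 + 0.11 * (sex == "M") + 0.01 * age + 0.15 * hl +
                rnorm(n, 0, sigma_resid)))
}
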