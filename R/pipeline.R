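#' Simulate a full synthetic study and optionally write its input files
#'
#' Runs every generator in order — genotypes, habitat use, homozygosity,
#' phenotypes (with body condition), availability points, translocations —
#' and returns the bundle plus the ground-truth record. With `dir` set, the
#' files are written (Genepop for genotypes, CSV for the tables, JSON for
#' config and truth) and the paths returned.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @param n_avail_points random availability points per unit (the full study
#'   used 150000 across the system; default 2000/unit desk-scale).
#' @param n_transloc,p_cross,p_north translocation scenario (defaults:
#'   the recorded provincial history).
#' @return list of class `eco_study`: `genotypes`, `habitat_use`, `hl`,
#'   `phenotypes`, `availability`, `translocations`, `truth`, `config`,
#'   and `paths` when written.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL,
                           n_avail_points = 2000,
                           n_transloc = 362, p_cross = 229 / 362,
                           p_north = 204 / 229) {
  gen <- sim_genotypes(config)
  hab <- sim_habitat_use(config, gen$truth)
  hl <- homozygosity_by_loci(gen$genotypes)
  phe <- sim_phenotypes(config, hab$truth, hl$hl)
  phe$phenotypes <- compute_bci(phe$phenotypes)
  avail <- sim_availability_points(config, phe$truth, n_avail_points)
  tl <- sim_translocations(n_transloc, config$n_units, p_cross, p_north,
                           seed = sim_stage_seed(config, "translocations"))
  study <- structure(list(genotypes = gen$genotypes, habitat_use = hab$use,
                          hl = hl, phenotypes = phe$phenotypes,
                          availability = avail, translocations = tl,
                          truth = phe$truth, config = config),
                     class = "eco_study")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      genotypes = file.path(dir, "genotypes.gen"),
      habitat_use = file.path(dir, "habitat_use.csv"),
      hl = file.path(dir, "homozygosity.csv"),
      phenotypes = file.path(dir, "phenotypes.csv"),
      availability = file.path(dir, "availability.csv"),
      translocations = file.path(dir, "translocations.csv"),
      truth = file.path(dir, "truth.json"),
      config = file.path(dir, "config.json"))
    write_genepop(study$genotypes, paths$genotypes)
    write_result_csv(study$habitat_use, paths$habitat_use)
    write_result_csv(study$hl, paths$hl)
    write_result_csv(study$phenotypes, paths$phenotypes)
    write_result_csv(study$availability, paths$availability)
    write_result_csv(study$translocations, paths$translocations)
    truth_json <- study$truth
    truth_json$p_population <- lapply(truth_json$p_population, unclass)
    jsonlite::write_json(truth_json, paths$truth, digits = NA, auto_unbox = TRUE)
    cfg <- unclass(config)
    cfg$eco_concentrations <- unclass(cfg$eco_concentrations)
    jsonlite::write_json(cfg, paths$config, digits = NA, auto_unbox = TRUE)
    study$paths <- paths
  }
  study
}

# Availability profiles per unit: Dirichlet draw per unit around a
# south->north gradient between the two reference ecotype profiles, then
# multinomial point counts (emulates scoring random points in home ranges).
sim_availability_points <- function(config, truth, n_points_per_unit = 2000) {
  with_seed(sim_stage_seed(config, "fixes"), {
    U <- config$n_units
    base <- default_eco_concentrations(max(config$k_eco, 2))
    w <- seq(0, 1, length.out = U)
    prof <- t(vapply(w, function(wi)
      (1 - wi) * base[1, ] + wi * base[nrow(base), ], numeric(7)))
    props <- rdirichlet_mat(prof * 3)   # tighter than individual-level draws
    purrr::map_dfr(seq_len(U), function(u) {
      cls <- sample(habitat_classes, n_points_per_unit, replace = TRUE,
                    prob = props[u, ])
      tibble::tibble(unit = paste0("unit", u), class = cls)
    })
  })
}

#' @export
print.eco_study <- function(x, ...) {
  cat("<eco_study>", x$config$n_individuals, "individuals |",
      x$config$n_loci, "loci |", x$config$n_units, "units |",
      nrow(x$translocations), "translocation events\n")
  invisible(x)
}

#' Run the full genotype-ecotype-phenotype analysis
#'
#' Orchestrates every stage on a simulated (or equivalently structured)
#' study: genetic summaries and HL, genotype and habitat PCAs, ecotype
#' K-means profile, admixture profile with Evanno delta-K, assignment
#' correlation, the Mantel/partial-Mantel IBE battery for both genetic
#' metrics, the hierarchical phenotype model suite, the single-locus F-test,
#' availability chi-squared + neighbor-joining tree, and the translocation
#' summary. Desk-scale defaults throughout; every stage is seeded from the
#' one `seed`. With `dir` set, each stage's table is written as CSV (tree as
#' Newick) plus a JSON run manifest.
#'
#' @param study an `eco_study` from [simulate_study()].
#' @param seed integer seed for all stochastic stages.
#' @param dir optional results directory.
#' @param k_range_eco,k_range_gen k profiles for the two clusterings.
#' @param n_perm Mantel permutations.
#' @param sweeps admixture sweeps per replicate.
#' @param replicates admixture replicates.
#' @param sa_steps,sa_restarts K-means annealing budget.
#' @param mcmc_iterations,chains hierarchical-model settings.
#' @param skip character vector of stages to skip (`"clustering"`, `"ibe"`,
#'   `"hfc"`, `"habitat"`, `"translocations"`).
#' @return list of class `eco_results` with one element per stage.
#' @export
run_ibe_pipeline <- function(study, seed = 1L, dir = NULL,
                             k_range_eco = 1:6, k_range_gen = 1:5,
                             n_perm = 199, sweeps = 1500, replicates = 3,
                             sa_steps = 5000, sa_restarts = 5,
                             mcmc_iterations = 1500, chains = 2,
                             skip = character()) {
  seeds <- substream_seeds(seed, 10)
  res <- list(seed = seed)
  g <- study$genotypes
  res$diversity <- heterozygosities(g)
  res$hl <- study$hl
  res$gen_pca <- genotype_pca(g, 3)
  use_t <- arcsine_sqrt(study$habitat_use)
  res$hab_pca <- habitat_pca(use_t, 3)

  if (!"clustering" %in% skip) {
    res$kmeans <- sa_kmeans_profile(use_t, k_range_eco, steps = sa_steps,
                                    restarts = sa_restarts, seed = seeds[1])
    res$admixture <- admixture_profile(g, k_range_gen, iterations = sweeps,
                                       replicates = replicates, seed = seeds[2])
    eco_k <- res$kmeans$best_pseudo_f
    eco_assign <- res$kmeans$solutions[[paste0("k", eco_k)]]$assignment
    gen_assign <- res$admixture$fits[[paste0("k", res$admixture$best_k)]]$Q
    res$assignments <- dplyr::left_join(
      dplyr::rename(eco_assign, ecotype = "cluster"),
      dplyr::select(gen_assign, "id", genotype = "cluster"), by = "id")
    res$assignment_cor <- if (sd(res$assignments$ecotype) > 0 &&
                              sd(res$assignments$genotype) > 0)
      assignment_correlation(res$assignments$ecotype, res$assignments$genotype)
    else tibble::tibble(r = NA_real_, p_value = NA_real_,
                        n = nrow(res$assignments),
                        r_max_relabel = NA_real_, r_min_relabel = NA_real_)
  }

  if (!"ibe" %in% skip) {
    coords <- dplyr::select(study$phenotypes, "id", "x", "y")
    D <- geographic_distance(coords)
    S <- sex_matrix(dplyr::select(study$phenotypes, "id", "sex"))
    E <- lapply(1:3, function(ax) ecological_distance(res$hab_pca, ax))
    G <- list(qg = qg_relatedness(g), coancestry = molecular_coancestry(g))
    res$ibe <- ibe_suite(G, D, S, E, n_perm = n_perm, seed = seeds[3])
  }

  if (!"hfc" %in% skip) {
    clusters <- if (!is.null(res$assignments))
      list(genetic = dplyr::select(res$assignments, "id", cluster = "genotype"),
           habitat = dplyr::select(res$assignments, "id", cluster = "ecotype"))
    pc_scores <- list(genetic = res$gen_pca$scores, habitat = res$hab_pca$scores)
    suite <- run_model_suite(study$phenotypes, study$hl,
                             clusters = clusters, pc_scores = pc_scores,
                             chains = chains, iterations = mcmc_iterations,
                             seed = seeds[4])
    res$hfc <- suite
    des <- build_design(study$phenotypes, "log_mass", "M1")
    sl <- single_locus_homozygosities(g)
    sl <- sl[match(des$ids, rownames(sl)), , drop = FALSE]
    hlv <- study$hl$hl[match(des$ids, study$hl$id)]
    res$single_locus <- single_locus_ftest(des$y, des$X, hlv, sl)
  }

  if (!"habitat" %in% skip) {
    avail <- availability_from_points(study$availability)
    res$availability <- avail
    res$availability_chi2 <- availability_chi2(avail)
    d <- availability_distance(avail)
    res$nj_tree <- neighbor_joining(d)
    res$availability_distance <- d
  }

  if (!"translocations" %in% skip) {
    unit_order <- paste0("unit", seq_len(study$config$n_units))
    res$translocations <- translocation_summary(study$translocations, unit_order)
  }

  class(res) <- "eco_results"
  if (!is.null(dir)) write_results(res, dir)
  res
}

write_results <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) write_result_csv(x, file.path(dir, paste0(name, ".csv")))
  w(res$diversity, "diversity")
  w(res$hl, "homozygosity")
  w(res$gen_pca$scores, "genotype_pca_scores")
  w(res$hab_pca$scores, "habitat_pca_scores")
  if (!is.null(res$kmeans)) w(res$kmeans$stats, "kmeans_profile")
  if (!is.null(res$admixture)) {
    w(res$admixture$loglik, "admixture_loglik")
    w(res$admixture$delta_k, "evanno_delta_k")
  }
  if (!is.null(res$assignments)) w(res$assignments, "assignments")
  if (!is.null(res$assignment_cor)) w(res$assignment_cor, "assignment_correlation")
  if (!is.null(res$ibe)) w(tibble::as_tibble(res$ibe), "ibe_suite")
  if (!is.null(res$hfc)) {
    w(res$hfc$table, "hfc_model_table")
    w(res$hfc$coefficients, "hfc_coefficients")
  }
  if (!is.null(res$single_locus)) w(res$single_locus, "single_locus_ftest")
  if (!is.null(res$availability)) w(res$availability, "availability")
  if (!is.null(res$availability_chi2)) w(res$availability_chi2, "availability_chi2")
  if (!is.null(res$nj_tree))
    write_newick(res$nj_tree, file.path(dir, "availability_nj.nwk"))
  if (!is.null(res$translocations))
    w(tidy(res$translocations), "translocation_summary")
  manifest <- list(package = "ecogenlink",
                   version = as.character(utils::packageVersion("ecogenlink")),
                   seed = res$seed, timestamp = format(Sys.time(), tz = "UTC"),
                   stages = names(res))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.eco_results <- function(x, ...) {
  cat("<eco_results> stages:", paste(setdiff(names(x), "seed"), collapse = ", "), "\n")
  if (!is.null(x$assignment_cor))
    cat("  ecotype/genotype correlation r =", round(x$assignment_cor$r, 3), "\n")
  if (!is.null(x$availability_chi2))
    cat("  availability chi-squared =", round(x$availability_chi2$statistic, 2),
        "df =", x$availability_chi2$df, "\n")
  invisible(x)
}
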