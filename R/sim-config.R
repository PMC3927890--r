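#' Land-cover class vocabulary
#'
#' The seven land-cover classes over which habitat use and availability are
#' expressed, in fixed column order.
#' @export
habitat_classes <- c("wetland", "cutblock", "shrub", "wetland-herbaceous",
                     "upland-herbaceous", "barren", "upland-forest")

default_eco_concentrations <- function(k_eco) {
  # Two reference ecotypes: a closed-forest profile (upland forest ~60% of
  # use) and a more open/regenerating profile (cutblock+herbaceous heavy).
  # Extra ecotypes interpolate between them. Concentration totals ~27-31 give
  # realistic individual-level spread around the ecotype mean.
  forest <- c(1.5, 3, 3, 0.3, 2, 1, 16)
  open   <- c(2, 7, 5, 0.5, 5, 2.5, 9)
  if (k_eco == 1) return(matrix(forest, 1, 7, dimnames = list(NULL, habitat_classes)))
  w <- seq(0, 1, length.out = k_eco)
  out <- t(vapply(w, function(wi) (1 - wi) * forest + wi * open, numeric(7)))
  colnames(out) <- habitat_classes
  out
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: a diverged-subpopulation
#' genotype model (Balding-Nichols), ecotype-specific Dirichlet habitat-use
#' profiles coupled to the genetic clusters, and a hierarchical phenotype
#' model with management-unit intercepts and a homozygosity effect. Defaults
#' describe the study system the package targets: 88 collared bears typed at
#' 15 microsatellites (8 alleles per locus), 3 genetic clusters at modest
#' divergence, 2 ecotypes over 7 land-cover classes, 6 management units
#' ordered south to north.
#'
#' @param n_individuals,n_loci,alleles_per_locus panel dimensions.
#' @param k_gen number of genetic subpopulations.
#' @param fst Balding-Nichols divergence parameter, strictly in (0, 1).
#' @param k_eco number of ecotypes.
#' @param eco_concentrations `k_eco` x 7 matrix of Dirichlet concentration
#'   parameters over the land-cover classes (strictly positive).
#' @param coupling probability that an individual's ecotype equals its genetic
#'   cluster index (modulo `k_eco`); otherwise uniform over the other ecotypes.
#' @param n_units number of management units (south-to-north order).
#' @param phenotype_coeffs named list with elements `log_mass` and `log_sll`,
#'   each a named vector `(intercept, sex, age, northing, spring, summer, hl)`
#'   on natural covariate scales (sex 0/1 with male = 1, age in years,
#'   northing in planar map units, homozygosity-by-loci in \[0, 1\]).
#' @param sigma_unit sd of the management-unit intercepts.
#' @param sigma_resid residual sd of the log-scale phenotype models.
#' @param missing_rate genotype missingness rate (0 = complete panel).
#' @param seed integer master seed; expanded into per-stage substreams so the
#'   stages can be regenerated independently.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 88, n_loci = 15, alleles_per_locus = 8,
                       k_gen = 3, fst = 0.10, k_eco = 2,
                       eco_concentrations = NULL, coupling = 0.6,
                       n_units = 6,
                       phenotype_coeffs = list(
                         log_mass = c(intercept = 3.9, sex = 0.55, age = 0.03,
                                      northing = 0.0002, spring = 0.05,
                                      summer = 0.07, hl = 0.65),
                         log_sll = c(intercept = 4.89, sex = 0.11, age = 0.01,
                                     northing = 0.0001, spring = -0.01,
                                     summer = -0.02, hl = 0.15)),
                       sigma_unit = 0.1, sigma_resid = 0.15,
                       missing_rate = 0, seed = 1L) {
  if (is.null(eco_concentrations)) eco_concentrations <- default_eco_concentrations(k_eco)
  eco_concentrations <- as.matrix(eco_concentrations)
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              k_gen = as.integer(k_gen), fst = fst, k_eco = as.integer(k_eco),
              eco_concentrations = eco_concentrations, coupling = coupling,
              n_units = as.integer(n_units),
              phenotype_coeffs = phenotype_coeffs,
              sigma_unit = sigma_unit, sigma_resid = sigma_resid,
              missing_rate = missing_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!(fst > 0 && fst < 1)) stop("fst must be strictly in (0, 1)")
    if (n_individuals < 1 || n_loci < 1 || k_gen < 1 || k_eco < 1 || n_units < 1)
      stop("all counts must be >= 1")
    if (alleles_per_locus < 2) stop("alleles_per_locus must be >= 2")
    if (any(eco_concentrations <= 0)) stop("eco_concentrations must be strictly positive")
    if (nrow(eco_concentrations) != k_eco || ncol(eco_concentrations) != 7)
      stop("eco_concentrations must be k_eco x 7")
    if (coupling < 0 || coupling > 1) stop("coupling must be in [0, 1]")
    if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
    if (sigma_unit < 0 || sigma_resid <= 0) stop("invalid phenotype sds")
    for (r in c("log_mass", "log_sll")) {
      need <- c("intercept", "sex", "age", "northing", "spring", "summer", "hl")
      if (!all(need %in% names(phenotype_coeffs[[r]])))
        stop("phenotype_coeffs$", r, " must name ", paste(need, collapse = ", "))
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_individuals, "individuals,", x$n_loci, "loci,",
      x$alleles_per_locus, "alleles/locus\n")
  cat("  genetics: k =", x$k_gen, " fst =", x$fst,
      "| ecotypes: k =", x$k_eco, " coupling =", x$coupling, "\n")
  cat("  units:", x$n_units, "| seed:", x$seed, "\n")
  invisible(x)
}

# Per-stage substreams in fixed positions so stages regenerate independently.
sim_stage_seed <- function(cfg, stage) {
  stages <- c("genotypes", "habitat", "phenotypes", "translocations",
              "missing", "fixes")
  substream_seeds(cfg$seed, length(stages))[match(stage, stages)]
}
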