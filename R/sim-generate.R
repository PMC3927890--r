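#' Simulate diploid genotypes from diverged subpopulations
#'
#' Balding-Nichols scheme: per locus, ancestral allele frequencies are drawn
#' from a symmetric Dirichlet(1); each subpopulation's frequencies from
#' Dirichlet(p_anc * (1 - fst) / fst), so `fst` controls divergence from the
#' ancestral pool; diploid genotypes are two independent draws from the
#' individual's subpopulation frequencies. Individuals are assigned to the
#' `k_gen` subpopulations in near-equal contiguous blocks.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_table()]) and `truth`, a list
#'   recording per-individual cluster labels and ancestral / per-population
#'   allele frequencies (the ground-truth record used by recovery tests).
#' @export
sim_genotypes <- function(config) {
  validate_sim_config(config)
  n <- config$n_individuals; L <- config$n_loci; A <- config$alleles_per_locus
  K <- config$k_gen
  with_seed(sim_stage_seed(config, "genotypes"), {
    p_anc <- rdirichlet_mat(matrix(1, L, A))            # loci x alleles
    scale <- (1 - config$fst) / config$fst
    p_pop <- lapply(seq_len(K), function(k) rdirichlet_mat(p_anc * scale))
    cluster <- sort(rep_len(seq_len(K), n))
    draw <- function() {
      m <- matrix(NA_integer_, n, L)
      for (k in seq_len(K)) {
        rows <- which(cluster == k)
        for (l in seq_len(L)) {
          m[rows, l] <- sample.int(A, length(rows), replace = TRUE,
                                   prob = p_pop[[k]][l, ])
        }
      }
      m
    }
    a1 <- draw(); a2 <- draw()
    if (config$missing_rate > 0) {
      with_seed(sim_stage_seed(config, "missing"), {
        drop <- matrix(runif(n * L) < config$missing_rate, n, L)
        a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
      })
    }
    ids <- sprintf("bear%03d", seq_len(n))
    g <- genotype_table(a1, a2, ids, sprintf("L%02d", seq_len(L)),
                        pop = paste0("g", cluster))
    truth <- list(ids = ids, genetic_cluster = cluster,
                  p_ancestral = p_anc, p_population = p_pop)
    list(genotypes = g, truth = truth)
  })
}

#' Simulate habitat-use proportions coupled to genetic clusters
#'
#' Each individual receives an ecotype label: its genetic cluster index
#' (modulo `k_eco`) with probability `coupling`, else uniform over the other
#' ecotypes. Its 7-class habitat-use proportion vector is then one Dirichlet
#' draw from that ecotype's concentration parameters.
#'
#' @param config a [sim_config()].
#' @param truth truth record from [sim_genotypes()].
#' @return list with `use` (tibble: `id`, one column per land-cover class,
#'   `n_fixes` = NA until expanded) and `truth` extended with `ecotype`.
#' @export
sim_habitat_use <- function(config, truth) {
  validate_sim_config(config)
  if (is.null(truth$genetic_cluster)) stop("truth lacks genetic cluster labels")
  n <- config$n_individuals; ke <- config$k_eco
  with_seed(sim_stage_seed(config, "habitat"), {
    base <- ((truth$genetic_cluster - 1L) %% ke) + 1L
    eco <- base
    flip <- runif(n) >= config$coupling
    if (ke > 1 && any(flip)) {
      eco[flip] <- vapply(base[flip], function(b) {
        others <- setdiff(seq_len(ke), b)
        if (length(others) == 1L) others else sample(others, 1L)
      }, integer(1))
    }
    props <- rdirichlet_mat(config$eco_concentrations[eco, , drop = FALSE])
    colnames(props) <- habitat_classes
    use <- tibble::as_tibble(props)
    use <- dplyr::bind_cols(tibble::tibble(id = truth$ids), use)
    truth$ecotype <- eco
    list(use = use, truth = truth)
  })
}

#' Expand habitat-use proportions into discrete GPS fixes
#'
#' Thin convenience: multinomially expands each individual's proportion
#' vector into `n_fixes` pre-annotated fixes (no movement/autocorrelation
#' model). Coordinates are jittered around the unit box when unit info is
#' available, otherwise around the origin; the land-cover class column is the
#' analysis interface.
#'
#' @param use habitat-use tibble (`id` + 7 class columns).
#' @param n_fixes fixes per individual (default 1000, the desk-scale stand-in
#'   for a multi-year collar record).
#' @param seed integer seed.
#' @return tibble `id`, `fix`, `x`, `y`, `class`.
#' @export
expand_fixes <- function(use, n_fixes = 1000, seed = 1L) {
  stopifnot(all(habitat_classes %in% names(use)))
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(use)), function(i) {
      p <- as.numeric(use[i, habitat_classes])
      cls <- sample(habitat_classes, n_fixes, replace = TRUE, prob = p)
      tibble::tibble(id = use$id[i], fix = seq_len(n_fixes),
                     x = rnorm(n_fixes, 0, 5), y = rnorm(n_fixes, 0, 5),
                     class = cls)
    })
  })
}

#' Simulate phenotype records from the hierarchical model
#'
#' Generates sex, age, capture season, management unit and planar capture
#' coordinates, then log-mass and log-length as linear combinations of those
#' covariates plus the supplied per-individual homozygosity (HL), a
#' N(0, sigma_unit^2) unit intercept and N(0, sigma_resid^2) residual.
#' Units occupy south-to-north coordinate boxes so unit and northing are
#' meaningfully linked. Ages are truncated-geometric integers >= 2.
#'
#' @param config a [sim_config()].
#' @param truth truth record (cluster/ecotype labels; extended here with unit
#'   assignments, unit intercepts and the planted coefficient vectors).
#' @param hl per-individual homozygosity-by-loci in \[0, 1\], one per
#'   individual (typically [homozygosity_by_loci()] of the simulated panel).
#' @return list with `phenotypes` tibble (`id`, `sex`, `age`, `season`, `x`,
#'   `y`, `unit`, `mass`, `sll`) and updated `truth`.
#' @export
sim_phenotypes <- function(config, truth, hl) {
  validate_sim_config(config)
  n <- config$n_individuals
  if (length(hl) != n || anyNA(hl)) stop("hl must be complete, one value per individual")
  if (any(hl < 0 | hl > 1)) stop("hl values must lie in [0, 1]")
  with_seed(sim_stage_seed(config, "phenotypes"), {
    U <- config$n_units
    unit <- sample.int(U, n, replace = TRUE)
    sex <- ifelse(runif(n) < 0.5, "F", "M")
    age <- 2L + stats::rgeom(n, prob = 0.15)
    age <- pmin(age, 25L)
    season <- sample(c("spring", "summer", "fall"), n, replace = TRUE,
                     prob = c(0.45, 0.35, 0.20))
    # unit u box: x in [0, 300], y in [100(u-1), 100(u-1)+80] (south -> north)
    x <- runif(n, 0, 300)
    y <- 100 * (unit - 1) + runif(n, 0, 80)
    alpha <- rnorm(U, 0, config$sigma_unit)
    lin <- function(cf) {
      cf[["intercept"]] + cf[["sex"]] * (sex == "M") + cf[["age"]] * age +
        cf[["northing"]] * y + cf[["spring"]] * (season == "spring") +
        cf[["summer"]] * (season == "summer") + cf[["hl"]] * hl +
        alpha[unit]
    }
    log_mass <- lin(config$phenotype_coeffs$log_mass) + rnorm(n, 0, config$sigma_resid)
    log_sll <- lin(config$phenotype_coeffs$log_sll) + rnorm(n, 0, config$sigma_resid)
    ph <- tibble::tibble(id = truth$ids %||% sprintf("bear%03d", seq_len(n)),
                         sex = sex, age = age, season = season,
                         x = x, y = y, unit = paste0("unit", unit),
                         mass = exp(log_mass), sll = exp(log_sll))
    truth$unit <- unit
    truth$unit_intercepts <- alpha
    truth$hl_used <- hl
    truth$phenotype_coeffs <- config$phenotype_coeffs
    list(phenotypes = ph, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a translocation event table
#'
#' Each event has a source unit, destination unit and year. The destination
#' differs from the source with probability `p_cross`; cross-unit moves go to
#' a more northern unit with probability `p_north` (units carry a fixed
#' south-to-north ordering, unit1 southernmost). Defaults reproduce the
#' recorded provincial history: 362 events, 229 cross-unit, 204 of those
#' northward, 1974-2012.
#'
#' @param n_events number of events.
#' @param n_units number of management units.
#' @param p_cross probability an event crosses units.
#' @param p_north probability a cross-unit event moves north.
#' @param years inclusive year range events are drawn from.
#' @param seed integer seed.
#' @return tibble `event`, `year`, `source`, `dest`.
#' @export
sim_translocations <- function(n_events = 362, n_units = 6,
                               p_cross = 229 / 362, p_north = 204 / 229,
                               years = c(1974, 2012), seed = 1L) {
  if (p_cross < 0 || p_cross > 1 || p_north < 0 || p_north > 1)
    stop("probabilities must lie in [0, 1]")
  if (n_units < 2 && p_cross > 0)
    stop("cross-unit events require n_units >= 2")
  with_seed(seed, {
    cross <- runif(n_events) < p_cross
    north <- runif(n_events) < p_north
    # sources for cross-unit events are drawn so the intended direction is
    # always feasible (a northward move cannot start at the northernmost unit)
    src <- sample.int(n_units, n_events, replace = TRUE)
    src[cross & north] <- sample.int(n_units - 1L, sum(cross & north), replace = TRUE)
    src[cross & !north] <- 1L + sample.int(n_units - 1L, sum(cross & !north), replace = TRUE)
    dest <- src
    for (i in which(cross)) {
      s <- src[i]
      pool <- if (north[i]) seq_len(n_units)[seq_len(n_units) > s]
              else seq_len(n_units)[seq_len(n_units) < s]
      dest[i] <- if (length(pool) == 1) pool else sample(pool, 1)
    }
    tibble::tibble(event = seq_len(n_events),
                   year = sample(seq(years[1], years[2]), n_events, replace = TRUE),
                   source = paste0("unit", src), dest = paste0("unit", dest))
  })
}
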