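#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif rbinom rgamma rbeta sd var cor lm resid
#'   coef anova pt qnorm quantile chisq.test prcomp cov setNames as.formula
#' @importFrom utils head tail
NULL

# Derive `n` independent per-stage seeds from one global integer seed.
# Keeps every derived seed strictly below 2^31 so set.seed() accepts it.
substream_seeds <- function(seed, n, stage = "stage") {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, n)
  names(s) <- paste0(stage, seq_len(n))
  s
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# One Dirichlet draw per row of `alpha` (matrix or vector).
rdirichlet_mat <- function(alpha) {
  if (is.vector(alpha)) alpha <- matrix(alpha, nrow = 1)
  g <- matrix(rgamma(length(alpha), shape = alpha, rate = 1),
              nrow = nrow(alpha))
  g[g == 0] <- .Machine$double.xmin  # guard against underflow at tiny alpha
  g / rowSums(g)
}

#' Construct a tagged pairwise matrix
#'
#' Symmetric individual-by-individual matrices are the working currency of the
#' isolation-by-ecology machinery (relatedness, coancestry, geographic, sex and
#' ecological distances). This wraps a base matrix with an id check and a
#' `kind` tag used in printing and in the Mantel suite output.
#'
#' @param m square numeric matrix with identical row/column names.
#' @param kind one of `"relatedness"`, `"coancestry"`, `"geographic"`,
#'   `"sex"`, `"ecological"`, `"habitat-use"`.
#' @return the matrix with class `pairwise_matrix` and a `kind` attribute.
#' @export
pairwise_matrix <- function(m, kind) {
  kind <- match.arg(kind, c("relatedness", "coancestry", "geographic",
                            "sex", "ecological", "habitat-use"))
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) stop("pairwise matrix needs row/column ids")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column ids differ")
  d <- abs(m - t(m)); d <- d[!is.na(d)]
  if (length(d) && max(d) > 1e-12)
    stop("matrix not symmetric (max asymmetry ", max(d), ")")
  structure(m, class = c("pairwise_matrix", "matrix", "array"), kind = kind)
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("<pairwise_matrix> kind:", attr(x, "kind"),
      " n =", nrow(x), "individuals\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  if (nrow(x) > 6) cat("... (", nrow(x), "rows )\n")
  invisible(x)
}

# Strictly-lower-triangle vectorisation used by every Mantel-type test.
lower_vec <- function(m) m[lower.tri(m)]

check_same_ids <- function(a, b) {
  if (!identical(rownames(a), rownames(b)))
    stop("matrices must cover the same individuals in the same order")
}
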