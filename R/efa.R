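#' Sample moments of a response matrix
#'
#' Computes the unbiased (N-1 denominator) covariance matrix of the raw
#' category codes, the derived correlation matrix, and item means. Items
#' are treated as continuous, matching a maximum-likelihood analysis of
#' ordinal codes without categorical estimation.
#'
#' @param data A `prom_responses` object or a numeric matrix; rows must
#'   be complete.
#' @param items Optional character vector selecting/ordering columns
#'   (default: all columns of `data`).
#' @return A `prom_moments` object with `covariance`, `correlation`,
#'   `means`, `n`.
#' @export
sample_moments <- function(data, items = NULL) {
  m <- if (inherits(data, "prom_responses")) data$values else as.matrix(data)
  if (!is.null(items)) m <- m[, items, drop = FALSE]
  if (anyNA(m))
    stop("sample_moments requires complete cases; run complete_case_filter first")
  n <- nrow(m); p <- ncol(m)
  if (n <= p)
    stop(sprintf("N (%d) must exceed the number of items (%d) for ML fitting",
                 n, p))
  S <- stats::cov(m)
  sds <- sqrt(diag(S))
  if (any(sds == 0)) stop("zero-variance item(s): ",
                          paste(colnames(m)[sds == 0], collapse = ", "))
  structure(list(covariance = S, correlation = stats::cov2cor(S),
                 means = colMeans(m), n = n),
            class = "prom_moments")
}

#' Construct moments from known matrices
#'
#' Wraps an externally supplied covariance (or correlation) matrix in the
#' container used by the fitting functions; used for population-level
#' checks and worked examples.
#'
#' @param covariance p x p symmetric positive-definite matrix.
#' @param n Nominal sample size.
#' @param means Optional mean vector (default zeros).
#' @return A `prom_moments` object.
#' @export
moments_from_cov <- function(covariance, n, means = NULL) {
  covariance <- as.matrix(covariance)
  stopifnot(isSymmetric(unname(covariance), tol = 1e-8))
  if (is.null(means)) means <- rep(0, ncol(covariance))
  structure(list(covariance = covariance,
                 correlation = stats::cov2cor(covariance),
                 means = means, n = n),
            class = "prom_moments")
}

#' @export
print.prom_moments <- function(x, ...) {
  cat(sprintf("<prom_moments> p = %d, N = %d\n", ncol(x$covariance), x$n))
  invisible(x)
}

#' Eigenvalues of the sample correlation matrix
#'
#' @param moments A `prom_moments` object.
#' @return Descending eigenvalues; they sum to the number of items.
#' @export
pa_eigenvalues <- function(moments) {
  sort(eigen(moments$correlation, symmetric = TRUE,
             only.values = TRUE)$values, decreasing = TRUE)
}

efa_df <- function(p, m) {
  as.integer(p * (p + 1) / 2 - (p * m + p - m * (m - 1) / 2))
}

# Concentrated ML discrepancy over uniquenesses (Lawley-Maxwell):
# given psi, the optimal loadings come from the eigen decomposition of
# psi^-1/2 R psi^-1/2 and the profiled discrepancy is the sum of
# (e_j - log e_j - 1) over the p - m smallest eigenvalues.
efa_objective <- function(psi, R, m) {
  sc <- 1 / sqrt(psi)
  e <- eigen(R * tcrossprod(sc), symmetric = TRUE, only.values = TRUE)$values
  e <- e[(m + 1):length(psi)]
  sum(e - log(e) - 1)
}

efa_loadings_from_psi <- function(psi, R, m) {
  sc <- 1 / sqrt(psi)
  E <- eigen(R * tcrossprod(sc), symmetric = TRUE)
  lam <- sqrt(pmax(E$values[1:m] - 1, 0))
  L <- sqrt(psi) * E$vectors[, 1:m, drop = FALSE] %*% diag(lam, m)
  # column signs: make each column's sum positive
  sg <- ifelse(colSums(L) < 0, -1, 1)
  L %*% diag(sg, m)
}

#' Maximum-likelihood exploratory factor analysis
#'
#' Canonical ML factor analysis of the correlation matrix: the
#' discrepancy is minimized over uniquenesses with loadings profiled out
#' analytically, exactly the classical concentrated-likelihood approach.
#' The reported discrepancy, chi-square and degrees of freedom are on the
#' same scale as the confirmatory engine, so a one-factor EFA reproduces
#' the one-factor CFA fit.
#'
#' @param moments A `prom_moments` object.
#' @param m Number of factors.
#' @param rotation Oblique rotation applied when `m >= 2`: `"geomin"`
#'   (default), `"oblimin"`, or `"none"`.
#' @param chisq_n `"N-1"` (default, Wishart convention) or `"N"`: the
#'   multiplier turning the discrepancy into the chi-square.
#' @return A `prom_efa` object: `n_factors`, `unrotated_loadings`,
#'   `rotated_loadings`, `factor_correlations`, `eigenvalues`,
#'   `uniquenesses`, `discrepancy`, `chisq`, `df`, `p_value`,
#'   `heywood` flag, `n`.
#' @examples
#' x <- simulate_responses(n = 300, seed = 2)
#' fit <- ml_efa(sample_moments(x), m = 2)
#' fit$df   # 118 for 18 items and 2 factors
#' @export
ml_efa <- function(moments, m, rotation = c("geomin", "oblimin", "none"),
                   chisq_n = c("N-1", "N")) {
  rotation <- match.arg(rotation)
  chisq_n <- match.arg(chisq_n)
  R <- moments$correlation
  p <- ncol(R)
  stopifnot(m >= 1)
  df <- efa_df(p, m)
  if (df < 0) stop("too many factors: negative degrees of freedom")
  lower <- 0.005
  start <- pmax(1 - 0.5 * m / p, 0.2) * rep(1, p)  # generic uniqueness start
  opt <- stats::nlminb(start, efa_objective, R = R, m = m,
                       lower = lower, upper = 1,
                       control = list(iter.max = 500, eval.max = 1000,
                                      rel.tol = 1e-12))
  psi <- opt$par
  heywood <- any(psi <= lower + 1e-8)
  if (heywood)
    warning("Heywood case: uniqueness at lower bound for item(s) ",
            paste(colnames(R)[psi <= lower + 1e-8], collapse = ", "))
  L <- efa_loadings_from_psi(psi, R, m)
  dimnames(L) <- list(colnames(R), paste0("F", seq_len(m)))
  Fml <- efa_objective(psi, R, m)
  nmult <- if (chisq_n == "N-1") moments$n - 1 else moments$n
  chisq <- nmult * Fml
  res <- structure(list(
    n_factors = m,
    unrotated_loadings = L,
    rotated_loadings = L,
    factor_correlations = diag(m),
    eigenvalues = pa_eigenvalues(moments),
    uniquenesses = stats::setNames(psi, colnames(R)),
    discrepancy = Fml, chisq = chisq, df = df,
    p_value = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    heywood = heywood, n = moments$n, rotation = "none"),
    class = "prom_efa")
  if (m >= 2 && rotation != "none") res <- rotate(res, rotation)
  res
}

#' @export
print.prom_efa <- function(x, ...) {
  cat(sprintf("<prom_efa> m = %d, chisq(%d) = %.2f, rotation = %s\n",
              x$n_factors, x$df, x$chisq, x$rotation))
  invisible(x)
}

#' Horn's parallel analysis
#'
#' Compares the observed correlation eigenvalues with the per-rank
#' percentile of eigenvalues from null data of the same N x p shape.
#' Factors are retained from the top for as long as the observed
#' eigenvalue exceeds its reference (the sequential Horn rule). The null
#' is independent standard normal data (classical Horn) or column-wise
#' permutations of the observed data.
#'
#' @param data A `prom_responses` object or numeric matrix (complete
#'   cases).
#' @param n_replicates Number of null datasets (default 500).
#' @param percentile Reference percentile of the null eigenvalue
#'   distribution (default 0.95).
#' @param seed Integer seed for the null replicates.
#' @param method `"normal"` (classical Horn) or `"permute"`.
#' @return A `parallel_analysis` object: `observed_eigenvalues`,
#'   `reference_eigenvalues`, `suggested_factors`, `n_replicates`,
#'   `percentile`, `method`.
#' @export
parallel_analysis <- function(data, n_replicates = 500, percentile = 0.95,
                              seed = NULL, method = c("normal", "permute")) {
  method <- match.arg(method)
  stopifnot(n_replicates >= 100)
  m <- if (inherits(data, "prom_responses")) data$values else as.matrix(data)
  if (anyNA(m)) stop("parallel_analysis requires complete cases")
  n <- nrow(m); p <- ncol(m)
  obs <- sort(eigen(stats::cor(m), symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  null_eigs <- with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      x <- if (method == "normal") matrix(stats::rnorm(n * p), n, p)
           else apply(m, 2, sample)
      sort(eigen(stats::cor(x), symmetric = TRUE,
                 only.values = TRUE)$values, decreasing = TRUE)
    }, numeric(p))
  })
  ref <- apply(null_eigs, 1, stats::quantile, probs = percentile,
               names = FALSE)
  suggested <- sum(cumprod(obs > ref))
  structure(list(observed_eigenvalues = obs, reference_eigenvalues = ref,
                 suggested_factors = as.integer(suggested),
                 n_replicates = n_replicates, percentile = percentile,
                 method = method),
            class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf("<parallel_analysis> %d replicates, %.0fth percentile: retain %d factor(s)\n",
              x$n_replicates, 100 * x$percentile, x$suggested_factors))
  invisible(x)
}
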