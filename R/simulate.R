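#' Bifactor latent population for ordinal response simulation
#'
#' Describes a standardized bifactor population: every item loads on one
#' general factor and on exactly one specific (group) factor, all factors
#' orthogonal with unit variance, residuals completing each item's latent
#' variance to 1. Continuous latent responses are discretized through
#' per-item thresholds into ordered category codes.
#'
#' @param general_loadings Numeric vector of general-factor loadings, one
#'   per item.
#' @param specific_loadings Numeric vector of specific-factor loadings,
#'   same length.
#' @param group Factor/character vector assigning each item to its
#'   specific factor.
#' @param thresholds List of strictly increasing numeric vectors, one per
#'   item; an item with K categories has K-1 cut points on the latent
#'   N(0,1) scale.
#' @param item_ids Optional item labels.
#' @return A `bifactor_population` object with fields `general_loadings`,
#'   `specific_loadings`, `group`, `residual_variances` (computed as
#'   `1 - lambda_g^2 - lambda_s^2`), `thresholds`, `item_ids`.
#' @export
bifactor_population <- function(general_loadings, specific_loadings, group,
                                thresholds, item_ids = NULL) {
  p <- length(general_loadings)
  stopifnot(length(specific_loadings) == p, length(group) == p,
            length(thresholds) == p)
  theta <- 1 - general_loadings^2 - specific_loadings^2
  if (any(theta <= 0))
    stop("loadings imply non-positive residual variance; ",
         "lambda_g^2 + lambda_s^2 must stay below 1")
  for (tau in thresholds) {
    if (length(tau) < 1 || any(diff(tau) <= 0))
      stop("thresholds must be strictly increasing with at least one cut")
  }
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(p))
  structure(list(general_loadings = general_loadings,
                 specific_loadings = specific_loadings,
                 group = as.character(group),
                 residual_variances = theta,
                 thresholds = thresholds,
                 item_ids = as.character(item_ids)),
            class = "bifactor_population")
}

#' @export
print.bifactor_population <- function(x, ...) {
  cat(sprintf("<bifactor_population> %d items, groups: %s\n",
              length(x$item_ids),
              paste(sprintf("%s(%d)", names(table(x$group)),
                            as.integer(table(x$group))), collapse = ", ")))
  invisible(x)
}

#' Equally spaced latent thresholds
#'
#' For an item with `k` ordered categories, returns the `k - 1` standard
#' normal quantiles at probabilities `1/k, ..., (k-1)/k`, giving uniform
#' expected category use when the latent response is N(0,1).
#'
#' @param k Number of categories.
#' @return Numeric vector of `k - 1` strictly increasing cut points.
#' @export
equal_thresholds <- function(k) {
  stopifnot(k >= 2)
  stats::qnorm(seq_len(k - 1) / k)
}

#' Default IKDC-shaped bifactor population
#'
#' The reference population used throughout the test battery: the 18
#' scored IKDC items partitioned into the four content groups --
#' symptoms (2, 3, 4, 6), activity (1, 5, 7, 8, 10b), ADLs (9a-9f) and
#' sport (9g-9i). General loadings vary by item between 0.40 and 0.75
#' (mean about 0.6) and specific loadings vary within group between 0.25
#' and 0.55, all on the standardized scale. The within-group variation
#' is deliberate: with loadings constant inside a group the bifactor
#' population collapses to an exactly equivalent correlated four-factor
#' model, and the structures the analysis is meant to distinguish become
#' indistinguishable. Thresholds are the equal-probability cuts for each
#' item's category count (2, 5 or 11), the symmetric preset;
#' `skewed = TRUE` shifts every cut by +0.8 latent SD to emulate the low
#' post-injury score profile of ACL-deficient respondents.
#'
#' @param skewed Use the post-injury (low-score) threshold preset.
#' @return A `bifactor_population` over the 18 scored items, in
#'   instrument order.
#' @export
default_population <- function(skewed = FALSE) {
  ik <- ikdc_instrument()
  ids <- scored_ids(ik)
  ncat <- ik$items$n_categories[match(ids, ik$items$item_id)]
  group <- character(length(ids))
  group[ids %in% c("2", "3", "4", "6")] <- "symptoms"
  group[ids %in% c("1", "5", "7", "8", "10b")] <- "activity"
  group[ids %in% paste0("9", letters[1:6])] <- "adls"
  group[ids %in% paste0("9", letters[7:9])] <- "sport"
  lambda_g <- c(`1` = 0.65, `2` = 0.70, `3` = 0.75, `4` = 0.55, `5` = 0.60,
                `6` = 0.40, `7` = 0.60, `8` = 0.65,
                `9a` = 0.55, `9b` = 0.60, `9c` = 0.50, `9d` = 0.65,
                `9e` = 0.45, `9f` = 0.55, `9g` = 0.70, `9h` = 0.75,
                `9i` = 0.70, `10b` = 0.60)
  lambda_s <- c(`2` = 0.45, `3` = 0.50, `4` = 0.35, `6` = 0.30,
                `1` = 0.40, `5` = 0.45, `7` = 0.50, `8` = 0.40, `10b` = 0.35,
                `9a` = 0.30, `9b` = 0.35, `9c` = 0.25, `9d` = 0.30,
                `9e` = 0.40, `9f` = 0.35,
                `9g` = 0.50, `9h` = 0.55, `9i` = 0.45)
  thr <- lapply(ncat, equal_thresholds)
  if (skewed) thr <- lapply(thr, function(tau) tau + 0.8)
  bifactor_population(general_loadings = unname(lambda_g[ids]),
                      specific_loadings = unname(lambda_s[ids]),
                      group = group, thresholds = thr, item_ids = ids)
}

#' Latent covariance implied by a population
#'
#' Returns `Lambda Phi Lambda' + Theta` for the continuous latent
#' responses (a correlation matrix for a standardized population).
#'
#' @param population A `bifactor_population`.
#' @return p x p implied covariance matrix.
#' @export
implied_latent_covariance <- function(population) {
  L <- population_loading_matrix(population)
  S <- tcrossprod(L) + diag(population$residual_variances)
  dimnames(S) <- list(population$item_ids, population$item_ids)
  S
}

population_loading_matrix <- function(population) {
  groups <- unique(population$group)
  p <- length(population$item_ids)
  L <- matrix(0, p, 1 + length(groups),
              dimnames = list(population$item_ids, c("general", groups)))
  L[, "general"] <- population$general_loadings
  for (g in groups)
    L[population$group == g, g] <- population$specific_loadings[population$group == g]
  L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

discretize <- function(ystar, thresholds) {
  p <- ncol(ystar)
  out <- matrix(0L, nrow(ystar), p)
  for (j in seq_len(p))
    out[, j] <- findInterval(ystar[, j], thresholds[[j]])
  out
}

#' Simulate ordinal respondents from a bifactor population
#'
#' Draws one standard normal general factor and one per specific group
#' (all independent, matching bifactor orthogonality), forms continuous
#' latent responses `y* = lambda_g eta_g + lambda_s eta_k + eps` with
#' residual variance `theta`, and discretizes each `y*` through its
#' item's thresholds. Draw order is fixed -- factor scores first, then
#' residuals, items in instrument order -- so a seed pins the matrix
#' exactly.
#'
#' @param population A `bifactor_population` (default
#'   [default_population()]).
#' @param n Number of respondents.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A `prom_responses` object over the population's items.
#' @examples
#' x <- simulate_responses(n = 50, seed = 1)
#' dim(x$values)
#' @export
simulate_responses <- function(population = default_population(), n,
                               seed = NULL) {
  L <- population_loading_matrix(population)
  simulate_latent(L, Phi = diag(ncol(L)),
                  theta = population$residual_variances,
                  thresholds = population$thresholds,
                  item_ids = population$item_ids, n = n, seed = seed)
}

#' Simulate respondents from an arbitrary factor model
#'
#' As [simulate_responses()], but for any confirmatory loading matrix and
#' factor covariance matrix `Phi` (correlated factors drawn through the
#' Cholesky factor of `Phi`). With `Phi` the identity this reduces to the
#' orthogonal bifactor draw and, under the same seed, reproduces
#' [simulate_responses()] exactly.
#'
#' @param loadings p x k loading matrix on the latent scale.
#' @param Phi k x k factor covariance matrix (positive definite).
#' @param theta Residual variances (length p).
#' @param thresholds List of p strictly increasing threshold vectors.
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @param item_ids Optional item labels.
#' @return A `prom_responses` object.
#' @export
simulate_from_model <- function(loadings, Phi = diag(ncol(loadings)), theta,
                                thresholds, n, seed = NULL, item_ids = NULL) {
  if (is.null(item_ids))
    item_ids <- rownames(loadings) %||% paste0("item", seq_len(nrow(loadings)))
  simulate_latent(loadings, Phi, theta, thresholds, item_ids, n, seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simulate_latent <- function(loadings, Phi, theta, thresholds, item_ids, n,
                            seed) {
  p <- nrow(loadings); k <- ncol(loadings)
  stopifnot(n >= 1, length(theta) == p, length(thresholds) == p,
            nrow(Phi) == k, ncol(Phi) == k)
  for (tau in thresholds)
    if (any(diff(tau) <= 0)) stop("thresholds must be strictly increasing")
  ch <- tryCatch(chol(Phi),
                 error = function(e) stop("Phi is not positive definite"))
  with_seed(seed, {
    eta <- matrix(stats::rnorm(n * k), n, k) %*% ch
    eps <- matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(theta), p)
    ystar <- eta %*% t(loadings) + eps
    codes <- discretize(ystar, thresholds)
    colnames(codes) <- item_ids
    ncat <- vapply(thresholds, length, 1L) + 1L
    inst <- new_instrument("simulated", data.frame(
      item_id = item_ids, description = item_ids,
      n_categories = as.integer(ncat), scored = TRUE,
      stringsAsFactors = FALSE))
    new_responses(codes, inst)
  })
}
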