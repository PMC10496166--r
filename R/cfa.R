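#' Declarative confirmatory factor model specification
#'
#' Describes a covariance-structure model by its item-to-factor loading
#' pattern: a named list of factors with their item sets, a factor
#' covariance structure, optional correlated residuals, and an optional
#' general factor loaded by every item (the bifactor layout, in which all
#' factors are orthogonal).
#'
#' @param factors Named list; each element is the character vector of
#'   item ids loading on that factor.
#' @param covariance `"free"` (factor correlations estimated),
#'   `"orthogonal"`, or a fixed k x k correlation matrix.
#' @param general Optional name for a general factor loaded by all items
#'   appearing in `factors`; forces orthogonality (bifactor
#'   identification).
#' @param correlated_residuals Optional list of length-2 character
#'   vectors naming item pairs whose residual covariance is freed.
#' @param name Optional model label.
#' @return A `factor_model_spec` object.
#' @examples
#' spec <- factor_model(list(painful = c("a", "b"), active = c("c", "d")))
#' model_df(spec, p = 4)
#' @export
factor_model <- function(factors, covariance = "free", general = NULL,
                         correlated_residuals = list(), name = NULL) {
  stopifnot(is.list(factors), length(factors) >= 1,
            !is.null(names(factors)), all(nzchar(names(factors))))
  items <- unique(unlist(factors))
  if (!is.null(general)) {
    if (general %in% names(factors))
      stop("general factor name clashes with a specific factor")
    if (!identical(covariance, "orthogonal") && !identical(covariance, "free"))
      stop("bifactor models use orthogonal factors")
    covariance <- "orthogonal"
    for (f in names(factors)) {
      dup <- intersect(factors[[f]], unlist(factors[setdiff(names(factors), f)]))
      if (length(dup))
        stop("bifactor items may load on at most one specific factor: ",
             paste(dup, collapse = ", "))
    }
  }
  for (pr in correlated_residuals)
    if (length(pr) != 2 || !all(pr %in% items))
      stop("correlated_residuals must be pairs of known item ids")
  structure(list(factors = factors, covariance = covariance,
                 general = general,
                 correlated_residuals = correlated_residuals,
                 items = items,
                 name = name %||% "model"),
            class = "factor_model_spec")
}

#' @export
print.factor_model_spec <- function(x, ...) {
  cat(sprintf("<factor_model_spec> %s: %d item(s), %d factor(s)%s%s\n",
              x$name, length(x$items), length(x$factors),
              if (!is.null(x$general)) " + general" else "",
              if (length(x$correlated_residuals))
                sprintf(", %d correlated residual(s)",
                        length(x$correlated_residuals)) else ""))
  invisible(x)
}

spec_factor_names <- function(spec) {
  c(if (!is.null(spec$general)) spec$general, names(spec$factors))
}

# Logical p x k pattern of free loadings, items in spec order.
spec_pattern <- function(spec) {
  items <- spec$items
  fns <- spec_factor_names(spec)
  P <- matrix(FALSE, length(items), length(fns),
              dimnames = list(items, fns))
  if (!is.null(spec$general)) P[, spec$general] <- TRUE
  for (f in names(spec$factors)) P[spec$factors[[f]], f] <- TRUE
  P
}

spec_phi_free <- function(spec) {
  k <- length(spec_factor_names(spec))
  if (identical(spec$covariance, "free") && k > 1) k * (k - 1) / 2 else 0
}

#' Model degrees of freedom
#'
#' Counts free parameters under the fixed-factor-variance identification
#' (all free loadings, residual variances, freed residual covariances,
#' and factor correlations when the covariance structure is free) and
#' subtracts from the `p(p+1)/2` distinct sample moments.
#'
#' @param spec A `factor_model_spec`.
#' @param p Number of observed items (default: the items in the spec).
#' @return Integer degrees of freedom.
#' @examples
#' model_df(ikdc_model("bifactor"))   # 117
#' @export
model_df <- function(spec, p = length(spec$items)) {
  n_load <- sum(spec_pattern(spec))
  n_free <- n_load + p + length(spec$correlated_residuals) + spec_phi_free(spec)
  df <- as.integer(p * (p + 1) / 2 - n_free)
  if (df < 0) stop("model is under-identified: negative degrees of freedom")
  df
}

#' Bundled IKDC model fixtures
#'
#' The four confirmatory structures examined for the IKDC: the intended
#' one-factor model; the two-factor model (symptoms: items 2, 4, 6,
#' 9a-9i; activity: items 1, 5, 7, 8, 10b); the four content factors
#' (symptoms 2, 3, 4, 6; activity 1, 5, 7, 8, 10b; ADLs 9a-9f; sport
#' 9g-9i) with free correlations; and the bifactor model adding a
#' general factor over the four orthogonal content factors. Item 10a
#' never appears. Degrees of freedom over the 18 scored items are 135,
#' 134, 129 and 117 respectively.
#'
#' @param which One of `"one_factor"`, `"two_factor"`, `"four_factor"`,
#'   `"bifactor"`.
#' @return A `factor_model_spec`.
#' @export
ikdc_model <- function(which = c("one_factor", "two_factor", "four_factor",
                                 "bifactor")) {
  which <- match.arg(which)
  ids <- scored_ids(ikdc_instrument())
  content <- list(
    symptoms = c("2", "3", "4", "6"),
    activity = c("1", "5", "7", "8", "10b"),
    adls = paste0("9", letters[1:6]),
    sport = paste0("9", letters[7:9]))
  switch(which,
    one_factor = factor_model(list(general = ids), name = "one_factor"),
    two_factor = factor_model(list(
      # item 3 (severity of pain) sits with the other pain items so the
      # two-factor structure covers all 18 scored items
      symptoms = c("2", "3", "4", "6", paste0("9", letters[1:9])),
      activity = c("1", "5", "7", "8", "10b")), name = "two_factor"),
    four_factor = factor_model(content, name = "four_factor"),
    bifactor = factor_model(content, general = "general", name = "bifactor"))
}

# ---- parameter vector layout -------------------------------------------
# theta = c(free loadings (column-major over pattern),
#           log residual variances (p),
#           residual covariances (one per freed pair),
#           phi parameters (row-normalized Cholesky, strictly lower
#           triangular, when covariance is free),
#           log factor variances (marker identification only))

cfa_layout <- function(spec, p, identification) {
  P <- spec_pattern(spec)
  k <- ncol(P)
  marker_idx <- NULL
  if (identification == "marker") {
    P_free <- P
    marker_idx <- integer(k)
    for (j in seq_len(k)) {
      marker_idx[j] <- which(P[, j])[1]
      P_free[marker_idx[j], j] <- FALSE
    }
  } else P_free <- P
  n_load <- sum(P_free)
  n_res <- length(spec$correlated_residuals)
  n_phi <- spec_phi_free(spec)
  n_fvar <- if (identification == "marker") k else 0
  list(P = P, P_free = P_free, marker_idx = marker_idx, k = k, p = p,
       n_load = n_load, n_res = n_res, n_phi = n_phi, n_fvar = n_fvar,
       idx_load = seq_len(n_load),
       idx_theta = n_load + seq_len(p),
       idx_res = n_load + p + seq_len(n_res),
       idx_phi = n_load + p + n_res + seq_len(n_phi),
       idx_fvar = n_load + p + n_res + n_phi + seq_len(n_fvar),
       n_par = n_load + p + n_res + n_phi + n_fvar)
}

# Correlation matrix from strictly-lower-triangular raw entries via
# row-normalized Cholesky rows: guarantees positive definiteness.
phi_from_x <- function(x, k) {
  W <- diag(k)
  W[lower.tri(W)] <- x
  W <- W / sqrt(rowSums(W^2))
  tcrossprod(W)
}

cfa_matrices <- function(par, layout, spec) {
  p <- layout$p; k <- layout$k
  L <- matrix(0, p, k, dimnames = dimnames(layout$P))
  L[layout$P_free] <- par[layout$idx_load]
  if (!is.null(layout$marker_idx))
    for (j in seq_len(k)) L[layout$marker_idx[j], j] <- 1
  Theta <- diag(exp(par[layout$idx_theta]), p)
  dimnames(Theta) <- list(rownames(L), rownames(L))
  for (i in seq_along(spec$correlated_residuals)) {
    pr <- spec$correlated_residuals[[i]]
    Theta[pr[1], pr[2]] <- Theta[pr[2], pr[1]] <- par[layout$idx_res[i]]
  }
  if (is.matrix(spec$covariance)) {
    Phi <- spec$covariance
  } else {
    Phi <- if (layout$n_phi > 0) phi_from_x(par[layout$idx_phi], k) else diag(k)
  }
  if (layout$n_fvar > 0) {
    d <- sqrt(exp(par[layout$idx_fvar]))
    Phi <- Phi * tcrossprod(d)
  }
  dimnames(Phi) <- list(colnames(L), colnames(L))
  list(L = L, Phi = Phi, Theta = Theta,
       Sigma = L %*% Phi %*% t(L) + Theta)
}

fml_value <- function(Sigma, S, logdetS) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  v <- logdet + tr - logdetS - ncol(S)
  if (!is.finite(v)) 1e10 else v
}

cfa_objective <- function(par, layout, spec, S, logdetS) {
  fml_value(cfa_matrices(par, layout, spec)$Sigma, S, logdetS)
}

cfa_gradient <- function(par, layout, spec, S, logdetS) {
  mats <- cfa_matrices(par, layout, spec)
  ch <- tryCatch(chol(mats$Sigma), error = function(e) NULL)
  if (is.null(ch)) return(rep(0, length(par)))
  Sinv <- chol2inv(ch)
  G <- Sinv %*% (mats$Sigma - S) %*% Sinv   # dF/dSigma
  g <- numeric(length(par))
  GLP <- 2 * G %*% mats$L %*% mats$Phi
  g[layout$idx_load] <- GLP[layout$P_free]
  g[layout$idx_theta] <- diag(G) * exp(par[layout$idx_theta])
  for (i in seq_along(spec$correlated_residuals)) {
    pr <- match(spec$correlated_residuals[[i]], rownames(mats$L))
    g[layout$idx_res[i]] <- 2 * G[pr[1], pr[2]]
  }
  # phi / factor-variance parameters: chain dF/dPhi through the map
  # numerically (few parameters, exact enough at h = 1e-6)
  phi_par_idx <- c(layout$idx_phi, layout$idx_fvar)
  if (length(phi_par_idx)) {
    M <- t(mats$L) %*% G %*% mats$L    # dF = sum(M * dPhi)
    h <- 1e-6
    for (j in phi_par_idx) {
      pp <- par; pp[j] <- pp[j] + h
      Php <- cfa_matrices(pp, layout, spec)$Phi
      pm <- par; pm[j] <- pm[j] - h
      Phm <- cfa_matrices(pm, layout, spec)$Phi
      g[j] <- sum(M * (Php - Phm)) / (2 * h)
    }
  }
  g
}

cfa_start <- function(layout, spec, S) {
  sds <- sqrt(diag(S))[rownames(layout$P)]
  par <- numeric(layout$n_par)
  lstart <- matrix(0.7 * sds, layout$p, layout$k,
                   dimnames = dimnames(layout$P))
  if (!is.null(spec$general)) {
    # split variance between general and specific columns
    lstart[, spec$general] <- 0.6 * sds
    lstart[, colnames(layout$P) != spec$general] <- 0.35 * sds
  }
  par[layout$idx_load] <- lstart[layout$P_free]
  par[layout$idx_theta] <- log(0.5 * diag(S)[rownames(layout$P)])
  if (layout$n_fvar > 0) par[layout$idx_fvar] <- 0
  par
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over the free parameters of the specified covariance structure, with
#' residual variances log-transformed to stay positive and free factor
#' correlations parameterized through a row-normalized Cholesky factor so
#' the factor covariance matrix stays a positive-definite correlation
#' matrix. Optimization is quasi-Newton (`nlminb`) with the analytic
#' gradient; convergence requires a gradient max-norm below `1e-6` (a
#' fit failing that is returned with `converged = FALSE`, never hidden).
#'
#' @param spec A `factor_model_spec`.
#' @param moments A `prom_moments` object whose covariance contains all
#'   of the spec's items.
#' @param identification `"variance"` (factor variances fixed to 1,
#'   default, giving a standardized factor metric) or `"marker"` (first
#'   loading per factor fixed to 1, factor variances free).
#' @param chisq_n `"N-1"` (Wishart convention, default) or `"N"`: the
#'   chi-square multiplier dialect.
#' @param start Optional full start vector (expert use).
#' @return A `fitted_model` object: `loadings`, `factor_covariances`,
#'   `residual_covariances` (matrix `Theta`), `implied_covariance`,
#'   `discrepancy`, `chisq`, `df`, `p_value`, `standardized_loadings`,
#'   `standardized_theta`, `converged`, `n_free_parameters`, `n`,
#'   `spec`, `gradient_norm`, `heywood`.
#' @examples
#' x <- simulate_responses(n = 400, seed = 3)
#' fit <- fit_ml(ikdc_model("bifactor"), sample_moments(x))
#' fit$df   # 117
#' @export
fit_ml <- function(spec, moments, identification = c("variance", "marker"),
                   chisq_n = c("N-1", "N"), start = NULL) {
  identification <- match.arg(identification)
  chisq_n <- match.arg(chisq_n)
  items <- spec$items
  missing_items <- setdiff(items, colnames(moments$covariance))
  if (length(missing_items))
    stop("moments lack item(s): ", paste(missing_items, collapse = ", "))
  S <- moments$covariance[items, items, drop = FALSE]
  p <- length(items)
  df <- model_df(spec, p)
  chS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite"))
  logdetS <- 2 * sum(log(diag(chS)))
  layout <- cfa_layout(spec, p, identification)
  if (is.null(start)) start <- cfa_start(layout, spec, S)
  opt <- stats::nlminb(start, cfa_objective, gradient = cfa_gradient,
                       layout = layout, spec = spec, S = S,
                       logdetS = logdetS,
                       control = list(iter.max = 1000, eval.max = 2000,
                                      rel.tol = 1e-14))
  # polish: a few extra gradient steps if needed
  par <- opt$par
  gn <- max(abs(cfa_gradient(par, layout, spec, S, logdetS)))
  if (gn >= 1e-6) {
    opt2 <- stats::optim(par, cfa_objective, cfa_gradient, layout = layout,
                         spec = spec, S = S, logdetS = logdetS,
                         method = "BFGS",
                         control = list(maxit = 500, reltol = 1e-15))
    if (opt2$value <= opt$objective) {
      par <- opt2$par
      gn <- max(abs(cfa_gradient(par, layout, spec, S, logdetS)))
    }
  }
  mats <- cfa_matrices(par, layout, spec)
  # sign convention: each factor's loading column sums positive
  sg <- ifelse(colSums(mats$L) < 0, -1, 1)
  if (any(sg < 0)) {
    D <- diag(sg, layout$k)
    mats$L <- mats$L %*% D
    mats$Phi <- D %*% mats$Phi %*% D
    dimnames(mats$L) <- dimnames(layout$P)
    dimnames(mats$Phi) <- list(colnames(layout$P), colnames(layout$P))
  }
  Fml <- fml_value(mats$Sigma, S, logdetS)
  converged <- gn < 1e-6
  if (!converged)
    warning(sprintf("fit_ml did not reach gradient tolerance (|g| = %.2e)", gn))
  sdSigma <- sqrt(diag(mats$Sigma))
  sdPhi <- sqrt(diag(mats$Phi))
  Lstd <- sweep(sweep(mats$L, 2, sdPhi, "*"), 1, sdSigma, "/")
  theta_std <- diag(mats$Theta) / diag(mats$Sigma)
  heywood <- any(diag(mats$Theta) < 1e-6 * diag(S)) || any(abs(Lstd) > 1)
  if (heywood)
    warning("Heywood case: near-zero residual variance or |standardized loading| > 1")
  nmult <- if (chisq_n == "N-1") moments$n - 1 else moments$n
  structure(list(
    loadings = mats$L,
    factor_covariances = mats$Phi,
    residual_covariances = mats$Theta,
    implied_covariance = mats$Sigma,
    discrepancy = Fml,
    chisq = nmult * Fml,
    df = df,
    p_value = if (df > 0) stats::pchisq(nmult * Fml, df, lower.tail = FALSE)
              else NA_real_,
    standardized_loadings = Lstd,
    standardized_theta = stats::setNames(theta_std, items),
    converged = converged,
    gradient_norm = gn,
    heywood = heywood,
    n_free_parameters = layout$n_par,
    n = moments$n,
    chisq_n = chisq_n,
    identification = identification,
    sample_covariance = S,
    spec = spec),
    class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s: chisq(%d) = %.2f, F_ML = %.5f, converged = %s\n",
              x$spec$name, x$df, x$chisq, x$discrepancy, x$converged))
  invisible(x)
}

#' Chi-square difference test for nested models
#'
#' @param nested The more restrictive `fitted_model` (larger df).
#' @param parent The less restrictive `fitted_model`, fit to the same
#'   moments.
#' @return A list with `delta_chisq`, `delta_df`, `p_value`.
#' @examples
#' \dontrun{
#' chisq_difference_test(fit_four, fit_bifactor)
#' }
#' @export
chisq_difference_test <- function(nested, parent) {
  if (nested$n != parent$n)
    stop("models were fit to different sample sizes")
  if (nested$df < parent$df)
    stop("first model must be nested in (more restrictive than) the second")
  d_chisq <- nested$chisq - parent$chisq
  d_df <- nested$df - parent$df
  p <- if (d_df > 0) stats::pchisq(d_chisq, d_df, lower.tail = FALSE) else 1
  list(delta_chisq = d_chisq, delta_df = d_df, p_value = p)
}

#' Adequacy criteria for factor solutions
#'
#' The conventional cut-offs: CFI and TLI above 0.9, RMSEA and SRMR below
#' 0.08, all standardized loadings above 0.3, and all factor correlations
#' below 0.85 (so that separate factors are distinct enough to keep).
#'
#' @param min_loading,max_factor_covariance,min_cfi_tli,max_rmsea_srmr
#'   Thresholds, all in (0, 1).
#' @return An `adequacy_criteria` object.
#' @export
adequacy_criteria <- function(min_loading = 0.3, max_factor_covariance = 0.85,
                              min_cfi_tli = 0.9, max_rmsea_srmr = 0.08) {
  vals <- c(min_loading, max_factor_covariance, min_cfi_tli, max_rmsea_srmr)
  stopifnot(all(vals > 0), all(vals < 1))
  structure(list(min_loading = min_loading,
                 max_factor_covariance = max_factor_covariance,
                 min_cfi_tli = min_cfi_tli,
                 max_rmsea_srmr = max_rmsea_srmr),
            class = "adequacy_criteria")
}

#' Check a fitted model against adequacy criteria
#'
#' @param model A `fitted_model`.
#' @param criteria An `adequacy_criteria` object.
#' @param indices Optional `fit_index_set` for the model (computed via
#'   [compute_indices()]); fit-index checks are skipped when absent.
#' @return A list with per-criterion booleans (`loadings_ok`,
#'   `covariances_ok`, and with indices `cfi_ok`, `tli_ok`, `rmsea_ok`,
#'   `srmr_ok`), offending item/factor labels, and an overall `adequate`
#'   verdict over the evaluated checks.
#' @export
check_adequacy <- function(model, criteria = adequacy_criteria(),
                           indices = NULL) {
  P <- spec_pattern(model$spec)
  lam <- model$standardized_loadings[P]
  lab <- outer(rownames(P), colnames(P), paste, sep = ":")[P]
  low <- lab[lam <= criteria$min_loading]
  Phi <- model$factor_covariances
  offd <- abs(Phi[upper.tri(Phi)])
  flab <- outer(rownames(Phi), colnames(Phi), paste, sep = ":")[upper.tri(Phi)]
  high <- flab[offd >= criteria$max_factor_covariance]
  out <- list(loadings_ok = length(low) == 0,
              low_loadings = low,
              covariances_ok = length(high) == 0,
              high_covariances = high)
  if (!is.null(indices)) {
    out$cfi_ok <- indices$cfi > criteria$min_cfi_tli
    out$tli_ok <- indices$tli > criteria$min_cfi_tli
    out$rmsea_ok <- indices$rmsea < criteria$max_rmsea_srmr
    out$srmr_ok <- indices$srmr < criteria$max_rmsea_srmr
  }
  out$adequate <- all(unlist(out[grepl("_ok$", names(out))]))
  out
}
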