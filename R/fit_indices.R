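#' Independence baseline model
#'
#' Fits the null model with a free variance per item and all covariances
#' fixed to zero, the reference point of the incremental fit indices.
#' Its ML solution is closed form: the implied covariance is `diag(S)`,
#' the discrepancy is `-log|R|` with `R` the sample correlation matrix,
#' and the degrees of freedom are `p(p-1)/2`.
#'
#' @param moments A `prom_moments` object.
#' @param items Optional subset/order of items.
#' @param chisq_n Chi-square multiplier dialect, as in [fit_ml()].
#' @return A list of class `baseline_model` with `chisq`, `df`,
#'   `discrepancy`, `implied_covariance`, `n`.
#' @export
baseline_model <- function(moments, items = NULL, chisq_n = c("N-1", "N")) {
  chisq_n <- match.arg(chisq_n)
  S <- moments$covariance
  if (!is.null(items)) S <- S[items, items, drop = FALSE]
  p <- ncol(S)
  R <- stats::cov2cor(S)
  Fb <- -determinant(R, logarithm = TRUE)$modulus[1]
  Fb <- max(Fb, 0)
  nmult <- if (chisq_n == "N-1") moments$n - 1 else moments$n
  structure(list(chisq = nmult * Fb, df = as.integer(p * (p - 1) / 2),
                 discrepancy = Fb, implied_covariance = diag(diag(S), p),
                 n = moments$n, chisq_n = chisq_n),
            class = "baseline_model")
}

rmsea_ci_bound <- function(chisq, df, n_mult, prob, tol = 1e-8) {
  # solve pchisq(chisq, df, ncp = lambda) == prob for lambda >= 0 by
  # bisection; lambda = 0 returned when even the central quantile sits
  # below the requested probability
  if (stats::pchisq(chisq, df) < prob) return(0)
  lo <- 0
  hi <- max(10 * chisq, df + 10)
  while (stats::pchisq(chisq, df, ncp = hi) > prob) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e8) break
  }
  while (hi - lo > tol * (1 + hi)) {
    mid <- (lo + hi) / 2
    if (stats::pchisq(chisq, df, ncp = mid) > prob) lo <- mid else hi <- mid
  }
  lam <- (lo + hi) / 2
  sqrt(lam / (df * n_mult))
}

#' Fit-index battery for a fitted model
#'
#' Computes the chi-square test, CFI, TLI, RMSEA with its 90% confidence
#' interval (noncentrality solved from the noncentral chi-square
#' distribution), and SRMR against the independence baseline:
#' \itemize{
#'   \item `CFI = 1 - max(chisq_m - df_m, 0) / max(chisq_b - df_b,
#'     chisq_m - df_m, 0)` (clamped to `[0, 1]` by construction);
#'   \item `TLI = ((chisq_b/df_b) - (chisq_m/df_m)) / ((chisq_b/df_b) - 1)`
#'     (not clamped; it can leave `[0, 1]`);
#'   \item `RMSEA = sqrt(max(chisq_m - df_m, 0) / (df_m * n))` with `n`
#'     the chi-square multiplier, CI limits from the noncentralities at
#'     which the observed chi-square is the 0.95 and 0.05 quantiles;
#'   \item `SRMR`: root mean square of residual moments standardized by
#'     the observed standard deviations, diagonal included by default
#'     (`srmr_diagonal = FALSE` gives the off-diagonal-only variant).
#' }
#'
#' @param model A `fitted_model`.
#' @param baseline A `baseline_model` on the same moments (computed from
#'   the model's own sample covariance when omitted).
#' @param ci_level RMSEA confidence level (default 0.90).
#' @param srmr_diagonal Include diagonal standardized residuals in SRMR.
#' @return A `fit_index_set`: `chisq`, `df`, `p_value`, `cfi`, `tli`,
#'   `rmsea`, `rmsea_ci90` (length-2), `srmr`, `baseline_chisq`,
#'   `baseline_df`, `n`. With `df = 0`, RMSEA and TLI are `NA`
#'   (undefined) and reported as such.
#' @export
compute_indices <- function(model, baseline = NULL, ci_level = 0.90,
                            srmr_diagonal = TRUE) {
  S <- model$sample_covariance
  if (is.null(baseline)) {
    bm <- moments_from_cov(S, model$n)
    baseline <- baseline_model(bm, chisq_n = model$chisq_n)
  }
  if (!identical(model$chisq_n, baseline$chisq_n))
    stop("model and baseline use different chi-square dialects")
  nmult <- if (model$chisq_n == "N-1") model$n - 1 else model$n
  cm <- model$chisq; dm <- model$df
  cb <- baseline$chisq; db <- baseline$df
  num <- max(cm - dm, 0)
  den <- max(cb - db, cm - dm, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  if (dm > 0) {
    tli <- ((cb / db) - (cm / dm)) / ((cb / db) - 1)
    rmsea <- sqrt(max(cm - dm, 0) / (dm * nmult))
    alpha <- (1 - ci_level) / 2
    ci <- c(rmsea_ci_bound(cm, dm, nmult, 1 - alpha),
            rmsea_ci_bound(cm, dm, nmult, alpha))
  } else {
    tli <- NA_real_
    rmsea <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  sds <- sqrt(diag(S))
  E <- (S - model$implied_covariance) / tcrossprod(sds)
  vals <- if (srmr_diagonal) E[upper.tri(E, diag = TRUE)]
          else E[upper.tri(E)]
  srmr <- sqrt(mean(vals^2))
  structure(list(chisq = cm, df = dm,
                 p_value = if (dm > 0)
                   stats::pchisq(cm, dm, lower.tail = FALSE) else NA_real_,
                 cfi = cfi, tli = tli, rmsea = rmsea, rmsea_ci90 = ci,
                 srmr = srmr, baseline_chisq = cb, baseline_df = db,
                 n = model$n),
            class = "fit_index_set")
}

#' @export
print.fit_index_set <- function(x, ...) {
  cat(sprintf(
    "chisq(%d) = %.2f, p %s; CFI = %.3f, TLI = %.3f, RMSEA = %.3f (%.3f-%.3f), SRMR = %.3f\n",
    x$df, x$chisq,
    if (is.na(x$p_value)) "= NA" else sprintf("= %.3g", x$p_value),
    x$cfi, x$tli, x$rmsea, x$rmsea_ci90[1], x$rmsea_ci90[2], x$srmr))
  invisible(x)
}
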