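# Univariate score-test modification indices: expected chi-square drop
# from freeing one fixed parameter (a residual covariance or a
# cross-loading) at the restricted ML solution.
#
# With F the ML discrepancy, n the chi-square multiplier, g_j = dF/dtheta_j
# and E the expected information E_jk = tr(Sigma^-1 dSigma_j Sigma^-1
# dSigma_k), the index for fixed parameter j given free set f is
#   MI_j = (n/2) g_j^2 / (E_jj - E_jf E_ff^-1 E_fj).

# dSigma/dtheta matrices for the free parameters of a fitted model
cfa_dsigma_free <- function(model) {
  spec <- model$spec
  L <- model$loadings
  Phi <- model$factor_covariances
  p <- nrow(L); k <- ncol(L)
  P <- spec_pattern(spec)
  out <- list()
  LP <- L %*% Phi
  # free loadings (variance identification assumed for the derivative
  # basis; the spanned tangent space is identification-invariant)
  for (j in seq_len(k)) for (i in seq_len(p)) if (P[i, j]) {
    D <- matrix(0, p, p)
    D[i, ] <- D[i, ] + LP[, j]
    D[, i] <- D[, i] + LP[, j]
    out[[length(out) + 1]] <- D
  }
  # residual variances
  for (i in seq_len(p)) {
    D <- matrix(0, p, p); D[i, i] <- 1
    out[[length(out) + 1]] <- D
  }
  # freed residual covariances
  for (pr in spec$correlated_residuals) {
    ij <- match(pr, rownames(L))
    D <- matrix(0, p, p)
    D[ij[1], ij[2]] <- D[ij[2], ij[1]] <- 1
    out[[length(out) + 1]] <- D
  }
  # free factor correlations
  if (identical(spec$covariance, "free") && k > 1) {
    for (b in seq_len(k - 1)) for (a in (b + 1):k) {
      Eab <- matrix(0, k, k); Eab[a, b] <- Eab[b, a] <- 1
      out[[length(out) + 1]] <- L %*% Eab %*% t(L)
    }
  }
  out
}

#' Modification indices for a fitted model
#'
#' Score-test estimates of the chi-square drop expected from freeing, one
#' at a time, each currently fixed residual covariance and each fixed
#' cross-loading, sorted descending. Candidates whose information is
#' numerically singular are skipped with a warning.
#'
#' @param model A converged `fitted_model`.
#' @param types Candidate kinds to scan: residual covariances and/or
#'   cross-loadings.
#' @return A data frame with columns `parameter`, `type`,
#'   `expected_chisq_drop`, sorted descending; zero rows for a saturated
#'   model.
#' @export
modification_indices <- function(model,
                                 types = c("residual", "loading")) {
  types <- match.arg(types, several.ok = TRUE)
  if (model$df == 0)
    return(data.frame(parameter = character(), type = character(),
                      expected_chisq_drop = numeric()))
  spec <- model$spec
  L <- model$loadings
  p <- nrow(L); k <- ncol(L)
  S <- model$sample_covariance
  Sigma <- model$implied_covariance
  Sinv <- solve(Sigma)
  G <- Sinv %*% (Sigma - S) %*% Sinv
  nmult <- if (model$chisq_n == "N-1") model$n - 1 else model$n
  Dfree <- cfa_dsigma_free(model)
  Afree <- lapply(Dfree, function(D) Sinv %*% D)
  q <- length(Afree)
  Eff <- matrix(0, q, q)
  for (a in seq_len(q)) for (b in a:q) {
    Eff[a, b] <- Eff[b, a] <- sum(Afree[[a]] * t(Afree[[b]]))
  }
  Eff_inv <- tryCatch(solve(Eff), error = function(e) NULL)
  if (is.null(Eff_inv)) {
    warning("free-parameter information is singular; using pseudo-inverse")
    sv <- svd(Eff)
    pos <- sv$d > max(sv$d) * 1e-10
    Eff_inv <- sv$v[, pos] %*% diag(1 / sv$d[pos]) %*% t(sv$u[, pos])
  }
  P <- spec_pattern(spec)
  LP <- L %*% model$factor_covariances
  cands <- list()
  if ("residual" %in% types) {
    freed <- vapply(spec$correlated_residuals,
                    function(pr) paste(sort(pr), collapse = "~~"), "")
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      key <- paste(sort(rownames(L)[c(i, j)]), collapse = "~~")
      if (key %in% freed) next
      D <- matrix(0, p, p)
      D[i, j] <- D[j, i] <- 1
      cands[[length(cands) + 1]] <-
        list(parameter = key, type = "residual", D = D)
    }
  }
  if ("loading" %in% types) {
    for (j in seq_len(k)) for (i in seq_len(p)) if (!P[i, j]) {
      D <- matrix(0, p, p)
      D[i, ] <- D[i, ] + LP[, j]
      D[, i] <- D[, i] + LP[, j]
      cands[[length(cands) + 1]] <-
        list(parameter = paste0(rownames(L)[i], "=~", colnames(L)[j]),
             type = "loading", D = D)
    }
  }
  rows <- lapply(cands, function(cd) {
    Aj <- Sinv %*% cd$D
    g <- sum(G * cd$D)
    Ejj <- sum(Aj * t(Aj))
    Ejf <- vapply(Afree, function(A) sum(Aj * t(A)), 0)
    denom <- Ejj - drop(Ejf %*% Eff_inv %*% Ejf)
    if (!is.finite(denom) || denom <= 1e-12) return(NULL)
    mi <- (nmult / 2) * g^2 / denom
    data.frame(parameter = cd$parameter, type = cd$type,
               expected_chisq_drop = max(mi, 0))
  })
  skipped <- sum(vapply(rows, is.null, TRUE))
  if (skipped > 0)
    warning(skipped, " candidate(s) skipped (singular information)")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(parameter = character(), type = character(),
                      expected_chisq_drop = numeric())
  out[order(-out$expected_chisq_drop), , drop = FALSE]
}
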