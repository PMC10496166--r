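# Independent oracles used across the suite. These deliberately share no
# code with the package internals: the discrepancy is written out with
# plain determinants, and the brute-force fitter drives optim() over a
# naive parameter vector.

# ML discrepancy, written directly from its definition
naive_fml <- function(Sigma, S) {
  as.numeric(log(det(Sigma)) + sum(diag(S %*% solve(Sigma))) -
               log(det(S)) - ncol(S))
}

# Brute-force bifactor ML fit: general loadings, one specific loading per
# item (grouped), log residual variances; orthogonal unit-variance
# factors. Numerical-gradient BFGS, nothing shared with fit_ml().
naive_fit_bifactor <- function(S, group) {
  p <- ncol(S)
  groups <- unique(group)
  obj <- function(par) {
    lg <- par[1:p]
    ls <- par[(p + 1):(2 * p)]
    th <- exp(par[(2 * p + 1):(3 * p)])
    L <- cbind(lg, vapply(groups, function(g) ifelse(group == g, ls, 0),
                          numeric(p)))
    Sigma <- L %*% t(L) + diag(th)
    v <- tryCatch(naive_fml(Sigma, S), error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  sds <- sqrt(diag(S))
  start <- c(0.6 * sds, 0.3 * sds, log(0.5 * diag(S)))
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  lg <- opt$par[1:p]
  ls <- opt$par[(p + 1):(2 * p)]
  th <- exp(opt$par[(2 * p + 1):(3 * p)])
  L <- cbind(general = lg,
             vapply(groups, function(g) ifelse(group == g, ls, 0),
                    numeric(p)))
  colnames(L) <- c("general", groups)
  Sigma <- L %*% t(L) + diag(th)
  sg <- c(sign(sum(lg)), vapply(groups,
                                function(g) sign(sum(ls[group == g])), 0))
  Lstd <- sweep(L %*% diag(sg, ncol(L)), 1, sqrt(diag(Sigma)), "/")
  colnames(Lstd) <- c("general", groups)
  list(fml = opt$value, loadings_std = Lstd, theta = th)
}

# Brute-force one/multi-factor confirmatory fit with free correlations,
# used for small zero-noise recovery problems.
naive_fit_pattern <- function(S, pattern, free_phi = TRUE) {
  p <- nrow(pattern); k <- ncol(pattern)
  nl <- sum(pattern)
  nphi <- if (free_phi && k > 1) k * (k - 1) / 2 else 0
  obj <- function(par) {
    L <- matrix(0, p, k)
    L[pattern] <- par[1:nl]
    th <- exp(par[(nl + 1):(nl + p)])
    Phi <- diag(k)
    if (nphi) {
      Phi[lower.tri(Phi)] <- tanh(par[(nl + p + 1):(nl + p + nphi)])
      Phi[upper.tri(Phi)] <- t(Phi)[upper.tri(Phi)]
    }
    Sigma <- L %*% Phi %*% t(L) + diag(th)
    v <- tryCatch(naive_fml(Sigma, S), error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  start <- c(rep(0.6, nl) * sqrt(diag(S))[row(pattern)[pattern]],
             log(0.5 * diag(S)), rep(0, nphi))
  opt <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt$value
}

# Noncentrality solver for the RMSEA interval, via uniroot (the package
# uses bisection on its own)
oracle_ncp <- function(chisq, df, prob) {
  if (stats::pchisq(chisq, df) < prob) return(0)
  f <- function(l) stats::pchisq(chisq, df, ncp = l) - prob
  stats::uniroot(f, c(0, max(10 * chisq, 100)), tol = 1e-10)$root
}

# align estimated loading columns/signs with a truth matrix (EFA
# rotation ambiguity): best column permutation and sign per column
align_loadings <- function(est, truth) {
  k <- ncol(truth)
  perms <- if (k == 1) list(1) else {
    if (k == 2) list(c(1, 2), c(2, 1)) else
      stop("alignment helper supports k <= 2")
  }
  best <- NULL
  for (pm in perms) {
    cand <- est[, pm, drop = FALSE]
    for (j in seq_len(k))
      if (sum(cand[, j] * truth[, j]) < 0) cand[, j] <- -cand[, j]
    err <- mean(abs(cand - truth))
    if (is.null(best) || err < best$err) best <- list(est = cand, err = err)
  }
  best
}
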