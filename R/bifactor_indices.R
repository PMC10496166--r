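# Reliability and dimensionality indices for orthogonal bifactor
# solutions, computed on the standardized loading metric. The core
# ingredients are the general loading vector lambda_g, the specific
# loading vector lambda_s with its item->group map, and the standardized
# residual variances theta.

bifactor_parts <- function(model) {
  UseMethod("bifactor_parts")
}

#' @export
bifactor_parts.fitted_model <- function(model) {
  spec <- model$spec
  if (is.null(spec$general))
    stop("bifactor indices require a model with a general factor ",
         "(orthogonal bifactor structure)")
  Phi <- model$factor_covariances
  off <- Phi; diag(off) <- 0
  if (any(abs(off) > 1e-8))
    stop("bifactor indices assume orthogonal factors")
  L <- model$standardized_loadings
  gname <- spec$general
  snames <- setdiff(colnames(L), gname)
  group <- rep(NA_character_, nrow(L))
  for (s in snames) group[L[, s] != 0 | rownames(L) %in% spec$factors[[s]]] <- s
  list(lambda_g = L[, gname],
       lambda_s = rowSums(L[, snames, drop = FALSE]),
       group = group,
       theta = model$standardized_theta,
       group_levels = snames)
}

#' @export
bifactor_parts.bifactor_population <- function(model) {
  list(lambda_g = stats::setNames(model$general_loadings, model$item_ids),
       lambda_s = stats::setNames(model$specific_loadings, model$item_ids),
       group = model$group,
       theta = stats::setNames(model$residual_variances, model$item_ids),
       group_levels = unique(model$group))
}

#' @export
bifactor_parts.list <- function(model) {
  stopifnot(all(c("lambda_g", "lambda_s", "group", "theta") %in% names(model)))
  model$group_levels <- model$group_levels %||% unique(model$group)
  model
}

#' Omega total for a bifactor solution
#'
#' Model-based reliability of the total score (general row) and of each
#' specific factor's subscale score: the squared loading sums over the
#' relevant items divided by those sums plus the residual variance.
#'
#' @param model A converged bifactor `fitted_model`, a
#'   `bifactor_population`, or a list with `lambda_g`, `lambda_s`,
#'   `group`, `theta` (standardized).
#' @return Named numeric vector: `general`, then one entry per specific
#'   factor.
#' @export
omega_total <- function(model) {
  pt <- bifactor_parts(model)
  gsum2 <- sum(pt$lambda_g)^2
  ssums2 <- vapply(pt$group_levels,
                   function(g) sum(pt$lambda_s[which(pt$group == g)])^2, 0)
  gen <- (gsum2 + sum(ssums2)) / (gsum2 + sum(ssums2) + sum(pt$theta))
  sub <- vapply(pt$group_levels, function(g) {
    i <- which(pt$group == g)
    num <- sum(pt$lambda_g[i])^2 + sum(pt$lambda_s[i])^2
    num / (num + sum(pt$theta[i]))
  }, 0)
  c(general = gen, sub)
}

#' Omega hierarchical for a bifactor solution
#'
#' Proportion of total-score variance due to the general factor alone
#' (general row), and for each specific factor the proportion of its
#' subscale variance due to that specific factor alone (omega-HS).
#' Denominators match [omega_total()], so `omega_h <= omega` always.
#'
#' @inheritParams omega_total
#' @return Named numeric vector: `general`, then one entry per specific
#'   factor.
#' @export
omega_hierarchical <- function(model) {
  pt <- bifactor_parts(model)
  gsum2 <- sum(pt$lambda_g)^2
  ssums2 <- vapply(pt$group_levels,
                   function(g) sum(pt$lambda_s[which(pt$group == g)])^2, 0)
  gen <- gsum2 / (gsum2 + sum(ssums2) + sum(pt$theta))
  sub <- vapply(pt$group_levels, function(g) {
    i <- which(pt$group == g)
    den <- sum(pt$lambda_g[i])^2 + sum(pt$lambda_s[i])^2 + sum(pt$theta[i])
    sum(pt$lambda_s[i])^2 / den
  }, 0)
  c(general = gen, sub)
}

#' Relative omega
#'
#' The ratio `omega_h / omega` per factor: the share of reliable
#' variance attributable to the factor itself.
#'
#' @param omega_h Named vector from [omega_hierarchical()], or a model
#'   accepted by [omega_total()] (in which case both ingredients are
#'   computed).
#' @param omega Named vector from [omega_total()]; ignored when
#'   `omega_h` is a model.
#' @return Named numeric vector; `NA` where `omega` is zero.
#' @examples
#' relative_omega(omega_h = c(general = 0.810), omega = c(general = 0.932))
#' @export
relative_omega <- function(omega_h, omega = NULL) {
  if (!is.numeric(omega_h)) {
    model <- omega_h
    omega_h <- omega_hierarchical(model)
    omega <- omega_total(model)
  }
  out <- ifelse(omega > 0, omega_h / omega, NA_real_)
  stats::setNames(out, names(omega_h))
}

#' Explained common variance
#'
#' Decomposes the common variance (sum of all squared loadings) into the
#' share explained by the general factor and by each specific factor;
#' the entries sum to one.
#'
#' @inheritParams omega_total
#' @return Named numeric vector: `general`, then one entry per specific
#'   factor.
#' @export
ecv <- function(model) {
  pt <- bifactor_parts(model)
  g2 <- sum(pt$lambda_g^2)
  s2 <- vapply(pt$group_levels,
               function(g) sum(pt$lambda_s[which(pt$group == g)]^2), 0)
  total <- g2 + sum(s2)
  if (total <= 0) stop("zero common variance: ECV undefined")
  c(general = g2 / total, s2 / total)
}

#' Percent uncontaminated correlations
#'
#' The fraction of item pairs whose covariance reflects only the general
#' factor, i.e. pairs of items from different specific groups. Purely
#' structural: it depends only on the group partition.
#'
#' @param spec A bifactor `factor_model_spec`, a `bifactor_population`,
#'   or an integer vector of group sizes.
#' @return A single proportion in `[0, 1]`.
#' @examples
#' puc(c(4, 5, 6, 3))   # 0.7777... for the IKDC partition
#' @export
puc <- function(spec) {
  sizes <- if (inherits(spec, "factor_model_spec")) {
    if (is.null(spec$general)) stop("puc needs a bifactor spec")
    lengths(spec$factors)
  } else if (inherits(spec, "bifactor_population")) {
    as.integer(table(spec$group))
  } else as.integer(spec)
  p <- sum(sizes)
  if (p < 2) stop("puc undefined for fewer than 2 items")
  total <- p * (p - 1) / 2
  within <- sum(sizes * (sizes - 1) / 2)
  (total - within) / total
}

#' Factor determinacy
#'
#' Validity of regression factor-score estimates: per factor, the square
#' root of the corresponding diagonal of `Phi L' Sigma^-1 L Phi` on the
#' standardized metric -- the correlation between the estimated factor
#' score and the factor itself.
#'
#' @param model A converged `fitted_model` (any factor structure), a
#'   `bifactor_population`, or a list with `lambda_g`, `lambda_s`,
#'   `group`, `theta`.
#' @return Named numeric vector of determinacies in `[0, 1]`.
#' @export
factor_determinacy <- function(model) {
  if (inherits(model, "fitted_model")) {
    L <- model$standardized_loadings
    Phi <- stats::cov2cor(model$factor_covariances)
    Theta_std <- model$residual_covariances /
      tcrossprod(sqrt(diag(model$implied_covariance)))
    Sigma <- L %*% Phi %*% t(L) + Theta_std
    gname <- if (!is.null(model$spec$general)) model$spec$general
  } else {
    pt <- bifactor_parts(model)
    L <- cbind(general = pt$lambda_g,
               vapply(pt$group_levels,
                      function(g) ifelse(pt$group == g, pt$lambda_s, 0),
                      numeric(length(pt$lambda_g))))
    colnames(L) <- c("general", pt$group_levels)
    Phi <- diag(ncol(L))
    Sigma <- tcrossprod(L) + diag(pt$theta, length(pt$theta))
  }
  Sinv <- tryCatch(solve(Sigma), error = function(e)
    stop("implied covariance is singular: factor determinacy undefined"))
  M <- Phi %*% t(L) %*% Sinv %*% L %*% Phi
  stats::setNames(sqrt(pmin(pmax(diag(M), 0), 1)), colnames(L))
}

#' Full bifactor index report
#'
#' Assembles omega, omega hierarchical, relative omega, factor
#' determinacy, ECV and PUC for an orthogonal bifactor solution into one
#' report, rows ordered general first then the specific factors in spec
#' order. An `essentially_unidimensional` flag -- an interpretive
#' heuristic, not a test -- is set when the general factor shows
#' `omega_h > 0.8` and determinacy above 0.9.
#'
#' @param model A converged bifactor `fitted_model` or a
#'   `bifactor_population`.
#' @return A `bifactor_report` list: `table` (data frame with columns
#'   `factor`, `omega`, `omega_h`, `omega_r`, `fd`, `ecv`), `puc`,
#'   `essentially_unidimensional`.
#' @export
bifactor_report <- function(model) {
  om <- omega_total(model)
  oh <- omega_hierarchical(model)
  orel <- relative_omega(oh, om)
  fd <- factor_determinacy(model)
  ev <- ecv(model)
  fac <- names(om)
  fd <- fd[match(c("general", fac[-1]), names(fd))]
  pu <- puc(if (inherits(model, "fitted_model")) model$spec else model)
  tab <- data.frame(factor = fac,
                    omega = unname(om), omega_h = unname(oh),
                    omega_r = unname(orel), fd = unname(fd),
                    ecv = unname(ev[fac]),
                    row.names = NULL)
  structure(list(table = tab, puc = pu,
                 essentially_unidimensional =
                   unname(oh["general"] > 0.8 & fd[1] > 0.9)),
            class = "bifactor_report")
}

#' @export
print.bifactor_report <- function(x, digits = 3, ...) {
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf("PUC = %.3f; essentially unidimensional (heuristic): %s\n",
              x$puc, x$essentially_unidimensional))
  invisible(x)
}
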