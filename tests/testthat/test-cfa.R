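test_that("model df matches analytic parameter counting for all fixtures", {
  expect_equal(model_df(ikdc_model("one_factor")), 135L)
  expect_equal(model_df(ikdc_model("two_factor")), 134L)
  expect_equal(model_df(ikdc_model("four_factor")), 129L)
  expect_equal(model_df(ikdc_model("bifactor")), 117L)
  # df always equals moments minus the optimizer's actual free-parameter
  # count (no drift between the spec counter and the engine)
  mom <- default_cohort_moments()
  for (m in c("one_factor", "two_factor", "four_factor", "bifactor")) {
    fit <- fit_ml(ikdc_model(m), mom)
    expect_equal(fit$df, 18 * 19 / 2 - fit$n_free_parameters)
  }
  tiny <- factor_model(list(f1 = c("a", "b"), f2 = c("c", "d"),
                            f3 = c("e", "f")))
  expect_error(model_df(tiny, p = 3), "under-identified")
})

test_that("a just-identified three-item model fits perfectly", {
  S <- matrix(c(1, .4, .3, .4, 1, .35, .3, .35, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fit <- fit_ml(factor_model(list(f = c("a", "b", "c"))),
                moments_from_cov(S, 200))
  expect_equal(fit$df, 0L)
  expect_lt(fit$discrepancy, 1e-9)
  expect_true(is.na(fit$p_value))
})

test_that("fitting the true spec to its exact population covariance recovers it", {
  ids <- paste0("v", 1:8)
  L <- matrix(0, 8, 2, dimnames = list(ids, c("f1", "f2")))
  L[1:4, 1] <- c(0.7, 0.6, 0.5, 0.65)
  L[5:8, 2] <- c(0.55, 0.7, 0.6, 0.45)
  Phi <- matrix(c(1, 0.5, 0.5, 1), 2)
  Theta <- diag(1 - rowSums((L %*% Phi) * L))
  Sigma <- L %*% Phi %*% t(L) + Theta
  dimnames(Sigma) <- list(ids, ids)
  spec <- factor_model(list(f1 = ids[1:4], f2 = ids[5:8]))
  fit <- fit_ml(spec, moments_from_cov(Sigma, 500))
  expect_lt(fit$discrepancy, 1e-10)
  expect_lt(max(abs(fit$loadings[fit$loadings != 0] -
                      L[L != 0])), 1e-4)
  expect_equal(fit$factor_covariances[1, 2], 0.5, tolerance = 1e-4)
  expect_lt(max(abs(diag(fit$residual_covariances) - diag(Theta))), 1e-4)
})

test_that("refitting a model to its own implied covariance yields zero misfit", {
  mom <- default_cohort_moments()
  for (m in c("four_factor", "bifactor")) {
    fit <- fit_ml(ikdc_model(m), mom)
    refit <- fit_ml(ikdc_model(m),
                    moments_from_cov(fit$implied_covariance, mom$n))
    expect_lt(refit$discrepancy, 1e-10)
  }
})

test_that("the engine matches a brute-force optimizer on a bifactor cohort", {
  ids <- paste0("v", 1:9)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  L <- cbind(c(0.7, 0.6, 0.55, 0.65, 0.5, 0.6, 0.7, 0.45, 0.6),
             rep(0, 9), rep(0, 9), rep(0, 9))
  for (g in unique(grp))
    L[grp == g, 1 + match(g, unique(grp))] <-
      c(0.45, 0.3, 0.5)[match(g, unique(grp))]
  x <- simulate_from_model(L, diag(4), theta = 1 - rowSums(L^2),
                           thresholds = rep(list(equal_thresholds(5)), 9),
                           n = 1500, seed = 71, item_ids = ids)
  mom <- sample_moments(x)
  spec <- factor_model(split(ids, grp), general = "general")
  fit <- fit_ml(spec, mom)
  oracle <- naive_fit_bifactor(mom$covariance, grp)
  expect_lt(abs((mom$n - 1) * oracle$fml - fit$chisq), 0.1)
  est <- cbind(fit$standardized_loadings[ids, "general"],
               rowSums(fit$standardized_loadings[ids, c("g1", "g2", "g3")]))
  orc <- cbind(oracle$loadings_std[, "general"],
               rowSums(oracle$loadings_std[, -1]))
  expect_lt(max(abs(est - orc)), 0.01)
})

test_that("identification conventions give the same fit and standardization", {
  mom <- default_cohort_moments()
  for (m in c("one_factor", "four_factor")) {
    fv <- fit_ml(ikdc_model(m), mom, identification = "variance")
    fm <- fit_ml(ikdc_model(m), mom, identification = "marker")
    expect_lt(abs(fv$discrepancy - fm$discrepancy), 1e-8)
    expect_lt(max(abs(fv$standardized_loadings - fm$standardized_loadings)),
              1e-5)
    # standardized loading identity on the marker solution
    lam_std <- sweep(sweep(fm$loadings, 2,
                           sqrt(diag(fm$factor_covariances)), "*"),
                     1, sqrt(diag(fm$implied_covariance)), "/")
    expect_equal(lam_std, fm$standardized_loadings, tolerance = 1e-12)
  }
})

test_that("the chi-square dialect switch rescales the statistic", {
  mom <- default_cohort_moments()
  a <- fit_ml(ikdc_model("one_factor"), mom, chisq_n = "N-1")
  b <- fit_ml(ikdc_model("one_factor"), mom, chisq_n = "N")
  expect_equal(b$chisq / a$chisq, mom$n / (mom$n - 1), tolerance = 1e-10)
})

test_that("nested chi-square difference test behaves at its boundaries", {
  mom <- default_cohort_moments()
  f4 <- fit_ml(ikdc_model("four_factor"), mom)
  fb <- fit_ml(ikdc_model("bifactor"), mom)
  same <- chisq_difference_test(f4, f4)
  expect_equal(same$delta_chisq, 0)
  expect_equal(same$delta_df, 0L)
  expect_equal(same$p_value, 1)
  cmp <- chisq_difference_test(f4, fb)
  expect_equal(cmp$delta_df, 12L)
  expect_equal(cmp$delta_chisq, f4$chisq - fb$chisq, tolerance = 1e-8)
  expect_error(chisq_difference_test(fb, f4), "nested")
})

test_that("modification indices localize a planted residual correlation", {
  ids <- paste0("it", 1:8)
  set.seed(81)
  eta <- rnorm(3000)
  y <- outer(eta, rep(0.6, 8)) +
    matrix(rnorm(3000 * 8), 3000) %*% diag(sqrt(rep(0.64, 8)))
  shared <- rnorm(3000)
  y[, 3] <- y[, 3] + 0.5 * shared
  y[, 4] <- y[, 4] + 0.5 * shared
  colnames(y) <- ids
  fit <- fit_ml(factor_model(list(g = ids)), sample_moments(y))
  mi <- modification_indices(fit)
  expect_equal(mi$parameter[1], "it3~~it4")
  expect_true(all(mi$expected_chisq_drop >= 0))
  # freeing the flagged pair recoups roughly the predicted chi-square
  fit2 <- fit_ml(factor_model(list(g = ids),
                              correlated_residuals = list(c("it3", "it4"))),
                 sample_moments(y))
  drop_real <- fit$chisq - fit2$chisq
  expect_gt(drop_real, 0.5 * mi$expected_chisq_drop[1])

  sat <- fit_ml(factor_model(list(f = c("a", "b", "c"))),
                moments_from_cov(
                  matrix(c(1, .4, .3, .4, 1, .35, .3, .35, 1), 3,
                         dimnames = list(c("a", "b", "c"),
                                         c("a", "b", "c"))), 200))
  expect_equal(nrow(modification_indices(sat)), 0L)
})

test_that("Heywood cases and non-convergence are reported, never silent", {
  # one-factor structure inconsistent with the high a-b correlation: the
  # ML solution drives item a's residual variance to the zero boundary
  ids <- c("a", "b", "c", "d")
  R <- diag(4)
  dimnames(R) <- list(ids, ids)
  R["a", "b"] <- R["b", "a"] <- 0.85
  R["a", c("c", "d")] <- R[c("c", "d"), "a"] <- 0.45
  R["b", c("c", "d")] <- R[c("c", "d"), "b"] <- 0.15
  R["c", "d"] <- R["d", "c"] <- 0.3
  expect_warning(fit <- fit_ml(factor_model(list(g = ids)),
                               moments_from_cov(R, 300)),
                 "Heywood")
  expect_true(fit$heywood)
})

test_that("adequacy checks name the offending loadings and covariances", {
  ids <- paste0("v", 1:8)
  L <- matrix(0, 8, 2, dimnames = list(ids, c("f1", "f2")))
  L[1:4, 1] <- c(0.7, 0.7, 0.7, 0.2)    # one weak item
  L[5:8, 2] <- 0.7
  build <- function(phi) {
    Phi <- matrix(c(1, phi, phi, 1), 2)
    Sigma <- L %*% Phi %*% t(L) + diag(1 - rowSums((L %*% Phi) * L))
    dimnames(Sigma) <- list(ids, ids)
    fit_ml(factor_model(list(f1 = ids[1:4], f2 = ids[5:8])),
           moments_from_cov(Sigma, 400))
  }
  weak <- build(0.5)
  rep1 <- check_adequacy(weak)
  expect_false(rep1$loadings_ok)
  expect_true(any(grepl("^v4:", rep1$low_loadings)))
  expect_true(rep1$covariances_ok)

  tight <- build(0.9)
  rep2 <- check_adequacy(tight)
  expect_false(rep2$covariances_ok)
  expect_true(any(grepl("f1:f2", rep2$high_covariances)))

  strong <- L; strong[strong == 0.2] <- 0.7
  Sigma <- strong %*% t(strong) + diag(1 - rowSums(strong^2))
  dimnames(Sigma) <- list(ids, ids)
  fitg <- fit_ml(factor_model(list(f1 = ids[1:4], f2 = ids[5:8]),
                              covariance = "orthogonal"),
                 moments_from_cov(Sigma, 400))
  ixg <- compute_indices(fitg)
  rep3 <- check_adequacy(fitg, indices = ixg)
  expect_true(rep3$adequate)
})
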