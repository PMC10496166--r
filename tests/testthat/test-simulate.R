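test_that("default population matches the IKDC group structure", {
  pop <- default_population()
  sizes <- table(pop$group)
  expect_equal(sizes[["symptoms"]], 4L)
  expect_equal(sizes[["activity"]], 5L)
  expect_equal(sizes[["adls"]], 6L)
  expect_equal(sizes[["sport"]], 3L)
  expect_equal(length(pop$item_ids), 18L)
  expect_false("10a" %in% pop$item_ids)
  # standardization identity
  expect_lt(max(abs(pop$general_loadings^2 + pop$specific_loadings^2 +
                      pop$residual_variances - 1)), 1e-12)
  # implied correlation matrix positive definite
  ev <- eigen(implied_latent_covariance(pop), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("population construction rejects inadmissible inputs", {
  expect_error(bifactor_population(0.9, 0.6, "a", list(0)),
               "residual variance")
  expect_error(bifactor_population(0.5, 0.3, "a", list(c(0.5, 0.2))),
               "strictly increasing")
  expect_error(simulate_from_model(matrix(0.7, 4, 1),
                                   Phi = matrix(1, 1, 1),
                                   theta = rep(0.51, 4),
                                   thresholds = rep(list(c(1, 0)), 4),
                                   n = 10, seed = 1),
               "strictly increasing")
  expect_error(simulate_from_model(matrix(0.5, 4, 2),
                                   Phi = matrix(c(1, 2, 2, 1), 2),
                                   theta = rep(0.5, 4),
                                   thresholds = rep(list(0), 4),
                                   n = 10, seed = 1),
               "positive definite")
})

test_that("the implied latent covariance equals Lambda Phi Lambda' + Theta", {
  pop <- default_population()
  S <- implied_latent_covariance(pop)
  # rebuild by hand from the population fields
  p <- length(pop$item_ids)
  M <- diag(pop$residual_variances)
  for (i in 1:p) for (j in 1:p) if (i != j) {
    M[i, j] <- pop$general_loadings[i] * pop$general_loadings[j] +
      if (pop$group[i] == pop$group[j])
        pop$specific_loadings[i] * pop$specific_loadings[j] else 0
  }
  diag(M) <- pop$general_loadings^2 + pop$specific_loadings^2 +
    pop$residual_variances
  expect_equal(unname(S), M, tolerance = 1e-12)
})

test_that("simulation is deterministic under a seed and leaves the RNG alone", {
  a <- simulate_responses(n = 120, seed = 9)
  b <- simulate_responses(n = 120, seed = 9)
  expect_identical(a$values, b$values)
  set.seed(500); before <- rnorm(1)
  set.seed(500); invisible(simulate_responses(n = 10, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("zero loadings give independent items", {
  pop <- default_population()
  null_pop <- bifactor_population(rep(0, 18), rep(0, 18), pop$group,
                                  pop$thresholds, pop$item_ids)
  x <- simulate_responses(null_pop, n = 20000, seed = 13)
  r <- cor(x$values)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("category frequencies follow the threshold-interval probabilities", {
  x <- simulate_responses(n = 50000, seed = 21)
  pop <- default_population()
  pvals <- vapply(seq_along(pop$item_ids), function(j) {
    tau <- pop$thresholds[[j]]
    probs <- diff(c(0, pnorm(tau), 1))   # y* is standard normal
    obs <- tabulate(x$values[, j] + 1L, nbins = length(probs))
    suppressWarnings(chisq.test(obs, p = probs)$p.value)
  }, 0)
  expect_gt(min(pvals), 0.001)
})

test_that("observed correlations match a brute-force Monte-Carlo oracle", {
  # oracle: independent re-simulation written inline, N = 200000
  pop <- default_population()
  L <- cbind(pop$general_loadings,
             vapply(unique(pop$group),
                    function(g) ifelse(pop$group == g,
                                       pop$specific_loadings, 0),
                    numeric(18)))
  set.seed(4242)
  n_big <- 200000
  eta <- matrix(rnorm(n_big * ncol(L)), n_big)
  y <- eta %*% t(L) + matrix(rnorm(n_big * 18), n_big) %*%
    diag(sqrt(pop$residual_variances))
  d <- vapply(1:18, function(j) findInterval(y[, j], pop$thresholds[[j]]),
              numeric(n_big))
  r_oracle <- cor(d)
  rm(eta, y, d)

  x <- simulate_responses(pop, n = 5000, seed = 33)
  r_obs <- cor(x$values)
  expect_lt(max(abs(r_obs - r_oracle)), 0.05)
  # and the attenuation is real: observed ordinal correlations sit below
  # the latent ones on average
  r_latent <- implied_latent_covariance(pop)
  expect_lt(mean(r_obs[upper.tri(r_obs)]),
            mean(r_latent[upper.tri(r_latent)]))
})

test_that("one-factor closed form gives the pre-discretization correlations", {
  L <- matrix(0.7, 12, 1)
  theta <- rep(1 - 0.49, 12)
  S <- L %*% t(L) + diag(theta)
  off <- S[upper.tri(S)]
  expect_true(all(abs(off - 0.49) < 1e-12))
})

test_that("correlated four-factor draws weaken between-group correlations", {
  L <- matrix(0, 16, 4)
  for (g in 1:4) L[(4 * g - 3):(4 * g), g] <- 0.7
  Phi <- matrix(0.5, 4, 4); diag(Phi) <- 1
  x <- simulate_from_model(L, Phi, theta = 1 - rowSums(L^2),
                           thresholds = rep(list(equal_thresholds(5)), 16),
                           n = 20000, seed = 17)
  r <- cor(x$values)
  grp <- rep(1:4, each = 4)
  within <- r[outer(grp, grp, "==") & upper.tri(r)]
  between <- r[outer(grp, grp, "!=") & upper.tri(r)]
  expect_gt(mean(within), mean(between))
  expect_gt(mean(between), 0.1)   # correlations do propagate across groups
})

test_that("identity factor covariance reproduces the bifactor draw", {
  pop <- default_population()
  L <- cbind(pop$general_loadings,
             vapply(unique(pop$group),
                    function(g) ifelse(pop$group == g,
                                       pop$specific_loadings, 0),
                    numeric(18)))
  colnames(L) <- c("general", unique(pop$group))
  rownames(L) <- pop$item_ids
  a <- simulate_responses(pop, n = 200, seed = 3)
  b <- simulate_from_model(L, diag(5), pop$residual_variances,
                           pop$thresholds, n = 200, seed = 3,
                           item_ids = pop$item_ids)
  expect_identical(a$values, b$values)
})
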