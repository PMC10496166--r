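# Shared fixtures built in code at test time.

ik <- promstruct::ikdc_instrument()

# a small fully specified response block: 3 respondents, all items
toy_full_matrix <- function() {
  m <- matrix(0L, 3, 19)
  colnames(m) <- ik$items$item_id
  m
}

# write a response CSV and return its path
write_toy_csv <- function(m, file = tempfile(fileext = ".csv")) {
  utils::write.csv(as.data.frame(m), file, row.names = FALSE, na = "")
  file
}

# moments of a modest default-population cohort, reused across files
default_cohort_moments <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      x <- promstruct::simulate_responses(n = 800, seed = 101)
      cache <<- promstruct::sample_moments(x)
    }
    cache
  }
})

# two clean orthogonal 9+9 factors, 5-category items
two_factor_cohort <- function(n, seed, lambda = 0.7, phi = 0) {
  L <- matrix(0, 18, 2)
  L[1:9, 1] <- lambda
  L[10:18, 2] <- lambda
  theta <- 1 - rowSums(L^2)
  promstruct::simulate_from_model(
    L, Phi = matrix(c(1, phi, phi, 1), 2), theta = theta,
    thresholds = rep(list(promstruct::equal_thresholds(5)), 18),
    n = n, seed = seed)
}

# pure-noise matrix for null calibration
with_null_noise <- function(seed, n = 1000, p = 18) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * p), n, p)
  colnames(m) <- paste0("v", seq_len(p))
  m
}

# six-item worked bifactor fixture: lambda_g 0.6, lambda_s 0.4,
# theta 0.48, two groups of three
six_item_fixture <- function() {
  list(lambda_g = rep(0.6, 6), lambda_s = rep(0.4, 6),
       group = rep(c("g1", "g2"), each = 3), theta = rep(0.48, 6))
}
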