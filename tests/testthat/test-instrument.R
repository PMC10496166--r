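test_that("built-in IKDC instrument matches its published layout", {
  expect_equal(nrow(ik$items), 19L)
  expect_equal(sum(ik$items$scored), 18L)
  expect_false(ik$items$scored[ik$items$item_id == "10a"])
  expect_equal(ik$items$n_categories[ik$items$item_id == "6"], 2L)
  it10b <- ik$items[ik$items$item_id == "10b", ]
  expect_equal(it10b$n_categories, 11L)
  expect_true(it10b$scored)
  expect_equal(ik$items$n_categories[1:8], c(5L, 11L, 11L, 5L, 5L, 2L, 5L, 5L))
  expect_equal(ik$items$n_categories[9:17], rep(5L, 9L))
  expect_equal(ik$min_raw, 0L)
  expect_equal(ik$max_raw, 87L)
})

test_that("CSV reading validates codes and flags missing cells", {
  m <- toy_full_matrix()
  x <- read_responses(write_toy_csv(m), ik)
  expect_equal(x$n, 3L)
  expect_false(anyNA(x$values))
  expect_true(all(x$values == 0L))

  m2 <- m
  m2[2, "9c"] <- NA
  x2 <- read_responses(write_toy_csv(m2), ik)
  expect_equal(sum(is.na(x2$values)), 1L)
  expect_true(is.na(x2$values[2, "9c"]))

  m3 <- m
  m3[1, "6"] <- 5L   # item 6 is dichotomous
  expect_error(read_responses(write_toy_csv(m3), ik), "out-of-range.*\"6\"")

  m4 <- cbind(m, bogus = 0L)
  expect_error(read_responses(write_toy_csv(m4), ik), "unknown item")
})

test_that("one-based CSV coding is shifted to the internal zero base", {
  m <- toy_full_matrix() + 1L
  m[, "6"] <- c(1L, 2L, 1L)
  x <- read_responses(write_toy_csv(m), ik, coding = "one")
  expect_equal(unname(x$values[, "6"]), c(0L, 1L, 0L))
  expect_true(all(x$values[, "1"] == 0L))
})

test_that("read/write round-trips codes bit-identically", {
  x <- simulate_responses(n = 40, seed = 77)
  inst <- new_instrument("sim", data.frame(
    item_id = colnames(x$values), description = colnames(x$values),
    n_categories = ik$items$n_categories[match(colnames(x$values),
                                               ik$items$item_id)],
    scored = TRUE))
  f <- tempfile(fileext = ".csv")
  write_responses(x, f)
  y <- read_responses(f, inst)
  expect_identical(unname(y$values), unname(x$values))
})

test_that("complete-case filter counts and percentages are exact", {
  m <- toy_full_matrix()[rep(1, 10), ]
  m[1, "2"] <- NA; m[2, "9a"] <- NA; m[3, "10b"] <- NA
  x <- new_responses(m, ik)
  cc <- complete_case_filter(x, ik)
  expect_equal(cc$summary$n_complete, 7L)
  expect_equal(cc$summary$pct_complete, 70)
  expect_equal(cc$responses$n, 7L)

  full <- new_responses(toy_full_matrix(), ik)
  cc2 <- complete_case_filter(full, ik)
  expect_identical(cc2$responses$values, full$values)
  expect_equal(cc2$summary$pct_complete, 100)

  # missing 10a alone must not drop a row
  m3 <- toy_full_matrix(); m3[1, "10a"] <- NA
  expect_equal(complete_case_filter(new_responses(m3, ik), ik)$summary$n_complete, 3L)

  allna <- toy_full_matrix(); allna[, "3"] <- NA
  expect_error(complete_case_filter(new_responses(allna, ik), ik),
               "no complete cases")
})

test_that("percent complete is the complement of the removal rate", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    m <- toy_full_matrix()[rep(1, n), ]
    drop <- sample(n, sample(0:(n - 1), 1))
    for (i in drop) m[i, sample(scored <- ik$items$item_id[ik$items$scored], 1)] <- NA
    cc <- complete_case_filter(new_responses(m, ik), ik)
    removed_pct <- 100 * (n - cc$summary$n_complete) / n
    expect_equal(cc$summary$pct_complete, 100 - removed_pct)
  }
})

test_that("total score anchors at 0 and 100 and matches hand arithmetic", {
  worst <- new_responses(toy_full_matrix(), ik)
  expect_equal(total_score(worst, ik), rep(0, 3))

  m <- toy_full_matrix()
  for (id in ik$items$item_id)
    m[, id] <- ik$items$n_categories[ik$items$item_id == id] - 1L
  best <- new_responses(m, ik)
  expect_equal(total_score(best, ik), rep(100, 3))

  # mid-range row checked by independent arithmetic: sum the codes,
  # divide by the 87-point raw range
  mid <- toy_full_matrix()[1, , drop = FALSE]
  codes <- c(`1` = 2L, `2` = 7L, `3` = 4L, `4` = 1L, `5` = 3L, `6` = 1L,
             `7` = 2L, `8` = 0L, `9a` = 4L, `9b` = 3L, `9c` = 2L,
             `9d` = 1L, `9e` = 4L, `9f` = 2L, `9g` = 3L, `9h` = 1L,
             `9i` = 2L, `10a` = 9L, `10b` = 6L)
  mid[1, names(codes)] <- codes
  raw <- sum(codes[names(codes) != "10a"])
  expect_equal(total_score(new_responses(mid, ik), ik),
               100 * raw / 87)
})

test_that("total score is monotone in every single item code", {
  set.seed(19)
  x <- simulate_responses(n = 25, seed = 55)
  base <- cbind(x$values, `10a` = 0L)
  s0 <- total_score(new_responses(base, ik), ik)
  for (trial in 1:40) {
    i <- sample(nrow(base), 1)
    id <- sample(ik$items$item_id[ik$items$scored], 1)
    top <- ik$items$n_categories[ik$items$item_id == id] - 1L
    if (base[i, id] >= top) next
    bumped <- base
    bumped[i, id] <- bumped[i, id] + 1L
    s1 <- total_score(new_responses(bumped, ik), ik)
    expect_gte(s1[i], s0[i])
    expect_equal(s1[-i], s0[-i])
  }
})

test_that("partial rows are NA by default and pro-rated only on request", {
  m <- toy_full_matrix()
  m[1, c("2", "3")] <- c(5L, 5L)
  m[2, "4"] <- NA                   # 17 of 18 answered
  m[3, c("4", "5", "6")] <- NA      # 15 of 18: below the pro-rating floor
  x <- new_responses(m, ik)
  s <- total_score(x, ik)
  expect_true(is.na(s[2]) && is.na(s[3]))
  sp <- total_score(x, ik, allow_partial = TRUE)
  # row 2: all answered codes are 0, so the imputed item is 0 as well
  expect_equal(sp[2], 0)
  expect_true(is.na(sp[3]))
  expect_equal(sp[1], s[1])
})

test_that("instrument serialization round-trips through YAML and JSON", {
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_instrument(ik, f)
    back <- read_instrument(f)
    expect_equal(back$items$item_id, ik$items$item_id)
    expect_equal(back$items$n_categories, ik$items$n_categories)
    expect_equal(back$items$scored, ik$items$scored)
    expect_equal(back$max_raw, ik$max_raw)
  }
})
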