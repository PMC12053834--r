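test_that("an extreme point is the only one flagged", {
  set.seed(42)
  x <- c(rnorm(12, 0, 0.05), 4)
  y <- c(rnorm(12, 0, 0.05), 4)
  rep <- flag_outliers(x, y)
  expect_identical(which(rep$flags), 13L)
  expect_equal(rep$method, "mcd")
  expect_lte(sum(rep$flags), ceiling(0.1 * 13))
})

test_that("contamination outside (0, 0.5) is rejected", {
  expect_error(flag_outliers(1:10, 1:10, contamination = 0), "contamination")
  expect_error(flag_outliers(1:10, 1:10, contamination = 0.5),
               "contamination")
})

test_that("clean bivariate Gaussian data is flagged at most once at n = 10", {
  set.seed(7)
  x <- rnorm(10); y <- rnorm(10)
  rep <- flag_outliers(x, y, contamination = 0.1)
  expect_lte(sum(rep$flags), 1L)
  # decision-level cross-check against a brute-force MCD over all size-h
  # subsets: applying the same cutoff-and-cap rule to the brute-force
  # distances must flag the same points
  Z <- cbind((x - mean(x)) / sd(x), (y - mean(y)) / sd(y))
  bf <- brute_mcd(Z)
  d2_bf <- stats::mahalanobis(Z, bf$center, bf$cov)
  flag_rule <- function(d2, contamination = 0.1) {
    flags <- rep(FALSE, length(d2))
    cand <- d2 > stats::qchisq(1 - contamination, 2)
    if (any(cand)) {
      keep <- order(d2, decreasing = TRUE)[
        seq_len(min(ceiling(contamination * length(d2)), sum(cand)))]
      flags[intersect(keep, which(cand))] <- TRUE
    }
    flags
  }
  expect_identical(rep$flags, flag_rule(d2_bf))
  # the most extreme point agrees between the two estimates
  expect_identical(which.max(rep$robust_distance), which.max(d2_bf))
})

test_that("outlier flagging is invariant to affine axis rescaling", {
  set.seed(3)
  x <- c(rnorm(11), 6)
  y <- c(rnorm(11), -5)
  a <- flag_outliers(x, y)
  b <- flag_outliers(100 * x - 3, -2 * y + 40)
  expect_identical(a$flags, b$flags)
})

test_that("small samples fall back to robust z-scores", {
  x <- c(1, 2, 3, 4, 50)
  y <- c(1, 1.1, 0.9, 1.2, 1.0)
  rep <- flag_outliers(x, y, contamination = 0.2)
  expect_equal(rep$method, "robust_z")
  expect_identical(which(rep$flags), 5L)
})

test_that("flagging reports but never mutates", {
  d <- generate_volcano(sim_config(n = 15, seed = 1, n_outliers = 1,
                                   outlier_shift = -10))
  before <- performance_values(d)
  rep <- flag_outliers(d$x, performance_values(d))
  expect_identical(performance_values(d), before)
  expect_length(rep$flags, 15)
})

test_that("operator augmentation emits the closed-form candidate count", {
  df <- data.frame(a = c(1, 2, 3, 4), b = c(2, 5, 1, 3),
                   c = c(0.5, 0.25, 1, 2))
  cands <- augment_features(df)
  # d + d(d-1)/2 + d(d-1) + 3d with d = 3
  expect_length(cands, 21L)
  exprs <- vapply(cands, function(f) f$expression, character(1))
  expect_true(all(c("a", "a * b", "a / b", "b / a", "(a)^2", "sqrt(a)",
                    "log(a)") %in% exprs))
  expect_false(any(duplicated(exprs)))
  for (d_n in 2:4) {
    dfp <- as.data.frame(matrix(runif(8 * d_n) + 0.1, ncol = d_n))
    expect_length(augment_features(dfp),
                  d_n + d_n * (d_n - 1) / 2 + d_n * (d_n - 1) + 3 * d_n)
  }
})

test_that("domain guards drop sqrt and log of non-positive descriptors", {
  df <- data.frame(a = c(1, -2, 3), b = c(2, 5, 1))
  cands <- augment_features(df)
  exprs <- vapply(cands, function(f) f$expression, character(1))
  expect_false("sqrt(a)" %in% exprs)
  expect_false("log(a)" %in% exprs)
  expect_true(all(c("sqrt(b)", "log(b)") %in% exprs))
  excl <- attr(cands, "excluded")
  expect_true("sqrt(a)" %in% excl$expression)
  expect_match(excl$reason[excl$expression == "log(a)"], "non-positive")
})

test_that("an empty operator set returns the originals unchanged", {
  df <- data.frame(a = 1:4, b = c(2, 1, 5, 3))
  cands <- augment_features(df, ops = character(0))
  expect_length(cands, 2L)
  expect_equal(vapply(cands, function(f) f$expression, character(1)),
               c("a", "b"))
  expect_equal(cands[[1]]$values, as.numeric(1:4))
})

test_that("near-zero denominators exclude the ratio with a reason", {
  df <- data.frame(a = c(1, 2, 3), b = c(1, 0, 2))
  cands <- augment_features(df, ops = "divide")
  exprs <- vapply(cands, function(f) f$expression, character(1))
  expect_false("a / b" %in% exprs)
  expect_true("b / a" %in% exprs)
  excl <- attr(cands, "excluded")
  expect_match(excl$reason[excl$expression == "a / b"], "zero")
})

test_that("depth 2 composes unary operators over binary results", {
  df <- data.frame(a = c(1, 4, 9, 16), b = c(1, 2, 3, 4))
  c2 <- augment_features(df, ops = c("divide", "sqrt"), depth = 2)
  exprs <- vapply(c2, function(f) f$expression, character(1))
  expect_true("sqrt((a / b))" %in% exprs)
  i <- which(exprs == "sqrt((a / b))")
  expect_equal(c2[[i]]$values, sqrt(df$a / df$b))
})

test_that("screening ranks the planted descriptor first", {
  hits <- 0L
  for (seed in 1:5) {
    d <- generate_descriptor_table(sim_config(
      n = 25, seed = seed, n_decoys = 2, x_range = c(1, 10),
      noise_sd = 0.4))
    res <- screen_descriptors(d, augment_features(d, ops = character(0)))
    if (res$ranking$expression[1] == attr(d, "planted")) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("identical value vectors tie-break by expression string", {
  d <- generate_volcano(sim_config(n = 20, seed = 9))
  v <- d$x
  cands <- list(
    structure(list(expression = "zz_copy", values = v),
              class = "feature_candidate"),
    structure(list(expression = "aa_copy", values = v),
              class = "feature_candidate"))
  res <- screen_descriptors(d, cands)
  expect_equal(res$ranking$r2[1], res$ranking$r2[2])
  expect_equal(res$ranking$expression, c("aa_copy", "zz_copy"))
})

test_that("the volcano block of a ranking is sorted nonincreasing in R2", {
  d <- generate_descriptor_table(sim_config(
    n = 25, seed = 33, n_decoys = 2, x_range = c(1, 10)))
  res <- screen_descriptors(d)
  volc <- res$ranking[res$ranking$is_volcano, ]
  if (nrow(volc) > 1) expect_true(all(diff(volc$r2) <= 1e-12))
  expect_true(all(which(res$ranking$is_volcano) <
                  min(c(which(!res$ranking$is_volcano), Inf))))
})

test_that("screening a single candidate equals a direct select_model call", {
  d <- generate_volcano(sim_config(n = 22, seed = 17))
  cand <- list(structure(list(expression = "x", values = d$x),
                         class = "feature_candidate"))
  res <- screen_descriptors(d, cand, min_segment = 5)
  direct <- suppressWarnings(
    select_model(d$x, performance_values(d), d$weight, min_segment = 5))
  expect_equal(res$ranking$r2, direct$fit$r2)
  expect_equal(res$ranking$bic, direct$fit$bic)
  expect_equal(res$ranking$chosen_b, direct$chosen_b)
  expect_equal(res$ranking$shape, direct$shape)
})

test_that("re-running a screen reproduces the ranking exactly", {
  d <- generate_descriptor_table(sim_config(
    n = 20, seed = 55, n_decoys = 1, x_range = c(1, 10)))
  r1 <- screen_descriptors(d)
  r2 <- screen_descriptors(d)
  expect_identical(r1$ranking, r2$ranking)
})
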