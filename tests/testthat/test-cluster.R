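test_that("composite features are the medium and top level values", {
  sch <- criterion_scheme()
  vss <- lapply(1:10, random_value_system, scheme = sch)
  comp <- build_composite(vss)
  expect_equal(dim(comp$features), c(10L, 16L))
  expect_equal(unname(comp$features[3, 1:8]), unname(vss[[3]]$values[, 3]))
  expect_equal(unname(comp$features[3, 9:16]), unname(vss[[3]]$values[, 5]))
  # retained components reach the variance target with the smallest prefix
  m <- comp$n_components
  expect_gte(sum(comp$explained[seq_len(m)]), 0.80 - 1e-12)
  if (m > 1L) expect_lt(sum(comp$explained[seq_len(m - 1L)]), 0.80)
  expect_equal(ncol(comp$scores), m)
  expect_error(build_composite(vss[1:2]), "at least 3")
})

test_that("zero-variance features are dropped with a warning", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 2)
  # two-criterion, two-level systems: features are v[,1] (all zero in the
  # medium slot = level 1) and the weights
  vss <- lapply(1:6, random_value_system, scheme = sch)
  expect_warning(comp <- build_composite(vss), "zero-variance")
  expect_true(length(comp$dropped) >= 1L)
})

test_that("consensus clustering recovers two separated blobs", {
  set.seed(17)
  x <- rbind(matrix(stats::rnorm(60, 0), ncol = 2),
             matrix(stats::rnorm(60, 8), ncol = 2))
  cm <- choose_k(x, k_range = 2:6, seed = 1)
  expect_equal(cm$k, 2L)
  truth <- rep(1:2, each = 30)
  expect_true(max(mean(cm$assignments == truth),
                  mean(cm$assignments == 3 - truth)) == 1)
  # deterministic given the seed
  cm2 <- choose_k(x, k_range = 2:6, seed = 1)
  expect_identical(cm$assignments, cm2$assignments)
  expect_identical(cm$votes, cm2$votes)
})

test_that("choose_k validates its range", {
  x <- matrix(stats::rnorm(20), ncol = 2)
  expect_error(choose_k(x, k_range = 1:3), "k_range")
  expect_error(choose_k(x[1:3, ], k_range = 2:3), "at least 4")
})

test_that("cluster profiles summarise member weights", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 3)
  v1 <- value_system(rbind(c(0, 20, 80), c(0, 10, 20)), sch)
  v2 <- value_system(rbind(c(0, 10, 20), c(0, 20, 80)), sch)
  prof <- cluster_weight_profiles(c(1L, 2L), list(v1, v2))
  expect_equal(prof$size, c(1L, 1L))
  expect_equal(prof$a, c(80, 20))
  expect_equal(prof$dominant, c("a+b", "b+a"))
})

test_that("membership GLM matches the glm oracle", {
  set.seed(31)
  n <- 120
  x <- stats::runif(n)
  f <- factor(sample(c("u", "v", "w"), n, TRUE))
  y <- as.integer(stats::runif(n) < stats::plogis(-0.5 + 1.2 * x))
  m <- fit_membership_glm(y + 1L, data.frame(x = x, f = f))
  oracle <- stats::glm(y ~ x + f, family = stats::binomial())
  expect_equal(m$table$or, unname(exp(stats::coef(oracle))), tolerance = 1e-9)
  expect_false(m$separation)
  expect_equal(m$target_cluster, 2L)
})

test_that("perfect separation is detected and flagged", {
  y <- rep(1:2, each = 20)
  sep <- data.frame(z = rep(c(0, 1), each = 20))
  m <- fit_membership_glm(y, sep)
  expect_true(m$separation)
  expect_true(any(!m$table$estimable))
  expect_error(fit_membership_glm(rep(1L, 10), data.frame(z = 1:10)),
               "two clusters")
})

test_that("two-proportion power behaves monotonically", {
  p <- power_two_proportions(0.30, 0.15, 95, 178)
  expect_gt(p, power_two_proportions(0.25, 0.15, 95, 178))
  expect_gt(power_two_proportions(0.30, 0.15, 200, 300), p)
  expect_lt(power_two_proportions(0.16, 0.15, 95, 178), 0.10)
})

test_that("min_detectable_or brackets the baseline and warns when hopeless", {
  or <- min_detectable_or(95, 178, 0.15)
  expect_lt(or[["or_low"]], 1)
  expect_gt(or[["or_high"]], 1)
  # the detected prevalences reach the stated power
  odds_inv <- function(o, p0) { o * p0 / (1 - p0) / (1 + o * p0 / (1 - p0)) }
  expect_equal(power_two_proportions(odds_inv(or[["or_high"]], 0.15), 0.15,
                                     95, 178), 0.80, tolerance = 1e-4)
  expect_warning(res <- min_detectable_or(8, 10, 0.15), "too small")
  expect_true(is.na(res[["or_low"]]))
})
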