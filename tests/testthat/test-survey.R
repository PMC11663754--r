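test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.345, 2), 2.35)
  expect_equal(round_half_up(46.5), 47)
  expect_equal(round(2.5), 2)   # base R differs; that is why the helper exists
})

test_that("identity hashing is normalised and deterministic", {
  a <- hash_identity("Ada Lovelace", "ada@example.org")
  b <- hash_identity("  ada  LOVELACE ", "ADA@example.org ")
  c <- hash_identity("Ada Lovelace", "other@example.org")
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_match(a, "^[0-9a-f]{32}$")
})

test_that("exclusion rules keep the first complete submission", {
  resp <- data.frame(
    respondent_hash = c("h1", "h1", "h2", "h2", "h3", "h4", "h5"),
    complete = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    straight_lined = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    mark = 1:7, stringsAsFactors = FALSE
  )
  out <- apply_exclusions(resp)
  r <- out$report
  expect_equal(r$received, 7L)
  expect_equal(r$complete, 5L)
  expect_equal(r$incomplete, 2L)
  expect_equal(r$duplicates, 1L)       # h1's second complete submission
  expect_equal(r$straight_lined, 1L)   # h3
  expect_equal(r$invalid, 2L)
  expect_equal(r$analysed, 3L)
  expect_setequal(out$analysed$respondent_hash, c("h1", "h2", "h5"))
  expect_equal(out$analysed$mark[out$analysed$respondent_hash == "h1"], 1L)
  # arithmetic identities
  expect_equal(r$received, r$analysed + r$incomplete + r$duplicates +
                 r$straight_lined)
  expect_equal(r$analysed, r$complete - r$invalid)
})

test_that("exclusion report validates and rounds half-up", {
  r <- exclusion_report(received = 200, complete = 101, duplicates = 0,
                        straight_lined = 0)
  expect_equal(r$pct_complete, 51)     # 50.5 rounds up
  expect_error(exclusion_report(10, 11), "received >= complete")
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test", {
  set.seed(12)
  for (i in 1:25) {
    t <- matrix(rpois(4, 6), 2)
    if (any(rowSums(t) == 0) || any(colSums(t) == 0)) next
    expect_equal(fisher_exact_2x2(t), stats::fisher.test(t)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 2), 2)), "zero margin")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 2), 2)), "integers")
})

test_that("adjusted mean differences equal the lm oracle", {
  set.seed(14)
  n <- 80
  cov <- data.frame(g = factor(sample(c("x", "y"), n, TRUE)),
                    z = stats::rnorm(n))
  W <- cbind(a = stats::rnorm(n, 50, 5), b = stats::rnorm(n, 50, 5))
  res <- adjusted_mean_differences(W, cov)
  for (cr in c("a", "b")) {
    fit <- stats::lm(W[, cr] ~ g + z, data = cov)
    co <- summary(fit)$coefficients
    tab <- res$table[res$table$criterion == cr, ]
    expect_equal(tab$amd, unname(co[-1, "Estimate"]), tolerance = 1e-9)
    expect_equal(tab$ci_low,
                 unname(co[-1, "Estimate"] - 1.96 * co[-1, "Std. Error"]),
                 tolerance = 1e-9)
  }
  expect_length(res$aliased, 0L)
})

test_that("aliased covariates are dropped and reported", {
  set.seed(15)
  n <- 60
  cov <- data.frame(z = stats::rnorm(n))
  cov$z2 <- 2 * cov$z                      # perfectly collinear
  W <- cbind(a = stats::rnorm(n, 50, 5))
  res <- adjusted_mean_differences(W, cov)
  expect_identical(res$aliased$a, "z2")
  expect_error(adjusted_mean_differences(W[1:2, , drop = FALSE], cov[1:2, ]),
               "more model terms")
})

test_that("the GEE reduces to plain logistic regression for singleton clusters", {
  set.seed(16)
  n <- 150
  x <- stats::rnorm(n)
  g <- factor(sample(c("p", "q"), n, TRUE))
  y <- as.integer(stats::runif(n) < stats::plogis(-0.3 + 0.8 * x))
  fit <- completion_bias_gee(y, data.frame(x = x, g = g), id = seq_len(n))
  oracle <- stats::glm(y ~ x + g, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(oracle)),
               tolerance = 1e-6)
  expect_equal(fit$alpha, 0)
  expect_true(fit$converged)
})

test_that("the GEE estimates a positive working correlation when present", {
  set.seed(18)
  G <- 150
  id <- rep(seq_len(G), each = 4)
  b <- stats::rnorm(G, 0, 1.5)[id]
  x <- stats::rnorm(4 * G)
  y <- as.integer(stats::runif(4 * G) < stats::plogis(-0.2 + b))
  fit <- completion_bias_gee(y, data.frame(x = x), id = id)
  expect_gt(fit$alpha, 0.05)
  expect_true(fit$converged)
  expect_true(all(c("(Intercept)", "x") %in% fit$table$term))
})
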