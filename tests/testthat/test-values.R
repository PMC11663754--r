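test_that("value_system enforces its invariants", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 3)
  good <- rbind(c(0, 20, 60), c(0, 10, 40))
  expect_s3_class(value_system(good, sch), "value_system")
  expect_error(value_system(rbind(c(0, 20, 60), c(5, 10, 40)), sch), "worth 0")
  expect_error(value_system(rbind(c(0, 70, 60), c(0, 10, 40)), sch),
               "non-decreasing")
  expect_error(value_system(rbind(c(0, 20, 61), c(0, 10, 40)), sch), "sum to 100")
  expect_error(value_system(good[, 1:2], sch), "criteria x levels")
})

test_that("solved values reproduce a truthful session's relation", {
  sch <- criterion_scheme(c("a", "b", "c"), n_levels = 3)
  for (seed in 1:5) {
    truth <- random_value_system(sch, seed)
    s <- simulate_session(truth, epsilon = 0)
    vs <- solve_values(s)
    expect_equal(sum(vs$weights), 100, tolerance = 1e-9)
    expect_gt(vs$gap, 0)
    got <- comparison_signs(s, vs$values)
    want <- comparison_signs(s, truth$values)
    expect_identical(got, want)
  }
})

test_that("solve_values refuses an incomplete session", {
  s <- paprika_session(criterion_scheme(c("a", "b"), n_levels = 3))
  next_question(s)
  record_answer(s, "first")
  expect_error(solve_values(s), "not complete")
})

test_that("indifference answers solve to exactly equal increments", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 2)
  s <- paprika_session(sch, allow_indifference = TRUE)
  next_question(s)
  record_answer(s, "indifferent")
  next_question(s)
  vs <- solve_values(s)
  expect_equal(unname(vs$weights), c(50, 50), tolerance = 1e-9)
})

test_that("inconsistent answers still solve, with a negative gap", {
  sch <- criterion_scheme(c("a", "b", "c"), n_levels = 3)
  truth <- random_value_system(sch, 42)
  found <- FALSE
  for (seed in 1:20) {
    set.seed(seed)
    s <- simulate_session(truth, epsilon = 0.35)
    vs <- solve_values(s)
    expect_equal(sum(vs$weights), 100, tolerance = 1e-9)
    expect_true(all(diff(t(vs$values)) >= -1e-9))
    if (vs$gap < 0) found <- TRUE
  }
  # heavy noise must produce at least one additively inconsistent session
  expect_true(found)
})

test_that("rank_alternatives totals and tie annotation are exact", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 2)
  vs <- value_system(rbind(c(0, 60), c(0, 40)), sch)
  sm <- score_matrix(matrix(c(2L, 1L, 2L,
                              1L, 2L, 2L), ncol = 2,
                            dimnames = list(c("p1", "p2", "p3"), sch$criteria)),
                     region = "R1", scheme = sch)
  pl <- rank_alternatives(vs, sm)
  expect_equal(pl$pathogen, c("p3", "p1", "p2"))
  expect_equal(pl$total_weight, c(100, 60, 40))
  expect_equal(pl$rank, c(1L, 2L, 3L))
  expect_false(any(pl$tied))
  # equal weights tie p1/p2 at rank 2
  vs2 <- value_system(rbind(c(0, 50), c(0, 50)), sch)
  pl2 <- rank_alternatives(vs2, sm)
  expect_equal(pl2$rank, c(1L, 2L, 2L))
  expect_equal(pl2$tied, c(FALSE, TRUE, TRUE))
})

test_that("value systems roundtrip through CSV and JSON", {
  sch <- criterion_scheme()
  vs <- random_value_system(sch, 3)
  for (ext in c("csv", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_value_system(vs, f)
    back <- read_value_system(f, sch)
    expect_equal(back$values, vs$values, tolerance = 1e-8,
                 ignore_attr = TRUE)
    unlink(f)
  }
})

test_that("answer logs roundtrip and replay to the same graph", {
  sch <- criterion_scheme(c("a", "b", "c"), n_levels = 3)
  truth <- random_value_system(sch, 11)
  s <- simulate_session(truth, epsilon = 0)
  f <- tempfile(fileext = ".jsonl")
  write_answer_log(s, f, respondent_id = "r42")
  log <- read_answer_log(f)
  unlink(f)
  expect_equal(nrow(log), session_questions_asked(s))
  expect_true(all(log$respondent_id == "r42"))
  s2 <- replay_answer_log(log, sch, allow_indifference = FALSE)
  expect_identical(s2$geq, s$geq)
  expect_identical(s2$strict, s$strict)
  expect_equal(solve_values(s2)$values, solve_values(s)$values,
               tolerance = 1e-9)
})
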