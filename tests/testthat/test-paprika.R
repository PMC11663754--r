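test_that("a 2x2 session is a single question", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 2)
  s <- paprika_session(sch)
  expect_equal(session_total_comparisons(s), 1L)
  q <- next_question(s)
  expect_s3_class(q, "choice_question")
  expect_setequal(q$active_criteria, c("a", "b"))
  # the two hypotheticals differ on exactly the two active criteria
  expect_equal(sum(q$first != q$second), 2L)
  record_answer(s, "first")
  expect_null(next_question(s))
  expect_true(session_complete(s))
  expect_equal(session_questions_asked(s), 1L)
  expect_equal(compare_alternatives(s, c(2L, 1L), c(1L, 2L)), "first")
  expect_equal(compare_alternatives(s, c(1L, 2L), c(2L, 1L)), "second")
})

test_that("questions present undominated alternatives and sessions terminate", {
  sch <- criterion_scheme(c("a", "b", "c"), n_levels = 3)
  s <- paprika_session(sch)
  asked <- 0L
  repeat {
    q <- next_question(s)
    if (is.null(q)) break
    d <- which(q$first != q$second)
    expect_length(d, 2L)
    expect_true(sign(q$first[d[1]] - q$second[d[1]]) !=
                  sign(q$first[d[2]] - q$second[d[2]]))
    record_answer(s, "first")
    asked <- asked + 1L
  }
  expect_true(session_complete(s))
  # transitivity must save questions relative to asking everything
  expect_lt(asked, session_total_comparisons(s))
})

test_that("interval containment is seeded into the preference graph", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 3)
  s <- paprika_session(sch)
  wide <- s$idx[1, 1, 3]; narrow <- s$idx[1, 1, 2]
  expect_equal(s$geq[wide, narrow], 1)
  expect_equal(s$geq[narrow, wide], 0)
  other <- s$idx[2, 1, 2]
  expect_equal(s$geq[wide, other], 0)          # no cross-criterion seeding
})

test_that("answers contradicting the closure are rejected", {
  # after answering indifferent then first x3 on the deterministic question
  # sequence of the 2x3 scheme, the 5th question has one verdict that would
  # close a preference cycle through the indifference; it must be refused
  # and the session must continue to completion on the consistent verdict
  sch <- criterion_scheme(c("a", "b"), n_levels = 3)
  s <- paprika_session(sch, allow_indifference = TRUE)
  for (v in c("indifferent", "first", "first", "first")) {
    next_question(s)
    record_answer(s, v)
  }
  next_question(s)
  expect_error(record_answer(s, "first"), "preference cycle")
  record_answer(s, "second")
  expect_null(next_question(s))
  expect_true(session_complete(s))
})

test_that("indifference answers merge increments and propagate", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 2)
  s <- paprika_session(sch, allow_indifference = TRUE)
  next_question(s)
  record_answer(s, "indifferent")
  expect_true(session_complete(s) || is.null(next_question(s)))
  expect_equal(compare_alternatives(s, c(2L, 1L), c(1L, 2L)), "indifferent")
})

test_that("indifference is refused when the session forbids it", {
  s <- paprika_session(criterion_scheme(c("a", "b"), n_levels = 2),
                       allow_indifference = FALSE)
  next_question(s)
  expect_error(record_answer(s, "indifferent"), "does not accept")
})

test_that("question selection is deterministic", {
  sch <- criterion_scheme(c("a", "b", "c"), n_levels = 3)
  run <- function() {
    s <- paprika_session(sch)
    seq <- character()
    repeat {
      q <- next_question(s)
      if (is.null(q)) break
      seq <- c(seq, paste(q$first, collapse = ""), paste(q$second, collapse = ""))
      record_answer(s, "second")
    }
    seq
  }
  expect_identical(run(), run())
})

test_that("a truthful session reproduces the true two-criterion relation", {
  sch <- criterion_scheme(c("a", "b", "c"), n_levels = 3)
  for (seed in 1:5) {
    truth <- random_value_system(sch, seed)
    s <- simulate_session(truth, epsilon = 0)
    tc <- two_criterion_pairs(sch)
    for (r in seq_len(nrow(tc$pairs))) {
      a <- tc$alts[tc$pairs[r, 1], ]; b <- tc$alts[tc$pairs[r, 2], ]
      got <- compare_alternatives(s, a, b)
      dt <- total_value(truth, a) - total_value(truth, b)
      want <- if (abs(dt) < 1e-9) "indifferent" else if (dt > 0) "first" else "second"
      # without indifference, exact ties are answered "first"; the generator
      # draws continuous values, so ties do not occur
      expect_identical(got, want)
    }
  }
})

test_that("noisy sessions always terminate", {
  sch <- criterion_scheme(c("a", "b", "c"), n_levels = 3)
  truth <- random_value_system(sch, 42)
  set.seed(99)
  s <- simulate_session(truth, epsilon = 0.3)
  expect_true(session_complete(s))
})
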