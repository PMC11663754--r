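#' Value systems: point values and criterion weights
#'
#' A value system assigns each criterion level a point value on a percentage
#' scale, with the lowest level worth 0 and the top levels summing to 100
#' across criteria, so that a hypothetical pathogen scoring the top level on
#' every criterion has total weight 100. A criterion's weight is the point
#' value of its top level.
#'
#' @param values numeric matrix, criteria x levels, of point values.
#' @param scheme the [criterion_scheme()] the values refer to.
#' @param gap optional solved minimum strict-preference separation.
#' @return An object of class `value_system`.
#' @export
value_system <- function(values, scheme, gap = NA_real_) {
  stopifnot_scheme(scheme)
  values <- as.matrix(values)
  nc <- n_criteria(scheme); L <- scheme$n_levels
  if (!all(dim(values) == c(nc, L))) stop("values must be criteria x levels")
  if (any(values < -1e-9)) stop("point values must be non-negative")
  if (any(abs(values[, 1L]) > 1e-9)) stop("lowest level must be worth 0")
  if (any(values[, -1L, drop = FALSE] - values[, -L, drop = FALSE] < -1e-9))
    stop("point values must be non-decreasing in level")
  if (abs(sum(values[, L]) - 100) > 1e-6)
    stop("criterion weights must sum to 100")
  dimnames(values) <- list(scheme$criteria, scheme$level_labels)
  structure(list(values = values, weights = values[, L], scheme = scheme, gap = gap),
            class = "value_system")
}

#' @export
print.value_system <- function(x, ...) {
  cat("Value system (criterion weights, percent):\n")
  print(round(x$weights, 2))
  invisible(x)
}

#' Solve point values from a completed session
#'
#' Finds point values consistent with every explicit (and therefore every
#' implied) preference of the session by linear programming: level values are
#' non-negative and non-decreasing within each criterion, each strict
#' preference holds with a common separation that the solver maximises
#' (max-min gap), indifferences hold with equality, and the criterion
#' weights (top-level values) sum to 100. The max-min-gap objective returns
#' a central solution of the feasible polytope rather than an arbitrary
#' vertex.
#'
#' Acyclicity of the preference graph does not by itself guarantee an
#' additive representation (answers from an error-prone respondent can
#' order increments consistently while contradicting their sum
#' decompositions), so the separation is allowed to go negative: the
#' solver then returns the value system whose worst preference violation
#' is smallest, and the solved `gap` reports it. Noiseless consistent
#' respondents always solve with a strictly positive gap.
#'
#' @param session a completed `paprika_session`.
#' @return A [value_system()]; its `gap` element is the solved max-min
#'   separation (negative iff the answers admit no additive representation).
#' @export
solve_values <- function(session) {
  s <- session
  refresh_resolved(s)
  if (any(!s$resolved)) stop("session is not complete")
  s$status <- "complete"
  scheme <- s$scheme
  nc <- n_criteria(scheme); L <- scheme$n_levels

  # variables: v[c, l] for l = 2..L (column-major by criterion), then eps
  nv <- nc * (L - 1L)
  vidx <- function(c, l) (c - 1L) * (L - 1L) + (l - 1L)  # valid for l >= 2
  inc_coef <- function(k) {
    row <- numeric(nv + 1L)
    ci <- s$inc$crit[k]; lo <- s$inc$lo[k]; hi <- s$inc$hi[k]
    row[vidx(ci, hi)] <- row[vidx(ci, hi)] + 1
    if (lo > 1L) row[vidx(ci, lo)] <- row[vidx(ci, lo)] - 1
    row
  }

  # Constraint set. Without indifference answers the closure is a partial
  # order whose covering relation (transitive reduction) entails, together
  # with level monotonicity, every explicit and implied preference at the
  # same minimum gap -- every cross-criterion covering pair is strict, so
  # each chain carries at least one gap. This shrinks the LP considerably.
  # With indifference answers the (deduplicated) explicit constraints are
  # used directly.
  has_indiff <- any(vapply(s$answers, function(a)
    a$verdict == "indifferent", logical(1)))
  if (!has_indiff) {
    M <- s$geq
    diag(M) <- 0
    red <- M > 0 & !((M %*% M) > 0)
    strict_red <- which(red & s$strict > 0, arr.ind = TRUE)
    answers <- lapply(seq_len(nrow(strict_red)), function(r) {
      list(i = strict_red[r, 1L], j = strict_red[r, 2L], verdict = "first")
    })
  } else {
    key <- vapply(s$answers, function(a) {
      ij <- if (a$verdict == "second") c(a$j, a$i) else c(a$i, a$j)
      paste(ij[1], ij[2], a$verdict == "indifferent")
    }, character(1))
    answers <- s$answers[!duplicated(key)]
  }

  # The gap variable is shifted so it may go negative: eps = t - SHIFT with
  # t >= 0. Each strict preference d1 - d2 >= eps becomes the upper-bound
  # row (d2 - d1) + t <= SHIFT, which is always satisfiable, so inconsistent
  # respondents get the least-violating solution instead of a solver failure.
  SHIFT <- 200
  run_lp <- function(answers) {
    ge_rows <- list(); le_rows <- list(); eq_rows <- list()
    # monotonicity between successive free levels
    for (ci in seq_len(nc)) {
      for (l in 2:(L - 1L)) {
        if (L < 3L) break
        row <- numeric(nv + 1L)
        row[vidx(ci, l + 1L)] <- 1; row[vidx(ci, l)] <- -1
        ge_rows[[length(ge_rows) + 1L]] <- row
      }
    }
    for (a in answers) {
      ij <- switch(a$verdict, first = c(a$i, a$j), second = c(a$j, a$i), c(a$i, a$j))
      row <- inc_coef(ij[1]) - inc_coef(ij[2])
      if (a$verdict == "indifferent") {
        eq_rows[[length(eq_rows) + 1L]] <- row
      } else {
        row <- -row; row[nv + 1L] <- 1        # d2 - d1 + t <= SHIFT
        le_rows[[length(le_rows) + 1L]] <- row
      }
    }
    norm_row <- numeric(nv + 1L)
    for (ci in seq_len(nc)) norm_row[vidx(ci, L)] <- 1
    eq_rows[[length(eq_rows) + 1L]] <- norm_row
    # cap row t <= SHIFT + 150 (the gap cannot exceed the 0..100 value
    # range); also guarantees at least one upper-bound row is present
    le_rows[[length(le_rows) + 1L]] <- c(numeric(nv), 1)

    A1 <- do.call(rbind, le_rows)
    b1 <- c(rep(SHIFT, length(le_rows) - 1L), SHIFT + 150)
    A2 <- if (length(ge_rows)) do.call(rbind, ge_rows) else NULL
    b2 <- if (length(ge_rows)) rep(0, length(ge_rows)) else NULL
    A3 <- do.call(rbind, eq_rows)
    b3 <- c(rep(0, length(eq_rows) - 1L), 100)
    obj <- c(numeric(nv), 1)
    sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                         A3 = A3, b3 = b3,
                         maxi = TRUE, n.iter = 100L * (nv + 20L))
    if (sol$solved != 1)
      stop("internal error: value LP did not solve (status ", sol$solved, ")")
    sol
  }

  sol <- run_lp(answers)
  gap <- unname(sol$soln[nv + 1L]) - SHIFT
  if (!has_indiff && gap <= 1e-9) {
    # The covering-relation shortcut is only equivalent to the explicit
    # constraint set when the solved gap is positive (a chain of m covering
    # steps then carries at least one full gap); with a non-positive gap it
    # is weaker, so re-solve on the deduplicated explicit answers.
    key <- vapply(s$answers, function(a) {
      ij <- if (a$verdict == "second") c(a$j, a$i) else c(a$i, a$j)
      paste(ij[1], ij[2], a$verdict == "indifferent")
    }, character(1))
    sol <- run_lp(s$answers[!duplicated(key)])
    gap <- unname(sol$soln[nv + 1L]) - SHIFT
  }

  x <- sol$soln
  v <- matrix(0, nc, L)
  for (ci in seq_len(nc)) v[ci, 2:L] <- x[vidx(ci, 2:L)]
  v <- pmax(v, 0)
  v <- v * (100 / sum(v[, L]))               # remove float drift exactly
  value_system(v, scheme, gap = gap)
}

#' Total weights of scored alternatives under a value system
#'
#' The total weight of a pathogen is the sum, over criteria, of the point
#' value of its scored level. A pathogen at the top level everywhere totals
#' 100; at the lowest level everywhere, 0.
#'
#' @param values a [value_system()] (or regional mean values from
#'   [regional_mean_weights()]).
#' @param score_matrix a [score_matrix()] on the same scheme.
#' @return A `priority_list` data frame (pathogen, total_weight, rank, tied)
#'   sorted by total weight descending; ties share the minimum rank and are
#'   annotated.
#' @export
rank_alternatives <- function(values, score_matrix) {
  v <- values$values
  scheme <- values$scheme
  sm <- score_matrix
  if (!inherits(sm, "score_matrix")) stop("score_matrix must be a score_matrix")
  if (!identical(colnames(sm$scores), scheme$criteria))
    stop("score matrix and value system use different schemes")
  if (any(sm$scores < 1L) || any(sm$scores > scheme$n_levels))
    stop("score level outside 1..", scheme$n_levels)
  totals <- vapply(seq_len(nrow(sm$scores)), function(p) {
    sum(v[cbind(seq_len(ncol(sm$scores)), sm$scores[p, ])])
  }, numeric(1))
  out <- data.frame(pathogen = rownames(sm$scores), total_weight = totals,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total_weight, out$pathogen), , drop = FALSE]
  r <- rank(-round(out$total_weight, 9), ties.method = "min")
  out$rank <- as.integer(r)
  out$tied <- duplicated(r) | duplicated(r, fromLast = TRUE)
  rownames(out) <- NULL
  class(out) <- c("priority_list", "data.frame")
  out
}

#' Export a value system
#'
#' Long-format CSV (criterion, level, value) or a JSON mirror.
#'
#' @param values a [value_system()].
#' @param path file to write; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_value_system <- function(values, path) {
  long <- data.frame(
    criterion = rep(values$scheme$criteria, times = values$scheme$n_levels),
    level = rep(seq_len(values$scheme$n_levels), each = n_criteria(values$scheme)),
    value = as.vector(values$values)
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(long, path, digits = NA)
  } else {
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a value system written by [write_value_system()]
#' @param path CSV or JSON file.
#' @param scheme the [criterion_scheme()] the file refers to.
#' @return A [value_system()].
#' @export
read_value_system <- function(path, scheme = criterion_scheme()) {
  long <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  v <- matrix(0, n_criteria(scheme), scheme$n_levels)
  v[cbind(match(long$criterion, scheme$criteria), long$level)] <- long$value
  value_system(v, scheme)
}

#' Write a session's answer log as JSON lines
#'
#' One record per answer: respondent id, question index, the two active
#' criteria with the level pair on each, and the verdict.
#'
#' @param session a `paprika_session`.
#' @param path output file.
#' @param respondent_id identifier echoed into every record.
#' @return `path`, invisibly.
#' @export
write_answer_log <- function(session, path, respondent_id = "r1") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (a in session$answers) {
    rec <- list(respondent_id = respondent_id, question_index = a$question_index,
                criterion_a = a$criterion_a, level_a1 = a$level_a1, level_a2 = a$level_a2,
                criterion_b = a$criterion_b, level_b1 = a$level_b1, level_b2 = a$level_b2,
                verdict = a$verdict)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read an answer log written by [write_answer_log()]
#' @param path JSONL file.
#' @return A data frame with one row per answer.
#' @export
read_answer_log <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l)))
  do.call(rbind, recs)
}

#' Replay a recorded answer log into a fresh session
#'
#' Rebuilds the preference graph by feeding each recorded verdict to the
#' engine's own questioning sequence; because question selection is
#' deterministic, a log produced by this engine replays exactly.
#'
#' @param log data frame from [read_answer_log()] (one respondent).
#' @param scheme the [criterion_scheme()].
#' @param allow_indifference passed to [paprika_session()].
#' @return The rebuilt `paprika_session`.
#' @export
replay_answer_log <- function(log, scheme = criterion_scheme(),
                              allow_indifference = TRUE) {
  s <- paprika_session(scheme, allow_indifference = allow_indifference)
  for (k in seq_len(nrow(log))) {
    q <- next_question(s)
    if (is.null(q)) break
    record_answer(s, log$verdict[k])
  }
  s
}
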