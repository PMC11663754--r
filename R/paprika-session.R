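#' Pairwise trade-off elicitation sessions
#'
#' A session walks one respondent through PAPRIKA-style discrete choice
#' questions: each question presents two hypothetical pathogens that differ
#' on exactly two criteria, with neither dominating the other, and all other
#' criteria tied. Answering a question ranks the value gain on one criterion
#' against the value gain on the other; transitivity then determines further
#' comparisons without asking, and the session is complete when every
#' undominated two-criterion comparison is determined.
#'
#' Internally each comparison is a pair of level *increments* (criterion,
#' lower level -> higher level). The session keeps a transitively closed
#' preference graph over increments: `geq[x, y]` records that increment x is
#' known to be worth at least increment y, `strict[x, y]` that it is worth
#' strictly more. Interval containment within a criterion (a wider level jump
#' is worth at least a narrower jump it contains) seeds the graph, so
#' cross-criterion answers propagate along within-criterion structure too.
#'
#' @param scheme a [criterion_scheme()].
#' @param allow_indifference should the "indifferent" verdict be accepted?
#'   The field survey offered a binary choice; both modes are supported.
#' @return An object of class `paprika_session` (an environment; functions
#'   such as [record_answer()] update it in place).
#' @seealso [next_question()], [record_answer()], [solve_values()]
#' @examples
#' s <- paprika_session(criterion_scheme(c("a", "b"), n_levels = 2))
#' q <- next_question(s)
#' record_answer(s, "first")
#' @export
paprika_session <- function(scheme = criterion_scheme(), allow_indifference = TRUE) {
  stopifnot_scheme(scheme)
  inc <- increment_table(scheme)
  n <- nrow(inc)

  # index array: increment id by (criterion, lo, hi)
  idx <- array(NA_integer_, dim = c(n_criteria(scheme), scheme$n_levels, scheme$n_levels))
  idx[cbind(inc$crit, inc$lo, inc$hi)] <- seq_len(n)

  # seed graph: identity + interval containment within a criterion
  geq <- matrix(0, n, n)
  same_crit <- outer(inc$crit, inc$crit, "==")
  contains <- outer(inc$lo, inc$lo, "<=") & outer(inc$hi, inc$hi, ">=")
  geq[same_crit & contains] <- 1
  strict <- matrix(0, n, n)

  # canonical list of all undominated two-criterion comparisons: ordered
  # pairs of increments on distinct criteria, criterion of i before j
  lower <- which(outer(inc$crit, inc$crit, "<"), arr.ind = TRUE)
  comp <- data.frame(i = lower[, "row"], j = lower[, "col"])
  comp$span <- (inc$hi[comp$i] - inc$lo[comp$i]) + (inc$hi[comp$j] - inc$lo[comp$j])
  ord <- order(inc$crit[comp$i], inc$lo[comp$i], inc$hi[comp$i],
               inc$crit[comp$j], inc$lo[comp$j], inc$hi[comp$j])
  comp <- comp[ord, , drop = FALSE]
  rownames(comp) <- NULL

  s <- new.env(parent = emptyenv())
  s$scheme <- scheme
  s$allow_indifference <- isTRUE(allow_indifference)
  s$inc <- inc
  s$idx <- idx
  s$geq <- geq
  s$strict <- strict
  s$comp <- comp
  # precomputed linear indices into the n x n relation matrices
  s$li_ij <- (comp$j - 1L) * n + comp$i
  s$li_ji <- (comp$i - 1L) * n + comp$j
  s$resolved <- rep(FALSE, nrow(comp))
  s$pending <- NULL          # comparison row index of the issued question
  s$answers <- list()
  s$status <- "in_progress"
  class(s) <- "paprika_session"
  s
}

#' @export
print.paprika_session <- function(x, ...) {
  cat("PAPRIKA session:", n_criteria(x$scheme), "criteria x", x$scheme$n_levels,
      "levels;", length(x$answers), "answers;", x$status, "\n")
  invisible(x)
}

# relation between two increments given the closed graph
inc_relation <- function(s, i, j) {
  if (s$strict[i, j] > 0) return("gt")
  if (s$strict[j, i] > 0) return("lt")
  if (s$geq[i, j] > 0 && s$geq[j, i] > 0) return("eq")
  "undetermined"
}

inc_determined <- function(s, i, j) {
  s$strict[i, j] > 0 || s$strict[j, i] > 0 || (s$geq[i, j] > 0 && s$geq[j, i] > 0)
}

refresh_resolved <- function(s) {
  un <- which(!s$resolved)
  if (!length(un)) return(invisible(s))
  a <- s$li_ij[un]; b <- s$li_ji[un]
  det <- s$strict[a] > 0 | s$strict[b] > 0 | (s$geq[a] > 0 & s$geq[b] > 0)
  s$resolved[un[det]] <- TRUE
  invisible(s)
}

#' Total number of undominated two-criterion comparisons of a session
#' @param session a `paprika_session`.
#' @return Integer count; questions asked can never exceed it.
#' @export
session_total_comparisons <- function(session) nrow(session$comp)

#' Number of questions asked so far
#' @param session a `paprika_session`.
#' @export
session_questions_asked <- function(session) length(session$answers)

#' Is the session complete?
#' @param session a `paprika_session`.
#' @export
session_complete <- function(session) identical(session$status, "complete")

#' Next trade-off question
#'
#' Selects the next undetermined two-criterion comparison to put to the
#' respondent. Questions are asked in increasing span (adjacent-level trades
#' first); among minimal-span candidates the one whose answer is guaranteed
#' to determine the most currently-undetermined comparisons is chosen
#' (greedy, scored through the closed preference graph), with remaining ties
#' broken by the canonical lexicographic order of criteria and levels. The
#' selection is fully deterministic.
#'
#' @param session a `paprika_session` in progress.
#' @return A `choice_question` (two hypothetical alternatives differing on
#'   exactly two criteria), or `NULL` when every comparison is determined;
#'   in that case the session is marked complete.
#' @export
next_question <- function(session) {
  s <- session
  if (s$status == "complete") stop("session already complete")
  if (s$status == "abandoned") stop("session abandoned")
  if (!is.null(s$pending)) return(build_question(s, s$pending))

  refresh_resolved(s)
  un <- which(!s$resolved)
  if (!length(un)) {
    s$status <- "complete"
    return(NULL)
  }

  spans <- s$comp$span[un]
  cand <- un[spans == min(spans)]
  if (length(cand) > 1L) {
    # guaranteed elimination count for a hypothetical strict answer a > b:
    # N[a, b] = #{unresolved (x, y): x >= a and b >= y in the closed graph}
    nn <- nrow(s$inc)
    U <- matrix(0, nn, nn)
    U[s$li_ij[un]] <- 1
    U[s$li_ji[un]] <- 1
    Gt <- t(s$geq)
    N <- Gt %*% U %*% Gt
    n_ij <- N[s$li_ij[cand]]
    n_ji <- N[s$li_ji[cand]]
    # an answer contradicting a known weak relation can never be given, so
    # it does not bound the guaranteed elimination
    blocked_ij <- s$geq[s$li_ji[cand]] > 0  # j >= i known -> "i > j" impossible
    blocked_ji <- s$geq[s$li_ij[cand]] > 0
    score <- pmin(ifelse(blocked_ij, Inf, n_ij), ifelse(blocked_ji, Inf, n_ji))
    pick <- cand[which.max(score)]  # first maximum = canonical order tie-break
  } else {
    pick <- cand
  }

  s$pending <- pick
  build_question(s, pick)
}

build_question <- function(s, comp_row) {
  i <- s$comp$i[comp_row]; j <- s$comp$j[comp_row]
  inc <- s$inc
  base <- rep(1L, n_criteria(s$scheme))
  a <- b <- base
  a[inc$crit[i]] <- inc$hi[i]; a[inc$crit[j]] <- inc$lo[j]
  b[inc$crit[i]] <- inc$lo[i]; b[inc$crit[j]] <- inc$hi[j]
  structure(
    list(
      first = a, second = b,
      active_criteria = s$scheme$criteria[c(inc$crit[i], inc$crit[j])],
      increments = c(i, j),
      scheme = s$scheme
    ),
    class = "choice_question"
  )
}

#' @export
print.choice_question <- function(x, ...) {
  cat("Which hypothetical pathogen would you prioritise?\n")
  labs <- x$scheme$level_labels
  act <- match(x$active_criteria, x$scheme$criteria)
  for (k in act) {
    cat(sprintf("  %-14s  first: %-10s  second: %-10s\n",
                x$scheme$criteria[k], labs[x$first[k]], labs[x$second[k]]))
  }
  cat("  (all other criteria tied)\n")
  invisible(x)
}

#' Record the respondent's answer to the pending question
#'
#' Stores the explicit preference and recomputes the transitive closure of
#' implied preferences: strict preferences compose through known
#' at-least-as-good relations, and indifference merges the two increments'
#' standing in the graph. An answer that would contradict the closure (create
#' a preference cycle) is rejected; the question selection never issues a
#' question both of whose strict answers are impossible.
#'
#' @param session a `paprika_session` with a pending question.
#' @param verdict `"first"`, `"second"`, or `"indifferent"` (the latter only
#'   when the session allows it).
#' @return The session, invisibly (updated in place).
#' @export
record_answer <- function(session, verdict) {
  s <- session
  if (is.null(s$pending)) stop("no pending question; call next_question() first")
  verdict <- match.arg(verdict, c("first", "second", "indifferent"))
  if (verdict == "indifferent" && !s$allow_indifference)
    stop("this session does not accept indifference")

  i <- s$comp$i[s$pending]; j <- s$comp$j[s$pending]
  if (verdict == "first") {
    if (s$geq[j, i] > 0) stop("inconsistent answer: would create a preference cycle")
    add_strict(s, i, j)
  } else if (verdict == "second") {
    if (s$geq[i, j] > 0) stop("inconsistent answer: would create a preference cycle")
    add_strict(s, j, i)
  } else {
    if (s$strict[i, j] > 0 || s$strict[j, i] > 0)
      stop("inconsistent answer: would create a preference cycle")
    add_equal(s, i, j)
  }

  inc <- s$inc
  s$answers[[length(s$answers) + 1L]] <- list(
    question_index = length(s$answers) + 1L,
    i = i, j = j,
    criterion_a = s$scheme$criteria[inc$crit[i]],
    level_a1 = inc$lo[i], level_a2 = inc$hi[i],
    criterion_b = s$scheme$criteria[inc$crit[j]],
    level_b1 = inc$lo[j], level_b2 = inc$hi[j],
    verdict = verdict
  )
  s$resolved[s$pending] <- TRUE
  s$pending <- NULL
  invisible(s)
}

# add strict edge a > b and close the graph (exact one-edge closure update)
add_strict <- function(s, a, b) {
  new <- outer(s$geq[, a], s$geq[b, ])
  s$geq <- pmax(s$geq, new)
  s$strict <- pmax(s$strict, new)
  invisible(s)
}

# add indifference a ~ b: both weak edges, then recompute strict reachability
add_equal <- function(s, a, b) {
  g <- s$geq
  for (rep in 1:2) {  # two passes reach the fixpoint for a single 2-cycle
    g <- pmax(g, outer(g[, a], g[b, ]), outer(g[, b], g[a, ]))
  }
  s$geq <- g
  # strict paths must traverse an old strict edge (the new edges are weak)
  s$strict <- pmax(s$strict, (g %*% s$strict %*% g > 0) + 0)
  invisible(s)
}

#' Compare two full alternatives through the session's implied relation
#'
#' Only alternatives differing on exactly two criteria (neither dominating)
#' are comparable through a session; others are the province of
#' [solve_values()] and the additive model.
#'
#' @param session a `paprika_session`.
#' @param alt1,alt2 integer level vectors over the scheme's criteria.
#' @return `"first"`, `"second"`, `"indifferent"`, or `"undetermined"`.
#' @export
compare_alternatives <- function(session, alt1, alt2) {
  s <- session
  nc <- n_criteria(s$scheme)
  stopifnot(length(alt1) == nc, length(alt2) == nc)
  diff <- which(alt1 != alt2)
  if (length(diff) != 2L) stop("alternatives must differ on exactly two criteria")
  up1 <- diff[alt1[diff] > alt2[diff]]   # criteria where alt1 is better
  if (length(up1) != 1L) stop("one alternative dominates the other")
  c1 <- up1; c2 <- setdiff(diff, up1)
  i <- s$idx[c1, min(alt1[c1], alt2[c1]), max(alt1[c1], alt2[c1])]
  j <- s$idx[c2, min(alt1[c2], alt2[c2]), max(alt1[c2], alt2[c2])]
  switch(inc_relation(s, i, j),
         gt = "first", lt = "second", eq = "indifferent", "undetermined")
}
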