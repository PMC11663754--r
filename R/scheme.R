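#' Criteria for pathogen prioritisation
#'
#' The default scheme holds the eight criteria used to weight endemic
#' pathogens for vaccine R&D, each with five ordered performance levels
#' (Very low to Very high). The first three criteria are quantitative
#' (scored from burden data); the remaining five are qualitative.
#'
#' @format Character vector of criterion identifiers, in display order.
#' @export
mcda_criteria <- c(
  "deaths_under5",   # annual deaths attributable to the pathogen, < 5 years
  "deaths_5plus",    # annual deaths, >= 5 years
  "ylds",            # years lived with disability, all ages
  "socioeconomic",   # social and economic burden per case
  "outbreaks",       # disruption due to outbreaks and epidemics
  "inequity",        # contribution to inequity
  "amr",             # contribution to antimicrobial resistance
  "unmet_needs"      # unmet needs for prevention and treatment
)

#' Default level labels, lowest to highest.
#' @export
mcda_levels <- c("Very low", "Low", "Medium", "High", "Very high")

#' Construct a criterion scheme
#'
#' A scheme names the criteria and the ordered performance levels shared by
#' all criteria. It is the common frame for elicitation sessions, score
#' matrices and value systems.
#'
#' @param criteria character vector of criterion identifiers (>= 2, unique).
#' @param n_levels number of ordered levels per criterion (>= 2).
#' @param level_labels optional labels, lowest to highest; defaults to the
#'   Very low .. Very high scale when `n_levels == 5`, else `"L1"..`.
#' @return An object of class `criterion_scheme`.
#' @examples
#' sch <- criterion_scheme()
#' sch$criteria
#' @export
criterion_scheme <- function(criteria = mcda_criteria, n_levels = 5L,
                             level_labels = NULL) {
  criteria <- as.character(criteria)
  n_levels <- as.integer(n_levels)
  if (length(criteria) < 2L) stop("a scheme needs at least 2 criteria")
  if (anyDuplicated(criteria)) stop("criterion identifiers must be unique")
  if (is.na(n_levels) || n_levels < 2L) stop("a scheme needs at least 2 levels")
  if (is.null(level_labels)) {
    level_labels <- if (n_levels == 5L) mcda_levels else paste0("L", seq_len(n_levels))
  }
  if (length(level_labels) != n_levels) stop("level_labels must have length n_levels")
  if (anyDuplicated(level_labels)) stop("level labels must be unique")
  structure(
    list(criteria = criteria, n_levels = n_levels, level_labels = level_labels),
    class = "criterion_scheme"
  )
}

#' @export
print.criterion_scheme <- function(x, ...) {
  cat("Criterion scheme:", length(x$criteria), "criteria x", x$n_levels, "levels\n")
  cat("  criteria:", paste(x$criteria, collapse = ", "), "\n")
  cat("  levels:  ", paste(x$level_labels, collapse = " < "), "\n")
  invisible(x)
}

n_criteria <- function(scheme) length(scheme$criteria)

stopifnot_scheme <- function(scheme) {
  if (!inherits(scheme, "criterion_scheme")) stop("not a criterion_scheme")
  invisible(scheme)
}

# Table of all level increments (lo -> hi, lo < hi) per criterion. Increments
# are the elementary quantities a two-criterion trade-off question compares:
# choosing between alternatives that differ on criteria a and b amounts to
# ranking the value gain on a against the value gain on b.
increment_table <- function(scheme) {
  L <- scheme$n_levels
  pairs <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)  # lo = row < hi = col
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  nc <- n_criteria(scheme)
  data.frame(
    crit = rep(seq_len(nc), each = nrow(pairs)),
    lo = rep(pairs[, 1L], nc),
    hi = rep(pairs[, 2L], nc)
  )
}
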