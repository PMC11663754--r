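#' Round half away from zero
#'
#' Reported percentages use commercial rounding (0.5 rounds up), matching
#' the presentation of survey results, rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalised identity hash for duplicate screening
#'
#' Duplicate submissions are detected from a case-folded,
#' whitespace-stripped hash of name and email, so screening is
#' deterministic and no identifying text is kept downstream.
#'
#' @param name,email character vectors.
#' @return Character vector of hex digests.
#' @export
hash_identity <- function(name, email) {
  norm <- function(s) gsub("[[:space:]]+", "", tolower(trimws(s)))
  key <- paste0(norm(name), "|", norm(email))
  vapply(key, function(s) {
    f <- tempfile()
    on.exit(unlink(f))
    writeChar(s, f, eos = NULL)
    unname(tools::md5sum(f))
  }, character(1), USE.NAMES = FALSE)
}

#' Apply the response exclusion rules
#'
#' Keeps, per respondent, the first fully-completed submission. Incomplete
#' submissions, duplicate complete submissions (same identity hash), and
#' straight-lined sessions (the same verdict position chosen on every
#' trade-off question) are excluded. The counts satisfy
#' `received = analysed + incomplete + duplicates + straight_lined` and
#' `analysed = complete - invalid` with
#' `invalid = duplicates + straight_lined`.
#'
#' @param responses data frame with one row per submission, in submission
#'   order, containing at least `respondent_hash`, `complete` (logical) and
#'   `straight_lined` (logical).
#' @return A list: `analysed` (the retained rows) and `report`, an
#'   `exclusion_report` with counts and half-up-rounded integer
#'   percentages of received.
#' @export
apply_exclusions <- function(responses) {
  stopifnot(all(c("respondent_hash", "complete", "straight_lined") %in%
                  names(responses)))
  received <- nrow(responses)
  comp <- responses[responses$complete, , drop = FALSE]
  n_complete <- nrow(comp)
  dup <- duplicated(comp$respondent_hash)
  n_dup <- sum(dup)
  firsts <- comp[!dup, , drop = FALSE]
  sl <- firsts$straight_lined
  n_sl <- sum(sl)
  analysed <- firsts[!sl, , drop = FALSE]
  report <- exclusion_report(received = received, complete = n_complete,
                             duplicates = n_dup, straight_lined = n_sl)
  list(analysed = analysed, report = report)
}

#' Build an exclusion report from counts
#'
#' @param received total submissions received.
#' @param complete fully-completed submissions.
#' @param duplicates duplicate complete submissions excluded.
#' @param straight_lined straight-lined complete submissions excluded.
#' @param invalid total invalid complete submissions; defaults to
#'   `duplicates + straight_lined` but can be given directly when the
#'   breakdown is unknown.
#' @return An `exclusion_report` list of counts plus `pct_complete` and
#'   `pct_analysed` (percent of received, rounded half-up to integers).
#' @export
exclusion_report <- function(received, complete, duplicates = 0L,
                             straight_lined = 0L,
                             invalid = duplicates + straight_lined) {
  analysed <- complete - invalid
  stopifnot(received >= complete, complete >= invalid, invalid >= 0)
  structure(
    list(received = as.integer(received), complete = as.integer(complete),
         incomplete = as.integer(received - complete),
         duplicates = as.integer(duplicates),
         straight_lined = as.integer(straight_lined),
         invalid = as.integer(invalid), analysed = as.integer(analysed),
         pct_complete = round_half_up(100 * complete / received),
         pct_analysed = round_half_up(100 * analysed / received)),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Responses: %d received; %d complete (%d%%); %d invalid (%d duplicate, %d straight-lined); %d analysed (%d%% of received)\n",
              x$received, x$complete, x$pct_complete, x$invalid,
              x$duplicates, x$straight_lined, x$analysed, x$pct_analysed))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test by full enumeration of the support: the
#' two-sided p-value is the total probability of all tables (with the
#' observed margins) whose probability does not exceed that of the
#' observed table (probability-mass method, no mid-p correction).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(0, 55, 4, 41), 2, byrow = TRUE))  # ~0.038
#' @export
fisher_exact_2x2 <- function(table) {
  t <- as.matrix(table)
  if (!all(dim(t) == c(2L, 2L))) stop("table must be 2x2")
  if (any(t < 0) || any(t != round(t))) stop("counts must be non-negative integers")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("undefined: table has a zero margin")
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(t[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Adjusted mean differences in criterion weights
#'
#' Ordinary least squares of each criterion's weight on the full covariate
#' set, reporting the adjusted mean difference of every non-reference term
#' with a normal-theory 95 percent confidence interval. Rank-deficient
#' designs are handled by dropping aliased terms, which are reported.
#'
#' @param weights numeric matrix, respondents x criteria (columns named by
#'   criterion), of criterion weights in percent.
#' @param covariates data frame of respondent covariates.
#' @return A list: `table` (criterion, term, amd, ci_low, ci_high, p) and
#'   `aliased` (terms dropped per criterion).
#' @export
adjusted_mean_differences <- function(weights, covariates) {
  weights <- as.matrix(weights)
  if (nrow(weights) != nrow(covariates)) stop("weights/covariates mismatch")
  n_terms <- ncol(stats::model.matrix(~ ., covariates))
  if (nrow(weights) <= n_terms) stop("more model terms than respondents")
  res <- list(); aliased <- list()
  for (cr in colnames(weights)) {
    dat <- cbind(data.frame(.w = weights[, cr]), covariates)
    fit <- stats::lm(.w ~ ., data = dat)
    al <- names(which(is.na(stats::coef(fit))))
    if (length(al)) aliased[[cr]] <- al
    co <- summary(fit)$coefficients
    keep <- rownames(co) != "(Intercept)"
    res[[cr]] <- data.frame(
      criterion = cr, term = rownames(co)[keep],
      amd = co[keep, "Estimate"],
      ci_low = co[keep, "Estimate"] - 1.96 * co[keep, "Std. Error"],
      ci_high = co[keep, "Estimate"] + 1.96 * co[keep, "Std. Error"],
      p = co[keep, 4], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  list(table = out, aliased = aliased)
}

# logistic GEE with exchangeable working correlation (Liang-Zeger),
# moment estimate of the correlation, robust sandwich covariance
gee_logit_exchangeable <- function(y, X, id, max_iter = 50L, tol = 1e-10) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    X <- X[, setdiff(colnames(X), drop), drop = FALSE]
  } else drop <- character()
  p <- ncol(X)
  beta <- stats::coef(stats::glm.fit(X, y, family = stats::binomial()))
  clusters <- split(seq_along(y), id)
  alpha <- 0; iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    r <- (y - mu) / sqrt(w)
    # moment estimate of the exchangeable correlation
    num <- 0; pairs <- 0
    for (ix in clusters) {
      ni <- length(ix)
      if (ni > 1L) {
        ri <- r[ix]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        pairs <- pairs + ni * (ni - 1) / 2
      }
    }
    alpha <- if (pairs > p) num / (pairs - p) else 0
    alpha <- max(min(alpha, 0.99), -0.99)
    M <- matrix(0, p, p); U <- numeric(p); B <- matrix(0, p, p)
    for (ix in clusters) {
      ni <- length(ix)
      Ai <- sqrt(w[ix])
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Vi <- Ri * tcrossprod(Ai)                    # A^1/2 R A^1/2
      Di <- X[ix, , drop = FALSE] * w[ix]          # dmu/dbeta
      Vi_inv_D <- solve(Vi, Di)
      Vi_inv_e <- solve(Vi, y[ix] - mu[ix])
      M <- M + crossprod(Di, Vi_inv_D)
      ui <- drop(crossprod(Di, Vi_inv_e))
      U <- U + ui
      B <- B + tcrossprod(ui)
    }
    delta <- solve(M, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  vb <- solve(M) %*% B %*% solve(M)
  list(coefficients = stats::setNames(drop(beta), colnames(X)),
       robust_se = sqrt(diag(vb)), vcov = vb, alpha = alpha,
       n_iter = iter, converged = converged, dropped = drop)
}

#' Completion-bias check via logistic GEE
#'
#' Measures associations between participant characteristics and survey
#' completion over all submissions (including incompletes), accounting for
#' repeated submissions per respondent with a generalized estimating
#' equation: binomial family, logit link, exchangeable working
#' correlation, robust (sandwich) standard errors. When every respondent
#' has a single submission the estimating equations coincide with the
#' ordinary logistic score equations, so the estimates equal a plain GLM
#' fit.
#'
#' @param completed logical/0-1 vector, one element per submission.
#' @param covariates data frame of characteristics, one row per submission.
#' @param id respondent identifier per submission (the clustering unit).
#' @return A list: `table` (term, or, ci_low, ci_high, robust_se, p),
#'   `alpha` (working correlation), `n_iter`, `converged`, `dropped`
#'   (aliased terms).
#' @export
completion_bias_gee <- function(completed, covariates, id) {
  y <- as.integer(completed)
  X <- stats::model.matrix(~ ., covariates)
  fit <- gee_logit_exchangeable(y, X, id)
  if (!fit$converged)
    warning("GEE did not converge in ", fit$n_iter, " iterations")
  est <- fit$coefficients; se <- fit$robust_se
  tab <- data.frame(
    term = names(est), or = exp(est),
    ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
    robust_se = se, p = 2 * stats::pnorm(-abs(est / se)),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  list(table = tab, alpha = fit$alpha, n_iter = fit$n_iter,
       converged = fit$converged, dropped = fit$dropped,
       coefficients = est)
}
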