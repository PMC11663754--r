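#' Configuration of the synthetic study generator
#'
#' Bundles every knob of the seeded generator that emulates the study's
#' respondents and regional pathogen score matrices: a two-cluster mixture
#' of latent weight profiles (one weighting AMR and outbreak disruption,
#' one weighting the mortality criteria, mixed 65/35), simplex-constrained
#' individual weights around the cluster means, ordered stick-breaking
#' level spacings, respondent covariates drawn independently of cluster
#' (the study found no association), a logistic completion model,
#' duplicate and straight-liner contamination, and latent pathogen
#' severities with cross-region correlation and a globally dominant
#' subset.
#'
#' @param seed integer seed; identical config and seed give byte-identical
#'   output.
#' @param n_respondents number of survey submissions received.
#' @param regions named sampling weights over WHO regions (defaults
#'   proportional to the analysed per-region counts).
#' @param cluster_props mixture proportions of the two weight profiles.
#' @param cluster_means 2 x n-criteria matrix of mean weight vectors
#'   (percent, rows sum to 100).
#' @param concentration Dirichlet concentration of individual weights
#'   around the cluster mean (larger = tighter).
#' @param choice_error probability a trade-off verdict is flipped.
#' @param allow_indifference do sessions accept an indifferent verdict?
#' @param completion_intercept logit of the completion probability when
#'   all completion coefficients are zero.
#' @param completion_coefs named list of logit coefficients on covariates
#'   (e.g. `list(experience_low = -0.5)`); all zero by default (completion
#'   independent of characteristics).
#' @param duplicate_rate probability a completer submits a second time.
#' @param straightline_rate probability a completed submission is
#'   straight-lined.
#' @param pathogens pathogen panel (default the 26-pathogen panel).
#' @param dominant_pathogens subset made severe in every region.
#' @param dominance_boost latent-severity boost (SD units) for the subset.
#' @param rho cross-region correlation of latent pathogen severities.
#' @param scheme the [criterion_scheme()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    seed = 1L,
    n_respondents = 577L,
    regions = c(AFR = 55, AMR = 45, EMR = 37, EUR = 26, SEAR = 45, WPR = 65),
    cluster_props = c(amr_outbreak = 0.65, mortality = 0.35),
    cluster_means = rbind(
      amr_outbreak = c(10, 10, 11, 11, 16, 11, 17, 14),
      mortality    = c(19, 16, 12, 10, 10, 11, 11, 11)),
    concentration = 25,
    choice_error = 0.05,
    allow_indifference = FALSE,
    completion_intercept = stats::qlogis(0.49),
    completion_coefs = list(),
    duplicate_rate = 0.02,
    straightline_rate = 0.02,
    pathogens = mcda_pathogens,
    dominant_pathogens = c("Mycobacterium tuberculosis", "HIV-1",
                           "Klebsiella pneumoniae", "Staphylococcus aureus",
                           "ExPEC"),
    dominance_boost = 1.5,
    rho = 0.7,
    scheme = criterion_scheme()) {
  stopifnot_scheme(scheme)
  cluster_props <- cluster_props / sum(cluster_props)
  if (any(cluster_props < 0)) stop("mixture proportions must be in [0, 1]")
  if (ncol(cluster_means) != n_criteria(scheme))
    stop("cluster_means must have one column per criterion")
  if (any(abs(rowSums(cluster_means) - 100) > 1e-6))
    stop("cluster mean weight vectors must sum to 100")
  if (choice_error < 0 || choice_error >= 0.5)
    stop("choice_error must be in [0, 0.5)")
  stopifnot(rho >= 0, rho <= 1, duplicate_rate >= 0, duplicate_rate <= 1,
            straightline_rate >= 0, straightline_rate <= 1)
  if (!all(dominant_pathogens %in% pathogens))
    stop("dominant_pathogens must be drawn from the panel")
  structure(as.list(environment()), class = "generator_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# draw one respondent's true point values: Dirichlet weights around the
# cluster mean, ordered stick-breaking spacing of interior levels
draw_true_values <- function(config, cluster) {
  scheme <- config$scheme
  nc <- n_criteria(scheme); L <- scheme$n_levels
  mean_w <- config$cluster_means[cluster, ] / 100
  w <- 100 * rdirichlet1(config$concentration * mean_w)
  v <- matrix(0, nc, L)
  for (ci in seq_len(nc)) {
    inc <- rdirichlet1(rep(1, L - 1L))
    v[ci, ] <- w[ci] * c(0, cumsum(inc))
  }
  v[, L] <- w                                    # exact top values
  value_system(v * (100 / sum(v[, L])), scheme)
}

covariate_margins <- function() {
  list(
    experience = c("<=10" = 0.45, "11-20" = 0.35, ">20" = 0.20),
    expertise = c(epidemiology = 0.52, vaccine_rd = 0.45, health_policy = 0.39,
                  clinical = 0.30, regulatory = 0.15, manufacturing = 0.10),
    organisation = c(academic = 0.39, government = 0.33, ngo = 0.15,
                     who = 0.10, pharma = 0.08, funder = 0.05,
                     hospital = 0.12, regulator = 0.06, other = 0.08),
    gavi = 0.25,
    income = c(high = 0.30, upper_middle = 0.25, lower_middle = 0.30, low = 0.15),
    language_by_region = list(
      AFR = c(English = 0.6, French = 0.35, Portuguese = 0.05),
      AMR = c(English = 0.40, Spanish = 0.50, Portuguese = 0.10),
      EMR = c(English = 0.5, Arabic = 0.5),
      EUR = c(English = 0.6, Russian = 0.2, French = 0.2),
      SEAR = c(English = 1.0),
      WPR = c(English = 0.7, Chinese = 0.3)
    )
  )
}

#' Draw the latent respondent population
#'
#' Samples cluster labels from the mixture, criterion weights on the
#' simplex around the cluster means, level spacings by ordered
#' stick-breaking, covariates from fixed margins (independent of cluster),
#' and a completion propensity from the logistic completion model.
#'
#' @param config a [generator_config()]. The caller controls the RNG state
#'   (use `set.seed` or [simulate_study()]).
#' @return A list: `covariates` (data frame, one row per respondent),
#'   `truth` (list of true [value_system()]s), `cluster` (integer labels,
#'   1 = first profile row), `completion_prob`.
#' @export
sample_respondents <- function(config) {
  n <- config$n_respondents
  m <- covariate_margins()
  region <- sample(names(config$regions), n, replace = TRUE,
                   prob = config$regions / sum(config$regions))
  language <- vapply(region, function(rg) {
    p <- m$language_by_region[[rg]]
    sample(names(p), 1L, prob = p)
  }, character(1), USE.NAMES = FALSE)
  cov <- data.frame(
    respondent_id = sprintf("id%04d", seq_len(n)),
    region = region, language = language,
    experience = sample(names(m$experience), n, TRUE, m$experience),
    gavi = stats::runif(n) < m$gavi,
    income = sample(names(m$income), n, TRUE, m$income),
    stringsAsFactors = FALSE
  )
  for (e in names(m$expertise))
    cov[[paste0("exp_", e)]] <- stats::runif(n) < m$expertise[e]
  for (o in names(m$organisation))
    cov[[paste0("org_", o)]] <- stats::runif(n) < m$organisation[o]
  cluster <- 1L + (stats::runif(n) >= config$cluster_props[1])
  truth <- lapply(cluster, function(cl) draw_true_values(config, cl))
  eta <- rep(config$completion_intercept, n)
  for (nm in names(config$completion_coefs)) {
    x <- cov[[nm]]
    if (is.null(x)) stop("completion coefficient on unknown covariate: ", nm)
    eta <- eta + config$completion_coefs[[nm]] * as.numeric(x)
  }
  list(covariates = cov, truth = truth, cluster = cluster,
       completion_prob = stats::plogis(eta))
}

#' Simulate one respondent's elicitation session
#'
#' Answers each question the engine asks by comparing true value sums;
#' with probability `epsilon` a strict verdict is flipped. Ties in true
#' value are reported as indifferent when the session allows it. A flipped
#' verdict that would contradict the implied relation (the engine rejects
#' cycle-creating answers) falls back to the truthful verdict, so the
#' session always terminates; at `epsilon = 0` no answer is ever rejected.
#'
#' @param truth a [value_system()] of true point values.
#' @param epsilon verdict flip probability in `[0, 0.5)`.
#' @param allow_indifference passed to [paprika_session()].
#' @param max_questions stop early after this many answers (simulates
#'   noncompletion); default unlimited.
#' @param session optionally, an existing session to continue.
#' @return The (possibly incomplete) `paprika_session`.
#' @export
simulate_session <- function(truth, epsilon = 0, allow_indifference = FALSE,
                             max_questions = Inf, session = NULL) {
  stopifnot(epsilon >= 0, epsilon < 0.5)
  s <- if (is.null(session)) {
    paprika_session(truth$scheme, allow_indifference = allow_indifference)
  } else session
  v <- truth$values
  nc <- n_criteria(truth$scheme)
  asked <- 0L
  while (asked < max_questions) {
    q <- next_question(s)
    if (is.null(q)) break
    t1 <- sum(v[cbind(seq_len(nc), q$first)])
    t2 <- sum(v[cbind(seq_len(nc), q$second)])
    verdict <- if (abs(t1 - t2) < 1e-9) {
      if (allow_indifference) "indifferent" else "first"
    } else if (t1 > t2) "first" else "second"
    if (verdict != "indifferent" && epsilon > 0 && stats::runif(1) < epsilon)
      verdict <- if (verdict == "first") "second" else "first"
    ok <- tryCatch({ record_answer(s, verdict); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      truthful <- if (abs(t1 - t2) < 1e-9) {
        if (allow_indifference) "indifferent" else "second"
      } else if (t1 > t2) "first" else "second"
      ok2 <- tryCatch({ record_answer(s, truthful); TRUE },
                      error = function(e) FALSE)
      if (!ok2) {
        other <- setdiff(c("first", "second"), truthful)[1]
        record_answer(s, other)
      }
    }
    asked <- asked + 1L
  }
  s
}

#' Sample regional pathogen score matrices
#'
#' Latent pathogen severities are drawn per criterion with cross-region
#' correlation `rho` (a shared global component plus regional noise); a
#' configurable subset of pathogens receives a global severity boost, to
#' emulate pathogens that are priorities in every region. Latents are then
#' mapped to ordinal levels with the same rank-quintile rule as burden
#' scoring. Qualitative criteria carry sampled provenance codes; the
#' cytomegalovirus row's quantitative scores are coded preliminary
#' (systematic burden estimates do not exist for it).
#'
#' @param config a [generator_config()]. Caller controls the RNG state.
#' @return Named list of [score_matrix()] objects, one per region.
#' @export
sample_score_matrices <- function(config) {
  scheme <- config$scheme
  pats <- config$pathogens
  np <- length(pats); nc <- n_criteria(scheme)
  boost <- config$dominance_boost * (pats %in% config$dominant_pathogens)
  z_global <- matrix(stats::rnorm(np * nc), np, nc) + boost
  out <- lapply(names(config$regions), function(rg) {
    z <- sqrt(config$rho) * z_global +
      sqrt(1 - config$rho) * (matrix(stats::rnorm(np * nc), np, nc) + boost)
    lv <- apply(z, 2, function(col) {
      r <- rank(col, ties.method = "min")
      as.integer(floor((r - 1) * scheme$n_levels / np) + 1)
    })
    dimnames(lv) <- list(pats, scheme$criteria)
    prov <- matrix("regional_data", np, nc, dimnames = dimnames(lv))
    qual <- scheme$criteria[-(1:3)]
    prov[, qual] <- ifelse(matrix(stats::runif(np * length(qual)), np) < 0.3,
                           "inferred", "regional_data")
    if ("Cytomegalovirus" %in% pats)
      prov["Cytomegalovirus", scheme$criteria[1:3]] <- "preliminary"
    score_matrix(lv, region = rg, provenance = prov, scheme = scheme)
  })
  names(out) <- names(config$regions)
  out
}

#' Simulate a complete synthetic study
#'
#' Draws the respondent population, regional score matrices, completion,
#' duplicate and straight-liner contamination, and runs the elicitation
#' engine for every submission that survives the exclusion rules (the
#' excluded submissions contribute covariates and flags, which is all the
#' downstream analysis reads from them).
#'
#' @param config a [generator_config()].
#' @return A `synthetic_study` list: `config`, `respondents` (covariates,
#'   truth, cluster, completion_prob), `responses` (one row per
#'   submission, with `respondent_hash`, `complete`, `straight_lined`),
#'   `sessions` (completed `paprika_session` per analysed respondent id),
#'   `score_matrices`.
#' @export
simulate_study <- function(config = generator_config()) {
  set.seed(config$seed)
  pop <- sample_respondents(config)
  score_matrices <- sample_score_matrices(config)
  n <- config$n_respondents
  completed <- stats::runif(n) < pop$completion_prob
  straight <- completed & (stats::runif(n) < config$straightline_rate)
  duplicated_sub <- completed & (stats::runif(n) < config$duplicate_rate)

  rows <- pop$covariates
  rows$respondent_hash <- rows$respondent_id
  rows$complete <- completed
  rows$straight_lined <- straight
  extra <- rows[duplicated_sub, , drop = FALSE]      # second submissions
  responses <- rbind(rows, extra)
  responses <- responses[order(match(responses$respondent_hash,
                                     rows$respondent_hash)), , drop = FALSE]
  rownames(responses) <- NULL

  analysed_ids <- rows$respondent_id[completed & !straight]
  sessions <- lapply(which(completed & !straight), function(i) {
    simulate_session(pop$truth[[i]], epsilon = config$choice_error,
                     allow_indifference = config$allow_indifference)
  })
  names(sessions) <- analysed_ids
  structure(
    list(config = config, respondents = pop, responses = responses,
         sessions = sessions, score_matrices = score_matrices),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study: seed", x$config$seed, "-",
      nrow(x$responses), "submissions,",
      sum(x$responses$complete), "complete,",
      length(x$sessions), "sessions run\n")
  invisible(x)
}
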