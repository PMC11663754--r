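#' Composite indicator of respondent weights
#'
#' To avoid collinearity among the full set of level values, clustering
#' works on a PCA composite built from each respondent's point values at
#' the Medium and Very high levels of every criterion (16 features for the
#' default 8-criterion scheme). Features are standardised, decomposed, and
#' the smallest leading set of components whose cumulative explained
#' variance reaches the target (default 80 percent) is retained.
#'
#' @param value_systems list of [value_system()] objects (>= 3).
#' @param var_target cumulative explained-variance threshold.
#' @return An object of class `composite_indicator`: `scores` (respondents
#'   x retained components, centred), `explained` (per-component variance
#'   ratios), `n_components`, `features` (the raw feature matrix),
#'   `dropped` (zero-variance features removed).
#' @export
build_composite <- function(value_systems, var_target = 0.80) {
  if (length(value_systems) < 3L) stop("need at least 3 respondents")
  scheme <- value_systems[[1]]$scheme
  L <- scheme$n_levels
  med <- as.integer(ceiling(L / 2))            # "Medium" on the 5-level scale
  feats <- t(vapply(value_systems, function(v)
    c(v$values[, med], v$values[, L]), numeric(2L * n_criteria(scheme))))
  colnames(feats) <- c(paste0(scheme$criteria, ".medium"),
                       paste0(scheme$criteria, ".very_high"))
  sds <- apply(feats, 2, stats::sd)
  dropped <- colnames(feats)[sds < 1e-12]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ", paste(dropped, collapse = ", "))
    feats_use <- feats[, sds >= 1e-12, drop = FALSE]
  } else {
    feats_use <- feats
  }
  pca <- stats::prcomp(feats_use, center = TRUE, scale. = TRUE)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  m <- which(cumsum(expl) >= var_target - 1e-12)[1]
  structure(
    list(scores = pca$x[, seq_len(m), drop = FALSE], explained = expl,
         n_components = m, features = feats, dropped = dropped, pca = pca),
    class = "composite_indicator"
  )
}

#' @export
print.composite_indicator <- function(x, ...) {
  cat("Composite indicator:", x$n_components, "components retained (",
      round(100 * sum(x$explained[seq_len(x$n_components)]), 1),
      "% of variance)\n")
  invisible(x)
}

# Calinski-Harabasz pseudo-F and Davies-Bouldin index for a k-means fit
ch_index <- function(km, n) {
  k <- nrow(km$centers)
  (km$betweenss / (k - 1)) / (km$tot.withinss / (n - k))
}
db_index <- function(x, km) {
  k <- nrow(km$centers)
  s <- vapply(seq_len(k), function(c) {
    pts <- x[km$cluster == c, , drop = FALSE]
    if (!nrow(pts)) return(0)
    mean(sqrt(rowSums((pts - matrix(km$centers[c, ], nrow(pts),
                                    ncol(x), byrow = TRUE))^2)))
  }, numeric(1))
  d <- as.matrix(stats::dist(km$centers))
  mean(vapply(seq_len(k), function(ci) {
    max(vapply(setdiff(seq_len(k), ci), function(cj)
      (s[ci] + s[cj]) / d[ci, cj], numeric(1)))
  }, numeric(1)))
}

#' Choose the number of clusters by consensus
#'
#' Runs k-means (multiple restarts, fixed seed) for every candidate k and
#' collects four votes: the elbow of the within-cluster sum-of-squares
#' curve (maximum discrete curvature), the maximum mean silhouette width,
#' the gap statistic (uniform reference over the score bounding box,
#' first-SE-max rule), and an index battery vote summarising the
#' Calinski-Harabasz and Davies-Bouldin optima. The consensus k is the mode
#' of the four votes, smaller k on ties. If the gap statistic prefers a
#' k below the candidate range (a single homogeneous cloud), its vote is
#' clamped to the smallest candidate and annotated.
#'
#' @param scores matrix of composite scores (respondents x components).
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed RNG seed for restarts and the gap reference draws.
#' @param nstart k-means restarts per k.
#' @param gap_B number of uniform reference draws for the gap statistic.
#' @return An object of class `cluster_model`: consensus `k`,
#'   `assignments`, `centroids`, per-k `diagnostics`, and the `votes`
#'   decision record.
#' @export
choose_k <- function(scores, k_range = 2:10, seed = 1L, nstart = 25L,
                     gap_B = 50L) {
  x <- as.matrix(scores)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 observations to cluster")
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2L || max(k_range) > min(25L, n - 1L))
    stop("k_range must lie within 2..min(25, n-1)")

  set.seed(seed)
  kfit <- function(k) stats::kmeans(x, centers = k, nstart = nstart,
                                    iter.max = 100L)
  kseq <- seq(max(1L, min(k_range) - 1L), min(n - 1L, max(k_range) + 1L))
  fits <- lapply(kseq, function(k) {
    if (k == 1L) NULL else kfit(k)
  })
  names(fits) <- kseq
  wss <- vapply(seq_along(kseq), function(ii) {
    if (kseq[ii] == 1L) sum(scale(x, scale = FALSE)^2) else fits[[ii]]$tot.withinss
  }, numeric(1))

  dmat <- stats::dist(x)
  in_range <- kseq %in% k_range
  sil <- rep(NA_real_, length(kseq))
  ch <- rep(NA_real_, length(kseq))
  db <- rep(NA_real_, length(kseq))
  for (ii in which(in_range)) {
    km <- fits[[ii]]
    sil[ii] <- mean(cluster::silhouette(km$cluster, dmat)[, 3])
    ch[ii] <- ch_index(km, n)
    db[ii] <- db_index(x, km)
  }

  # elbow: maximum discrete curvature of the WSS curve inside the range
  curv <- rep(NA_real_, length(kseq))
  for (ii in seq_along(kseq)) {
    if (ii > 1L && ii < length(kseq) && in_range[ii])
      curv[ii] <- wss[ii - 1L] - 2 * wss[ii] + wss[ii + 1L]
  }
  vote_elbow <- kseq[in_range][which.max(curv[in_range])]
  vote_sil <- kseq[in_range][which.max(sil[in_range])]

  set.seed(seed + 1L)
  gap_fun <- function(x, k, ...) stats::kmeans(x, centers = k, nstart = nstart,
                                               iter.max = 100L)
  gap <- cluster::clusGap(x, FUNcluster = gap_fun, K.max = max(k_range),
                          B = gap_B, spaceH0 = "original", verbose = FALSE)
  gtab <- gap$Tab
  gk <- cluster::maxSE(gtab[, "gap"], gtab[, "SE.sim"], method = "firstSEmax")
  gap_clamped <- gk < min(k_range)
  vote_gap <- max(gk, min(k_range))

  vote_ch <- kseq[in_range][which.max(ch[in_range])]
  vote_db <- kseq[in_range][which.min(db[in_range])]
  vote_battery <- if (vote_ch == vote_db) vote_ch else min(vote_ch, vote_db)

  votes <- c(elbow = vote_elbow, silhouette = vote_sil, gap = vote_gap,
             battery = vote_battery)
  tab <- table(votes)
  consensus <- min(as.integer(names(tab)[tab == max(tab)]))

  final <- fits[[as.character(consensus)]]
  structure(
    list(k = consensus, assignments = final$cluster, centroids = final$centers,
         diagnostics = data.frame(k = kseq, wss = wss, silhouette = sil,
                                  gap = c(gtab[kseq[kseq <= max(k_range)], "gap"],
                                          rep(NA, sum(kseq > max(k_range)))),
                                  ch = ch, db = db),
         votes = votes, gap_clamped = gap_clamped, seed = seed),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Cluster model: consensus k =", x$k, "\n")
  cat("  votes:", paste(names(x$votes), x$votes, sep = "=", collapse = ", "),
      if (x$gap_clamped) "(gap vote clamped to smallest candidate)", "\n")
  cat("  sizes:", paste(table(x$assignments), collapse = "/"), "\n")
  invisible(x)
}

#' Describe clusters by their dominant criteria
#'
#' Downstream reports identify clusters by weight profile, not by index
#' (k-means labels are permutation-arbitrary). For each cluster this gives
#' the mean criterion weights of its members and the top two criteria.
#'
#' @param assignments integer cluster labels.
#' @param value_systems the corresponding list of [value_system()] objects.
#' @return Data frame: cluster, size, share, dominant criteria, and one
#'   column of mean weight per criterion.
#' @export
cluster_weight_profiles <- function(assignments, value_systems) {
  scheme <- value_systems[[1]]$scheme
  W <- t(vapply(value_systems, function(v) unname(v$weights),
                numeric(n_criteria(scheme))))
  colnames(W) <- scheme$criteria
  out <- do.call(rbind, lapply(sort(unique(assignments)), function(cl) {
    m <- colMeans(W[assignments == cl, , drop = FALSE])
    top <- names(sort(m, decreasing = TRUE))[1:2]
    cbind(data.frame(cluster = cl, size = sum(assignments == cl),
                     share = mean(assignments == cl),
                     dominant = paste(top, collapse = "+"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(m)))
  }))
  rownames(out) <- NULL
  out
}

#' Logistic model of cluster membership
#'
#' Fits a binomial GLM with logit link (iteratively reweighted least
#' squares via [stats::glm()]) of membership in the target cluster on
#' respondent covariates, reporting odds ratios with Wald 95 percent
#' confidence intervals. Perfect separation is detected and the affected
#' coefficients reported as non-estimable; aliased (collinear) terms are
#' dropped and listed.
#'
#' @param assignments two-cluster integer labels.
#' @param covariates data frame of respondent covariates (factors or
#'   numerics; factor reference levels are the model's references).
#' @param target_cluster the cluster whose membership odds are modelled
#'   (default the higher label).
#' @return An object of class `membership_model`: `table` (term, or,
#'   ci_low, ci_high, p, estimable), `aliased`, `separation`, `fit`.
#' @export
fit_membership_glm <- function(assignments, covariates,
                               target_cluster = max(assignments)) {
  labs <- sort(unique(assignments))
  if (length(labs) != 2L) stop("membership model requires two clusters")
  if (anyNA(covariates)) stop("covariates must be complete")
  y <- as.integer(assignments == target_cluster)
  dat <- cbind(data.frame(.member = y), covariates)
  fit <- suppressWarnings(stats::glm(.member ~ ., data = dat, family = stats::binomial()))
  co <- summary(fit)$coefficients
  aliased <- names(which(is.na(stats::coef(fit))))
  mu <- stats::fitted(fit)
  separation <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8) ||
    any(co[, "Std. Error"] > 1e3)
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  estimable <- se <= 1e3
  tab <- data.frame(
    term = rownames(co),
    or = exp(est), ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
    p = co[, 4], estimable = estimable, stringsAsFactors = FALSE
  )
  tab[!tab$estimable, c("or", "ci_low", "ci_high", "p")] <- NA_real_
  rownames(tab) <- NULL
  structure(list(table = tab, aliased = aliased, separation = separation,
                 target_cluster = target_cluster, fit = fit),
            class = "membership_model")
}

#' @export
print.membership_model <- function(x, ...) {
  cat("Cluster membership model (odds of cluster", x$target_cluster, ")\n")
  if (x$separation) cat("  WARNING: separation detected; some terms non-estimable\n")
  print(cbind(x$table[, "term", drop = FALSE],
              round(x$table[, c("or", "ci_low", "ci_high")], 3)))
  invisible(x)
}

#' Power of the continuity-corrected two-proportion test
#'
#' Fleiss-style normal approximation with continuity correction for a
#' two-sided two-sample comparison of proportions.
#'
#' @param p1 proportion in the index group (size `n1`).
#' @param p0 proportion in the reference group (size `n2`).
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
power_two_proportions <- function(p1, p0, n1, n2, alpha = 0.05) {
  d <- abs(p1 - p0)
  cc <- (1 / n1 + 1 / n2) / 2
  pbar <- (n1 * p1 + n2 * p0) / (n1 + n2)
  s0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  s1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n2)
  stats::pnorm((d - cc - stats::qnorm(1 - alpha / 2) * s0) / s1)
}

#' Minimum detectable odds ratio for cluster membership
#'
#' Given two cluster sizes and the baseline prevalence of a background
#' characteristic, finds by bisection the comparison-group prevalences
#' (one above, one below baseline) at which the continuity-corrected
#' two-proportion test attains the stated power, and converts them to odds
#' ratios against the baseline odds. Effects inside (or_low, or_high) are
#' too small for the design to detect reliably.
#'
#' @param n1 size of the index cluster.
#' @param n2 size of the reference cluster.
#' @param p0 baseline characteristic prevalence (in the reference cluster).
#' @param power target power.
#' @param alpha two-sided significance level.
#' @param tol bisection tolerance on the prevalence.
#' @return Named numeric vector `c(or_low, or_high)`. A side is `NA` (with
#'   a warning) when no prevalence in (0, 1) attains the target power on
#'   that side of the baseline, i.e. the groups are too small to detect
#'   even the most extreme shift in that direction.
#' @examples
#' min_detectable_or(95, 178, 0.15)   # about (0.213, 2.475)
#' @export
min_detectable_or <- function(n1, n2, p0, power = 0.80, alpha = 0.05,
                              tol = 1e-6) {
  stopifnot(p0 > 0, p0 < 1, power > 0, power < 1, alpha > 0, alpha < 1)
  f <- function(p) power_two_proportions(p, p0, n1, n2, alpha) - power
  bisect <- function(lo, hi, side) {
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
      warning("no detectable prevalence ", side, " the baseline at the ",
              "stated power; groups too small")
      return(NA_real_)
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) * flo <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  eps <- 1e-9
  p_hi <- bisect(p0 + eps, 1 - eps, "above")  # power increases away from p0
  p_lo <- bisect(eps, p0 - eps, "below")
  odds <- function(p) p / (1 - p)
  c(or_low = odds(p_lo) / odds(p0), or_high = odds(p_hi) / odds(p0))
}
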