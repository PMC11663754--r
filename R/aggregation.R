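#' Regional mean point values and criterion weights
#'
#' Regional criteria weights are the arithmetic means of individual
#' respondents' criterion weights; mean point values are averaged per
#' criterion and level, so level-spacing heterogeneity across respondents is
#' preserved in the aggregate. By linearity the means keep the sum-to-100
#' normalisation, and ranking pathogens by mean point values equals ranking
#' by the mean of per-respondent totals.
#'
#' @param value_systems list of [value_system()] objects on one scheme.
#' @param region optional region label carried into the result.
#' @return An object of class `regional_weights` with elements `values`
#'   (mean point-value matrix), `weights`, `weight_sd`, `n`, `region`,
#'   `scheme`; usable wherever a [value_system()] is (e.g.
#'   [rank_alternatives()]).
#' @export
regional_mean_weights <- function(value_systems, region = NA_character_) {
  if (!length(value_systems)) stop("no value systems supplied")
  scheme <- value_systems[[1]]$scheme
  ok <- vapply(value_systems, function(v)
    identical(v$scheme$criteria, scheme$criteria) &&
      v$scheme$n_levels == scheme$n_levels, logical(1))
  if (!all(ok)) stop("value systems are on different schemes")
  arr <- simplify2array(lapply(value_systems, function(v) v$values))
  mv <- apply(arr, c(1, 2), mean)
  W <- vapply(value_systems, function(v) unname(v$weights), numeric(n_criteria(scheme)))
  sds <- if (length(value_systems) > 1L) apply(W, 1, stats::sd) else rep(0, nrow(W))
  structure(
    list(values = mv, weights = mv[, scheme$n_levels],
         weight_sd = stats::setNames(sds, scheme$criteria),
         n = length(value_systems), region = region, scheme = scheme),
    class = c("regional_weights", "value_system")
  )
}

#' @export
print.regional_weights <- function(x, ...) {
  cat("Regional weights", if (!is.na(x$region)) paste0("(", x$region, ")"),
      "- n =", x$n, "respondents\n")
  tab <- cbind(mean = round(x$weights, 2), sd = round(x$weight_sd, 2))
  print(tab)
  invisible(x)
}

#' Regional top-k priority list
#'
#' Ranks the region's pathogens by total weight under the regional mean
#' point values and truncates to the `k` highest. Pathogens tied with the
#' pathogen at rank `k` are all included and annotated, rather than broken
#' arbitrarily.
#'
#' @param regional_weights a [regional_mean_weights()] result (or any
#'   [value_system()]).
#' @param score_matrix the region's [score_matrix()].
#' @param k list size (default 10).
#' @return A `priority_list` data frame with an `in_top_k` column.
#' @export
regional_top_k <- function(regional_weights, score_matrix, k = 10L) {
  if (k > nrow(score_matrix$scores))
    stop("k exceeds the number of pathogens")
  pl <- rank_alternatives(regional_weights, score_matrix)
  cut <- pl$total_weight[order(-pl$total_weight)][k]
  pl$in_top_k <- round(pl$total_weight, 9) >= round(cut, 9)
  attr(pl, "k") <- as.integer(k)
  attr(pl, "region") <- score_matrix$region
  pl
}

#' Combine regional top-k lists into the global priority list
#'
#' The global list is the union of the regional top-k lists. Each pathogen
#' carries the set of regions where it is top-k; the list is ordered by
#' number of regions (descending), then best regional rank (ascending),
#' then name.
#'
#' @param regional_lists named list of [regional_top_k()] results (names =
#'   regions, or taken from the lists' region attribute).
#' @return A `global_list` data frame (pathogen, region_count, regions,
#'   best_rank).
#' @export
build_global_list <- function(regional_lists) {
  if (!length(regional_lists)) stop("no regional lists supplied")
  if (is.null(names(regional_lists)) || any(!nzchar(names(regional_lists)))) {
    names(regional_lists) <- vapply(regional_lists, function(l)
      as.character(attr(l, "region")), character(1))
  }
  rows <- do.call(rbind, lapply(names(regional_lists), function(rg) {
    l <- regional_lists[[rg]]
    kept <- l[l$in_top_k, , drop = FALSE]
    data.frame(region = rg, pathogen = kept$pathogen, rank = kept$rank,
               stringsAsFactors = FALSE)
  }))
  agg <- lapply(split(rows, rows$pathogen), function(d) {
    data.frame(pathogen = d$pathogen[1],
               region_count = length(unique(d$region)),
               regions = paste(sort(unique(d$region)), collapse = ";"),
               best_rank = min(d$rank), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(-out$region_count, out$best_rank, out$pathogen), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("global_list", "data.frame")
  out
}

#' Criterion-omission robustness of the global list
#'
#' Recomputes the whole pipeline omitting one criterion at a time: the
#' omitted criterion's additive contribution is simply removed (no
#' renormalisation -- rankings are scale-free, so renormalising cannot
#' change the order) and regional top-k lists and the global list are
#' rebuilt. The report gives, per omitted criterion, the pathogens dropped
#' from and added to the baseline global list.
#'
#' @param regional_weights_by_region named list of
#'   [regional_mean_weights()], one per region.
#' @param score_matrices named list of [score_matrix()], same regions.
#' @param k regional list size.
#' @return A list with `baseline` (the [build_global_list()] result) and
#'   `deltas`, a data frame (omitted_criterion, dropped, added).
#' @export
robustness_leave_one_out <- function(regional_weights_by_region,
                                     score_matrices, k = 10L) {
  scheme <- regional_weights_by_region[[1]]$scheme
  if (n_criteria(scheme) < 2L) stop("need at least 2 criteria")
  regions <- names(regional_weights_by_region)
  global_for <- function(drop_crit) {
    lists <- lapply(regions, function(rg) {
      rw <- regional_weights_by_region[[rg]]
      if (!is.null(drop_crit)) {
        rw$values[match(drop_crit, scheme$criteria), ] <- 0
      }
      regional_top_k(rw, score_matrices[[rg]], k = k)
    })
    names(lists) <- regions
    build_global_list(lists)
  }
  baseline <- global_for(NULL)
  deltas <- do.call(rbind, lapply(scheme$criteria, function(cr) {
    g <- global_for(cr)
    data.frame(
      omitted_criterion = cr,
      dropped = paste(sort(setdiff(baseline$pathogen, g$pathogen)), collapse = ";"),
      added = paste(sort(setdiff(g$pathogen, baseline$pathogen)), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  list(baseline = baseline, deltas = deltas)
}

#' Recompute the global list from a subset of respondents
#'
#' Runs the baseline aggregation pipeline restricted to a subset of value
#' systems (e.g. the members of one response cluster), as in the cluster
#' sensitivity analysis.
#'
#' @param value_systems_by_region named list (region -> list of
#'   [value_system()]) for the subset.
#' @param score_matrices named list of [score_matrix()] per region.
#' @param k regional list size.
#' @return A [build_global_list()] result.
#' @export
subset_reanalysis <- function(value_systems_by_region, score_matrices, k = 10L) {
  keep <- vapply(value_systems_by_region, length, integer(1)) > 0L
  value_systems_by_region <- value_systems_by_region[keep]
  if (!length(value_systems_by_region)) stop("empty respondent subset")
  lists <- lapply(names(value_systems_by_region), function(rg) {
    rw <- regional_mean_weights(value_systems_by_region[[rg]], region = rg)
    regional_top_k(rw, score_matrices[[rg]], k = k)
  })
  names(lists) <- names(value_systems_by_region)
  build_global_list(lists)
}
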