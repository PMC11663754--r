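#' Analysis settings for an end-to-end study run
#'
#' Collects everything [run_study()] needs: the synthetic-study generator
#' settings, the regional list size, the candidate cluster range, the
#' covariates entering the regression models, and the power-calculation
#' settings. Can be loaded from a YAML or JSON document with
#' [read_study_config()].
#'
#' @param seed master seed; also seeds the generator unless a custom
#'   `generator` is given.
#' @param k regional top-k size.
#' @param k_range candidate numbers of clusters.
#' @param power_p0 baseline characteristic prevalence for the minimum
#'   detectable odds ratio.
#' @param power,alpha power-calculation settings.
#' @param covariates covariate columns used in the membership, adjusted
#'   mean difference and completion models.
#' @param generator a [generator_config()].
#' @return A `study_config` list.
#' @export
study_config <- function(seed = 1L, k = 10L, k_range = 2:10,
                         power_p0 = 0.15, power = 0.80, alpha = 0.05,
                         covariates = c("region", "experience", "gavi",
                                        "income", "exp_epidemiology",
                                        "exp_vaccine_rd", "exp_health_policy",
                                        "exp_clinical", "exp_regulatory",
                                        "exp_manufacturing"),
                         generator = generator_config(seed = seed)) {
  structure(list(seed = as.integer(seed), k = as.integer(k),
                 k_range = as.integer(k_range), power_p0 = power_p0,
                 power = power, alpha = alpha, covariates = covariates,
                 generator = generator),
            class = "study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [study_config()]; keys under
#' `generator` mirror [generator_config()]. Omitted keys keep their
#' defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  gen_args <- raw$generator
  raw$generator <- NULL
  top <- raw[intersect(names(raw), names(formals(study_config)))]
  cfg <- do.call(study_config, top)
  if (length(gen_args)) {
    gen_args <- gen_args[intersect(names(gen_args), names(formals(generator_config)))]
    if (is.null(gen_args$seed)) gen_args$seed <- cfg$seed
    cfg$generator <- do.call(generator_config, gen_args)
  }
  cfg
}

# factor covariates with the models' reference levels
model_covariates <- function(cov, which) {
  out <- cov[, intersect(which, names(cov)), drop = FALSE]
  relevel_if <- function(col, ref) {
    f <- factor(col)
    if (ref %in% levels(f)) stats::relevel(f, ref) else f
  }
  if ("region" %in% names(out)) out$region <- relevel_if(out$region, "AFR")
  if ("experience" %in% names(out)) out$experience <- relevel_if(out$experience, "<=10")
  if ("income" %in% names(out)) out$income <- relevel_if(out$income, "high")
  if ("language" %in% names(out)) out$language <- relevel_if(out$language, "English")
  out
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full prioritisation analysis on a synthetic study
#'
#' Executes the pipeline end to end: response exclusions, value solving
#' per analysed respondent, regional mean weights, regional top-k lists,
#' the global priority list, criterion-omission robustness, the PCA
#' composite and consensus clustering, the cluster membership model and
#' minimum detectable odds ratio, adjusted mean differences in weights,
#' and the completion-bias GEE. Results are returned as a `study_report`
#' and optionally written out as CSV/JSON artefacts plus a run manifest.
#'
#' @param config a [study_config()].
#' @param study optionally, a pre-generated [simulate_study()] result (its
#'   generator settings then take precedence).
#' @param out_dir if non-NULL, directory to write the report bundle to.
#' @param quiet suppress per-stage count logging.
#' @return A `study_report` list; see the elements of the return value.
#' @export
run_study <- function(config = study_config(), study = NULL, out_dir = NULL,
                      quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  panel <- if (is.null(study)) config$generator$pathogens else
    study$config$pathogens
  if (config$k > length(panel))
    stop("[stage validate] k exceeds the pathogen panel size")
  if (is.null(study)) {
    study <- with_stage("simulate", simulate_study(config$generator))
  }
  say("stage simulate: ", nrow(study$responses), " submissions")

  excl <- with_stage("exclusions", apply_exclusions(study$responses))
  rep_x <- excl$report
  say("stage exclusions: received ", rep_x$received, ", complete ",
      rep_x$complete, ", analysed ", rep_x$analysed)

  ids <- intersect(excl$analysed$respondent_id, names(study$sessions))
  vsys <- with_stage("values",
                     lapply(study$sessions[ids], solve_values))
  cov <- excl$analysed[match(ids, excl$analysed$respondent_id), , drop = FALSE]
  say("stage values: ", length(vsys), " value systems solved")

  by_region <- split(seq_along(ids), cov$region)
  regional <- with_stage("aggregate", {
    rw <- lapply(names(by_region), function(rg)
      regional_mean_weights(vsys[by_region[[rg]]], region = rg))
    names(rw) <- names(by_region)
    rw
  })
  top <- with_stage("aggregate", {
    l <- lapply(names(regional), function(rg)
      regional_top_k(regional[[rg]], study$score_matrices[[rg]], k = config$k))
    names(l) <- names(regional)
    l
  })
  global <- with_stage("aggregate", build_global_list(top))
  robust <- with_stage("robustness",
                       robustness_leave_one_out(regional, study$score_matrices,
                                                k = config$k))
  say("stage aggregate: global list of ", nrow(global), " pathogens")

  composite <- with_stage("cluster", build_composite(vsys))
  clusters <- with_stage("cluster",
                         choose_k(composite$scores, k_range = config$k_range,
                                  seed = config$seed))
  profiles <- with_stage("cluster",
                         cluster_weight_profiles(clusters$assignments, vsys))
  say("stage cluster: consensus k = ", clusters$k)

  mcov <- model_covariates(cov, config$covariates)
  membership <- NULL; power_bounds <- NULL
  if (clusters$k == 2L) {
    sizes <- sort(table(clusters$assignments))
    membership <- with_stage("membership",
                             fit_membership_glm(clusters$assignments, mcov))
    power_bounds <- with_stage("power",
                               min_detectable_or(n1 = sizes[[1]], n2 = sizes[[2]],
                                                 p0 = config$power_p0,
                                                 power = config$power,
                                                 alpha = config$alpha))
  }

  W <- t(vapply(vsys, function(v) unname(v$weights),
                numeric(n_criteria(vsys[[1]]$scheme))))
  colnames(W) <- vsys[[1]]$scheme$criteria
  amd <- with_stage("amd", adjusted_mean_differences(W, mcov))

  all_cov <- model_covariates(study$responses, config$covariates)
  gee <- with_stage("completion",
                    completion_bias_gee(study$responses$complete, all_cov,
                                        id = study$responses$respondent_hash))

  manifest <- list(
    package_version = as.character(utils::packageVersion("vaxmcda")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = config_hash(config),
    counts = list(received = rep_x$received, complete = rep_x$complete,
                  invalid = rep_x$invalid, analysed = rep_x$analysed,
                  regions = as.list(table(cov$region)),
                  consensus_k = clusters$k)
  )

  report <- structure(
    list(config = config, exclusions = rep_x, value_systems = vsys,
         respondents = cov, regional_weights = regional,
         regional_lists = top, global_list = global, robustness = robust,
         composite = composite, clusters = clusters, profiles = profiles,
         membership = membership, power_bounds = power_bounds,
         adjusted_differences = amd, completion_bias = gee,
         manifest = manifest),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_report_bundle(report, out_dir)
  report
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' @export
print.study_report <- function(x, ...) {
  print(x$exclusions)
  cat("Global priority list (", nrow(x$global_list), " pathogens):\n", sep = "")
  print(utils::head(x$global_list, 20))
  cat("Consensus clusters: k =", x$clusters$k, "\n")
  if (!is.null(x$power_bounds))
    cat("Minimum detectable OR: ", round(x$power_bounds[1], 3), " to ",
        round(x$power_bounds[2], 3), "\n")
  invisible(x)
}

#' Write a study report bundle to disk
#'
#' Emits regional rankings, the global list, the robustness deltas,
#' cluster assignments and diagnostics, the membership model, the
#' exclusion report and the run manifest as plain CSV/JSON files.
#'
#' @param report a `study_report` from [run_study()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  regional <- do.call(rbind, lapply(names(report$regional_lists), function(rg) {
    l <- report$regional_lists[[rg]]
    data.frame(region = rg, pathogen = l$pathogen,
               total_weight = l$total_weight, rank = l$rank,
               in_top_k = l$in_top_k, stringsAsFactors = FALSE)
  }))
  utils::write.csv(regional, p("regional_rankings.csv"), row.names = FALSE)
  utils::write.csv(report$global_list, p("global_list.csv"), row.names = FALSE)
  jsonlite::write_json(report$robustness$deltas, p("robustness_deltas.json"),
                       dataframe = "rows")
  utils::write.csv(data.frame(respondent_id = rownames(report$respondents),
                              respondent = report$respondents$respondent_id,
                              cluster = report$clusters$assignments),
                   p("cluster_assignments.csv"), row.names = FALSE)
  jsonlite::write_json(list(votes = as.list(report$clusters$votes),
                            k = report$clusters$k,
                            diagnostics = report$clusters$diagnostics),
                       p("cluster_diagnostics.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$membership))
    utils::write.csv(report$membership$table, p("membership_model.csv"),
                     row.names = FALSE)
  jsonlite::write_json(unclass(report$exclusions), p("exclusion_report.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(report$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
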