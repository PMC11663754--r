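#' Default pathogen panel
#'
#' The 26 endemic pathogens evaluated in the prioritisation exercise.
#' @format Character vector of pathogen names.
#' @export
mcda_pathogens <- c(
  "Chikungunya virus", "Chlamydia trachomatis", "Cytomegalovirus",
  "Dengue virus", "ExPEC", "Group A streptococcus", "Group B streptococcus",
  "Hepatitis C virus", "Herpes simplex virus", "Hookworm", "HIV-1",
  "Influenza virus", "InPEC", "Klebsiella pneumoniae", "Leishmania species",
  "Mycobacterium leprae", "Mycobacterium tuberculosis", "Neisseria gonorrhoeae",
  "Non-typhoidal Salmonella", "Norovirus", "Plasmodium falciparum",
  "Respiratory syncytial virus", "Salmonella Paratyphi", "Schistosomes",
  "Shigella species", "Staphylococcus aureus"
)

provenance_codes <- c("regional_data", "inferred", "preliminary")

#' Regional pathogen score matrix
#'
#' Ordinal performance levels (1 = Very low .. 5 = Very high) of each
#' pathogen on each criterion for one region, with a provenance code per
#' cell recording whether the score rests on regional data, was inferred
#' from other regions, or is preliminary. Scores are comparative within a
#' region and must not be compared across regions. Provenance propagates
#' into downstream reports but never changes arithmetic.
#'
#' @param scores integer matrix, pathogens x criteria, levels in
#'   `1..scheme$n_levels`; dimnames give pathogen and criterion names.
#' @param region region identifier.
#' @param provenance character matrix matching `scores`
#'   (`"regional_data"`, `"inferred"`, `"preliminary"`); defaults to
#'   `"regional_data"` everywhere.
#' @param scheme the [criterion_scheme()].
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(scores, region, provenance = NULL,
                         scheme = criterion_scheme()) {
  stopifnot_scheme(scheme)
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (is.null(rownames(scores))) stop("scores must have pathogen rownames")
  if (is.null(colnames(scores))) colnames(scores) <- scheme$criteria
  if (!identical(colnames(scores), scheme$criteria))
    stop("score columns must match the scheme's criteria")
  if (is.null(provenance)) {
    provenance <- matrix("regional_data", nrow(scores), ncol(scores),
                         dimnames = dimnames(scores))
  }
  provenance <- as.matrix(provenance)
  dimnames(provenance) <- dimnames(scores)
  structure(list(region = region, scores = scores, provenance = provenance,
                 scheme = scheme),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("Score matrix, region", x$region, ":", nrow(x$scores), "pathogens x",
      ncol(x$scores), "criteria\n")
  prelim <- rownames(x$scores)[apply(x$provenance == "preliminary", 1, any)]
  if (length(prelim)) cat("  preliminary scores:", paste(prelim, collapse = ", "), "\n")
  invisible(x)
}

#' Map quantitative burden data onto ordinal levels
#'
#' Quantitative criteria (deaths under 5, deaths 5 plus, years lived with
#' disability) are scored comparatively: within a region, pathogens are
#' ranked on each burden measure and binned into `n_levels` rank-based
#' quantile levels. Tied burden values share the lower level, so identical
#' burdens always receive identical levels and zero burden maps to level 1.
#'
#' @param burden_table data frame with columns `pathogen`, `region`,
#'   `deaths_under5`, `deaths_5plus`, `ylds` (non-negative, finite).
#' @param region region to score.
#' @param n_levels number of ordinal levels (default 5).
#' @param scheme the [criterion_scheme()]; its first three criteria are
#'   taken as the quantitative ones, in the order above.
#' @return A partial [score_matrix()]: quantitative columns filled, the
#'   qualitative columns `NA` (they are input data scored against an
#'   external rubric, not computed).
#' @export
assign_quantitative_levels <- function(burden_table, region, n_levels = 5L,
                                       scheme = criterion_scheme()) {
  quant <- c("deaths_under5", "deaths_5plus", "ylds")
  bt <- burden_table[burden_table$region == region, , drop = FALSE]
  if (!nrow(bt)) stop("no burden rows for region ", region)
  if (anyDuplicated(bt$pathogen)) stop("duplicate pathogen in burden table")
  vals <- as.matrix(bt[, quant])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("burden values must be non-negative and finite")
  n <- nrow(bt)
  if (n < n_levels) stop("degenerate binning: fewer pathogens than levels")
  scores <- matrix(NA_integer_, n, n_criteria(scheme),
                   dimnames = list(bt$pathogen, scheme$criteria))
  for (cr in quant) {
    r <- rank(bt[[cr]], ties.method = "min")          # ties share the lower level
    scores[, cr] <- as.integer(floor((r - 1) * n_levels / n) + 1)
  }
  prov <- matrix(NA_character_, n, n_criteria(scheme),
                 dimnames = dimnames(scores))
  prov[, quant] <- "regional_data"
  score_matrix_partial(scores, region, prov, scheme)
}

# internal: like score_matrix() but tolerates NA cells (pre-validation state)
score_matrix_partial <- function(scores, region, provenance, scheme) {
  structure(list(region = region, scores = scores, provenance = provenance,
                 scheme = scheme),
            class = "score_matrix")
}

#' Validate a score matrix against a scheme
#'
#' @param matrix a [score_matrix()] (possibly partial or hand-edited).
#' @param scheme the [criterion_scheme()] to validate against.
#' @return A data frame of violations (pathogen, criterion, problem); zero
#'   rows iff the matrix is valid.
#' @export
validate_matrix <- function(matrix, scheme = criterion_scheme()) {
  sm <- matrix
  out <- data.frame(pathogen = character(), criterion = character(),
                    problem = character(), stringsAsFactors = FALSE)
  add <- function(p, cr, problem) {
    rbind(out, data.frame(pathogen = p, criterion = cr, problem = problem,
                          stringsAsFactors = FALSE))
  }
  sc <- sm$scores
  if (!identical(colnames(sc), scheme$criteria)) {
    return(add("*", "*", "criteria do not match scheme"))
  }
  for (p in rownames(sc)) for (cr in colnames(sc)) {
    v <- sc[p, cr]
    if (is.na(v)) {
      out <- add(p, cr, "missing cell")
    } else if (v < 1L || v > scheme$n_levels) {
      out <- add(p, cr, sprintf("level %d out of range 1..%d", v, scheme$n_levels))
    }
    pr <- sm$provenance[p, cr]
    if (is.na(pr) || !(pr %in% provenance_codes)) {
      out <- add(p, cr, "missing or unknown provenance")
    }
  }
  out
}

#' Write score matrices as CSV
#'
#' Wide layout: rows are pathogens, columns are criteria, cells are
#' `"level:provenance"`. Several regions are written long-form with a
#' leading region column.
#'
#' @param matrices a single [score_matrix()] or a list of them.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_score_matrices <- function(matrices, path) {
  if (inherits(matrices, "score_matrix")) matrices <- list(matrices)
  rows <- lapply(matrices, function(sm) {
    cells <- matrix(paste0(sm$scores, ":", sm$provenance),
                    nrow(sm$scores), ncol(sm$scores),
                    dimnames = dimnames(sm$scores))
    data.frame(region = sm$region, pathogen = rownames(sm$scores),
               cells, check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read score matrices written by [write_score_matrices()]
#' @param path CSV file.
#' @param scheme the [criterion_scheme()].
#' @return A named list of [score_matrix()] objects, one per region.
#' @export
read_score_matrices <- function(path, scheme = criterion_scheme()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$region), function(d) {
    cells <- as.matrix(d[, scheme$criteria, drop = FALSE])
    lv <- matrix(as.integer(sub(":.*$", "", cells)), nrow(cells),
                 dimnames = list(d$pathogen, scheme$criteria))
    pr <- matrix(sub("^[^:]*:", "", cells), nrow(cells),
                 dimnames = list(d$pathogen, scheme$criteria))
    score_matrix(lv, region = d$region[1], provenance = pr, scheme = scheme)
  })
  out[unique(df$region)]
}
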