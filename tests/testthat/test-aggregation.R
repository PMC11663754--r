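test_that("regional means preserve normalisation and equal hand means", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 3)
  v1 <- value_system(rbind(c(0, 20, 60), c(0, 10, 40)), sch)
  v2 <- value_system(rbind(c(0, 10, 40), c(0, 30, 60)), sch)
  rw <- regional_mean_weights(list(v1, v2), region = "AFR")
  expect_equal(unname(rw$weights), c(50, 50))
  expect_equal(unname(rw$values), unname((v1$values + v2$values) / 2))
  expect_equal(sum(rw$weights), 100)
  expect_equal(rw$n, 2L)
  expect_equal(unname(rw$weight_sd),
               c(stats::sd(c(60, 40)), stats::sd(c(40, 60))))
})

test_that("ranking by mean values equals ranking by mean of totals", {
  sch <- criterion_scheme(c("a", "b", "c"), n_levels = 3)
  vss <- lapply(1:6, random_value_system, scheme = sch)
  set.seed(8)
  sc <- matrix(sample(1:3, 30, TRUE), 10, 3,
               dimnames = list(paste0("p", 1:10), sch$criteria))
  sm <- score_matrix(sc, "AMR", scheme = sch)
  rw <- regional_mean_weights(vss, "AMR")
  by_mean <- rank_alternatives(rw, sm)
  totals <- rowMeans(vapply(vss, function(v)
    rank_alternatives(v, sm)$total_weight[
      match(paste0("p", 1:10), rank_alternatives(v, sm)$pathogen)],
    numeric(10)))
  expect_equal(by_mean$total_weight[match(paste0("p", 1:10), by_mean$pathogen)],
               unname(totals), tolerance = 1e-9)
})

test_that("regional top-k includes and annotates boundary ties", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 2)
  vs <- value_system(rbind(c(0, 50), c(0, 50)), sch)
  sc <- matrix(c(2L, 2L, 1L, 2L,
                 1L, 1L, 2L, 2L), ncol = 2,
               dimnames = list(paste0("p", 1:4), sch$criteria))
  sm <- score_matrix(sc, "EUR", scheme = sch)
  # totals: p1 = 50, p2 = 50, p3 = 50, p4 = 100; k = 2 ties all three 50s in
  pl <- regional_top_k(vs, sm, k = 2)
  expect_true(all(pl$in_top_k))
  expect_equal(sum(pl$in_top_k), 4L)
  expect_error(regional_top_k(vs, sm, k = 9), "exceeds")
})

test_that("global list ordering follows count, best rank, then name", {
  mk <- function(region, pathogens, ranks) {
    d <- data.frame(pathogen = pathogens, total_weight = 0, rank = ranks,
                    tied = FALSE, in_top_k = TRUE, stringsAsFactors = FALSE)
    attr(d, "region") <- region
    d
  }
  lists <- list(
    AFR = mk("AFR", c("x", "y"), c(1L, 2L)),
    AMR = mk("AMR", c("y", "z"), c(1L, 2L))
  )
  g <- build_global_list(lists)
  expect_equal(g$pathogen, c("y", "x", "z"))   # y in 2 regions; x rank 1 < z rank 2
  expect_equal(g$region_count, c(2L, 1L, 1L))
  expect_equal(g$regions[g$pathogen == "y"], "AFR;AMR")
  expect_equal(g$best_rank, c(1L, 1L, 2L))
})

test_that("leave-one-out robustness equals a column-zeroing oracle", {
  sch <- criterion_scheme(c("a", "b", "c"), n_levels = 3)
  set.seed(21)
  vss_by_region <- list(
    AFR = lapply(1:3, random_value_system, scheme = sch),
    AMR = lapply(4:6, random_value_system, scheme = sch)
  )
  sms <- lapply(c(AFR = "AFR", AMR = "AMR"), function(rg) {
    sc <- matrix(sample(1:3, 24, TRUE), 8, 3,
                 dimnames = list(paste0("p", 1:8), sch$criteria))
    score_matrix(sc, rg, scheme = sch)
  })
  rws <- lapply(names(vss_by_region), function(rg)
    regional_mean_weights(vss_by_region[[rg]], rg))
  names(rws) <- names(vss_by_region)
  rob <- robustness_leave_one_out(rws, sms, k = 3)
  expect_equal(nrow(rob$deltas), 3L)
  # oracle: zero the criterion's column in the mean value matrix by hand
  for (cr in sch$criteria) {
    lists <- lapply(names(rws), function(rg) {
      rw <- rws[[rg]]
      rw$values[match(cr, sch$criteria), ] <- 0
      regional_top_k(rw, sms[[rg]], k = 3)
    })
    names(lists) <- names(rws)
    g <- build_global_list(lists)
    d <- rob$deltas[rob$deltas$omitted_criterion == cr, ]
    drop_want <- paste(sort(setdiff(rob$baseline$pathogen, g$pathogen)),
                       collapse = ";")
    add_want <- paste(sort(setdiff(g$pathogen, rob$baseline$pathogen)),
                      collapse = ";")
    expect_identical(d$dropped, drop_want)
    expect_identical(d$added, add_want)
  }
})

test_that("subset reanalysis equals the pipeline run on the subset", {
  sch <- criterion_scheme(c("a", "b"), n_levels = 3)
  vss <- lapply(1:4, random_value_system, scheme = sch)
  sc <- matrix(c(1:3, 3:1), 3, 2, dimnames = list(paste0("p", 1:3),
                                                  sch$criteria))
  sms <- list(AFR = score_matrix(sc, "AFR", scheme = sch))
  g1 <- subset_reanalysis(list(AFR = vss[1:2]), sms, k = 2)
  rw <- regional_mean_weights(vss[1:2], "AFR")
  g2 <- build_global_list(list(AFR = regional_top_k(rw, sms$AFR, k = 2)))
  expect_identical(g1, g2)
  expect_error(subset_reanalysis(list(AFR = list()), sms, k = 2), "empty")
})

test_that("value systems on different schemes are refused", {
  a <- random_value_system(criterion_scheme(c("a", "b"), n_levels = 3), 1)
  b <- random_value_system(criterion_scheme(c("a", "c"), n_levels = 3), 2)
  expect_error(regional_mean_weights(list(a, b)), "different schemes")
})
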