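calls_ab <- tibble::tibble(
  participant_id = c("c1", "c2", "c3", "n1", "n2"),
  group = c("difficulty", "difficulty", "difficulty", "normal", "normal"),
  reason = NA_character_)

test_that("per-gene loads sum alleles or carriers by group", {
  v <- make_variants(2, gene_id = "GA")
  gt <- matrix(c(1L, 0L,   # c1
                 2L, 0L,   # c2
                 0L, 0L,   # c3
                 0L, 0L,   # n1
                 1L, 0L),  # n2
               nrow = 2, ncol = 5,
               dimnames = list(c("v01", "v02"),
                               c("c1", "c2", "c3", "n1", "n2")))
  loads <- per_gene_load(v, make_geno(gt), calls_ab,
                         counting_mode = "alleles")
  expect_equal(loads$load_case[loads$gene_id == "GA"], 3)
  expect_equal(loads$load_control[loads$gene_id == "GA"], 1)
  expect_equal(attr(loads, "n_case"), 3L)
  expect_equal(attr(loads, "n_control"), 2L)

  loads_c <- per_gene_load(v, make_geno(gt), calls_ab,
                           counting_mode = "carriers")
  expect_equal(loads_c$load_case[loads_c$gene_id == "GA"], 2)
  expect_equal(loads_c$load_control[loads_c$gene_id == "GA"], 1)

  # empty gene retained as a (0, 0) row via the universe
  loads_u <- per_gene_load(v, make_geno(gt), calls_ab,
                           universe = c("GA", "GB"))
  expect_equal(nrow(loads_u), 2)
  expect_equal(loads_u$load_case[loads_u$gene_id == "GB"], 0)

  # missing calls contribute zero
  gt_na <- gt; gt_na["v01", "c1"] <- NA_integer_
  loads_na <- per_gene_load(v, make_geno(gt_na), calls_ab)
  expect_equal(loads_na$load_case, 2)

  # unknown sample is an error
  gt_bad <- cbind(gt, xx = c(1L, 1L))
  expect_error(per_gene_load(v, make_geno(gt_bad), calls_ab),
               class = "hearload_validation_error")
})

test_that("load regression matches the closed form and lm oracle", {
  loads <- tibble::tibble(gene_id = c("a", "b", "c"),
                          load_control = c(1, 2, 3),
                          load_case = c(2, 4, 6))
  fit <- fit_load_regression(loads)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$data$residual, c(0, 0, 0))

  withr::local_seed(7)
  for (rep in 1:5) {
    loads <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                            load_control = rpois(100, 20),
                            load_case = rpois(100, 20) + rnorm(100))
    fit <- fit_load_regression(loads)
    oracle <- stats::lm(load_case ~ load_control, data = loads)
    expect_equal(fit$intercept, unname(coef(oracle)[1]),
                 tolerance = 1e-10)
    expect_equal(fit$slope, unname(coef(oracle)[2]), tolerance = 1e-10)
    expect_equal(fit$data$residual, unname(residuals(oracle)),
                 tolerance = 1e-10)
    # residuals of an OLS fit with intercept sum to zero
    expect_lt(abs(sum(fit$data$residual)) /
                max(1, sum(abs(fit$data$residual))), 1e-8)
  }

  # shift equivariance: adding c to case loads shifts only the intercept
  shifted <- dplyr::mutate(loads, load_case = load_case + 10)
  fit0 <- fit_load_regression(loads)
  fit1 <- fit_load_regression(shifted)
  expect_equal(fit1$intercept, fit0$intercept + 10)
  expect_equal(fit1$slope, fit0$slope)
  expect_equal(fit1$data$residual, fit0$data$residual)

  expect_error(fit_load_regression(loads[1:2, ]),
               class = "hearload_validation_error")
  expect_error(fit_load_regression(
    tibble::tibble(gene_id = c("a", "b", "c"), load_control = c(2, 2, 2),
                   load_case = c(1, 2, 3))),
    class = "hearload_validation_error")
})

test_that("outlier rule handles degenerate spreads and strict thresholds", {
  res <- detect_outliers(make_fit(c(rep(0, 100), 10)))
  expect_equal(res$d, 0)
  expect_equal(res$upper_threshold, 0)
  expect_equal(res$outliers_case, "g0101")
  expect_length(res$outliers_control, 0)

  # all residuals equal: strict inequality yields no outliers
  res <- detect_outliers(make_fit(rep(2.5, 50)))
  expect_length(res$outliers_case, 0)
  expect_length(res$outliers_control, 0)

  expect_error(detect_outliers(make_fit(rep(0, 10)), multiplier = -1),
               class = "hearload_validation_error")
  expect_error(detect_outliers(make_fit(c(1, 2, 3))),
               class = "hearload_validation_error")
})

test_that("outlier sets match a brute-force quantile oracle", {
  withr::local_seed(11)
  for (rep in 1:20) {
    r <- round(rnorm(20, sd = 5), 2)
    res <- detect_outliers(make_fit(r), multiplier = 6)
    q <- quantile(r, c(0.25, 0.75), type = 7, names = FALSE)
    up <- q[2] + 6 * (q[2] - q[1])
    lo <- q[1] - 6 * (q[2] - q[1])
    expect_setequal(res$outliers_case,
                    sprintf("g%04d", which(r > up)))
    expect_setequal(res$outliers_control,
                    sprintf("g%04d", which(r < lo)))
    expect_length(intersect(res$outliers_case, res$outliers_control), 0)
  }
})

test_that("scaling all loads by k scales thresholds but not outlier sets", {
  withr::local_seed(19)
  loads <- tibble::tibble(gene_id = sprintf("g%03d", 1:80),
                          load_control = rpois(80, 30),
                          load_case = rpois(80, 30))
  res1 <- detect_outliers(fit_load_regression(loads))
  loads_k <- dplyr::mutate(loads, load_control = load_control * 3,
                           load_case = load_case * 3)
  res3 <- detect_outliers(fit_load_regression(loads_k))
  expect_equal(res3$d, 3 * res1$d)
  expect_equal(res3$upper_threshold, 3 * res1$upper_threshold)
  expect_equal(res3$lower_threshold, 3 * res1$lower_threshold)
  expect_setequal(res3$outliers_case, res1$outliers_case)
  expect_setequal(res3$outliers_control, res1$outliers_control)
})

test_that("variant-type summary normalises per person and per gene", {
  v <- make_variants(2, gene_id = "GA")
  v$consequence <- c("missense_variant", "missense_variant&intron_variant")
  ten <- sprintf("p%02d", 1:10)
  calls <- tibble::tibble(participant_id = ten,
                          group = rep(c("difficulty", "normal"), c(10, 0)),
                          reason = NA_character_)
  gt <- matrix(0L, 2, 10, dimnames = list(c("v01", "v02"), ten))
  gt[1, 1:3] <- 1L  # 3 missense alleles among 10 people, 1-gene list
  s <- summarize_variant_types(v, make_geno(gt), calls,
                               list(case = "GA"))
  missense <- s[s$consequence == "missense_variant" &
                  s$group == "difficulty", ]
  expect_equal(missense$rate, 0.3)
  # the second variant's most severe class is still missense
  expect_false("intron_variant" %in% s$consequence)

  # duplicating every person leaves normalised values unchanged
  gt2 <- cbind(gt, gt)
  colnames(gt2) <- c(ten, sprintf("q%02d", 1:10))
  calls2 <- dplyr::bind_rows(calls,
                             dplyr::mutate(calls,
                                           participant_id = sprintf("q%02d", 1:10)))
  s2 <- summarize_variant_types(v, make_geno(gt2), calls2,
                                list(case = "GA"))
  expect_equal(s2$rate[s2$consequence == "missense_variant" &
                         s2$group == "difficulty"], 0.3)
  # empty list: empty summary, not an error
  expect_equal(nrow(summarize_variant_types(v, make_geno(gt), calls,
                                            list(none = character(0)))), 0)
})

test_that("stratified loads are additive and strata must be populated", {
  fx <- small_sim()
  v <- select_variants(fx$variants, "high", 0.1, qc = fx$qc)
  res <- stratified_load_outliers(v, fx$geno, fx$calls, fx$cohort,
                                  universe = fx$cfg$gene_universe)
  expect_named(res, c("all", "male", "female"))
  load_all <- res$all$data
  load_m <- res$male$data
  load_f <- res$female$data
  expect_equal(load_all$load_case, load_m$load_case + load_f$load_case)
  expect_equal(load_all$load_control,
               load_m$load_control + load_f$load_control)

  # a stratum left without participants errors
  male_only <- dplyr::filter(fx$cohort, sex == "male")
  male_calls <- dplyr::filter(fx$calls,
                              participant_id %in% male_only$participant_id)
  male_geno <- list(gt = fx$geno$gt[, intersect(colnames(fx$geno$gt),
                                                male_only$participant_id)])
  expect_error(stratified_load_outliers(v, male_geno, male_calls,
                                        male_only, strata = "female"),
               class = "hearload_validation_error")
})

test_that("sex-specific spiking is preferentially recovered by its stratum", {
  cfg <- sim_config(n_participants = 600, n_genes = 400,
                    mean_variants_per_gene = 30, n_spiked = 20,
                    sex_specific_spiking = TRUE, deafness_list_size = 60,
                    variable_list_size = 30, seed = 21)
  cohort <- simulate_cohort(cfg)
  calls <- classify_hearing(cohort)
  sim <- simulate_variants(cfg, cohort)
  geno <- mask_calls(sim$geno)
  v <- select_variants(classify_impact(add_max_external_maf(sim$variants)),
                       "high", 0.1, qc = site_qc(sim$variants, geno))
  res <- stratified_load_outliers(v, geno, calls, cohort,
                                  strata = c("male", "female"),
                                  universe = cfg$gene_universe)
  male_genes <- sim$truth$gene_id[sim$truth$spiked_sex == "male"]
  female_genes <- sim$truth$gene_id[sim$truth$spiked_sex == "female"]
  own_m <- length(intersect(res$male$outliers_case, male_genes))
  cross_m <- length(intersect(res$male$outliers_case, female_genes))
  own_f <- length(intersect(res$female$outliers_case, female_genes))
  cross_f <- length(intersect(res$female$outliers_case, male_genes))
  expect_gt(own_m, cross_m)
  expect_gt(own_f, cross_f)
})
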