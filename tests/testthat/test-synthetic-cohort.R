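test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_families = 300, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cohort_config(n_families = 300, seed = 43)
  expect_false(identical(generate_cohort(cfg2), a))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(mixing_proportions = c(.5, .4, .19, .23, .15)),
               "mixing_proportions")
  expect_error(cohort_config(residual_sd = rep(-1, 18)), "residual_sd")
  expect_error(cohort_config(weight_dispersion = 0), "weight_dispersion")
  expect_error(cohort_config(missing_outcome_rate = 1.2),
               "missing_outcome_rate")
  bad_prev <- c(depression = 0.07, bipolar = 0.08, anxiety = 1.38,
                ocd = 0.12, behavioral = 0.16, adhd = 0.21)
  expect_error(cohort_config(diagnosis_base_prevalence = bad_prev),
               "diagnosis_base_prevalence")
})

test_that("sampling weights are positive with mean one", {
  co <- generate_cohort(cohort_config(n_families = 500, seed = 3))
  expect_true(all(co$sampling_weight > 0))
  expect_equal(mean(co$sampling_weight), 1, tolerance = 1e-12)
})

test_that("diagnosis prevalence matches its configured base rate", {
  prev <- c(depression = 0.07, bipolar = 0.08, anxiety = 0.40,
            ocd = 0.12, behavioral = 0.16, adhd = 0.21)
  cfg <- cohort_config(n_families = 8000, prob_second_child = 0.25,
                       diagnosis_base_prevalence = prev,
                       diagnosis_class_logodds =
                         lapply(default_diagnosis_logodds(5),
                                function(v) rep(0, 5)),
                       seed = 7)
  co <- generate_cohort(cfg)
  expect_gt(nrow(co), 9000)
  expect_lt(abs(mean(co$anxiety) - 0.40), 0.02)
})

test_that("equal outcome effects leave no class signal in outcomes", {
  cfg <- cohort_config(n_families = 2500,
                       outcome_effects = null_outcome_effects(5),
                       missing_outcome_rate = 0, site_sd = 0, seed = 11)
  co <- generate_cohort(cfg)
  ps <- vapply(outcome_names(), function(o) {
    summary(stats::aov(co[[paste0(o, "_bl")]] ~
                         factor(co$true_class)))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  expect_gte(mean(ps > 0.01), 5 / 7)  # no systematic class-outcome link
})

test_that("marginal indicator covariance matches the mixture-implied one", {
  cfg <- cohort_config(n_families = 16500, prob_second_child = 0.25,
                       seed = 5)
  co <- generate_cohort(cfg)
  lay <- indicator_layout()
  rs <- brainprofiles:::roi_scale_table()
  Z <- sweep(sweep(as.matrix(co[, lay$indicator]), 2, rs$center),
             2, rs$scale, "/")
  p <- cfg$mixing_proportions
  M <- cfg$class_means
  gm <- colSums(p * M)
  Mc <- sweep(M, 2, gm)
  implied <- t(Mc) %*% (p * Mc) +
    outer(cfg$icv_loadings, cfg$icv_loadings) * var(co$icv) /
      cfg$icv_sd^2 +
    diag(cfg$residual_sd^2)
  emp <- cov(Z)
  expect_lt(max(abs(emp - implied)), 0.08)  # Monte-Carlo tolerance
})

test_that("zero ICV loadings decouple indicators from ICV", {
  cfg <- cohort_config(n_families = 8500, icv_loadings = rep(0, 18),
                       seed = 9)
  co <- generate_cohort(cfg)
  lay <- indicator_layout()
  r <- cor(as.matrix(co[, lay$indicator]), co$icv)
  expect_lt(max(abs(r)), 0.03)
})

test_that("one participant per family is kept, uniformly at random", {
  co <- generate_cohort(cohort_config(n_families = 400, seed = 2))
  one <- select_one_per_family(co, seed = 1)
  expect_equal(nrow(one), 400)
  expect_equal(anyDuplicated(one$family_id), 0)

  # singleton families pass through unchanged
  cfg1 <- cohort_config(n_families = 200, prob_second_child = 0,
                        seed = 4)
  co1 <- generate_cohort(cfg1)
  sel1 <- select_one_per_family(co1, seed = 8)
  expect_equal(sel1$subject_id, co1$subject_id)

  # two-child families: the first child is chosen about half the time
  cfg2 <- cohort_config(n_families = 100, prob_second_child = 1, seed = 6)
  co2 <- generate_cohort(cfg2)
  firstborn <- tapply(seq_len(nrow(co2)), co2$family_id, min)
  frac <- vapply(1:500, function(s) {
    sel <- select_one_per_family(co2, seed = s)
    mean(match(sel$subject_id, co2$subject_id) %in% firstborn)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.5), 0.05)

  expect_error(select_one_per_family(co[0, , drop = FALSE]), "empty")
})

test_that("follow-up scores correlate with baseline via the AR parameter", {
  cfg <- cohort_config(n_families = 4000, baseline_followup_cor = 0.55,
                       missing_outcome_rate = 0, floor_outcomes = FALSE,
                       seed = 12)
  co <- generate_cohort(cfg)
  r <- cor(co$internalizing_bl, co$internalizing_fu)
  expect_lt(abs(r - 0.55), 0.05)
})

test_that("cohort round-trips through CSV with config and manifest", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_families = 50, seed = 3)
  co <- generate_cohort(cfg)
  paths <- write_cohort(co, cfg, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["cohort"]])
  expect_equal(back$icv, co$icv, tolerance = 1e-12)
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$seed, 3)
})
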