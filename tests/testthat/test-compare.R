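test_that("outcome model specs enforce the baseline-adjustment contract", {
  expect_error(outcome_model_spec("x_fu", "continuous",
                                  "followup_dimensional"),
               "baseline_adjustment")
  expect_error(outcome_model_spec("x_bl", "continuous",
                                  "baseline_dimensional",
                                  baseline_adjustment = "x_bl"),
               "only for")
  sp <- default_outcome_specs()
  expect_length(sp, 2 * length(outcome_names()) + length(diagnosis_names()))
})

test_that("pseudo-class draws follow the posterior rows deterministically", {
  onehot <- diag(3)[c(1, 2, 3, 1), ]
  d <- pseudo_class_draws(onehot, M = 6, seed = 1)
  expect_true(all(d == c(1, 2, 3, 1)))
  p <- rbind(c(.5, .5))
  d2 <- pseudo_class_draws(p[rep(1, 1), , drop = FALSE], M = 2000, seed = 2)
  expect_lt(abs(mean(d2 == 1) - 0.5), 0.03)
  expect_identical(pseudo_class_draws(onehot, M = 5, seed = 9),
                   pseudo_class_draws(onehot, M = 5, seed = 9))
})

test_that("duplicated classes with identical data show a null contrast", {
  set.seed(1)
  n <- 300
  base <- data.frame(y = rnorm(n), age = runif(n, 9, 11),
                     sex = rbinom(n, 1, .5), icv = rnorm(n, 1500, 100),
                     site_id = sample(sprintf("s%02d", 1:10), n, TRUE),
                     sampling_weight = 1)
  df <- rbind(base, base)
  labels <- rep(1:2, each = n)
  sp <- outcome_model_spec("y", "continuous", "baseline_dimensional")
  fm <- fit_outcome_model(df, labels, sp)
  expect_lt(abs(fm$coef[[".class2"]]), 1e-10)
  expect_lt(abs(diff(fm$adjusted)), 1e-10)
  expect_error(fit_outcome_model(df, rep(1, 2 * n), sp, K = 2), "empty")
})

test_that("one cluster falls back to the unclustered robust sandwich", {
  set.seed(2)
  n <- 120
  df <- data.frame(y = rnorm(n), age = runif(n, 9, 11),
                   sex = rbinom(n, 1, .5), icv = rnorm(n, 1500, 100),
                   site_id = "site01", sampling_weight = runif(n, .5, 2))
  sp <- outcome_model_spec("y", "continuous", "baseline_dimensional")
  fm <- fit_outcome_model(df, rep(1:2, 60), sp)
  fit <- lm(y ~ factor(rep(1:2, 60)) + age + sex + icv, data = df,
            weights = df$sampling_weight)
  expect_equal(unname(fm$vcov), unname(sandwich::vcovHC(fit, type = "HC0")),
               tolerance = 1e-10)
  # and per-observation clusters reproduce the same HC0 sandwich
  vcl <- sandwich::vcovCL(fit, cluster = seq_len(n), type = "HC0",
                          cadjust = FALSE)
  expect_equal(unname(vcl), unname(sandwich::vcovHC(fit, type = "HC0")),
               tolerance = 1e-10)
})

test_that("estimates stay near truth under cluster sampling", {
  # linear outcome with known class means and independent site clusters
  set.seed(3)
  cover <- vapply(1:120, function(r) {
    n <- 400
    cl <- sample(1:2, n, TRUE)
    site <- sample(sprintf("s%02d", 1:15), n, TRUE)
    df <- data.frame(y = 0.4 * (cl == 2) + rnorm(n),
                     age = runif(n, 9, 11), sex = rbinom(n, 1, .5),
                     icv = rnorm(n, 1500, 100), site_id = site,
                     sampling_weight = 1)
    sp <- outcome_model_spec("y", "continuous", "baseline_dimensional")
    fm <- fit_outcome_model(df, cl, sp)
    b <- fm$coef[[".class2"]]
    se <- sqrt(fm$vcov[".class2", ".class2"])
    abs(b - 0.4) < 2 * se
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("combination-rule pooling matches hand arithmetic", {
  pr <- pool_rubin(list(1, 3), list(matrix(1), matrix(1)))
  expect_equal(as.numeric(pr$est), 2)
  expect_equal(as.numeric(pr$vcov), 1 + 1.5 * 2)
  # identical per-draw results pool to themselves
  pid <- pool_rubin(list(c(1, 2), c(1, 2)),
                    list(diag(2) * 2, diag(2) * 2))
  expect_equal(as.numeric(pid$est), c(1, 2))
  expect_equal(pid$vcov, diag(2) * 2)
  expect_equal(max(abs(pid$between)), 0)
  # pooled variance never drops below the mean within-draw variance
  set.seed(4)
  for (i in 1:10) {
    ests <- lapply(1:5, function(m) rnorm(3))
    covs <- lapply(1:5, function(m) diag(runif(3, .5, 2)))
    pp <- pool_rubin(ests, covs)
    W <- Reduce(`+`, covs) / 5
    expect_true(all(diag(pp$vcov) >= diag(W) - 1e-12))
  }
})

test_that("Cohen's d follows its definitions", {
  expect_equal(cohens_d(1, 1), 1)
  expect_equal(cohens_d(0, 2), 0)
  expect_equal(cohens_d(1, log_odds = TRUE), sqrt(3) / pi)
  expect_error(cohens_d(1, 0), "positive")
})

test_that("omega-squared matches a brute-force ANOVA decomposition", {
  expect_equal(omega_squared(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3)), 0)
  set.seed(5)
  n <- 20000
  g <- rep(1:2, each = n / 2)
  y <- 2 * (g == 2) + rnorm(n)   # true d = 2 -> omega^2 just below 0.5
  om <- omega_squared(y, g)
  av <- summary(stats::aov(y ~ factor(g)))[[1]]
  ssb <- av[["Sum Sq"]][1]; ssw <- av[["Sum Sq"]][2]
  msw <- av[["Mean Sq"]][2]
  brute <- (ssb - 1 * msw) / (ssb + ssw + msw)
  expect_equal(om, brute, tolerance = 1e-12)
  expect_lt(om, 0.5)
  expect_gt(om, 0.45)
  # covariate-adjusted path: removing a covariate with no group link
  x <- rnorm(n)
  om2 <- omega_squared(y + 0.5 * x, g, covariates = cbind(x))
  expect_lt(abs(om2 - om), 0.02)
})

test_that("profile-linked effects of published magnitude stay tiny", {
  # d <= 0.13 class differences at large n produce omega^2 < 0.01
  set.seed(6)
  n <- 9000
  g <- sample(1:5, n, TRUE, c(.2, .23, .19, .23, .15))
  eff <- c(0.13, 0, 0.04, -0.02, -0.06)
  y <- eff[g] + rnorm(n)
  expect_lt(omega_squared(y, g), 0.01)
})

test_that("BH adjustment matches the step-up scan and spec examples", {
  expect_equal(bh_adjust(c(.01, .02, .03, .04)), rep(.04, 4))
  expect_true(all(bh_adjust(c(.01, .02, .03, .04)) <= .05))
  expect_equal(bh_adjust(c(.001, .8, .9)), c(.003, .9, .9))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(.5, 1.2)), "\\[0, 1\\]")
  # families adjusted independently
  p <- c(.01, .04, .01, .04)
  fam <- c("a", "a", "b", "b")
  expect_equal(bh_adjust(p, fam), c(.02, .04, .02, .04))
})

test_that("grouping letters encode exactly the pairwise significances", {
  check_letters <- function(sig) {
    lets <- grouping_letters(sig)
    K <- nrow(sig)
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        shared <- length(intersect(strsplit(lets[i], "")[[1]],
                                   strsplit(lets[j], "")[[1]])) > 0
        expect_identical(!shared, isTRUE(sig[i, j]),
                         label = paste("pair", i, j))
      }
    }
    expect_true(all(nchar(lets) > 0))
  }
  set.seed(7)
  for (r in 1:30) {
    K <- sample(2:6, 1)
    sig <- matrix(FALSE, K, K)
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        sig[i, j] <- sig[j, i] <- runif(1) < 0.4
      }
    }
    check_letters(sig)
  }
})

test_that("BCH weights invert the classification matrix", {
  onehot <- diag(3)[c(1, 2, 3, 2, 1), ]
  W <- bch_correction(onehot)
  expect_equal(unname(attr(W, "H")), diag(3))
  expect_equal(unname(W), onehot, ignore_attr = TRUE)
  # weights reproduce direct matrix inversion, row by modal class
  set.seed(8)
  p <- matrix(runif(600 * 3) + 0.2, 600)
  p <- p / rowSums(p)
  p <- 0.55 * diag(3)[max.col(p), ] + 0.45 * p  # sharpen: H invertible
  W2 <- bch_correction(p)
  H <- attr(W2, "H")
  Hi <- solve(H)
  modal <- assign_modal(p)
  for (i in c(1, 50, 300)) {
    expect_equal(unname(W2[i, ]), unname(Hi[modal[i], ]))
  }
  # nearly uniform posteriors are rejected as ill-conditioned
  flat <- matrix(1 / 3, 400, 3) + matrix(runif(1200, -1e-9, 1e-9), 400)
  flat <- flat / rowSums(flat)
  expect_error(bch_correction(flat), "ill-conditioned")
})

test_that("BCH correction undoes modal-assignment attenuation", {
  set.seed(9)
  n <- 20000
  mu <- c(0, 1)
  cl <- sample(1:2, n, TRUE)
  # 2-class model with symmetric ~20% misclassification
  z <- rnorm(n, c(-0.85, 0.85)[cl], 1)
  fitp <- list(prop = c(.5, .5), means = matrix(c(-0.85, 0.85), 2, 1),
               variances = 1)
  post <- posterior_probabilities(fitp, matrix(z))
  y <- mu[cl] + rnorm(n, sd = 0.5)
  modal <- assign_modal(post)
  naive <- tapply(y, modal, mean)
  corrected <- bch_estimates(y, post)
  expect_lt(max(abs(corrected - mu)), 0.02)
  expect_gt(naive[[1]], 0.1)       # attenuated toward the grand mean
  expect_lt(naive[[2]], 0.9)
})

test_that("K = 2 omnibus equals the squared pairwise z", {
  est <- c(0.1, 0.4)
  V <- matrix(c(0.01, 0.002, 0.002, 0.015), 2)
  ob <- omnibus_and_pairwise(est, V, K = 2, sigma = 1)
  expect_equal(ob$wald, ob$pairwise$z[1]^2, tolerance = 1e-8)
  expect_equal(ob$df, 1)
})

test_that("pooled pseudo-draw estimates are unbiased where modal means are attenuated", {
  set.seed(10)
  n <- 20000
  sep <- 1.45   # two-class means +-1.45 SD: entropy ~ 0.74
  cl <- sample(1:2, n, TRUE)
  z <- rnorm(n, c(-sep, sep)[cl], 1)
  fitp <- list(prop = c(.5, .5), means = matrix(c(-sep, sep), 2, 1),
               variances = 1)
  post <- posterior_probabilities(fitp, matrix(z))
  y <- 0.3 * (cl == 2) + rnorm(n)
  df <- data.frame(y = y,
                   site_id = sample(sprintf("s%02d", 1:21), n, TRUE),
                   sampling_weight = 1)
  sp <- list(y = outcome_model_spec("y", "continuous",
                                    "baseline_dimensional",
                                    covariates = character(0)))
  res <- compare_profiles(df, post, sp, M = 20, seed = 11)
  modal <- assign_modal(post)
  naive_delta <- diff(as.numeric(tapply(y, modal, mean)))
  corrected_delta <- diff(res$details$y$adjusted)
  expect_lt(abs(corrected_delta - 0.3), 0.06)
  expect_lt(naive_delta, 0.9 * 0.3)   # >= 10% attenuation
})

test_that("draw mixing matrix is the identity for one-hot posteriors", {
  onehot <- diag(2)[c(1, 1, 2, 2), ]
  D <- draw_classification_matrix(onehot)
  expect_equal(unname(as.matrix(D)), diag(2), ignore_attr = TRUE)
})
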