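test_that("information criteria match their defining formulas", {
  ic <- information_criteria(-100, 10, 100)
  expect_equal(ic[["AIC"]], 220)
  expect_equal(ic[["BIC"]], 10 * log(100) + 200)
  expect_equal(ic[["aBIC"]], 10 * log(102 / 24) + 200)
  expect_equal(ic[["AICC"]], 220 + 220 / 89)
  # AICC undefined when n <= p + 1
  expect_true(is.na(information_criteria(-5, 10, 11)[["AICC"]]))
  # independent scalar recomputation on random inputs
  set.seed(1)
  for (i in 1:20) {
    ll <- rnorm(1, -5000, 500); p <- sample(5:200, 1)
    n <- sample((p + 2):5000, 1)
    ic <- information_criteria(ll, p, n)
    expect_equal(ic[["AIC"]], 2 * p - 2 * ll, tolerance = 1e-10)
    expect_equal(ic[["BIC"]], p * log(n) - 2 * ll, tolerance = 1e-10)
    expect_equal(ic[["aBIC"]], p * log((n + 2) / 24) - 2 * ll,
                 tolerance = 1e-10)
    expect_equal(ic[["AICC"]],
                 2 * p - 2 * ll + 2 * p * (p + 1) / (n - p - 1),
                 tolerance = 1e-10)
  }
})

test_that("loglik is non-decreasing in K on the same data", {
  set.seed(2)
  sim <- rmix(500, c(.4, .6), rbind(rep(-1, 6), rep(1, 6)), rep(1, 6))
  rng <- fit_lpa_range(sim$z, K_range = 1:4, n_starts = 15, n_final = 5,
                       seed = 3, lmr = FALSE)
  expect_true(all(diff(rng$table$loglik) > -1e-6))
  expect_true(all(diff(rng$table$n_params) > 0))
})

test_that("screening flags low-prevalence and inadmissible solutions", {
  set.seed(3)
  sim <- rmix(400, c(.5, .5), rbind(rep(-2, 4), rep(2, 4)), rep(1, 4))
  f2 <- fit_lpa(sim$z, 2, n_starts = 10, n_final = 4, seed = 1)
  # a clean separated fit: no flags
  tab <- screen_solutions(list(f2))
  expect_false(tab$low_prevalence[1])
  expect_false(tab$inadmissible[1])
  # synthetic fit with a 2% modal share trips the 3% screen
  f_small <- f2
  f_small$posteriors <- cbind(c(rep(1, 8), rep(0, 392)),
                              c(rep(0, 8), rep(1, 392)))
  f_small$prop <- c(0.02, 0.98)
  tab2 <- screen_solutions(list(f_small), min_prevalence = 0.03)
  expect_true(tab2$low_prevalence[1])
  f_bad <- f2; f_bad$converged <- FALSE
  expect_true(screen_solutions(list(f_bad))$inadmissible[1])
})

test_that("selected_K follows interior BIC minima only", {
  mkfit <- function(K, ll, n = 1000) {
    structure(list(K = as.integer(K), loglik = ll,
                   n_params = count_parameters(4, K),
                   posteriors = diag(K)[rep(seq_len(K), length.out = 50), ,
                                        drop = FALSE],
                   n = 50L, entropy = 0.8, converged = TRUE,
                   replicated = TRUE, variance_floored = FALSE,
                   prop = rep(1 / K, K)),
              class = "lpa_fit")
  }
  # monotonically improving loglik that never pays the BIC penalty:
  # BIC decreasing across the range, no interior minimum
  lls <- c(-5000, -4800, -4650, -4520)
  tab <- screen_solutions(lapply(1:4, function(k) mkfit(k, lls[k])))
  expect_true(is.na(attr(tab, "selected_K")))
  # a clear interior BIC minimum at K = 2
  lls2 <- c(-5000, -4800, -4795, -4793)
  tab2 <- screen_solutions(lapply(1:4, function(k) mkfit(k, lls2[k])))
  expect_identical(attr(tab2, "selected_K"), 2L)
})

test_that("a zero loglik difference yields a null LMR statistic", {
  f1 <- structure(list(K = 1L, loglik = -1234.5, n_params = 36L,
                       converged = TRUE), class = "lpa_fit")
  f2 <- structure(list(K = 2L, loglik = -1234.5, n_params = 55L,
                       converged = TRUE), class = "lpa_fit")
  p <- lmr_lrt(f2, f1, matrix(rnorm(100 * 18), 100))
  expect_gte(as.numeric(p), 0.99)
  # an inverted ordering indicates a failed optimization
  f2$loglik <- -1300
  expect_error(lmr_lrt(f2, f1, matrix(rnorm(100 * 18), 100)),
               "failed to optimize")
})

test_that("LMR strongly rejects one class on well-separated data", {
  set.seed(4)
  sim <- rmix(1000, c(.5, .5),
              rbind(rep(-1.5, 18), rep(1.5, 18)), rep(1, 18))
  f1 <- fit_lpa(sim$z, 1)
  f2 <- fit_lpa(sim$z, 2, n_starts = 10, n_final = 4, seed = 2)
  expect_lt(as.numeric(lmr_lrt(f2, f1, sim$z)), 0.001)
  # the small-sample adjustment only shrinks the statistic slightly
  pa <- lmr_lrt(f2, f1, sim$z, adjusted = TRUE)
  expect_lte(attr(pa, "statistic"),
             attr(lmr_lrt(f2, f1, sim$z), "statistic"))
})

test_that("bootstrap LRT hits its granularity bounds at the extremes", {
  set.seed(5)
  sim <- rmix(300, c(.5, .5),
              rbind(rep(-2, 6), rep(2, 6)), rep(1, 6))
  f1 <- fit_lpa(sim$z, 1)
  f2 <- fit_lpa(sim$z, 2, n_starts = 8, n_final = 3, seed = 1)
  p <- bootstrap_lrt(f2, f1, sim$z, B = 19, seed = 2,
                     n_starts = 4, n_final = 2)
  expect_equal(as.numeric(p), 1 / 20)  # separated: all bootstrap LRs smaller
  # zero observed difference: p = 1 within granularity
  f2b <- f2; f2b$loglik <- f1$loglik
  p1 <- bootstrap_lrt(f2b, f1, sim$z, B = 19, seed = 3,
                      n_starts = 4, n_final = 2)
  expect_gte(as.numeric(p1), 19 / 20)
})
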