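#' @importFrom stats rnorm runif rbinom rlnorm rmultinom pchisq pnorm qnorm
#'   var complete.cases lm glm coef model.matrix binomial p.adjust
#'   weighted.mean integrate sd setNames as.formula residuals fitted
#'   lm.fit quantile cov cor qlogis plogis dist
NULL

## ---------------------------------------------------------------------------
## Latent profile engine: K-component Gaussian mixture with class-varying
## means and a class-invariant diagonal covariance, fitted by weighted EM.
## ---------------------------------------------------------------------------

#' Number of free parameters of the latent profile model
#'
#' Class-varying means (`K * n_indicators`), one shared diagonal variance per
#' indicator (`n_indicators`), and `K - 1` free mixing proportions.
#'
#' @param n_indicators number of indicators (columns).
#' @param K number of latent profiles.
#' @return integer parameter count.
#' @export
#' @examples
#' count_parameters(18, 5)  # 112
count_parameters <- function(n_indicators, K) {
  stopifnot(n_indicators >= 1, K >= 1)
  as.integer(K * n_indicators + n_indicators + (K - 1))
}

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## n x K matrix of log component densities log N(z_i; mu_k, diag(sigma2)).
lpa_log_dens <- function(Z, means, variances) {
  Z <- as.matrix(Z)
  means <- matrix(means, ncol = ncol(Z))
  J <- ncol(Z)
  const <- -0.5 * (J * log(2 * pi) + sum(log(variances)))
  quad <- drop(Z^2 %*% (1 / (2 * variances)))        # length n
  vrep <- matrix(variances, nrow(means), J, byrow = TRUE)
  cross <- Z %*% t(means / vrep)                      # n x K
  ck <- rowSums(means^2 / vrep) / 2
  out <- sweep(cross, 1, quad)
  out <- sweep(out, 2, ck)
  out + const
}

## E-step in the log domain: returns posteriors, per-row log mixture density.
lpa_estep <- function(Z, prop, means, variances) {
  lp <- sweep(lpa_log_dens(Z, means, variances), 2, log(prop), "+")
  m <- apply(lp, 1, max)
  p <- exp(lp - m)
  rs <- rowSums(p)
  list(posteriors = p / rs, logdens = m + log(rs))
}

#' Posterior profile membership probabilities
#'
#' Bayes responsibilities for each subject under a fitted latent profile
#' model. Computed in the log domain with log-sum-exp, so extreme
#' standardized values do not underflow.
#'
#' @param fit an `lpa_fit` object, or a list with elements `prop`, `means`
#'   (K x J), `variances` (length J).
#' @param indicators numeric matrix (n x J) on the scale the model was fitted
#'   on.
#' @return n x K matrix with rows summing to 1.
#' @export
posterior_probabilities <- function(fit, indicators) {
  Z <- as.matrix(indicators)
  stopifnot(ncol(Z) == ncol(fit$means))
  lpa_estep(Z, fit$prop, fit$means, fit$variances)$posteriors
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum(-p * log(p)) / (n * log(K))`, clipped to `[0, 1]`; 1 means
#' perfect assignment, 0 an uninformative one. Undefined for `K = 1`
#' (returns `NA`).
#'
#' @param posteriors n x K matrix of membership probabilities.
#' @param K number of profiles (defaults to `ncol(posteriors)`).
#' @return scalar in `[0, 1]`, or `NA_real_` when `K = 1`.
#' @export
relative_entropy <- function(posteriors, K = ncol(posteriors)) {
  if (K < 2) return(NA_real_)
  p <- as.matrix(posteriors)
  stopifnot(all(p >= -1e-12), all(abs(rowSums(p) - 1) < 1e-6))
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- 1 - sum(-plogp) / (nrow(p) * log(K))
  min(max(e, 0), 1)
}

## One weighted EM pass from given parameters to convergence (or max_iter).
lpa_em <- function(Z, weights, prop, means, variances, tol = 1e-7,
                   max_iter = 500L, variance_floor = 1e-4) {
  W <- sum(weights)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  floored <- FALSE
  S2 <- colSums(weights * Z^2)
  for (it in seq_len(max_iter)) {
    es <- lpa_estep(Z, prop, means, variances)
    ll <- sum(weights * es$logdens)
    ll_trace <- c(ll_trace, ll)
    r <- es$posteriors * weights
    Nk <- colSums(r)
    prop <- Nk / W
    means <- sweep(crossprod(r, Z), 1, Nk, "/")
    variances <- (S2 - colSums(means^2 * Nk)) / W
    if (any(variances < variance_floor)) {
      floored <- TRUE
      variances <- pmax(variances, variance_floor)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      return(list(prop = prop, means = means, variances = variances,
                  loglik = ll, converged = TRUE, iter = it,
                  ll_trace = ll_trace, floored = floored))
    }
    ll_old <- ll
  }
  list(prop = prop, means = means, variances = variances, loglik = ll_old,
       converged = FALSE, iter = max_iter, ll_trace = ll_trace,
       floored = floored)
}

## Canonical profile order: descending mixing proportion, ties broken
## lexicographically on the mean vectors.
lpa_order <- function(prop, means) {
  do.call(order, c(list(-round(prop, 10)),
                   lapply(seq_len(ncol(means)), function(j) means[, j])))
}

#' Fit a latent profile model by weighted EM with multi-start replication
#'
#' Maximizes the weighted log-likelihood
#' `sum_i w_i log sum_k pi_k prod_j N(z_ij; mu_kj, sigma2_j)` for a
#' K-profile Gaussian mixture with class-invariant diagonal covariance.
#' Random starts draw initial class means from randomly chosen observations;
#' all starts run a short EM burn-in, the best `n_final` continue to
#' convergence, and the solution replicates when the two best distinct final
#' log-likelihoods agree within `1e-4`. Profiles are reported in descending
#' mixing-proportion order.
#'
#' @param indicators numeric n x J matrix (standardized indicators).
#' @param K number of profiles (>= 1; `K = 1` uses the closed form).
#' @param weights positive sampling weights (default all 1).
#' @param n_starts number of random starts.
#' @param n_final number of best starts continued to full convergence.
#' @param seed integer seed controlling the starts.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param variance_floor lower bound on residual variances.
#' @return an object of class `lpa_fit`: mixing proportions `prop`, class
#'   means `means` (K x J), shared `variances`, `loglik`, `posteriors`,
#'   `entropy`, `n_params`, `converged`, `n_starts_replicated`, `seed`.
#' @export
fit_lpa <- function(indicators, K, weights = NULL, n_starts = 100L,
                    n_final = 20L, seed = 1L, tol = 1e-7, max_iter = 500L,
                    variance_floor = 1e-4) {
  Z <- as.matrix(indicators)
  storage.mode(Z) <- "double"
  n <- nrow(Z); J <- ncol(Z)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(K >= 1, n > K, length(weights) == n, all(is.finite(weights)),
            all(weights > 0), all(is.finite(Z)))
  W <- sum(weights)

  if (K == 1) {
    mu <- colSums(weights * Z) / W
    v <- colSums(weights * sweep(Z, 2, mu)^2) / W
    es <- lpa_estep(Z, 1, matrix(mu, 1), v)
    fit <- list(K = 1L, prop = 1, means = matrix(mu, 1, J),
                variances = v, loglik = sum(weights * es$logdens),
                posteriors = matrix(1, n, 1), entropy = NA_real_,
                n_params = count_parameters(J, 1L), converged = TRUE,
                n_starts_replicated = n_starts, seed = seed,
                n = n, max_ll_decrease = 0, variance_floored = FALSE)
    class(fit) <- "lpa_fit"
    colnames(fit$means) <- colnames(Z)
    return(fit)
  }

  marg_mu <- colSums(weights * Z) / W
  marg_var <- colSums(weights * sweep(Z, 2, marg_mu)^2) / W

  short <- with_seed(seed, {
    lapply(seq_len(n_starts), function(s) {
      idx <- sample.int(n, K)
      st <- lpa_em(Z, weights, prop = rep(1 / K, K), means = Z[idx, , drop = FALSE],
                   variances = marg_var, tol = tol,
                   max_iter = 15L, variance_floor = variance_floor)
      st
    })
  })
  lls <- vapply(short, `[[`, numeric(1), "loglik")
  keep <- order(lls, decreasing = TRUE)[seq_len(min(n_final, n_starts))]
  finals <- lapply(short[keep], function(st) {
    lpa_em(Z, weights, st$prop, st$means, st$variances, tol = tol,
           max_iter = max_iter, variance_floor = variance_floor)
  })
  fll <- vapply(finals, `[[`, numeric(1), "loglik")
  conv <- vapply(finals, `[[`, logical(1), "converged")
  if (!any(conv)) {
    stop("fit_lpa: no start converged (K=", K, "); best loglik ",
         format(max(fll)), " after ", max_iter, " iterations")
  }
  best_i <- which.max(ifelse(conv, fll, -Inf))
  best <- finals[[best_i]]

  ## replication: the two best *distinct* final log-likelihoods agree
  srt <- sort(fll[conv], decreasing = TRUE)
  distinct <- srt[c(TRUE, diff(srt) < -1e-10)]
  replicated <- sum(abs(fll[conv] - srt[1]) < 1e-4)
  rep_ok <- length(fll[conv]) >= 2 && replicated >= 2

  dec <- vapply(finals, function(st) {
    d <- diff(st$ll_trace)
    if (length(d)) min(d) else 0
  }, numeric(1))

  ord <- lpa_order(best$prop, best$means)
  prop <- best$prop[ord]
  means <- best$means[ord, , drop = FALSE]
  es <- lpa_estep(Z, prop, means, best$variances)
  fit <- list(K = as.integer(K), prop = prop, means = means,
              variances = best$variances, loglik = best$loglik,
              posteriors = es$posteriors,
              entropy = relative_entropy(es$posteriors, K),
              n_params = count_parameters(J, K),
              converged = best$converged,
              n_starts_replicated = as.integer(replicated),
              replicated = rep_ok, seed = seed, n = n,
              max_ll_decrease = -min(c(dec, 0)),
              variance_floored = best$floored)
  colnames(fit$means) <- colnames(Z)
  class(fit) <- "lpa_fit"
  fit
}

#' @export
print.lpa_fit <- function(x, ...) {
  cat(sprintf("Latent profile fit: K = %d, n = %d\n", x$K, x$n))
  cat(sprintf("  loglik %.3f | entropy %s | %d parameters | %s\n",
              x$loglik,
              ifelse(is.na(x$entropy), "NA", sprintf("%.3f", x$entropy)),
              x$n_params,
              if (isTRUE(x$replicated)) "loglik replicated" else "NOT replicated"))
  cat("  mixing proportions:", paste(sprintf("%.3f", x$prop), collapse = " "),
      "\n")
  invisible(x)
}
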