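## ---------------------------------------------------------------------------
## Lo-Mendell-Rubin style likelihood-ratio test of K vs K-1 profiles.
##
## The statistic 2*(LL_K - LL_{K-1}) is referred to the Vuong weighted
## chi-square approximation: with per-observation scores s_i for each fitted
## model, A = E[hessian] and B = E[s s'], the null distribution is
## sum_j lambda_j chi^2_1 where lambda_j are the eigenvalues of
##   W = [ -Af^+ Bf   -Af^+ Bfg ]
##       [  Ag^+ Bgf   Ag^+ Bg  ]
## Tail probabilities are computed by Imhof's (1961) numerical inversion.
## ---------------------------------------------------------------------------

## Pack model parameters into the unconstrained vector used for
## differentiation: class means, log variances, mixing logits (vs class K).
lpa_pack <- function(prop, means, variances) {
  K <- length(prop)
  c(as.numeric(t(means)), log(variances),
    if (K > 1) log(prop[-K] / prop[K]) else numeric(0))
}

lpa_unpack <- function(theta, K, J) {
  means <- matrix(theta[seq_len(K * J)], K, J, byrow = TRUE)
  variances <- exp(theta[K * J + seq_len(J)])
  if (K > 1) {
    a <- c(theta[K * J + J + seq_len(K - 1)], 0)
    prop <- exp(a - max(a)); prop <- prop / sum(prop)
  } else prop <- 1
  list(prop = prop, means = means, variances = variances)
}

## n x p matrix of per-observation weighted score vectors.
lpa_scores <- function(theta, Z, w, K) {
  J <- ncol(Z)
  par <- lpa_unpack(theta, K, J)
  post <- lpa_estep(Z, par$prop, par$means, par$variances)$posteriors
  n <- nrow(Z)
  S <- matrix(0, n, length(theta))
  vinv <- 1 / par$variances
  dv <- matrix(0, n, J)
  for (k in seq_len(K)) {
    R <- sweep(Z, 2, par$means[k, ])              # residuals vs class k
    Sk <- (post[, k] * w) * sweep(R, 2, vinv, "*")
    S[, (k - 1) * J + seq_len(J)] <- Sk
    dv <- dv + post[, k] * sweep(R^2, 2, vinv, "*")
  }
  ## d/d log sigma2_j: 0.5 * sum_k p_ik ((z-mu_k)^2/s2 - 1)
  S[, K * J + seq_len(J)] <- w * 0.5 * (dv - 1)
  if (K > 1) {
    S[, K * J + J + seq_len(K - 1)] <-
      w * sweep(post[, -K, drop = FALSE], 2, par$prop[-K])
  }
  S
}

## A = (1/n) d(total score)/d(theta), by central finite differences of the
## analytic score; symmetrized.
lpa_info_A <- function(theta, Z, w, K, h = 1e-4) {
  n <- nrow(Z)
  p <- length(theta)
  A <- matrix(0, p, p)
  for (t in seq_len(p)) {
    tp <- theta; tp[t] <- tp[t] + h
    tm <- theta; tm[t] <- tm[t] - h
    gp <- colSums(lpa_scores(tp, Z, w, K))
    gm <- colSums(lpa_scores(tm, Z, w, K))
    A[, t] <- (gp - gm) / (2 * h * n)
  }
  (A + t(A)) / 2
}

## P(sum_j lambda_j chi2_1j > x) by Imhof's integral, with a
## moment-matching fallback when the oscillatory integral fails.
pweightedchisq_upper <- function(x, lambda) {
  lambda <- lambda[abs(lambda) > 1e-10 * max(abs(lambda))]
  if (!length(lambda)) return(1)
  integrand <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * x * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(th) / (u * rho)
  }
  ## piecewise integration over oscillation half-periods of the sin term
  ## (frequency ~ (x + sum |lambda|) / 2), accumulated until negligible
  val <- tryCatch({
    step <- 2 * pi / max(abs(x) + sum(abs(lambda)), 1)
    I <- 0; a <- 0
    for (i in seq_len(5000L)) {
      piece <- integrate(integrand, a, a + step, rel.tol = 1e-10,
                         abs.tol = 1e-12, stop.on.error = TRUE)$value
      I <- I + piece
      a <- a + step
      if (i > 10 && abs(piece) < 1e-13) break
    }
    0.5 + I / pi
  }, error = function(e) {
    ## Satterthwaite-type fallback on the positive part
    m <- sum(lambda); v <- 2 * sum(lambda^2)
    if (m <= 0) return(as.numeric(x <= 0))
    a <- v / (2 * m); b <- 2 * m^2 / v
    pchisq(x / a, df = b, lower.tail = FALSE)
  })
  min(max(val, 0), 1)
}

#' Lo-Mendell-Rubin likelihood ratio test of K vs K-1 profiles
#'
#' Approximate p-value for the null that the `K - 1`-profile model is
#' adequate, using the Vuong weighted-chi-square reference distribution for
#' `2 * (LL_K - LL_{K-1})` with eigenvalue weights estimated from the two
#' fits' per-observation scores. The `adjusted` variant applies the ad hoc
#' small-sample (Bartlett-type) correction dividing the statistic by
#' `1 + 1 / (d * log n)` where `d` is the parameter-count difference.
#'
#' @param fit_k,fit_km1 `lpa_fit` objects on the same data with
#'   `fit_k$K == fit_km1$K + 1`; both converged.
#' @param indicators the n x J matrix both models were fitted on.
#' @param weights sampling weights used in the fits (default all 1).
#' @param adjusted apply the small-sample correction?
#' @return p-value, with attributes `statistic` and `lambda` (the
#'   eigenvalue weights).
#' @export
lmr_lrt <- function(fit_k, fit_km1, indicators, weights = NULL,
                    adjusted = FALSE) {
  Z <- as.matrix(indicators)
  n <- nrow(Z)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(fit_k$K == fit_km1$K + 1, fit_k$converged, fit_km1$converged)
  d <- fit_k$n_params - fit_km1$n_params
  T2 <- 2 * (fit_k$loglik - fit_km1$loglik)
  if (T2 < -1e-6 * (abs(fit_k$loglik) + 1)) {
    stop("lmr_lrt: loglik of the K-profile fit is below the K-1 fit; ",
         "the larger model failed to optimize")
  }
  T2 <- max(T2, 0)
  if (adjusted) T2 <- T2 / (1 + 1 / (d * log(n)))
  if (T2 < 1e-8) {
    return(structure(1, statistic = T2, lambda = numeric(0)))
  }
  th_f <- lpa_pack(fit_k$prop, fit_k$means, fit_k$variances)
  th_g <- lpa_pack(fit_km1$prop, fit_km1$means, fit_km1$variances)
  Sf <- lpa_scores(th_f, Z, weights, fit_k$K)
  Sg <- lpa_scores(th_g, Z, weights, fit_km1$K)
  Af <- lpa_info_A(th_f, Z, weights, fit_k$K)
  Ag <- lpa_info_A(th_g, Z, weights, fit_km1$K)
  Bj <- crossprod(cbind(Sf, Sg)) / n
  pf <- ncol(Sf)
  tolg <- 1e-6
  Afi <- MASS::ginv(Af, tol = tolg)
  Agi <- MASS::ginv(Ag, tol = tolg)
  M <- rbind(cbind(-Afi, matrix(0, pf, ncol(Sg))),
             cbind(matrix(0, ncol(Sg), pf), Agi))
  lam <- Re(eigen(M %*% Bj, only.values = TRUE)$values)
  p <- pweightedchisq_upper(T2, lam)
  structure(p, statistic = T2, lambda = lam)
}

#' Simulate data from a fitted latent profile model
#'
#' @param fit an `lpa_fit` (or parameter list).
#' @param n number of rows.
#' @return n x J matrix drawn from the fitted mixture. Uses the current RNG
#'   stream (seed management is the caller's).
#' @export
simulate_from_fit <- function(fit, n) {
  K <- length(fit$prop)
  J <- ncol(fit$means)
  cl <- sample.int(K, n, replace = TRUE, prob = fit$prop)
  fit$means[cl, , drop = FALSE] +
    matrix(rnorm(n * J), n, J) * rep(sqrt(fit$variances), each = n)
}

#' Parametric bootstrap likelihood ratio test of K vs K-1 profiles
#'
#' Simulates `B` datasets from the fitted `K - 1` model, refits both models
#' on each, and returns `p = (1 + #{LR_b >= LR_obs}) / (B_kept + 1)`.
#' Non-converged bootstrap fits are dropped (an error is raised when more
#' than 20\% drop).
#'
#' @inheritParams lmr_lrt
#' @param B number of bootstrap replicates (>= 19).
#' @param seed integer seed for the bootstrap draws and refits.
#' @param n_starts,n_final multi-start settings for the bootstrap refits.
#' @return p-value with attributes `statistic` and `lr_boot`.
#' @export
bootstrap_lrt <- function(fit_k, fit_km1, indicators, weights = NULL,
                          B = 99L, seed = 1L, n_starts = 8L, n_final = 4L) {
  Z <- as.matrix(indicators)
  n <- nrow(Z)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(fit_k$K == fit_km1$K + 1, B >= 19)
  lr_obs <- 2 * (fit_k$loglik - fit_km1$loglik)
  lrs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      Zb <- simulate_from_fit(fit_km1, n)
      sub_seed <- sample.int(.Machine$integer.max, 1)
      f0 <- tryCatch(
        fit_lpa(Zb, fit_km1$K, weights, n_starts = n_starts,
                n_final = n_final, seed = sub_seed, tol = 1e-6,
                max_iter = 300L),
        error = function(e) NULL)
      f1 <- tryCatch(
        fit_lpa(Zb, fit_k$K, weights, n_starts = n_starts,
                n_final = n_final, seed = sub_seed + 1L, tol = 1e-6,
                max_iter = 300L),
        error = function(e) NULL)
      if (is.null(f0) || is.null(f1)) return(NA_real_)
      2 * (f1$loglik - f0$loglik)
    }, numeric(1))
  })
  dropped <- sum(is.na(lrs))
  if (dropped > 0.2 * B) {
    stop("bootstrap_lrt: ", dropped, "/", B,
         " bootstrap fits failed to converge")
  }
  lrs <- lrs[!is.na(lrs)]
  p <- (1 + sum(lrs >= lr_obs)) / (length(lrs) + 1)
  structure(p, statistic = lr_obs, lr_boot = lrs)
}
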