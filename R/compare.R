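## ---------------------------------------------------------------------------
## Distal-outcome comparison of profiles: manual three-step via pseudo-class
## draws, cluster-robust Wald inference, Rubin pooling, BCH correction,
## effect sizes, and BH-FDR over outcome families.
## ---------------------------------------------------------------------------

#' Outcome model specification
#'
#' Describes one profile-comparison model: the outcome, its type, the a
#' priori covariates (age, sex at birth, ICV), an optional baseline
#' adjustment column (required exactly for follow-up dimensional outcomes),
#' the FDR family, the clustering variable, and the weight column.
#'
#' @param outcome outcome column name.
#' @param type `"continuous"` or `"binary"`.
#' @param family one of `"baseline_dimensional"`, `"baseline_diagnoses"`,
#'   `"followup_dimensional"`.
#' @param covariates covariate column names.
#' @param baseline_adjustment baseline score column for follow-up outcomes.
#' @param cluster clustering (site) column.
#' @param weights sampling-weight column.
#' @return validated list of class `outcome_model_spec`.
#' @export
outcome_model_spec <- function(outcome,
                               type = c("continuous", "binary"),
                               family = c("baseline_dimensional",
                                          "baseline_diagnoses",
                                          "followup_dimensional"),
                               covariates = c("age", "sex", "icv"),
                               baseline_adjustment = NULL,
                               cluster = "site_id",
                               weights = "sampling_weight") {
  type <- match.arg(type)
  family <- match.arg(family)
  if (family == "followup_dimensional" && is.null(baseline_adjustment)) {
    stop("outcome_model_spec: follow-up outcomes require baseline_adjustment")
  }
  if (family != "followup_dimensional" && !is.null(baseline_adjustment)) {
    stop("outcome_model_spec: baseline_adjustment is only for the ",
         "followup_dimensional family")
  }
  structure(list(outcome = outcome, type = type, family = family,
                 covariates = covariates,
                 baseline_adjustment = baseline_adjustment,
                 cluster = cluster, weights = weights),
            class = "outcome_model_spec")
}

#' Default outcome model specifications
#'
#' The three comparison families: baseline dimensional scores, baseline
#' lifetime diagnoses, and follow-up dimensional scores (each adjusted for
#' its baseline score).
#'
#' @return named list of `outcome_model_spec`.
#' @export
default_outcome_specs <- function() {
  sp <- list()
  for (o in outcome_names()) {
    sp[[paste0(o, "_bl")]] <- outcome_model_spec(
      paste0(o, "_bl"), "continuous", "baseline_dimensional")
  }
  for (d in diagnosis_names()) {
    sp[[d]] <- outcome_model_spec(d, "binary", "baseline_diagnoses")
  }
  for (o in outcome_names()) {
    sp[[paste0(o, "_fu")]] <- outcome_model_spec(
      paste0(o, "_fu"), "continuous", "followup_dimensional",
      baseline_adjustment = paste0(o, "_bl"))
  }
  sp
}

#' Pseudo-class draws from posterior membership probabilities
#'
#' Independent categorical draws per subject and imputation from the
#' subject's posterior row.
#'
#' @param posteriors n x K matrix.
#' @param M number of draws (>= 2).
#' @param seed integer seed.
#' @return n x M integer matrix of profile labels.
#' @export
pseudo_class_draws <- function(posteriors, M = 20L, seed = 1L) {
  p <- as.matrix(posteriors)
  stopifnot(M >= 2, all(abs(rowSums(p) - 1) < 1e-6))
  n <- nrow(p)
  K <- ncol(p)
  cum <- t(apply(p, 1, cumsum))[, -K, drop = FALSE]  # n x (K-1)
  with_seed(seed, {
    out <- matrix(NA_integer_, n, M)
    for (m in seq_len(M)) {
      u <- runif(n)
      out[, m] <- 1L + as.integer(rowSums(cum < u))
    }
    out
  })
}

#' Fit one outcome model for fixed profile labels
#'
#' Weighted regression of the outcome on profile indicators plus
#' covariates — linear for continuous outcomes, logistic for binary — with
#' a cluster-robust (CR0 sandwich over sites) covariance. Listwise deletion
#' over outcome, covariates and baseline adjustment; adjusted per-profile
#' estimates are evaluated at the weighted covariate means. With a single
#' cluster the covariance falls back to the heteroskedasticity-robust (HC0)
#' sandwich.
#'
#' @param cohort cohort data.frame.
#' @param labels length-n profile labels aligned with `cohort` rows.
#' @param spec an `outcome_model_spec`.
#' @param K number of profiles (defaults to `max(labels)`).
#' @return list: `coef`, `vcov` (cluster-robust), `adjusted` (per-profile
#'   estimates at covariate means; probabilities for binary outcomes),
#'   `class_terms` (names of the profile coefficients), `n_used`, `sigma`
#'   (pooled within-profile outcome SD, continuous only), `separation`.
#' @export
fit_outcome_model <- function(cohort, labels, spec, K = max(labels)) {
  stopifnot(inherits(spec, "outcome_model_spec"),
            length(labels) == nrow(cohort))
  vars <- c(spec$outcome, spec$covariates, spec$baseline_adjustment,
            spec$cluster, spec$weights)
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols)) {
    stop("fit_outcome_model: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- cohort[, vars, drop = FALSE]
  df$.class <- factor(labels, levels = seq_len(K))
  ok <- complete.cases(df)
  df <- df[ok, , drop = FALSE]
  tabk <- table(df$.class)
  if (any(tabk == 0)) {
    stop("fit_outcome_model: profile(s) ",
         paste(names(tabk)[tabk == 0], collapse = ", "),
         " empty after listwise deletion for outcome ", spec$outcome)
  }
  w <- df[[spec$weights]]
  rhs <- paste(c(".class", spec$covariates, spec$baseline_adjustment),
               collapse = " + ")
  fml <- as.formula(paste0("`", spec$outcome, "` ~ ", rhs))
  separation <- FALSE
  if (spec$type == "continuous") {
    fit <- lm(fml, data = df, weights = w)
  } else {
    fit <- suppressWarnings(
      glm(fml, data = df, weights = w, family = stats::quasibinomial()))
    big <- max(abs(coef(fit)[grep("^\\.class", names(coef(fit)))]), 0,
               na.rm = TRUE)
    if (!fit$converged || big > 10) {
      ## quasi-separation: Haldane-style smoothing via two half-weight
      ## pseudo-observations (one success, one failure) per profile
      separation <- TRUE
      aug <- df[!duplicated(df$.class), , drop = FALSE]
      aug <- aug[rep(seq_len(nrow(aug)), each = 2), , drop = FALSE]
      aug[[spec$outcome]] <- rep(c(0, 1), nrow(aug) / 2)
      aug[[spec$weights]] <- 0.5
      df2 <- rbind(df, aug)
      w <- df2[[spec$weights]]
      fit <- suppressWarnings(
        glm(fml, data = df2, weights = w,
            family = stats::quasibinomial()))
      df <- df2
    }
  }
  cl <- df[[spec$cluster]]
  V <- if (length(unique(cl)) < 2) {
    sandwich::vcovHC(fit, type = "HC0")
  } else {
    sandwich::vcovCL(fit, cluster = cl, type = "HC0", cadjust = FALSE)
  }
  b <- coef(fit)
  class_terms <- paste0(".class", 2:K)
  xbar <- vapply(c(spec$covariates, spec$baseline_adjustment),
                 function(v) weighted.mean(df[[v]], w), numeric(1))
  ## linear predictor of profile k at covariate means
  eta <- b[["(Intercept)"]] +
    c(0, b[class_terms]) +
    if (length(xbar)) sum(b[names(xbar)] * xbar) else 0
  L <- matrix(0, K, length(b), dimnames = list(NULL, names(b)))
  L[, "(Intercept)"] <- 1
  for (k in 2:K) L[k, class_terms[k - 1]] <- 1
  if (length(xbar)) L[, names(xbar)] <- rep(xbar, each = K)
  adj_v <- L %*% V %*% t(L)
  adjusted <- if (spec$type == "binary") plogis(eta) else eta
  sigma <- NA_real_
  if (spec$type == "continuous") {
    y <- df[[spec$outcome]]
    within <- vapply(levels(df$.class), function(kk) {
      i <- df$.class == kk
      sum(w[i] * (y[i] - weighted.mean(y[i], w[i]))^2) / sum(w[i])
    }, numeric(1))
    sigma <- sqrt(weighted.mean(within, tabulate(as.integer(df$.class), K)))
  }
  list(coef = b, vcov = V, adjusted = as.numeric(eta),
       adjusted_response = adjusted, adj_vcov = adj_v,
       class_terms = class_terms, n_used = sum(ok), K = K,
       type = spec$type, sigma = sigma, separation = separation)
}

#' Pool estimates over pseudo-class draws by the combination rules
#'
#' Pooled estimate = mean of per-draw estimates; total covariance =
#' mean within-draw covariance + `(1 + 1/M)` times the between-draw
#' covariance.
#'
#' @param estimates list of M conformable coefficient vectors.
#' @param covariances list of M covariance matrices.
#' @return list `est`, `vcov`, `within`, `between`, `M`.
#' @export
pool_rubin <- function(estimates, covariances) {
  M <- length(estimates)
  stopifnot(M >= 2, length(covariances) == M)
  Q <- do.call(rbind, lapply(estimates, as.numeric))
  qbar <- colMeans(Q)
  W <- Reduce(`+`, covariances) / M
  Bq <- crossprod(sweep(Q, 2, qbar)) / (M - 1)
  Tv <- W + (1 + 1 / M) * Bq
  list(est = setNames(qbar, names(estimates[[1]])), vcov = Tv,
       within = W, between = Bq, M = M)
}

#' Cohen's d for a profile contrast
#'
#' Continuous: adjusted mean difference over the pooled within-profile SD.
#' Binary: log-odds difference times `sqrt(3)/pi` (the logistic
#' latent-scale conversion).
#'
#' @param delta adjusted mean difference (continuous) or log-odds
#'   difference (binary).
#' @param pooled_sd pooled within-profile SD (continuous only).
#' @param log_odds is `delta` a log-odds difference?
#' @return standardized effect size.
#' @export
cohens_d <- function(delta, pooled_sd = NULL, log_odds = FALSE) {
  if (log_odds) return(delta * sqrt(3) / pi)
  if (is.null(pooled_sd) || !is.finite(pooled_sd) || pooled_sd <= 0) {
    stop("cohens_d: pooled SD must be positive")
  }
  delta / pooled_sd
}

#' Omega-squared effect size for an omnibus profile difference
#'
#' `(SSB - df_b * MSW) / (SST + MSW)`, truncated at 0, computed on the
#' outcome after removing covariate effects (when `covariates` given).
#'
#' @param y outcome vector.
#' @param labels group labels.
#' @param covariates optional numeric matrix to residualize `y` on
#'   (with intercept) before the decomposition.
#' @return nonnegative scalar.
#' @export
omega_squared <- function(y, labels, covariates = NULL) {
  ok <- is.finite(y) & !is.na(labels)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & complete.cases(covariates)
    y <- y[ok]; labels <- labels[ok]
    covariates <- covariates[ok, , drop = FALSE]
    y <- residuals(lm.fit(cbind(1, covariates), y))
  } else {
    y <- y[ok]; labels <- labels[ok]
  }
  labels <- factor(labels)
  g <- length(levels(labels))
  n <- length(y)
  gm <- mean(y)
  means <- tapply(y, labels, mean)
  nk <- tabulate(labels)
  ssb <- sum(nk * (means - gm)^2)
  sst <- sum((y - gm)^2)
  ssw <- sst - ssb
  msw <- ssw / (n - g)
  max((ssb - (g - 1) * msw) / (sst + msw), 0)
}

#' Benjamini-Hochberg adjustment within outcome families
#'
#' Step-up FDR adjustment applied independently within each family.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param families factor/character of family membership, same length.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p, families = rep("all", length(p))) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  for (f in unique(families)) {
    i <- which(families == f)
    out[i] <- p.adjust(p[i], method = "BH")
  }
  out
}

#' Grouping letters from a pairwise significance matrix
#'
#' Compact letter display: two profiles share no letter iff their pairwise
#' test is significant. Insert-and-absorb construction.
#'
#' @param sig K x K logical matrix (TRUE = significantly different).
#' @return character vector of letter strings, one per profile.
#' @export
grouping_letters <- function(sig) {
  K <- nrow(sig)
  sets <- list(seq_len(K))
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      if (!isTRUE(sig[i, j])) next
      for (si in rev(seq_along(sets))) {
        s <- sets[[si]]
        if (all(c(i, j) %in% s)) {
          sets[[si]] <- NULL
          sets <- c(sets, list(setdiff(s, i)), list(setdiff(s, j)))
        }
      }
      ## absorb sets contained in another
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) {
        for (b in seq_along(sets)) {
          if (a != b && keep[a] && keep[b] &&
              all(sets[[a]] %in% sets[[b]])) {
            if (length(sets[[a]]) < length(sets[[b]]) || a > b) {
              keep[a] <- FALSE
            }
          }
        }
      }
      sets <- sets[keep]
    }
  }
  sets <- sets[order(vapply(sets, min, 1L))]
  out <- character(K)
  for (si in seq_along(sets)) {
    for (k in sets[[si]]) {
      out[k] <- paste0(out[k], letters[si])
    }
  }
  out
}

#' BCH classification-error correction weights
#'
#' Average classification-probability matrix `H[k, s] = P(modal = s | true
#' = k)` estimated from the posteriors and modal assignments; each subject
#' receives the row of `solve(t(H))`... i.e. weight `w_ik = (H^-1)[s_i, k]`
#' for contribution to profile `k`. Weighted per-profile outcome means with
#' these weights are consistent under the mixture model.
#'
#' @param posteriors n x K matrix.
#' @param modal optional modal labels (computed if omitted).
#' @return n x K matrix of correction weights; attributes `H` and
#'   `condition` (condition number of H).
#' @export
bch_correction <- function(posteriors, modal = NULL) {
  p <- as.matrix(posteriors)
  K <- ncol(p)
  if (is.null(modal)) modal <- assign_modal(p)
  H <- matrix(0, K, K)
  for (s in seq_len(K)) {
    H[, s] <- colSums(p[modal == s, , drop = FALSE])
  }
  H <- H / rowSums(H)
  cnd <- kappa(H, exact = TRUE)
  if (!is.finite(cnd) || cnd > 1e6) {
    stop("bch_correction: classification matrix is ill-conditioned ",
         "(condition ", format(cnd, digits = 3),
         "); use the pseudo-class draw estimator instead")
  }
  Hi <- solve(H)
  W <- Hi[modal, , drop = FALSE]
  attr(W, "H") <- H
  attr(W, "condition") <- cnd
  W
}

#' BCH-corrected per-profile outcome means
#'
#' @param y outcome vector.
#' @param posteriors n x K posterior matrix aligned with `y`.
#' @param sampling_weights optional sampling weights.
#' @return length-K vector of corrected class means.
#' @export
bch_estimates <- function(y, posteriors, sampling_weights = NULL) {
  ok <- is.finite(y)
  p <- as.matrix(posteriors)[ok, , drop = FALSE]
  y <- y[ok]
  w <- if (is.null(sampling_weights)) rep(1, length(y)) else
    sampling_weights[ok]
  Wc <- bch_correction(p)
  colSums(Wc * w * y) / colSums(Wc * w)
}

#' Draw classification-error mixing matrix
#'
#' For labels drawn from the posterior rows, the expected composition of
#' each drawn class: `D[s, k] = P(true = k | drawn = s) =
#' pi_k Q[k, s] / q_s`, with `Q[k, s] = sum_i p_ik p_is / sum_i p_ik` the
#' average draw-classification probability and `q` the marginal draw
#' distribution. Per-drawn-class outcome estimates `a` relate to the true
#' per-profile estimates `mu` by `a = D mu`; `solve(D, a)` undoes the
#' classification error.
#'
#' @param posteriors n x K matrix.
#' @return K x K matrix `D`; attributes `Q`, `prop`, `condition`.
#' @export
draw_classification_matrix <- function(posteriors) {
  p <- as.matrix(posteriors)
  K <- ncol(p)
  prop <- colMeans(p)
  Q <- crossprod(p) / colSums(p)      # Q[k, s] = sum p_ik p_is / sum p_ik
  q <- as.numeric(prop %*% Q)
  D <- t(Q * prop) / q                # D[s, k] = pi_k Q[k, s] / q_s
  cnd <- kappa(D, exact = TRUE)
  if (!is.finite(cnd) || cnd > 1e6) {
    stop("draw_classification_matrix: mixing matrix is ill-conditioned ",
         "(condition ", format(cnd, digits = 3),
         "); posteriors are too uncertain for the correction")
  }
  structure(D, Q = Q, prop = prop, condition = cnd)
}

#' Omnibus and pairwise profile comparisons from pooled per-profile
#' estimates
#'
#' Wald chi-square on the `K - 1` profile contrasts, pairwise z-tests on
#' all profile pairs, and Cohen's d per pair.
#'
#' @param est length-K vector of pooled adjusted per-profile estimates
#'   (means, or probabilities for binary outcomes).
#' @param vcov K x K pooled covariance of `est`.
#' @param K number of profiles.
#' @param sigma pooled within-profile SD (continuous outcomes).
#' @param type outcome type.
#' @param alpha pairwise significance level.
#' @return list: `wald`, `df`, `p`, `pairwise` (data.frame with `i`, `j`,
#'   `delta`, `se`, `z`, `p`, `d`), `sig_matrix`.
#' @export
omnibus_and_pairwise <- function(est, vcov, K = length(est),
                                 sigma = NA_real_,
                                 type = "continuous", alpha = 0.05) {
  stopifnot(length(est) == K, all(dim(vcov) == K))
  L <- cbind(-1, diag(K - 1))          # contrasts vs profile 1
  b <- as.numeric(L %*% est)
  V <- L %*% vcov %*% t(L)
  cnd <- kappa(V, exact = TRUE)
  if (!all(is.finite(V)) || cnd > 1e10) {
    stop("omnibus_and_pairwise: pooled contrast covariance is singular ",
         "(condition number ", format(cnd, digits = 3), ")")
  }
  wald <- as.numeric(t(b) %*% solve(V, b))
  df <- K - 1
  p <- pchisq(wald, df, lower.tail = FALSE)
  pw <- list()
  sig <- matrix(FALSE, K, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      ci <- rep(0, K); ci[i] <- 1; ci[j] <- -1
      delta <- sum(ci * est)
      se <- sqrt(as.numeric(t(ci) %*% vcov %*% ci))
      z <- delta / se
      pp <- 2 * pnorm(-abs(z))
      d <- if (type == "binary") {
        pi_ <- min(max(est[i], 1e-12), 1 - 1e-12)
        pj_ <- min(max(est[j], 1e-12), 1 - 1e-12)
        cohens_d(qlogis(pi_) - qlogis(pj_), log_odds = TRUE)
      } else cohens_d(delta, sigma)
      pw[[length(pw) + 1]] <- data.frame(i = i, j = j, delta = delta,
                                         se = se, z = z, p = pp, d = d)
      sig[i, j] <- sig[j, i] <- pp < alpha
    }
  }
  list(wald = wald, df = df, p = p, pairwise = do.call(rbind, pw),
       sig_matrix = sig)
}

#' Compare profiles on all specified outcomes (manual three-step)
#'
#' For each outcome: draw `M` pseudo-class label sets from the posteriors,
#' fit the weighted cluster-robust outcome model per draw, undo the draw
#' classification error by the mixing-matrix correction
#' (see [draw_classification_matrix()]; uncorrected estimates treat drawn
#' labels as known and are attenuated toward the null), pool across draws
#' by the combination rules, and test the omnibus profile effect. Omnibus
#' p-values are BH-adjusted within the three outcome families; pairwise
#' contrasts (at raw `alpha`) and grouping letters are reported only where
#' the adjusted omnibus test is significant.
#'
#' @param cohort cohort data.frame (analysis sample; posteriors aligned).
#' @param posteriors n x K posterior matrix from the chosen LPA solution.
#' @param specs list of `outcome_model_spec` (default all three families).
#' @param M number of pseudo-class draws.
#' @param alpha significance level.
#' @param seed integer seed for the draws.
#' @param correct apply the classification-error correction (default) or
#'   report the naive pseudo-draw estimates?
#' @return object of class `comparison_result`: `summary` data.frame (one
#'   row per outcome: Wald, df, p, p_adjusted, omega^2, n_used, letters)
#'   and `details` per outcome (adjusted per-profile estimates, pairwise
#'   table).
#' @export
compare_profiles <- function(cohort, posteriors, specs =
                               default_outcome_specs(),
                             M = 20L, alpha = 0.05, seed = 1L,
                             correct = TRUE) {
  K <- ncol(posteriors)
  stopifnot(nrow(posteriors) == nrow(cohort))
  draws <- pseudo_class_draws(posteriors, M = M, seed = seed)
  D <- if (correct) draw_classification_matrix(posteriors) else diag(K)
  Di <- solve(D)
  details <- list()
  rows <- list()
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    ests <- vector("list", M); covs <- vector("list", M)
    omega_d <- rep(NA_real_, M)
    sig <- NA_real_; n_used <- NA_integer_; sep_any <- FALSE
    for (m in seq_len(M)) {
      fm <- fit_outcome_model(cohort, draws[, m], spec, K = K)
      a <- fm$adjusted
      V <- fm$adj_vcov
      if (spec$type == "binary") {
        ## delta method: logit -> probability scale
        pr <- plogis(a)
        g <- pr * (1 - pr)
        V <- diag(g) %*% V %*% diag(g)
        a <- pr
      }
      ests[[m]] <- as.numeric(Di %*% a)
      covs[[m]] <- Di %*% V %*% t(Di)
      sig <- fm$sigma; n_used <- fm$n_used
      sep_any <- sep_any || fm$separation
      if (spec$type == "continuous") {
        vars <- c(spec$covariates, spec$baseline_adjustment)
        okr <- complete.cases(cohort[, c(spec$outcome, vars,
                                         spec$cluster, spec$weights)])
        omega_d[m] <- omega_squared(
          cohort[[spec$outcome]][okr], draws[okr, m],
          covariates = as.matrix(cohort[okr, vars, drop = FALSE]))
      }
    }
    pooled <- pool_rubin(ests, covs)
    ob <- omnibus_and_pairwise(pooled$est, pooled$vcov, K,
                               sigma = sig, type = spec$type,
                               alpha = alpha)
    om2 <- if (spec$type == "continuous") mean(omega_d) else {
      ## latent-scale analogue for binary outcomes (approximate)
      pr <- pmin(pmax(pooled$est, 1e-12), 1 - 1e-12)
      lo <- qlogis(pr)
      vb <- var(lo) * (K - 1) / K
      vb / (vb + pi^2 / 3)
    }
    details[[nm]] <- list(spec = spec, pooled = pooled, omnibus = ob,
                          adjusted = pooled$est,
                          omega_squared = om2,
                          omega_approx = spec$type == "binary",
                          separation = sep_any)
    rows[[nm]] <- data.frame(outcome = nm, family = spec$family,
                             type = spec$type, wald = ob$wald,
                             df = ob$df, p = ob$p, omega2 = om2,
                             n_used = n_used,
                             stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, rows)
  summ$p_adjusted <- bh_adjust(summ$p, summ$family)
  summ$letters <- ""
  for (nm in names(specs)) {
    i <- which(summ$outcome == nm)
    if (summ$p_adjusted[i] < alpha) {
      lets <- grouping_letters(details[[nm]]$omnibus$sig_matrix)
      summ$letters[i] <- paste(lets, collapse = "|")
      details[[nm]]$letters <- lets
    } else {
      details[[nm]]$letters <- rep("", K)
    }
  }
  rownames(summ) <- NULL
  structure(list(summary = summ, details = details, K = K, M = M,
                 alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "Profile comparisons (K = %d, %d pseudo-class draws):\n", x$K, x$M))
  s <- x$summary
  stars <- ifelse(s$p_adjusted < .001, "***",
           ifelse(s$p_adjusted < .01, "**",
           ifelse(s$p_adjusted < .05, "*", "")))
  print(data.frame(outcome = s$outcome, wald = round(s$wald, 2),
                   p_adj = signif(s$p_adjusted, 3), sig = stars,
                   omega2 = signif(s$omega2, 2), letters = s$letters),
        row.names = FALSE)
  invisible(x)
}

#' Write comparison results as TSV and JSON
#'
#' @param res a `comparison_result`.
#' @param dir output directory.
#' @export
write_comparison_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$summary, file.path(dir, "comparisons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  det <- lapply(res$details, function(d) {
    list(adjusted = as.numeric(d$adjusted),
         omega_squared = d$omega_squared, letters = d$letters,
         pairwise = d$omnibus$pairwise)
  })
  jsonlite::write_json(det, file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
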