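## ---------------------------------------------------------------------------
## Model selection across a range of K: information criteria, screening
## flags, and the per-K solution table.
## ---------------------------------------------------------------------------

#' Information criteria for a fitted model
#'
#' `AIC = 2p - 2LL`; `BIC = p log(n) - 2LL`; the sample-size-adjusted BIC
#' replaces `n` by `(n + 2) / 24` in the penalty; `AICC` adds the
#' second-order correction `2p(p + 1) / (n - p - 1)` to AIC (undefined, and
#' returned as `NA`, when `n <= p + 1`).
#'
#' @param loglik maximized (weighted) log-likelihood.
#' @param n_params free parameter count.
#' @param n sample size (number of rows).
#' @return named numeric vector `AIC`, `BIC`, `aBIC`, `AICC`.
#' @export
information_criteria <- function(loglik, n_params, n) {
  stopifnot(is.finite(loglik), n_params >= 1, n >= 1)
  aic <- 2 * n_params - 2 * loglik
  bic <- n_params * log(n) - 2 * loglik
  abic <- n_params * log((n + 2) / 24) - 2 * loglik
  aicc <- if (n > n_params + 1) {
    aic + 2 * n_params * (n_params + 1) / (n - n_params - 1)
  } else NA_real_
  c(AIC = aic, BIC = bic, aBIC = abic, AICC = aicc)
}

#' Screen a set of latent profile solutions
#'
#' Builds the per-K solution table with fit criteria and screening flags:
#' `low_prevalence` when any modally assigned profile holds less than
#' `min_prevalence` of the sample, `inadmissible` when the fit did not
#' converge or a residual variance sits at the floor, `not_replicated` when
#' the best log-likelihood was not replicated across starts. `selected_K`
#' is the K at which BIC attains a strict interior minimum over the fitted
#' range, restricted to unflagged rows; it is left unset (`NA`) when no
#' criterion has an interior minimum, mirroring the situation where model
#' choice falls back to substantive grounds.
#'
#' @param fits list of `lpa_fit` objects (increasing K).
#' @param min_prevalence smallest admissible modal profile share.
#' @param lmr_p optional vector of LMR p-values aligned with `fits`
#'   (`NA` for the smallest K).
#' @return data.frame of class `solution_table`; attribute `selected_K`.
#' @export
screen_solutions <- function(fits, min_prevalence = 0.03, lmr_p = NULL) {
  stopifnot(length(fits) >= 1)
  Ks <- vapply(fits, `[[`, integer(1), "K")
  stopifnot(!is.unsorted(Ks))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    ic <- information_criteria(f$loglik, f$n_params, f$n)
    shares <- tabulate(assign_modal(f$posteriors), nbins = f$K) / f$n
    data.frame(K = f$K, loglik = f$loglik, n_params = f$n_params,
               AIC = ic[["AIC"]], BIC = ic[["BIC"]], aBIC = ic[["aBIC"]],
               AICC = ic[["AICC"]], entropy = f$entropy,
               min_share = min(shares),
               low_prevalence = min(shares) < min_prevalence,
               inadmissible = !f$converged || isTRUE(f$variance_floored),
               not_replicated = !isTRUE(f$replicated) && f$K > 1)
  })
  tab <- do.call(rbind, rows)
  tab$lmr_p <- if (is.null(lmr_p)) NA_real_ else lmr_p
  flagged <- tab$low_prevalence | tab$inadmissible
  sel <- NA_integer_
  if (nrow(tab) >= 3) {
    b <- tab$BIC
    interior <- which(diff(sign(diff(b))) > 0) + 1L  # strict local minima
    interior <- interior[!flagged[interior]]
    if (length(interior)) sel <- tab$K[interior[1]]
  }
  attr(tab, "selected_K") <- sel
  class(tab) <- c("solution_table", "data.frame")
  tab
}

#' Fit latent profile models over a range of K and build the solution table
#'
#' Fits each K with the shared multi-start EM settings, computes the
#' LMR-LRT between consecutive solutions, and screens the results.
#'
#' @inheritParams fit_lpa
#' @param K_range integer vector of profile counts (e.g. `2:9`).
#' @param lmr compute LMR-LRT p-values between consecutive K?
#' @param adjusted_lmr use the small-sample-adjusted LMR variant?
#' @param min_prevalence passed to [screen_solutions()].
#' @return list with `fits` (named list by K) and `table`
#'   (a `solution_table`).
#' @export
fit_lpa_range <- function(indicators, K_range = 2:9, weights = NULL,
                          n_starts = 100L, n_final = 20L, seed = 1L,
                          lmr = TRUE, adjusted_lmr = FALSE,
                          min_prevalence = 0.03, ...) {
  K_range <- sort(unique(as.integer(K_range)))
  fits <- lapply(K_range, function(K) {
    fit_lpa(indicators, K, weights = weights, n_starts = n_starts,
            n_final = n_final, seed = seed + K, ...)
  })
  names(fits) <- paste0("K", K_range)
  lmr_p <- rep(NA_real_, length(K_range))
  if (lmr) {
    for (i in seq_along(K_range)[-1]) {
      if (K_range[i] == K_range[i - 1] + 1) {
        lmr_p[i] <- tryCatch(
          as.numeric(lmr_lrt(fits[[i]], fits[[i - 1]], indicators,
                             weights = weights, adjusted = adjusted_lmr)),
          error = function(e) NA_real_)
      }
    }
  }
  list(fits = fits,
       table = screen_solutions(fits, min_prevalence = min_prevalence,
                                lmr_p = lmr_p))
}

#' Write a solution table as TSV
#'
#' @param tab a `solution_table`.
#' @param path output path.
#' @export
write_solution_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
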