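## ---------------------------------------------------------------------------
## Preprocessing: ICV residualization of subcortical volumes and full-sample
## standardization of all 18 indicators.
## ---------------------------------------------------------------------------

#' Indicator layout
#'
#' Canonical column order of the 18 structural indicators: 7 bilateral
#' subcortical volumes (residualized on ICV) followed by 2 bilateral
#' orbitofrontal (OFC) thicknesses (standardized only).
#'
#' @return data.frame with `indicator`, `roi`, `hemisphere`, `kind`
#'   (`volume_residual` / `thickness`), and `group` (striatal / limbic /
#'   thalamic / ofc) columns.
#' @export
indicator_layout <- function() {
  vols <- c("accumbens", "amygdala", "caudate", "hippocampus",
            "pallidum", "putamen", "thalamus")
  thk <- c("lateral_ofc", "medial_ofc")
  roi <- c(rep(vols, each = 2), rep(thk, each = 2))
  hemi <- rep(c("lh", "rh"), 9)
  group <- ifelse(roi %in% c("caudate", "putamen", "pallidum", "accumbens"),
                  "striatal",
           ifelse(roi %in% c("amygdala", "hippocampus"), "limbic",
           ifelse(roi == "thalamus", "thalamic", "ofc")))
  data.frame(
    indicator = paste(roi, hemi, sep = "_"),
    roi = roi, hemisphere = hemi,
    kind = ifelse(roi %in% vols, "volume_residual", "thickness"),
    group = group,
    stringsAsFactors = FALSE
  )
}

#' Residualize a volume on intracranial volume
#'
#' Ordinary least squares of `volume` on an intercept plus ICV; returns the
#' residuals, which are mean-zero and uncorrelated with ICV by construction.
#' Constant ICV is an error: silently falling back to centering would hide a
#' broken head-size covariate.
#'
#' @param volume,icv numeric vectors of equal length (>= 3).
#' @param params optional list `(intercept, slope)` from a previous fit; when
#'   supplied the stored line is applied instead of refitting.
#' @return numeric residual vector with attributes `intercept` and `slope`.
#' @export
residualize_on_icv <- function(volume, icv, params = NULL) {
  stopifnot(length(volume) == length(icv), length(volume) >= 3,
            all(is.finite(volume)), all(is.finite(icv)))
  if (is.null(params)) {
    if (var(icv) < .Machine$double.eps * max(1, mean(icv)^2)) {
      stop("residualize_on_icv: ICV is constant; residualization on ICV is ",
           "undefined (centering-only is not applied silently)")
    }
    slope <- cov(volume, icv) / var(icv)
    intercept <- mean(volume) - slope * mean(icv)
  } else {
    intercept <- params$intercept; slope <- params$slope
  }
  res <- volume - intercept - slope * icv
  attr(res, "intercept") <- intercept
  attr(res, "slope") <- slope
  res
}

#' Standardize a column over the full sample
#'
#' Centers and scales to mean 0, SD 1 (denominator `n - 1`), storing the
#' parameters so profiles read as deviations in SD units and the transform
#' can be replayed on new data.
#'
#' @param column numeric vector.
#' @param name indicator name used in error messages.
#' @param params optional list `(mean, sd)` to apply instead of refitting.
#' @return standardized vector with attributes `mean` and `sd`.
#' @export
standardize_full_sample <- function(column, name = "column", params = NULL) {
  stopifnot(all(is.finite(column)))
  if (is.null(params)) {
    m <- mean(column); s <- sd(column)
    if (!is.finite(s) || s <= .Machine$double.eps * max(1, abs(m))) {
      stop("standardize_full_sample: indicator '", name,
           "' has zero variance")
    }
  } else {
    m <- params$mean; s <- params$sd
  }
  z <- (column - m) / s
  attr(z, "mean") <- m
  attr(z, "sd") <- s
  z
}

#' Build the 18-column standardized indicator matrix
#'
#' Subcortical volumes are residualized on ICV and then standardized over
#' the full sample; OFC thicknesses are standardized only. Subjects with any
#' missing indicator or ICV are dropped (count recorded). Stored
#' residualization and scaling parameters replay the transform exactly.
#'
#' @param cohort a cohort data.frame with the 18 ROI columns named as in
#'   [indicator_layout()] and an `icv` column.
#' @param params optional `indicator_params` from a previous call; applies
#'   the stored transform instead of refitting.
#' @return object of class `indicator_matrix`: `values` (n x 18 matrix),
#'   `layout`, `params` (per-indicator residualization and scaling),
#'   `n_dropped`, `rows` (row indices of `cohort` retained).
#' @export
build_indicator_matrix <- function(cohort, params = NULL) {
  lay <- indicator_layout()
  need <- c(lay$indicator, "icv")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("build_indicator_matrix: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- as.matrix(cohort[, lay$indicator, drop = FALSE])
  icv <- cohort$icv
  ok <- complete.cases(raw) & is.finite(icv)
  raw <- raw[ok, , drop = FALSE]
  icv <- icv[ok]
  out <- matrix(NA_real_, nrow(raw), nrow(lay),
                dimnames = list(NULL, lay$indicator))
  pars <- vector("list", nrow(lay))
  names(pars) <- lay$indicator
  for (j in seq_len(nrow(lay))) {
    nm <- lay$indicator[j]
    col <- raw[, j]
    pj <- if (is.null(params)) NULL else params$params[[nm]]
    if (lay$kind[j] == "volume_residual") {
      r <- residualize_on_icv(col, icv, params = pj$residualization)
      z <- standardize_full_sample(as.numeric(r), nm, params = pj$scaling)
      pars[[j]] <- list(
        residualization = list(intercept = attr(r, "intercept"),
                               slope = attr(r, "slope")),
        scaling = list(mean = attr(z, "mean"), sd = attr(z, "sd")))
    } else {
      z <- standardize_full_sample(col, nm, params = pj$scaling)
      pars[[j]] <- list(
        scaling = list(mean = attr(z, "mean"), sd = attr(z, "sd")))
    }
    out[, j] <- z
  }
  structure(list(values = out, layout = lay,
                 params = list(params = pars),
                 n_dropped = sum(!ok), rows = which(ok)),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf("Indicator matrix: %d subjects x %d indicators (%d dropped)\n",
              nrow(x$values), ncol(x$values), x$n_dropped))
  invisible(x)
}

#' Write / read an indicator matrix as CSV plus a JSON parameter sidecar
#'
#' @param x an `indicator_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.params.json`.
#' @export
write_indicator_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x$values), path, row.names = FALSE)
  jsonlite::write_json(x$params, paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
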