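## ---------------------------------------------------------------------------
## Profile characterization: the +-0.30 SD deviation rule, auto-generated
## labels, modal assignment, and cross-fit stability.
## ---------------------------------------------------------------------------

#' Modal profile assignment
#'
#' Argmax over each posterior row; exact ties go to the lowest profile
#' index.
#'
#' @param posteriors n x K matrix.
#' @return integer vector of profile indices.
#' @export
assign_modal <- function(posteriors) {
  p <- as.matrix(posteriors)
  max.col(p, ties.method = "first")
}

## Human-readable label from the flag pattern of one profile.
profile_label <- function(elevated, reduced, layout) {
  describe <- function(idx, dir) {
    if (!length(idx)) return(character(0))
    sub <- layout[idx, ]
    subc <- sub[sub$group != "ofc", ]
    parts <- character(0)
    subc_all <- layout[layout$group != "ofc", "indicator"]
    if (length(unique(subc$indicator)) >= 0.8 * length(subc_all)) {
      parts <- c(parts, paste(dir, "subcortical volume"))
    } else {
      for (g in c("striatal", "limbic", "thalamic")) {
        gi <- layout$indicator[layout$group == g]
        ## a group is named once at least two of its regions (and a
        ## quarter of the group) deviate together, e.g. bilateral caudate
        ## plus one pallidum reads as a striatal pattern
        if (length(intersect(sub$indicator, gi)) >=
            max(2, length(gi) / 4)) {
          parts <- c(parts, paste(dir, g, "volume"))
        }
      }
    }
    ofc <- layout$indicator[layout$group == "ofc"]
    if (length(intersect(sub$indicator, ofc)) >= length(ofc) / 2) {
      parts <- c(parts, paste(dir, "OFC thickness"))
    }
    parts
  }
  parts <- c(describe(elevated, "elevated"), describe(reduced, "reduced"))
  if (!length(parts)) "average profile" else paste(parts, collapse = " / ")
}

#' Characterize profiles by the deviation rule
#'
#' Flags each model-estimated profile mean at least `threshold` SD above
#' (elevated) or below (reduced) the grand mean of the standardized
#' indicators, and builds a label from the flagged region groups
#' (striatal = caudate, putamen, pallidum, accumbens; limbic = amygdala,
#' hippocampus; thalamus grouped with subcortical; OFC thickness).
#' Bilateral wording requires both hemispheres flagged.
#'
#' @param fit a converged `lpa_fit` on standardized indicators.
#' @param threshold deviation threshold in SD units.
#' @return object of class `profile_characterization`: per-profile lists of
#'   `elevated` / `reduced` indicator names, near-threshold notes (within
#'   0.05 SD below threshold), modal shares, and label strings.
#' @export
characterize_profiles <- function(fit, threshold = 0.30) {
  stopifnot(isTRUE(fit$converged), threshold > 0)
  lay <- indicator_layout()
  M <- fit$means
  colnames(M) <- lay$indicator
  shares <- tabulate(assign_modal(fit$posteriors), nbins = fit$K) / fit$n
  profs <- lapply(seq_len(fit$K), function(k) {
    m <- M[k, ]
    el <- which(m >= threshold)
    rd <- which(m <= -threshold)
    near <- which(abs(m) < threshold & abs(m) >= threshold - 0.05)
    list(elevated = names(m)[el], reduced = names(m)[rd],
         near_threshold = setNames(round(m[near], 3), names(m)[near]),
         means = m, modal_share = shares[k],
         label = profile_label(el, rd, lay))
  })
  structure(list(profiles = profs, threshold = threshold, K = fit$K),
            class = "profile_characterization")
}

#' @export
print.profile_characterization <- function(x, ...) {
  cat(sprintf("Profile characterization (threshold %.2f SD):\n",
              x$threshold))
  for (k in seq_along(x$profiles)) {
    p <- x$profiles[[k]]
    cat(sprintf("  %d (%.1f%%): %s\n", k, 100 * p$modal_share, p$label))
  }
  invisible(x)
}

## All permutations of 1..k (k <= 9 here).
perms <- function(k) {
  if (k == 1) return(list(1L))
  do.call(c, lapply(seq_len(k), function(i) {
    lapply(perms(k - 1L), function(p) c(i, (seq_len(k))[-i][p]))
  }))
}

#' Match profiles between two fits
#'
#' Exact assignment (minimum total squared mean distance over label
#' permutations) mapping profiles of `fit_b` onto `fit_a`.
#'
#' @param fit_a,fit_b `lpa_fit` objects with equal K and indicator sets.
#' @return integer vector `m` with `m[k]` = profile of `fit_b` matched to
#'   profile `k` of `fit_a`.
#' @export
match_profiles <- function(fit_a, fit_b) {
  stopifnot(fit_a$K == fit_b$K, ncol(fit_a$means) == ncol(fit_b$means))
  D <- as.matrix(dist(rbind(fit_a$means, fit_b$means)))^2
  D <- D[seq_len(fit_a$K), fit_a$K + seq_len(fit_b$K), drop = FALSE]
  best <- NULL; bestc <- Inf
  for (p in perms(fit_a$K)) {
    cost <- sum(D[cbind(seq_len(fit_a$K), p)])
    if (cost < bestc) { bestc <- cost; best <- p }
  }
  best
}

#' Per-profile modal agreement between two fits
#'
#' Matches profiles by exact assignment on class-mean distance, then
#' reports, for the subjects common to both fits, the share of each
#' profile's members (by modal assignment under `fit_a`) assigned to the
#' matched profile under `fit_b`.
#'
#' @param fit_a,fit_b `lpa_fit` objects.
#' @param ids_a,ids_b subject identifiers aligned with the fits' posterior
#'   rows; defaults assume the fits cover the same subjects in order.
#' @return named numeric vector of per-profile agreement fractions;
#'   attribute `matching` holds the permutation used.
#' @export
stability_check <- function(fit_a, fit_b,
                            ids_a = seq_len(nrow(fit_a$posteriors)),
                            ids_b = seq_len(nrow(fit_b$posteriors))) {
  common <- intersect(ids_a, ids_b)
  if (!length(common)) {
    stop("stability_check: the two fits share no subjects")
  }
  m <- match_profiles(fit_a, fit_b)
  la <- assign_modal(fit_a$posteriors)[match(common, ids_a)]
  lb <- assign_modal(fit_b$posteriors)[match(common, ids_b)]
  agree <- vapply(seq_len(fit_a$K), function(k) {
    ink <- la == k
    if (!any(ink)) return(NA_real_)
    mean(lb[ink] == m[k])
  }, numeric(1))
  names(agree) <- paste0("profile", seq_len(fit_a$K))
  attr(agree, "matching") <- m
  agree
}

#' Write profile means and characterization
#'
#' Profile means go to TSV (indicators x profiles); the characterization to
#' a JSON report.
#'
#' @param characterization a `profile_characterization`.
#' @param fit the `lpa_fit` it came from.
#' @param dir output directory.
#' @export
write_profile_report <- function(characterization, fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mean_tab <- data.frame(indicator = indicator_layout()$indicator,
                         t(fit$means))
  names(mean_tab)[-1] <- paste0("profile", seq_len(fit$K))
  utils::write.table(mean_tab, file.path(dir, "profile_means.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  rep <- lapply(characterization$profiles, function(p) {
    list(label = p$label, modal_share = p$modal_share,
         elevated = p$elevated, reduced = p$reduced,
         near_threshold = as.list(p$near_threshold))
  })
  jsonlite::write_json(list(threshold = characterization$threshold,
                            profiles = rep),
                       file.path(dir, "profile_characterization.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
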