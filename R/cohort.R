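## ---------------------------------------------------------------------------
## Synthetic cohort generator: a multisite, family-clustered, probability-
## weighted pediatric neuroimaging cohort with a latent-profile structure on
## 18 brain-structure indicators, an ICV confound on the volume indicators,
## and weakly profile-linked psychopathology outcomes.
## ---------------------------------------------------------------------------

#' Dimensional outcome and diagnosis names used throughout
#' @export
outcome_names <- function() {
  c("internalizing", "externalizing", "detachment", "somatoform",
    "neurodevelopmental", "pdq_sum", "pdq_severity")
}

#' @rdname outcome_names
#' @export
diagnosis_names <- function() {
  c("depression", "bipolar", "anxiety", "ocd", "behavioral", "adhd")
}

#' Five-profile class-mean preset
#'
#' Default K = 5 class means (profiles x 18 indicators, SD units of the
#' latent indicator scale): a reduced-subcortical-volume profile, a
#' reduced-OFC-thickness profile, a reduced-limbic / elevated-striatal
#' profile, an elevated-OFC / reduced-striatal profile, and an elevated-OFC
#' and subcortical-volume profile. Entries are chosen so the mixture-implied
#' standardized profile means (see [true_standardized_means()]) reproduce
#' the intended above/below +-0.30 SD pattern of each profile.
#'
#' @return 5 x 18 matrix with indicator column names.
#' @export
profile_means_preset <- function() {
  M <- rbind(
    c(-.60, -.58, -.70, -.68, -.56, -.58, -.75, -.73, -.65, -.66,
      -.85, -.83, -.92, -.90,  .05,  .04,  .02,  .03),
    c( .10,  .10,  .16,  .16, -.15, -.15,  .14,  .14,  .10,  .10,
       .12,  .12,  .10,  .10, -.84, -.82, -.72, -.74),
    c( .15,  .14, -.41, -.38,  .89,  .90, -.41, -.40,  .20,  .57,
       .10,  .12,  .05,  .05, -.05, -.04, -.06, -.05),
    c(-.05, -.06,  .20,  .18, -.33, -.36,  .15,  .14, -.15, -.32,
      -.08, -.08, -.05, -.06,  .73,  .71,  .61,  .63),
    c( .47,  .49,  .55,  .57,  .60,  .62,  .70,  .72,  .65,  .67,
       .90,  .92, 1.08, 1.05,  .44,  .42,  .27,  .38))
  colnames(M) <- indicator_layout()$indicator
  rownames(M) <- c("reduced_subcortical", "reduced_ofc",
                   "reduced_limbic_elevated_striatal",
                   "elevated_ofc_reduced_striatal",
                   "elevated_ofc_and_subcortical")
  M
}

## Raw ROI location/scale used to place indicators on measurement units
## (volumes cm^3, thicknesses mm); cosmetic realism only.
roi_scale_table <- function() {
  lay <- indicator_layout()
  center <- c(accumbens = 0.55, amygdala = 1.70, caudate = 3.80,
              hippocampus = 4.10, pallidum = 1.50, putamen = 5.40,
              thalamus = 7.70, lateral_ofc = 2.65, medial_ofc = 2.45)
  scale <- c(accumbens = 0.08, amygdala = 0.20, caudate = 0.45,
             hippocampus = 0.45, pallidum = 0.20, putamen = 0.60,
             thalamus = 0.80, lateral_ofc = 0.12, medial_ofc = 0.12)
  data.frame(indicator = lay$indicator, center = center[lay$roi],
             scale = scale[lay$roi], stringsAsFactors = FALSE)
}

default_outcome_effects <- function(K) {
  base <- list(
    internalizing      = c(0.12,  0.00,  0.04, -0.01, -0.05),
    externalizing      = c(0.13,  0.01,  0.00, -0.01, -0.06),
    detachment         = c(0.12, -0.02,  0.06, -0.04, -0.05),
    somatoform         = c(0.05,  0.00,  0.03,  0.02, -0.04),
    neurodevelopmental = c(0.15,  0.04, -0.01, -0.01, -0.13),
    pdq_sum            = c(0.00,  0.00,  0.00,  0.00,  0.00),
    pdq_severity       = c(0.00,  0.00,  0.00,  0.00,  0.00))
  if (K == 5) return(base)
  lapply(base, function(v) rep(0, K))
}

default_diagnosis_logodds <- function(K) {
  base <- list(
    depression = c( 0.30, -0.05, -0.10,  0.05, -0.10),
    bipolar    = c( 0.30, -0.08, -0.08, -0.08, -0.15),
    anxiety    = c( 0.18, -0.10,  0.10, -0.08,  0.00),
    ocd        = c( 0.00,  0.00,  0.00,  0.00,  0.00),
    behavioral = c( 0.05,  0.02, -0.03, -0.03, -0.03),
    adhd       = c( 0.20,  0.10, -0.10,  0.05, -0.25))
  if (K == 5) return(base)
  lapply(base, function(v) rep(0, K))
}

## Raw-count location/scale used when outcomes are floored at zero, chosen
## to resemble checklist sum-score distributions.
outcome_scale_table <- function() {
  data.frame(
    outcome = outcome_names(),
    location = c(2.6, 4.7, 0.7, 1.2, 3.0, 2.6, 6.5),
    scale    = c(3.0, 5.6, 1.2, 1.6, 3.7, 3.5, 10.5),
    stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Builds and validates the generator configuration. Defaults emulate the
#' study conditions the analysis assumes: 21 sites, ~25% two-child
#' families, lognormal sampling weights normalized to mean 1, 47.8% female,
#' age uniform on 9-11 years, ICV ~ 1500 +- 100 cm^3 with a sex difference,
#' the five-profile class-mean preset with within-class SD calibrated so
#' the true-model relative entropy is ~0.75, and very small profile-outcome
#' effects (standardized differences ~0.05-0.15).
#'
#' @param n_families number of families.
#' @param prob_second_child probability a family contributes a sibling.
#' @param n_sites number of acquisition sites.
#' @param K_true number of latent profiles.
#' @param mixing_proportions length-`K_true` probabilities summing to 1.
#' @param class_means `K_true` x 18 matrix (SD units of the latent scale).
#' @param residual_sd length-18 within-profile SDs. Default
#'   `1.08 * sqrt(1 - B_j)` where `B_j` is the between-profile variance of
#'   indicator `j`, the calibration that puts true-model entropy near 0.75.
#' @param icv_mean,icv_sd intracranial volume distribution (cm^3).
#' @param icv_sex_d standardized male-female ICV difference.
#' @param icv_loadings length-18 loadings of standardized ICV on the
#'   indicators (thickness entries forced to 0 by default).
#' @param outcome_effects named list (one per dimensional outcome) of
#'   length-`K_true` class means in SD units.
#' @param baseline_followup_cor autoregressive correlation between baseline
#'   and follow-up dimensional scores.
#' @param diagnosis_base_prevalence named length-6 vector in (0, 1).
#' @param diagnosis_class_logodds named list of length-`K_true` log-odds
#'   shifts per diagnosis.
#' @param weight_dispersion sdlog of the lognormal sampling weights.
#' @param site_sd SD of site-level intercepts added to outcomes (SD units).
#' @param missing_outcome_rate i.i.d. missingness rate for each outcome cell.
#' @param floor_outcomes put dimensional scores on a nonnegative count-like
#'   scale (location + scale * latent, floored at 0)?
#' @param sex_p_female probability of female sex at birth.
#' @param age_range age range (years), sampled uniformly.
#' @param seed integer seed.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 5000,
                          prob_second_child = 0.25,
                          n_sites = 21,
                          K_true = 5,
                          mixing_proportions = c(.20, .23, .19, .23, .15),
                          class_means = profile_means_preset(),
                          residual_sd = NULL,
                          icv_mean = 1500, icv_sd = 100,
                          icv_sex_d = 0.7,
                          icv_loadings = NULL,
                          outcome_effects = default_outcome_effects(K_true),
                          baseline_followup_cor = 0.55,
                          diagnosis_base_prevalence =
                            c(depression = 0.07, bipolar = 0.08,
                              anxiety = 0.38, ocd = 0.12,
                              behavioral = 0.16, adhd = 0.21),
                          diagnosis_class_logodds =
                            default_diagnosis_logodds(K_true),
                          weight_dispersion = 0.35,
                          site_sd = 0.05,
                          missing_outcome_rate = 0.05,
                          floor_outcomes = TRUE,
                          sex_p_female = 0.478,
                          age_range = c(9, 11),
                          seed = 1L) {
  lay <- indicator_layout()
  class_means <- as.matrix(class_means)
  fail <- function(field, why) {
    stop("cohort_config: invalid `", field, "`: ", why, call. = FALSE)
  }
  if (!(is.numeric(n_families) && n_families >= 1)) {
    fail("n_families", "must be a positive count")
  }
  if (prob_second_child < 0 || prob_second_child > 1) {
    fail("prob_second_child", "must be a probability")
  }
  if (n_sites < 1) fail("n_sites", "must be a positive count")
  if (K_true < 1) fail("K_true", "must be >= 1")
  if (length(mixing_proportions) != K_true) {
    fail("mixing_proportions", "length must equal K_true")
  }
  if (abs(sum(mixing_proportions) - 1) > 1e-12) {
    fail("mixing_proportions", "must sum to 1 within 1e-12")
  }
  if (any(mixing_proportions <= 0)) {
    fail("mixing_proportions", "must be strictly positive")
  }
  if (!all(dim(class_means) == c(K_true, 18))) {
    fail("class_means", "must be a K_true x 18 matrix")
  }
  gm <- colSums(mixing_proportions * class_means)
  B <- colSums(mixing_proportions * sweep(class_means, 2, gm)^2)
  if (is.null(residual_sd)) residual_sd <- 1.08 * sqrt(pmax(1 - B, 0.25))
  if (length(residual_sd) == 1) residual_sd <- rep(residual_sd, 18)
  if (length(residual_sd) != 18 || any(residual_sd <= 0)) {
    fail("residual_sd", "must be 18 strictly positive SDs")
  }
  if (icv_sd <= 0) fail("icv_sd", "must be strictly positive")
  if (is.null(icv_loadings)) {
    icv_loadings <- ifelse(lay$kind == "volume_residual", 0.40, 0)
  }
  if (length(icv_loadings) != 18 || any(icv_loadings < 0)) {
    fail("icv_loadings", "must be 18 nonnegative loadings")
  }
  if (!setequal(names(outcome_effects), outcome_names())) {
    fail("outcome_effects", "must be a named list covering every outcome")
  }
  if (any(vapply(outcome_effects, length, 1L) != K_true)) {
    fail("outcome_effects", "each element must have length K_true")
  }
  if (!setequal(names(diagnosis_base_prevalence), diagnosis_names())) {
    fail("diagnosis_base_prevalence", "must name every diagnosis")
  }
  if (any(diagnosis_base_prevalence <= 0 | diagnosis_base_prevalence >= 1)) {
    fail("diagnosis_base_prevalence", "must lie in (0, 1)")
  }
  if (any(vapply(diagnosis_class_logodds, length, 1L) != K_true)) {
    fail("diagnosis_class_logodds", "each element must have length K_true")
  }
  if (weight_dispersion <= 0) fail("weight_dispersion", "must be positive")
  if (missing_outcome_rate < 0 || missing_outcome_rate >= 1) {
    fail("missing_outcome_rate", "must be a probability below 1")
  }
  if (abs(baseline_followup_cor) >= 1) {
    fail("baseline_followup_cor", "must lie in (-1, 1)")
  }
  cfg <- list(n_families = as.integer(n_families),
              prob_second_child = prob_second_child,
              n_sites = as.integer(n_sites), K_true = as.integer(K_true),
              mixing_proportions = mixing_proportions,
              class_means = class_means, residual_sd = residual_sd,
              icv_mean = icv_mean, icv_sd = icv_sd, icv_sex_d = icv_sex_d,
              icv_loadings = icv_loadings,
              outcome_effects = outcome_effects[outcome_names()],
              baseline_followup_cor = baseline_followup_cor,
              diagnosis_base_prevalence =
                diagnosis_base_prevalence[diagnosis_names()],
              diagnosis_class_logodds =
                diagnosis_class_logodds[diagnosis_names()],
              weight_dispersion = weight_dispersion, site_sd = site_sd,
              missing_outcome_rate = missing_outcome_rate,
              floor_outcomes = floor_outcomes,
              sex_p_female = sex_p_female, age_range = age_range,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Mixture-implied standardized profile means
#'
#' The class means the analysis pipeline should recover after ICV
#' residualization (volumes) and full-sample standardization:
#' `(mu_kj - mean_j) / sd_j`, where `sd_j` is the post-residualization
#' marginal SD, i.e. `sqrt(B_j + r_j^2)` for volume indicators (the ICV
#' loading's variance share is removed by residualization) and
#' `sqrt(B_j + r_j^2 + l_j^2)` for thickness indicators.
#'
#' @param config a `cohort_config`.
#' @return `K_true` x 18 matrix on the standardized indicator scale.
#' @export
true_standardized_means <- function(config) {
  M <- config$class_means
  p <- config$mixing_proportions
  lay <- indicator_layout()
  gm <- colSums(p * M)
  B <- colSums(p * sweep(M, 2, gm)^2)
  tot <- B + config$residual_sd^2 +
    ifelse(lay$kind == "thickness", config$icv_loadings^2, 0)
  sweep(sweep(M, 2, gm), 2, sqrt(tot), "/")
}

#' Generate a synthetic cohort
#'
#' Deterministic given `config$seed`. Each subject's 18 latent indicators
#' are drawn as class mean + `icv_loading * standardized ICV` + independent
#' Gaussian noise, then mapped to measurement units (cm^3 / mm).
#' Dimensional outcomes get class-specific means, a site intercept, and an
#' autoregressive baseline -> follow-up link; diagnoses are Bernoulli with
#' class-specific log-odds shifts. `true_class` records the simulation
#' truth and is never consumed by analysis stages.
#'
#' @param config a `cohort_config`.
#' @return data.frame with one row per subject (class `cohort_table`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_families < 1) stop("generate_cohort: n_families must be >= 1")
  lay <- indicator_layout()
  rs <- roi_scale_table()
  os <- outcome_scale_table()
  with_seed(config$seed, {
    nfam <- config$n_families
    kids <- 1L + rbinom(nfam, 1L, config$prob_second_child)
    fam <- rep(seq_len(nfam), kids)
    n <- length(fam)
    site_of_family <- sample.int(config$n_sites, nfam, replace = TRUE)
    site <- site_of_family[fam]
    sex <- rbinom(n, 1, config$sex_p_female)          # 1 = female
    age <- runif(n, config$age_range[1], config$age_range[2])
    icv_z <- rnorm(n, mean = (1 - sex) * config$icv_sex_d -
                     (1 - config$sex_p_female) * config$icv_sex_d)
    icv <- config$icv_mean + config$icv_sd * icv_z
    cl <- sample.int(config$K_true, n, replace = TRUE,
                     prob = config$mixing_proportions)
    noise <- matrix(rnorm(n * 18), n, 18) *
      rep(config$residual_sd, each = n)
    lat <- config$class_means[cl, , drop = FALSE] +
      outer(icv_z, config$icv_loadings) + noise
    raw <- sweep(sweep(lat, 2, rs$scale, "*"), 2, rs$center, "+")
    colnames(raw) <- lay$indicator

    ## site intercepts per outcome (SD units)
    site_int <- matrix(rnorm(config$n_sites * length(outcome_names()),
                             sd = config$site_sd),
                       config$n_sites, length(outcome_names()))
    rho <- config$baseline_followup_cor
    outc <- list()
    for (oi in seq_along(outcome_names())) {
      onm <- outcome_names()[oi]
      a <- config$outcome_effects[[onm]]
      mu <- a[cl] + site_int[site, oi]
      e0 <- rnorm(n)
      y0 <- mu + e0
      y1 <- mu + rho * e0 + sqrt(1 - rho^2) * rnorm(n)
      if (config$floor_outcomes) {
        loc <- os$location[os$outcome == onm]
        scl <- os$scale[os$outcome == onm]
        y0 <- pmax(loc + scl * y0, 0)
        y1 <- pmax(loc + scl * y1, 0)
      }
      outc[[paste0(onm, "_bl")]] <- y0
      outc[[paste0(onm, "_fu")]] <- y1
    }
    diag_cols <- list()
    for (dnm in diagnosis_names()) {
      lo <- qlogis(config$diagnosis_base_prevalence[[dnm]]) +
        config$diagnosis_class_logodds[[dnm]][cl]
      diag_cols[[dnm]] <- rbinom(n, 1, plogis(lo))
    }
    w <- rlnorm(n, sdlog = config$weight_dispersion)
    w <- w / mean(w)

    cohort <- data.frame(
      subject_id = sprintf("S%06d", seq_len(n)),
      family_id = sprintf("F%05d", fam),
      site_id = sprintf("site%02d", site),
      sampling_weight = w,
      age = age, sex = sex, icv = icv,
      stringsAsFactors = FALSE)
    cohort <- cbind(cohort, as.data.frame(raw), as.data.frame(outc),
                    as.data.frame(diag_cols))
    cohort$true_class <- cl

    if (config$missing_outcome_rate > 0) {
      ocols <- names(outc)
      for (cn in ocols) {
        miss <- runif(n) < config$missing_outcome_rate
        cohort[[cn]][miss] <- NA_real_
      }
    }
    class(cohort) <- c("cohort_table", "data.frame")
    cohort
  })
}

#' Select one participant per family
#'
#' Uniform random selection within each family, deterministic given `seed`.
#'
#' @param cohort a cohort data.frame with a `family_id` column.
#' @param seed integer seed.
#' @return the selected subset, one row per family.
#' @export
select_one_per_family <- function(cohort, seed = 1L) {
  if (is.null(cohort$family_id) || nrow(cohort) == 0) {
    stop("select_one_per_family: cohort is empty or lacks family_id")
  }
  with_seed(seed, {
    u <- runif(nrow(cohort))
    keep <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$family_id),
                          function(ix) ix[which.max(u[ix])]),
                   use.names = FALSE)
    out <- cohort[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write a cohort with config and manifest
#'
#' Writes the cohort as UTF-8 CSV, the configuration as YAML, and a JSON
#' manifest recording the seed and the config file's MD5 hash.
#'
#' @param cohort a cohort data.frame.
#' @param config the `cohort_config` that generated it.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "cohort.csv")
  cfgp <- file.path(dir, "cohort_config.yaml")
  manp <- file.path(dir, "manifest.json")
  utils::write.csv(cohort, csv, row.names = FALSE, fileEncoding = "UTF-8")
  cfg <- unclass(config)
  cfg$class_means <- apply(config$class_means, 1, as.numeric,
                           simplify = FALSE)
  yaml::write_yaml(cfg, cfgp)
  jsonlite::write_json(
    list(seed = config$seed, n_subjects = nrow(cohort),
         config_md5 = unname(tools::md5sum(cfgp))),
    manp, auto_unbox = TRUE)
  invisible(c(cohort = csv, config = cfgp, manifest = manp))
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "Cohort config: %d families, %d sites, K_true = %d, seed = %d\n",
    x$n_families, x$n_sites, x$K_true, x$seed))
  invisible(x)
}
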