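# Shared simulation helpers for the test suite.

# Parameters of the generating mixture on the standardized indicator scale
# (what the pipeline sees after residualization + standardization).
true_model_params <- function(cfg) {
  lay <- indicator_layout()
  M <- cfg$class_means
  p <- cfg$mixing_proportions
  gm <- colSums(p * M)
  B <- colSums(p * sweep(M, 2, gm)^2)
  tot <- B + cfg$residual_sd^2 +
    ifelse(lay$kind == "thickness", cfg$icv_loadings^2, 0)
  list(prop = p, means = true_standardized_means(cfg),
       variances = cfg$residual_sd^2 / tot)
}

null_outcome_effects <- function(K = 5) {
  lapply(default_outcome_effects(K), function(v) rep(0, K))
}

# A small cohort with defaults, one row per family, with indicators built.
make_analysis_sample <- function(n_families = 800, seed = 1, ...) {
  cfg <- cohort_config(n_families = n_families, seed = seed, ...)
  co <- generate_cohort(cfg)
  one <- select_one_per_family(co, seed = seed + 1)
  im <- build_indicator_matrix(one)
  list(cfg = cfg, cohort = one[im$rows, , drop = FALSE], indicators = im)
}

# Draw from a K-component Gaussian mixture with diagonal shared variances.
rmix <- function(n, prop, means, sds) {
  K <- length(prop)
  J <- ncol(means)
  cl <- sample.int(K, n, replace = TRUE, prob = prop)
  list(z = means[cl, , drop = FALSE] +
         matrix(rnorm(n * J), n, J) * rep(sds, each = n),
       cl = cl)
}
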