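# Shared fixture builders. Everything is generated in code at test time.

# Small cohort pushed through superimposition + PCA, with Mahalanobis
# distances from the overall mean shape (the screening phenotype).
make_distance_cohort <- function(n = 120, n_markers = 40, n_chromosomes = 4,
                                 n_pairs = 5, n_midline = 4, seed = 1,
                                 maf_range = c(0.05, 0.5),
                                 variance_pairs = list(),
                                 additive_qtl = list(), ...) {
  cfg <- simulation_config(
    n_individuals = n, n_markers = n_markers, n_chromosomes = n_chromosomes,
    n_pairs = n_pairs, n_midline = n_midline, maf_range = maf_range,
    variance_pairs = variance_pairs, additive_qtl = additive_qtl,
    seed = seed, ...
  )
  co <- simulate_cohort(cfg)
  dec <- shape_pca(gpa_object_symmetry(co$landmarks, co$map))
  Y <- dec$pca_scores
  model <- fit_marker_mean_model(Y)
  d <- residual_distance(Y, model, D = residual_covariance(model = model))
  list(cohort = co, decomposition = dec, Y = Y, model = model, d = d)
}

# Block-diagonal sibship relatedness (families of `fam`, within-family 0.5).
make_sibship_K <- function(n, fam = 4) {
  kronecker(diag(n / fam), matrix(0.5, fam, fam) + 0.5 * diag(fam))
}

# Random symmetric positive-definite matrix.
make_spd <- function(q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(q * q), q)
  crossprod(a) + diag(q) * 0.5
}

# Random landmark-basis covariance over L landmarks (3L coordinates).
make_landmark_cov <- function(n_landmarks, seed = NULL) {
  make_spd(3L * n_landmarks, seed = seed)
}

# Reflect-relabel as a linear operator test helper (flattened vectors).
apply_reflect_vec <- function(v, map) {
  p <- map$n_landmarks
  cfg <- matrix(v, p, 3, byrow = TRUE)
  as.numeric(t(reflect_relabel(cfg, map)))
}
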