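#' Configure an end-to-end analysis run
#'
#' Exactly one of `simulate` (a [simulation_config()]) or `input_paths` must
#' be supplied. `input_paths` is a named list with elements `landmarks`,
#' `symmetry_map`, `dosages`, `marker_map` and optionally `annotation`,
#' `craniofacial`, `growth` (gene category lists).
#'
#' @param simulate A `simulation_config`, or `NULL`.
#' @param input_paths Named list of file paths, or `NULL`.
#' @param screen_threshold Marginal-epistasis screening threshold (default
#'   1e-6).
#' @param pair_alpha Pairwise-interaction significance level (default
#'   0.001).
#' @param n_perm Permutations for genome-wide thresholds (default 1000).
#' @param levels Genome-wide significance levels (default 5\% and 10\%).
#' @param run_additive,run_epistasis Stage toggles.
#' @param seed Root seed; stages draw from deterministic substreams.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, input_paths = NULL,
                       screen_threshold = 1e-6, pair_alpha = 0.001,
                       n_perm = 1000L, levels = c(0.05, 0.10),
                       run_additive = TRUE, run_epistasis = TRUE,
                       seed = 1L, out_dir = tempfile("shaperobust_run_")) {
  if (is.null(simulate) == is.null(input_paths)) {
    abort("Supply exactly one of `simulate` or `input_paths`.")
  }
  if (!is.null(input_paths)) {
    need <- c("landmarks", "symmetry_map", "dosages", "marker_map")
    missing <- setdiff(need, names(input_paths))
    if (length(missing)) {
      abort(sprintf("`input_paths` is missing: %s.", paste(missing, collapse = ", ")))
    }
  }
  if (screen_threshold <= 0 || screen_threshold >= 1) abort("`screen_threshold` must be in (0, 1).")
  if (pair_alpha <= 0 || pair_alpha >= 1) abort("`pair_alpha` must be in (0, 1).")
  structure(list(simulate = simulate, input_paths = input_paths,
                 screen_threshold = screen_threshold, pair_alpha = pair_alpha,
                 n_perm = check_count(n_perm, "n_perm", 20L),
                 levels = as.numeric(levels),
                 run_additive = isTRUE(run_additive),
                 run_epistasis = isTRUE(run_epistasis),
                 seed = check_count(seed, "seed"), out_dir = out_dir),
            class = "run_config")
}

load_run_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    list(landmarks = cohort$landmarks, map = cohort$map,
         dosages = cohort$dosages, cohort = cohort)
  } else {
    ip <- config$input_paths
    for (f in c("landmarks", "symmetry_map", "dosages", "marker_map")) {
      if (!file.exists(ip[[f]])) {
        abort(sprintf("Missing input file for `%s`: %s", f, ip[[f]]))
      }
    }
    list(landmarks = read_landmarks(ip$landmarks),
         map = read_symmetry_map(ip$symmetry_map),
         dosages = read_dosages(ip$dosages, ip$marker_map),
         cohort = NULL)
  }
}

run_manifest <- function(config, stage, extra = list()) {
  cfg <- unclass(config)
  cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate) else NULL
  if (!is.null(cfg$simulate)) {
    cfg$simulate$additive_qtl <- lapply(cfg$simulate$additive_qtl, function(q) {
      list(marker = q$marker, effect_norm = sqrt(sum(q$effect^2)))
    })
  }
  c(list(stage = stage,
         config_hash = rlang::hash(cfg),
         defaults = list(distance_mode = "sqrt",
                         grm_standardization = "centered-scaled crossproduct / M",
                         mahalanobis_inverse = "pc-truncated pseudo-inverse",
                         subspace_k = "sweep 1..floor(q/2)",
                         power_beta = "0.9 / (1 + lambda_1)"),
         config = cfg),
    extra)
}

# Shared first stages: superimposition, PCA, distances.
run_morphometry <- function(inputs) {
  decomp <- gpa_object_symmetry(inputs$landmarks, inputs$map)
  decomp <- shape_pca(decomp)
  decomp
}

#' Run the canalization analysis pipeline
#'
#' Morphometry (object-symmetric Procrustes + PCA), Mahalanobis distances
#' from the overall mean shape, additive variance-QTL scan with permutation
#' thresholds, marginal-epistasis screen and pairwise interaction follow-up.
#' All result tables are written to the configured output directory together
#' with a YAML manifest carrying the configuration hash and the decision
#' defaults.
#'
#' @param config A [run_config()].
#' @return Invisibly, a result bundle: list with `decomposition`,
#'   `distances`, `scan`, `thresholds`, `screen`, `candidates`,
#'   `interactions`.
#' @export
run_canalization <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_run_inputs(config)
  decomp <- run_morphometry(inputs)
  Y <- decomp$pca_scores
  model <- fit_marker_mean_model(Y)
  S <- residual_covariance(model = model)
  dset <- residual_distance(Y, model, D = S)
  write_distance_set(dset, file.path(config$out_dir, "distances_canalization.tsv"))
  out <- list(decomposition = decomp, distances = dset)

  if (config$run_additive) {
    set.seed(config$seed + 101L)
    scan <- additive_scan(dset, inputs$dosages)
    thr <- permutation_thresholds(scan, n_perm = config$n_perm,
                                  levels = config$levels)
    write_scan_result(scan, file.path(config$out_dir, "additive_scan.tsv"))
    write_thresholds(thr, file.path(config$out_dir, "thresholds.json"))
    out$scan <- scan
    out$thresholds <- thr
  }
  if (config$run_epistasis) {
    set.seed(config$seed + 102L)
    screen <- epistasis_screen(dset, inputs$dosages)
    readr::write_tsv(screen, file.path(config$out_dir, "epistasis_screen.tsv"))
    candidates <- screen_markers(screen, threshold = config$screen_threshold)
    out$screen <- screen
    out$candidates <- candidates
    if (nrow(candidates) >= 2L) {
      inter <- pairwise_interaction_scan(Y, candidates$marker, inputs$dosages,
                                         alpha = config$pair_alpha)
      write_interaction_table(inter, file.path(config$out_dir, "interactions.tsv"))
      out$interactions <- inter
    }
  }
  yaml::write_yaml(run_manifest(config, "canalization"),
                   file.path(config$out_dir, "manifest.yaml"))
  invisible(out)
}

#' Run the developmental-stability (FA) analysis pipeline
#'
#' Same scan stages as [run_canalization()], applied to the per-individual
#' fluctuating-asymmetry distances.
#'
#' @param config A [run_config()].
#' @return Invisibly, a result bundle like [run_canalization()]'s.
#' @export
run_fa <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_run_inputs(config)
  decomp <- run_morphometry(inputs)
  dset <- fa_distance(decomp)
  write_distance_set(dset, file.path(config$out_dir, "distances_fa.tsv"))
  out <- list(decomposition = decomp, distances = dset)

  if (config$run_additive) {
    set.seed(config$seed + 201L)
    scan <- additive_scan(dset, inputs$dosages)
    thr <- permutation_thresholds(scan, n_perm = config$n_perm,
                                  levels = config$levels)
    write_scan_result(scan, file.path(config$out_dir, "additive_scan_fa.tsv"))
    write_thresholds(thr, file.path(config$out_dir, "thresholds_fa.json"))
    out$scan <- scan
    out$thresholds <- thr
  }
  if (config$run_epistasis) {
    set.seed(config$seed + 202L)
    screen <- epistasis_screen(dset, inputs$dosages)
    readr::write_tsv(screen, file.path(config$out_dir, "epistasis_screen_fa.tsv"))
    candidates <- screen_markers(screen, threshold = config$screen_threshold)
    out$screen <- screen
    out$candidates <- candidates
    if (nrow(candidates) >= 2L) {
      Y <- decomp$pca_scores
      inter <- pairwise_interaction_scan(Y, candidates$marker, inputs$dosages,
                                         alpha = config$pair_alpha)
      write_interaction_table(inter, file.path(config$out_dir, "interactions_fa.tsv"))
      out$interactions <- inter
    }
  }
  yaml::write_yaml(run_manifest(config, "fa"),
                   file.path(config$out_dir, "manifest.yaml"))
  invisible(out)
}

#' Estimate and compare the P, G, E and FA covariance matrices
#'
#' Estimates P and FA from the symmetric and asymmetric Procrustes
#' components, G and E by block REML of the shape PC scores on the GRM
#' (back-rotated to landmark coordinates), then runs the comparison suite:
#' Krzanowski subspace profile, pairwise distances/correlations/angles and
#' eccentricities on half configurations (midline excluded whenever the FA
#' matrix is involved), and the multivariate heritability spectrum.
#'
#' @param config A [run_config()].
#' @param block1_size Leading-PC block for [estimate_G_E()].
#' @param n_perm,n_random Monte-Carlo sizes for the comparison tests.
#' @return Invisibly, list with `matrices` (landmark basis), `similarity`
#'   (with and without midline), `subspace_profile`, `heritability`.
#' @export
run_matrices <- function(config, block1_size = 10L, n_perm = 1000L,
                         n_random = 10000L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_run_inputs(config)
  decomp <- run_morphometry(inputs)
  map <- inputs$map

  P <- sample_covariance(decomp$symmetric, "P")
  FAm <- sample_covariance(decomp$asymmetric, "FA")
  out <- list()
  have_geno <- !is.null(inputs$dosages)
  if (have_geno) {
    K <- genomic_relatedness(inputs$dosages)
    b1 <- min(block1_size, ncol(decomp$pca_scores))
    ge <- estimate_G_E(decomp$pca_scores, K, block1_size = b1)
    G <- cov_to_landmark_basis(ge$G, decomp$pca_vectors)
    E <- cov_to_landmark_basis(ge$E, decomp$pca_vectors)
    P_pc <- sample_covariance(decomp$pca_scores, "P", basis = "pc")
    herit <- heritability_spectrum(ge$G, P_pc)
    write_heritability_spectrum(herit, file.path(config$out_dir, "heritability.tsv"))
    out$heritability <- herit
    out$GE_fit <- ge
    mats <- list(P = P, G = G, E = E, FA = FAm)
  } else {
    warn("No genotypes available: skipping G and E, comparing P and FA only.")
    mats <- list(P = P, FA = FAm)
  }
  out$matrices <- mats

  set.seed(config$seed + 301L)
  # all-matrix comparisons exclude the midline (FA is involved)
  half <- lapply(mats, prepare_half_configuration, map = map,
                 include_midline = FALSE)
  sim_half <- similarity_table(half, n_perm = n_perm, n_random = n_random)
  sim_half$pairs$configuration <- "half"
  sim_all <- sim_half$pairs
  ecc_tab <- sim_half$eccentricity
  ecc_tab$configuration <- "half"
  sym_labels <- setdiff(names(mats), "FA")
  if (length(sym_labels) >= 2L) {
    with_mid <- lapply(mats[sym_labels], prepare_half_configuration, map = map,
                       include_midline = TRUE)
    sim_mid <- similarity_table(with_mid, n_perm = n_perm, n_random = n_random)
    sim_mid$pairs$configuration <- "half+midline"
    sim_all <- dplyr::bind_rows(sim_all, sim_mid$pairs)
    emid <- sim_mid$eccentricity
    emid$configuration <- "half+midline"
    ecc_tab <- dplyr::bind_rows(ecc_tab, emid)
  }
  readr::write_tsv(sim_all, file.path(config$out_dir, "similarity.tsv"))
  readr::write_tsv(ecc_tab, file.path(config$out_dir, "eccentricity.tsv"))
  out$similarity <- list(pairs = sim_all, eccentricity = ecc_tab)

  profile <- krzanowski_profile(half)
  readr::write_tsv(profile, file.path(config$out_dir, "subspace_profile.tsv"))
  out$subspace_profile <- profile

  for (lbl in names(mats)) {
    write_covariance_tsv(mats[[lbl]],
                         file.path(config$out_dir, sprintf("matrix_%s.tsv", lbl)))
  }
  yaml::write_yaml(run_manifest(config, "matrices"),
                   file.path(config$out_dir, "manifest.yaml"))
  invisible(out)
}
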