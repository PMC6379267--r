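#' Configure a synthetic genotype-and-shape cohort
#'
#' Bundles every parameter of the synthetic cohort generator: cohort and
#' genome size, the minor-allele-frequency range of the simulated dosages,
#' the landmark layout (bilateral pairs + midline points), additive QTL
#' acting on the symmetric mean shape, and epistatic marker pairs that scale
#' the residual variance — either the among-individual symmetric variance
#' (canalization) or the side-specific variance generating fluctuating
#' asymmetry (developmental stability).
#'
#' Variance effects are multiplicative on the noise variance: individual `i`
#' gets multiplier `exp(sum of lambda over pairs whose interaction genotype
#' fires)`, where a pair fires when the individual carries dosage >= 1 at
#' both markers. Additive effects are vectors in the free coordinates of the
#' symmetric shape space (`3 * n_pairs + 2 * n_midline` numbers).
#'
#' @param n_individuals,n_markers,n_chromosomes Cohort and genome size.
#' @param maf_range Length-2 interval in (0, 0.5] from which per-marker
#'   allele frequencies are drawn; the default lower bound 0.02 mirrors the
#'   usual 2\% MAF filter.
#' @param n_pairs,n_midline Landmark layout (defaults: the 17 + 10 skull
#'   layout).
#' @param additive_qtl List of `list(marker =, effect =)`; `effect` is a
#'   numeric vector of length `3 * n_pairs + 2 * n_midline` (free symmetric
#'   coordinates).
#' @param variance_pairs List of `list(marker_j =, marker_k =, lambda =,
#'   level =, coding =)` with `level` one of `"symmetric"` (among-individual,
#'   canalization) or `"fa"` (side-specific, developmental stability), and
#'   `coding` either `"and"` (default; fires when both markers carry dosage
#'   >= 1) or `"balanced"` (+/-1 product of carrier indicators — a purely
#'   epistatic XOR pattern with no marginal effect at carrier frequency
#'   1/2).
#' @param base_symmetric_noise_sd,base_fa_noise_sd Baseline standard
#'   deviations (in landmark coordinate units) of the symmetric and
#'   side-specific perturbations.
#' @param anisotropy Geometric decay ratio of successive noise variances
#'   across the free shape coordinates; 1 (default) is isotropic.
#' @param nuisance_transforms Apply a random similarity transform (rotation,
#'   translation, mild scaling) to each simulated configuration, emulating
#'   arbitrary digitizing coordinates.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 692, n_markers = 1000,
                              n_chromosomes = 19,
                              maf_range = c(0.02, 0.5),
                              n_pairs = 17, n_midline = 10,
                              additive_qtl = list(),
                              variance_pairs = list(),
                              base_symmetric_noise_sd = 0.02,
                              base_fa_noise_sd = 0.01,
                              anisotropy = 1,
                              nuisance_transforms = TRUE,
                              seed = 1L) {
  cfg <- list(
    n_individuals = check_count(n_individuals, "n_individuals", 2L),
    n_markers = check_count(n_markers, "n_markers", 1L),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes", 1L),
    maf_range = as.numeric(maf_range),
    n_pairs = check_count(n_pairs, "n_pairs"),
    n_midline = check_count(n_midline, "n_midline"),
    additive_qtl = additive_qtl,
    variance_pairs = variance_pairs,
    base_symmetric_noise_sd = check_number(base_symmetric_noise_sd,
                                           "base_symmetric_noise_sd", 0, TRUE),
    base_fa_noise_sd = check_number(base_fa_noise_sd, "base_fa_noise_sd", 0, TRUE),
    anisotropy = check_number(anisotropy, "anisotropy", 0, TRUE),
    nuisance_transforms = isTRUE(nuisance_transforms),
    seed = check_count(seed, "seed")
  )
  if (length(cfg$maf_range) != 2L || any(is.na(cfg$maf_range)) ||
      cfg$maf_range[1L] <= 0 || cfg$maf_range[2L] > 0.5 ||
      cfg$maf_range[1L] > cfg$maf_range[2L]) {
    abort("`maf_range` must be an interval inside (0, 0.5].")
  }
  if (cfg$n_markers < cfg$n_chromosomes) {
    abort("`n_markers` must be >= `n_chromosomes`.")
  }
  if (3L * cfg$n_pairs + 2L * cfg$n_midline > 0 &&
      cfg$n_pairs < 3L && cfg$n_midline < 3L) {
    abort("Degenerate shape: need n_pairs >= 3 or n_midline >= 3.")
  }
  d_sym <- 3L * cfg$n_pairs + 2L * cfg$n_midline
  for (q in cfg$additive_qtl) {
    if (!all(c("marker", "effect") %in% names(q))) {
      abort("Each additive_qtl entry needs `marker` and `effect`.")
    }
    if (q$marker < 1L || q$marker > cfg$n_markers) {
      abort("additive_qtl marker index out of range.")
    }
    if (length(q$effect) != d_sym) {
      abort(sprintf("additive_qtl effect must have length %d.", d_sym))
    }
  }
  for (vp in cfg$variance_pairs) {
    if (!all(c("marker_j", "marker_k", "lambda") %in% names(vp))) {
      abort("Each variance_pairs entry needs `marker_j`, `marker_k`, `lambda`.")
    }
    if (vp$marker_j == vp$marker_k) {
      abort("A variance pair must cite two distinct markers.")
    }
    if (max(vp$marker_j, vp$marker_k) > cfg$n_markers ||
        min(vp$marker_j, vp$marker_k) < 1L) {
      abort("variance_pairs marker index out of range.")
    }
    lvl <- vp$level %||% "symmetric"
    if (!lvl %in% c("symmetric", "fa")) {
      abort('variance_pairs level must be "symmetric" or "fa".')
    }
    coding <- vp$coding %||% "and"
    if (!coding %in% c("and", "balanced")) {
      abort('variance_pairs coding must be "and" or "balanced".')
    }
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate an allele-dosage matrix with a marker map
#'
#' Draws per-marker allele frequencies uniformly from `maf_range`, genotypes
#' as binomial(2, p) counts, and redraws any marker whose empirical minor
#' allele frequency falls below the configured lower bound (emulating the
#' MAF filter applied to real panels). Markers are assigned round-robin to
#' chromosomes with increasing physical positions.
#'
#' @param config A [simulation_config()].
#' @return An object of class `dosage_matrix`: list with `dosages`
#'   (n x M numeric matrix, entries in `[0, 2]`) and `map` (tibble with
#'   `marker`, `chrom`, `pos`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_markers
  lo <- config$maf_range[1L]
  hi <- config$maf_range[2L]
  x <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    for (try in seq_len(1000L)) {
      p <- runif(1L, lo, hi)
      g <- rbinom(n, 2L, p)
      maf <- min(mean(g) / 2, 1 - mean(g) / 2)
      if (maf >= lo || lo <= 1 / (2 * n)) break
    }
    x[, j] <- g
  }
  markers <- sprintf("m%04d", seq_len(m))
  colnames(x) <- markers
  rownames(x) <- sprintf("ind_%d", seq_len(n))
  chrom <- ((seq_len(m) - 1L) %% config$n_chromosomes) + 1L
  pos <- integer(m)
  for (c in seq_len(config$n_chromosomes)) {
    idx <- which(chrom == c)
    pos[idx] <- seq_along(idx) * 250000L
  }
  map <- tibble(marker = markers, chrom = sprintf("chr%d", chrom), pos = pos)
  new_dosage_matrix(x, map)
}

new_dosage_matrix <- function(dosages, map) {
  stopifnot(is.matrix(dosages), nrow(map) == ncol(dosages))
  structure(list(dosages = dosages, map = as_tibble(map)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d individuals x %d markers on %d chromosomes\n",
              nrow(x$dosages), ncol(x$dosages),
              dplyr::n_distinct(x$map$chrom)))
  invisible(x)
}

#' Simulate a perfectly symmetric template configuration
#'
#' Builds a random 3D landmark configuration that is exactly symmetric about
#' the x = 0 midsagittal plane: midline landmarks have zero x-coordinate and
#' paired landmarks are exact mirror images. Landmarks are ordered left_1,
#' right_1, ..., left_P, right_P, midline_1, ..., midline_U (the layout of
#' [default_symmetry_map()]).
#'
#' @param n_pairs,n_midline Landmark counts; their total must be >= 3.
#' @param seed Integer seed.
#' @return A p x 3 matrix with a `symmetry_map` attached as attribute `map`.
#' @export
simulate_base_shape <- function(n_pairs, n_midline, seed = 1L) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  n_midline <- check_count(n_midline, "n_midline")
  if (2L * n_pairs + n_midline < 3L) {
    abort("Degenerate shape: need at least 3 landmarks in total.")
  }
  set.seed(seed)
  map <- default_symmetry_map(n_pairs, n_midline)
  p <- 2L * n_pairs + n_midline
  cfg <- matrix(0, p, 3L)
  if (n_pairs > 0L) {
    left <- cbind(runif(n_pairs, 0.25, 1), runif(n_pairs, -1, 1),
                  runif(n_pairs, -1, 1))
    cfg[map$pairs[, 1L], ] <- left
    right <- left
    right[, 1L] <- -right[, 1L]
    cfg[map$pairs[, 2L], ] <- right
  }
  if (n_midline > 0L) {
    cfg[map$midline, 2L] <- runif(n_midline, -1, 1)
    cfg[map$midline, 3L] <- runif(n_midline, -1, 1)
  }
  colnames(cfg) <- c("x", "y", "z")
  attr(cfg, "map") <- map
  cfg
}

# Basis of the symmetric subspace in free coordinates: each pair contributes
# 3 dof (mirror-matched displacement), each midline landmark 2 in-plane dof.
sym_free_dim <- function(map) 3L * nrow(map$pairs) + 2L * length(map$midline)
asym_free_dim <- function(map) 3L * nrow(map$pairs) + length(map$midline)

# Map free symmetric coordinates to a vectorised p x 3 perturbation.
sym_perturbation <- function(z, map) {
  p <- map$n_landmarks
  ax <- map$reflection_axis
  out <- matrix(0, p, 3L)
  k <- 0L
  for (i in seq_len(nrow(map$pairs))) {
    delta <- z[k + 1:3]
    k <- k + 3L
    out[map$pairs[i, 1L], ] <- delta
    mirrored <- delta
    mirrored[ax] <- -mirrored[ax]
    out[map$pairs[i, 2L], ] <- mirrored
  }
  inplane <- setdiff(1:3, ax)
  for (m in map$midline) {
    out[m, inplane] <- z[k + 1:2]
    k <- k + 2L
  }
  vec_config(out)
}

# Map free asymmetric coordinates to a purely antisymmetric perturbation:
# pairs get delta on the left and minus the mirrored delta on the right;
# midline landmarks move only along the reflection axis.
asym_perturbation <- function(z, map) {
  p <- map$n_landmarks
  ax <- map$reflection_axis
  out <- matrix(0, p, 3L)
  k <- 0L
  for (i in seq_len(nrow(map$pairs))) {
    delta <- z[k + 1:3]
    k <- k + 3L
    out[map$pairs[i, 1L], ] <- delta
    mirrored <- delta
    mirrored[ax] <- -mirrored[ax]
    out[map$pairs[i, 2L], ] <- -mirrored
  }
  for (m in map$midline) {
    out[m, ax] <- z[k + 1L]
    k <- k + 1L
  }
  vec_config(out)
}

#' Draw a random additive effect in the symmetric shape space
#'
#' Helper for building [simulation_config()] QTL entries: a random direction
#' in the free symmetric coordinates, scaled to the requested norm. Uses the
#' current RNG stream.
#'
#' @param map A `symmetry_map`.
#' @param norm Euclidean norm of the effect vector.
#' @return Numeric vector of length `3 * n_pairs + 2 * n_midline`.
#' @export
random_symmetric_effect <- function(map, norm = 1) {
  z <- rnorm(sym_free_dim(map))
  z / sqrt(sum(z^2)) * norm
}

# Interaction codings: "and" fires when both markers carry the minor class
# (dosage >= 1), the simplest epistatic pattern but one with a marginal
# component; "balanced" uses the +/-1 product of carrier indicators (an XOR
# pattern), which has no marginal mean or variance effect when the carrier
# frequency is 1/2 at both markers.
variance_multipliers <- function(dosages, pairs, level) {
  n <- nrow(dosages)
  v <- rep(1, n)
  for (vp in pairs) {
    if ((vp$level %||% "symmetric") != level) next
    cj <- dosages[, vp$marker_j] >= 1
    ck <- dosages[, vp$marker_k] >= 1
    coding <- vp$coding %||% "and"
    term <- if (coding == "balanced") {
      (2 * cj - 1) * (2 * ck - 1)
    } else {
      as.numeric(cj & ck)
    }
    v <- v * exp(vp$lambda * term)
  }
  v
}

#' Simulate a full landmark + genotype cohort with ground truth
#'
#' For each individual the symmetric shape is the template plus additive QTL
#' effects plus symmetric Gaussian noise whose variance is multiplied by
#' `v_i` (driven by the configured `"symmetric"`-level variance pairs); a
#' purely asymmetric perturbation with variance multiplier `w_i` (the
#' `"fa"`-level pairs) then displaces the two sides independently, producing
#' fluctuating asymmetry. Optionally each configuration receives a random
#' similarity transform, which the Procrustes machinery must undo.
#'
#' @param config A [simulation_config()].
#' @return An object of class `shape_cohort`: list with `landmarks`
#'   (p x 3 x n array), `dosages` (a `dosage_matrix`), `map` (the symmetry
#'   map), `truth` (ground-truth record: template, per-QTL effects, variance
#'   pairs, per-individual multipliers `v` and `w`) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  geno <- simulate_genotypes(config)  # seeds the RNG with config$seed
  base <- simulate_base_shape(config$n_pairs, config$n_midline,
                              seed = config$seed + 1L)
  map <- attr(base, "map")
  set.seed(config$seed + 2L)

  n <- config$n_individuals
  p <- map$n_landmarks
  d_sym <- sym_free_dim(map)
  d_asym <- asym_free_dim(map)
  mu <- vec_config(base)

  v <- variance_multipliers(geno$dosages, config$variance_pairs, "symmetric")
  w <- variance_multipliers(geno$dosages, config$variance_pairs, "fa")

  # geometric eigenvalue decay across free coordinates (isotropic when 1)
  aniso_sd <- function(d) {
    if (config$anisotropy == 1 || d <= 1L) return(rep(1, d))
    sqrt(config$anisotropy^(seq_len(d) - 1L))
  }
  sd_sym <- aniso_sd(d_sym)
  sd_asym <- aniso_sd(d_asym)

  additive <- matrix(0, n, 3L * p)
  for (q in config$additive_qtl) {
    additive <- additive +
      tcrossprod(geno$dosages[, q$marker], sym_perturbation(q$effect, map))
  }

  arr <- array(NA_real_, dim = c(p, 3L, n),
               dimnames = list(NULL, c("x", "y", "z"), rownames(geno$dosages)))
  for (i in seq_len(n)) {
    e_sym <- rnorm(d_sym, sd = sd_sym) * config$base_symmetric_noise_sd * sqrt(v[i])
    e_fa <- rnorm(d_asym, sd = sd_asym) * config$base_fa_noise_sd * sqrt(w[i])
    cfg <- mu + additive[i, ] + sym_perturbation(e_sym, map) +
      asym_perturbation(e_fa, map)
    cfg <- unvec_config(cfg, p)
    if (config$nuisance_transforms) {
      cfg <- cfg %*% random_rotation() * exp(rnorm(1L, sd = 0.05))
      cfg <- sweep(cfg, 2L, rnorm(3L, sd = 0.5), "+")
    }
    arr[, , i] <- cfg
  }

  truth <- list(mu = base, map = map, additive_qtl = config$additive_qtl,
                variance_pairs = config$variance_pairs, v = v, w = w)
  structure(list(landmarks = arr, dosages = geno, map = map, truth = truth,
                 config = config),
            class = "shape_cohort")
}

random_rotation <- function() {
  qrz <- qr(matrix(rnorm(9L), 3L))
  q <- qr.Q(qrz) %*% diag(sign(diag(qr.R(qrz))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

#' @export
print.shape_cohort <- function(x, ...) {
  cat(sprintf("<shape_cohort> %d individuals, %d landmarks, %d markers\n",
              dim(x$landmarks)[3L], dim(x$landmarks)[1L],
              ncol(x$dosages$dosages)))
  cat(sprintf("  %d additive QTL, %d variance pairs\n",
              length(x$config$additive_qtl), length(x$config$variance_pairs)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `landmarks.csv` (wide format), `dosages.tsv`, `marker_map.tsv`,
#' `ground_truth.json` and a YAML run manifest echoing the configuration and
#' seed.
#'
#' @param cohort A `shape_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "shape_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landmarks(cohort$landmarks, file.path(dir, "landmarks.csv"))
  write_symmetry_map(cohort$map, file.path(dir, "symmetry_map.tsv"))
  dos <- as_tibble(cohort$dosages$dosages)
  dos <- dplyr::bind_cols(tibble(id = rownames(cohort$dosages$dosages)), dos)
  readr::write_tsv(dos, file.path(dir, "dosages.tsv"))
  readr::write_tsv(cohort$dosages$map, file.path(dir, "marker_map.tsv"))
  truth <- cohort$truth
  truth$mu <- unclass(truth$mu)
  attr(truth$mu, "map") <- NULL
  truth$map <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  manifest <- cohort$config
  manifest$additive_qtl <- lapply(manifest$additive_qtl, function(q) {
    list(marker = q$marker, effect_norm = sqrt(sum(q$effect^2)))
  })
  yaml::write_yaml(list(generator = "shaperobust::simulate_cohort",
                        config = unclass(manifest)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dosage matrix and marker map written by [write_cohort()]
#' @param dosage_path TSV of individuals x markers (first column `id`).
#' @param map_path TSV with columns `marker`, `chrom`, `pos`.
#' @return A `dosage_matrix`.
#' @export
read_dosages <- function(dosage_path, map_path) {
  dos <- readr::read_tsv(dosage_path, show_col_types = FALSE)
  ids <- dos$id
  x <- as.matrix(dos[setdiff(names(dos), "id")])
  rownames(x) <- ids
  map <- readr::read_tsv(map_path, show_col_types = FALSE)
  if (!all(c("marker", "chrom", "pos") %in% names(map))) {
    abort("Marker map must have columns marker, chrom, pos.")
  }
  if (!identical(colnames(x), map$marker)) {
    x <- x[, map$marker, drop = FALSE]
  }
  new_dosage_matrix(x, map)
}
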