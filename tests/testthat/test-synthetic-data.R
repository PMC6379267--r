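test_that("simulated genotypes respect allele-frequency and map contracts", {
  cfg <- simulation_config(n_individuals = 10000, n_markers = 1,
                           n_chromosomes = 1, maf_range = c(0.1, 0.1),
                           n_pairs = 4, n_midline = 3, seed = 3)
  g <- simulate_genotypes(cfg)
  f <- mean(g$dosages) / 2
  expect_gt(f, 0.09)
  expect_lt(f, 0.11)

  cfg2 <- simulation_config(n_individuals = 400, n_markers = 30,
                            n_chromosomes = 3, maf_range = c(0.5, 0.5),
                            n_pairs = 4, n_midline = 3, seed = 5)
  g2 <- simulate_genotypes(cfg2)
  means <- colMeans(g2$dosages)
  se3 <- 3 * sqrt(2 * 0.5 * 0.5 / 400)
  expect_true(all(abs(means - 1) < se3 + 0.05))
  # round-robin chromosome assignment with increasing positions
  expect_equal(sort(unique(g2$map$chrom)), sprintf("chr%d", 1:3))
  for (cc in unique(g2$map$chrom)) {
    expect_true(all(diff(g2$map$pos[g2$map$chrom == cc]) > 0))
  }
  # determinism
  expect_identical(simulate_genotypes(cfg2)$dosages, g2$dosages)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_markers = 2, n_chromosomes = 5),
               "n_markers")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(n_pairs = 1, n_midline = 1), "Degenerate")
  expect_error(
    simulation_config(variance_pairs = list(
      list(marker_j = 3, marker_k = 3, lambda = 1))),
    "distinct")
  expect_error(simulate_base_shape(1, 0), "at least 3")
})

test_that("base shape is exactly symmetric under reflect-relabel", {
  base <- simulate_base_shape(17, 10, seed = 2)
  map <- attr(base, "map")
  expect_equal(nrow(base), 44L)
  expect_equal(reflect_relabel(base, map), base, ignore_attr = TRUE)
  expect_true(all(base[map$midline, 1] == 0))
  # planar case: all landmarks in the midsagittal plane
  flat <- simulate_base_shape(0, 5, seed = 2)
  expect_true(all(flat[, 1] == 0))
})

test_that("null cohorts have unit variance multipliers and no dosage-distance slope", {
  fix <- make_distance_cohort(n = 500, n_markers = 30, seed = 11)
  expect_true(all(fix$cohort$truth$v == 1))
  expect_true(all(fix$cohort$truth$w == 1))
  tvals <- apply(fix$cohort$dosages$dosages, 2, function(a) {
    if (sd(a) == 0) return(0)
    summary(lm(fix$d$d ~ a))$coefficients[2, 3]
  })
  expect_gte(mean(abs(tvals) < 3), 0.95)
})

test_that("an additive QTL effect direction is recovered by least squares", {
  map <- default_symmetry_map(5, 4)
  set.seed(42)
  alpha <- random_symmetric_effect(map, norm = 0.05)
  fix <- make_distance_cohort(
    n = 500, n_markers = 20, seed = 13,
    additive_qtl = list(list(marker = 4L, effect = alpha)),
    base_symmetric_noise_sd = 0.1 * sqrt(sum(alpha^2)) / sqrt(length(alpha)),
    nuisance_transforms = FALSE
  )
  a <- fix$cohort$dosages$dosages[, 4]
  # recover the effect in tangent coordinates, compare against the truth
  fit <- fit_marker_mean_model(fix$decomposition$symmetric, a)
  truth_vec <- shaperobust:::sym_perturbation(alpha, map)
  # remove the per-axis mean (GPA removes translations)
  tm <- matrix(truth_vec, ncol = 3, byrow = TRUE)
  tm <- sweep(tm, 2, colMeans(tm))
  vcorr <- abs(cor(fit$alpha, as.numeric(t(tm))))
  expect_gt(vcorr, 0.95)
})

test_that("a planted among-individual variance pair raises group distances", {
  hits <- replicate(10, NA)
  for (r in seq_len(10)) {
    fix <- make_distance_cohort(
      n = 300, n_markers = 10, seed = 100 + r, maf_range = c(0.2, 0.3),
      variance_pairs = list(list(marker_j = 2L, marker_k = 7L, lambda = 1.5,
                                 level = "symmetric"))
    )
    x <- fix$cohort$dosages$dosages
    fires <- x[, 2] >= 1 & x[, 7] >= 1
    hits[r] <- t.test(fix$d$d[fires], fix$d$d[!fires],
                      alternative = "greater")$p.value
  }
  # strong effect: most replicates individually significant
  expect_gte(mean(hits < 0.01), 0.8)
})

test_that("cohorts are reproducible and FA noise leaves the symmetric component intact", {
  cfg <- simulation_config(n_individuals = 30, n_markers = 10,
                           n_chromosomes = 2, n_pairs = 4, n_midline = 3,
                           seed = 9)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$landmarks, co2$landmarks)
  expect_identical(co1$dosages$dosages, co2$dosages$dosages)

  # same cohort with and without tiny FA noise: symmetric components match
  base_cfg <- list(n_individuals = 25, n_markers = 10, n_chromosomes = 2,
                   n_pairs = 4, n_midline = 3, seed = 17,
                   nuisance_transforms = FALSE,
                   base_symmetric_noise_sd = 1e-3)
  co_a <- simulate_cohort(do.call(simulation_config,
                                  c(base_cfg, base_fa_noise_sd = 1e-8)))
  co_b <- simulate_cohort(do.call(simulation_config,
                                  c(base_cfg, base_fa_noise_sd = 1e-3)))
  dec_a <- gpa_object_symmetry(co_a$landmarks, co_a$map)
  dec_b <- gpa_object_symmetry(co_b$landmarks, co_b$map)
  diffs <- abs(dec_a$symmetric - dec_b$symmetric)
  expect_lt(max(diffs), 1e-4)
})

test_that("write_cohort produces the full plain-text bundle", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_individuals = 12, n_markers = 8,
                           n_chromosomes = 2, n_pairs = 3, n_midline = 3,
                           seed = 4)
  co <- simulate_cohort(cfg)
  write_cohort(co, dir)
  files <- c("landmarks.csv", "dosages.tsv", "marker_map.tsv",
             "ground_truth.json", "manifest.yaml", "symmetry_map.tsv")
  expect_true(all(file.exists(file.path(dir, files))))
  back <- read_dosages(file.path(dir, "dosages.tsv"),
                       file.path(dir, "marker_map.tsv"))
  expect_equal(back$dosages, co$dosages$dosages, ignore_attr = TRUE)
  arr <- read_landmarks(file.path(dir, "landmarks.csv"))
  expect_equal(arr, co$landmarks, tolerance = 1e-12, ignore_attr = TRUE)
})
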