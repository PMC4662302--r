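test_that("range size counts distinct half-open grid cells times 123", {
  one <- data.frame(lon = c(0.01, 0.05, 0.09), lat = c(0.02, 0.05, 0.08))
  expect_equal(range_size(one)$area_km2, 123)
  two <- data.frame(lon = c(0.05, 0.15), lat = c(0.05, 0.05))
  expect_equal(two_cells <- range_size(two)$n_cells, 2)
  expect_equal(range_size(two)$area_km2, 246)
  # five centroids at least 0.1 degrees apart occupy five cells
  occ <- simulate_occurrences(5, c(-106, -105, 38, 39), points_per_pop = 3,
                              jitter_sd = 0, seed = 4)
  cent <- unique(occ[, c("lon", "lat")])
  if (nrow(unique(floor(cent / 0.1))) == 5)
    expect_equal(range_size(occ)$area_km2, 5 * 123)
  expect_error(range_size(data.frame(lon = numeric(), lat = numeric())),
               "empty")
  expect_error(range_size(data.frame(lon = 200, lat = 0)), "out of range")
})

test_that("range size is invariant to duplication and permutation", {
  set.seed(90)
  pts <- data.frame(lon = runif(50, -106, -104), lat = runif(50, 37, 39))
  base <- range_size(pts)
  expect_equal(range_size(pts[sample(50), ]), base)
  expect_equal(range_size(rbind(pts, pts)), base)
  # brute-force distinct-cell enumeration
  cells <- unique(paste(floor(pts$lon / 0.1), floor(pts$lat / 0.1)))
  expect_equal(base$area_km2, 123 * length(cells))
})

test_that("Fst/Qst point ratios and degenerate distributions behave analytically", {
  f <- bootstrap_dist("Fst", rep(0.4, 100), 0.4)
  q <- bootstrap_dist("QST", rep(0.2, 100), 0.2)
  r <- fst_qst_ratio(f, q)
  expect_equal(r$point, 2)
  expect_equal(diff(r$ci), 0)
  expect_equal(r$mean, 2)
  # identical distributions: ratio exactly 1, drift not rejected
  set.seed(91)
  reps <- runif(200, 0.1, 0.4)
  a <- bootstrap_dist("Fst", reps, 0.25)
  b <- bootstrap_dist("QST", reps, 0.25)
  ri <- fst_qst_ratio(a, b)
  expect_true(all(ri$replicates == 1))
  expect_equal(ri$point, 1)
  expect_false(ri$drift_rejected_ci)
  expect_false(ri$drift_rejected_sd)
  # all-zero Qst replicates are an error
  z <- bootstrap_dist("QST", rep(0, 50), 0)
  expect_error(fst_qst_ratio(a, z), "near. zero")
})

test_that("near-zero Qst replicates are dropped and counted", {
  f <- bootstrap_dist("Fst", rep(0.3, 50), 0.3)
  q <- bootstrap_dist("QST", c(rep(0, 10), rep(0.15, 40)), 0.15)
  r <- fst_qst_ratio(f, q)
  expect_equal(r$n_dropped, 10)
  expect_equal(length(r$replicates), 40)
})

test_that("subsampling a 5-population species returns the whole species", {
  coords <- data.frame(pop = sprintf("p%d", 1:5),
                       lon = c(-105.1, -105.3, -105.5, -105.2, -105.4),
                       lat = c(38.1, 38.3, 38.2, 38.5, 38.4))
  draws <- spatial_subsample(coords, n_draws = 5, seed = 7)
  for (d in draws) expect_setequal(d$pops, coords$pop)
  expect_error(spatial_subsample(coords[1:3, ]), "fewer populations")
})

test_that("collinear populations give a zero-area hull but a valid group", {
  coords <- data.frame(pop = sprintf("p%d", 1:6),
                       lon = seq(-105, -104, length.out = 6), lat = 38)
  draws <- spatial_subsample(coords, n_draws = 3, seed = 8)
  expect_true(all(vapply(draws, function(d) d$hull_km2, 1) == 0))
  expect_true(all(vapply(draws, function(d) length(d$pops), 1) %in% 5:7))
})

test_that("subsample draws are seed-deterministic and cluster-local", {
  set.seed(93)
  cl1 <- data.frame(pop = sprintf("a%d", 1:6),
                    lon = -106 + runif(6, 0, 0.3), lat = 38 + runif(6, 0, 0.3))
  cl2 <- data.frame(pop = sprintf("b%d", 1:6),
                    lon = -101 + runif(6, 0, 0.3), lat = 38 + runif(6, 0, 0.3))
  coords <- rbind(cl1, cl2)
  d1 <- spatial_subsample(coords, n_draws = 10, seed = 9,
                          extent_window = c(0, 2000))
  d2 <- spatial_subsample(coords, n_draws = 10, seed = 9,
                          extent_window = c(0, 2000))
  expect_identical(d1, d2)
  # a window excluding the joint hull (clusters ~440 km apart) never mixes
  for (d in d1) {
    pref <- substr(d$pops, 1, 1)
    expect_equal(length(unique(pref)), 1)
  }
})

test_that("OLS on log10 range size matches the closed form", {
  vals <- c(0.31, 0.55, 0.48, 0.90)
  areas <- c(1113, 3339, 27080, 98924)
  reg <- range_regression(vals, areas)
  x <- log10(areas)
  b <- sum((x - mean(x)) * (vals - mean(vals))) / sum((x - mean(x))^2)
  r2 <- b^2 * sum((x - mean(x))^2) / sum((vals - mean(vals))^2)
  expect_equal(reg$slope, b, tolerance = 1e-10)
  expect_equal(reg$r2, r2, tolerance = 1e-10)
  expect_true(reg$low_power)
  # exact linear data: r2 = 1; constant data: r2 = 0 and slope 0
  # (lm warns about the deliberately perfect/degenerate fits)
  lin <- suppressWarnings(range_regression(2 + 3 * log10(areas), areas))
  expect_equal(lin$r2, 1, tolerance = 1e-12)
  cst <- suppressWarnings(range_regression(rep(0.4, 4), areas))
  expect_equal(cst$r2, 0)
  expect_equal(cst$slope, 0)
  expect_error(range_regression(vals[1:2], areas[1:2]), "3 species")
  expect_error(range_regression(vals, rep(100, 4)), "zero variance")
})

test_that("subsample regressions are deterministic and hit analytic extremes", {
  set.seed(94)
  mkspecies <- function(prefix, lon0) {
    data.frame(pop = sprintf("%s%d", prefix, 1:8),
               lon = lon0 + runif(8, 0, 2), lat = 38 + runif(8, 0, 2))
  }
  ws <- list(
    W1 = list(coords = mkspecies("w", -110), data = mkspecies("w", -110)),
    W2 = list(coords = mkspecies("v", -100), data = mkspecies("v", -100)))
  ws$W1$data <- ws$W1$coords; ws$W2$data <- ws$W2$coords
  rare <- list(R1 = list(value = log10(500), area_km2 = 500),
               R2 = list(value = log10(2000), area_km2 = 2000))
  # statistic that is exactly log10 of the group hull area -> r2 = 1
  stat_hull <- function(data, pops) {
    pts <- data[data$pop %in% pops, ]
    log10(rarecomp:::.hull_area_km2(pts$lon, pts$lat))
  }
  # lm warns about the deliberately perfect fit; that is the point here
  out <- suppressWarnings(
    subsample_analysis(ws, rare, stat_hull, n_draws = 8, seed = 10))
  expect_equal(out$median_r2, 1, tolerance = 1e-9)
  out2 <- suppressWarnings(
    subsample_analysis(ws, rare, stat_hull, n_draws = 8, seed = 10))
  expect_identical(out$draws, out2$draws)
  # constant statistic -> r2 = 0
  rare0 <- list(R1 = list(value = 0.3, area_km2 = 500),
                R2 = list(value = 0.3, area_km2 = 2000))
  out0 <- suppressWarnings(
    subsample_analysis(ws, rare0, function(data, pops) 0.3,
                       n_draws = 6, seed = 11))
  expect_equal(out0$median_r2, 0)
})

test_that("within-population diversity is robust to spatial subsampling", {
  cfg <- sim_config(n_pops = 12, inds_per_pop = 20, n_loci = 12,
                    target_fst = 0.3, seed = 95)
  gt <- simulate_genotypes(cfg)
  occ <- simulate_occurrences(12, c(-107, -104, 37, 40), points_per_pop = 1,
                              jitter_sd = 0, seed = 96)
  coords <- data.frame(pop = unique(gt$population),
                       lon = occ$lon, lat = occ$lat)
  full <- rarefy_bootstrap(gt, n_boot = 150, seed = 97)$Hs
  draws <- spatial_subsample(coords, n_draws = 8, seed = 98)
  sub_hs <- vapply(draws, function(d) {
    sub <- subset_individuals(gt, gt$population %in% d$pops)
    basic_stats(sub, "sample_corrected")$overall[["Hs"]]
  }, numeric(1))
  expect_lt(abs(median(sub_hs) - full$point), 2 * sd(full$replicates))
})

test_that("drift is rarely rejected for matched neutral species", {
  rejects <- 0; n_species <- 20
  for (i in seq_len(n_species)) {
    cfg <- sim_config(n_pops = 10, inds_per_pop = 32,
                      n_families_per_pop = 8, sibs_per_family = 4,
                      n_loci = 15, alleles_per_locus = 8, target_fst = 0.2,
                      v_pop = 0.2, v_fam = 0.8, v_err = 1, seed = 9100 + i)
    gt <- simulate_genotypes(cfg)
    fb <- rarefy_bootstrap(gt, n_boot = 250, seed = 9200 + i)$Fst
    pt <- derive_traits(simulate_phenotypes(cfg))
    fit <- variance_components(composite_phenotype(pt))
    qb <- parametric_bootstrap_vc(fit, n_boot = 250, seed = 9300 + i)$QST
    r <- fst_qst_ratio(fb, qb)
    rejects <- rejects + r$drift_rejected_ci
  }
  expect_lte(rejects / n_species, 0.1)
})
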