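test_that("derived ratio traits follow their printed definitions", {
  pt <- data.frame(individual = c("a", "b", "c"),
                   population = "p", family = "f",
                   height_55 = c(50, 100, 80),
                   leafarea_55 = c(500, 900, 640),
                   leafnum_55 = c(10, 30, 0))
  out <- suppressMessages(derive_traits(pt))
  expect_equal(out$internode_55[1], 10 / 50)       # leaves per mm, as printed
  expect_equal(out$leafsize_55[1], 500 / 10)       # mm^2 per leaf
  expect_true(is.na(out$leafsize_55[3]))           # zero leaf number flagged
  expect_equal(attr(out, "derive_excluded"), "c")
  inv <- suppressMessages(derive_traits(pt, invert_internode = TRUE))
  expect_equal(inv$internode_55[1], 50 / 10)
})

test_that("a single-trait composite is the standardized trait up to sign", {
  set.seed(1)
  pt <- data.frame(individual = sprintf("i%02d", 1:40),
                   population = rep(c("p1", "p2"), 20),
                   family = rep(c("f1", "f2", "f3", "f4"), 10),
                   height_21 = rlnorm(40))
  cs <- composite_phenotype(pt, traits = "height_21", n_axes = 1)
  expect_equal(abs(cor(cs$score, scale(pt$height_21)[, 1])), 1,
               tolerance = 1e-12)
  expect_equal(cs$pct_var, 100)
})

test_that("percent variance per axis matches an independent eigendecomposition", {
  set.seed(2)
  n <- 300
  latent <- matrix(rnorm(n * 3), n, 3)
  load <- matrix(rnorm(24, sd = 1), 3, 8)
  X <- latent %*% load + matrix(rnorm(n * 8, sd = 0.2), n, 8)
  pt <- data.frame(individual = sprintf("i%03d", 1:n), population = "p",
                   family = "f")
  trait_names <- sprintf("t%d", 1:8)
  pt[trait_names] <- as.data.frame(X)
  cs <- composite_phenotype(pt, traits = trait_names)
  ev <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(cs$pct_var, 100 * ev / sum(ev), tolerance = 1e-8)
  expect_true(all(diff(cs$pct_var) <= 1e-12))     # non-increasing
})

test_that("incomplete rows are dropped and too-few rows error", {
  pt <- data.frame(individual = c("a", "b", "c", "d"),
                   population = "p", family = "f",
                   height_21 = c(1, 2, NA, 4), leafarea_21 = c(2, 1, 3, 5))
  cs <- suppressMessages(composite_phenotype(pt,
    traits = c("height_21", "leafarea_21"), n_axes = 2))
  expect_equal(cs$dropped, "c")
  expect_equal(length(cs$score), 3)
  pt2 <- pt[1:2, ]; pt2$height_21 <- c(1, NA)
  expect_error(suppressMessages(
    composite_phenotype(pt2, traits = c("height_21", "leafarea_21"),
                        n_axes = 2)),
    "complete rows")
})

test_that("degenerate variance fits are all zero with undefined ratios", {
  y <- rep(5, 24)
  pop <- rep(c("p1", "p2"), each = 12)
  fam <- rep(sprintf("f%d", 1:6), each = 4)
  fit <- variance_components(y, pop, fam)
  expect_equal(unname(fit$vc), rep(0, 4))
  expect_true(is.na(fit$qst) && is.na(fit$h2))
})

test_that("equal family and population means force V_POP = 0 and Qst = 0", {
  # identical family-mean pattern in every population
  fam_means <- rep(c(-1, 1), each = 4)
  y <- rep(fam_means, 3) + rep(c(-0.1, 0.1), 12)
  pop <- rep(c("p1", "p2", "p3"), each = 8)
  fam <- paste0(pop, "_", rep(rep(c("fA", "fB"), each = 4), 3))
  fit <- variance_components(y, pop, fam, method = "anova_mom")
  expect_equal(fit$vc[["V_POP"]], 0)
  expect_equal(fit$qst, 0)
})

test_that("REML equals the nested ANOVA estimator on balanced interior fits", {
  for (i in 1:5) {
    set.seed(700 + i)
    P <- 15; Fm <- 6; S <- 4
    pop <- rep(sprintf("p%02d", 1:P), each = Fm * S)
    fam <- paste0(pop, "_", rep(rep(sprintf("f%d", 1:Fm), each = S), P))
    y <- rnorm(P, 0, sqrt(2))[as.integer(factor(pop))] +
      rnorm(P * Fm, 0, 1)[as.integer(factor(fam))] + rnorm(P * Fm * S)
    reml <- variance_components(y, pop, fam, method = "reml")
    mom <- variance_components(y, pop, fam, method = "anova_mom")
    if (all(mom$vc[1:3] > 0.05)) {   # interior solution
      expect_equal(reml$vc, mom$vc, tolerance = 1e-6)
      expect_equal(reml$qst, mom$qst, tolerance = 1e-6)
    }
  }
})

test_that("Qst is invariant to affine transformation of the score", {
  set.seed(31)
  pop <- rep(sprintf("p%d", 1:8), each = 12)
  fam <- paste0(pop, "_", rep(rep(c("f1", "f2", "f3"), each = 4), 8))
  y <- rnorm(8, 0, 1)[as.integer(factor(pop))] +
    rnorm(24, 0, 1)[as.integer(factor(fam))] + rnorm(96)
  f1 <- variance_components(y, pop, fam)
  f2 <- variance_components(-3.2 * y + 7, pop, fam)
  expect_equal(f1$qst, f2$qst, tolerance = 1e-6)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
  # identity: H2 + (V_POP + V_ERR) / V_TOT = 1
  expect_equal(f1$h2 + (f1$vc[["V_POP"]] + f1$vc[["V_ERR"]]) / f1$vc[["V_TOT"]],
               1, tolerance = 1e-12)
})

test_that("defective designs are rejected with informative errors", {
  expect_error(variance_components(rnorm(8), rep("p1", 8),
                                   rep(c("f1", "f2"), 4)),
               "2 populations")
  expect_error(variance_components(rnorm(8), rep(c("p1", "p2"), each = 4),
                                   rep(c("f1", "f2"), each = 4)),
               "singular design")
})

test_that("the parametric bootstrap is deterministic and handles degeneracy", {
  set.seed(41)
  pop <- rep(sprintf("p%d", 1:6), each = 8)
  fam <- paste0(pop, "_", rep(rep(c("f1", "f2"), each = 4), 6))
  y <- rnorm(6)[as.integer(factor(pop))] +
    rnorm(12, 0, 0.7)[as.integer(factor(fam))] + rnorm(48)
  fit <- variance_components(y, pop, fam)
  b1 <- parametric_bootstrap_vc(fit, n_boot = 25, seed = 9)
  b2 <- parametric_bootstrap_vc(fit, n_boot = 25, seed = 9)
  expect_identical(b1$QST$replicates, b2$QST$replicates)
  expect_equal(b1$V_TOT$replicates,
               b1$V_POP$replicates + b1$V_FAM$replicates +
                 b1$V_ERR$replicates, tolerance = 1e-10)
  # all-zero fit: every replicate 0, zero-width interval
  fit0 <- variance_components(rep(1, 24), rep(c("p1", "p2"), each = 12),
                              rep(sprintf("f%d", 1:6), each = 4))
  b0 <- parametric_bootstrap_vc(fit0, n_boot = 10)
  expect_true(all(b0$V_POP$replicates == 0))
  expect_equal(diff(b0$QST$ci), 0)
})

test_that("bootstrap intervals for Qst attain near-nominal coverage", {
  # generating Qst = 0.5; interval resolution needs a few hundred
  # replicates before the percentile tails stabilize
  covered <- 0; n_sim <- 150
  for (i in seq_len(n_sim)) {
    cfg <- sim_config(n_pops = 25, n_families_per_pop = 8,
                      sibs_per_family = 4, v_pop = 1, v_fam = 1, v_err = 1,
                      seed = 90000 + i)
    pt <- simulate_phenotypes(cfg)
    fit <- variance_components(attr(pt, "latent"), pt$population, pt$family)
    bt <- parametric_bootstrap_vc(fit, n_boot = 300, seed = 91000 + i)
    covered <- covered + (bt$QST$ci[1] <= 0.5 && 0.5 <= bt$QST$ci[2])
  }
  expect_gte(covered / n_sim, 0.90)
  expect_lte(covered / n_sim, 0.99)
})
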