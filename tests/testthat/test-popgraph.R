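test_that("dosage encoding drops one reference class and scores halves", {
  geno <- list(rbind(c(1, 1), c(2, 1)),   # het at locus 1, homo ref at locus 2
               rbind(c(2, 2), c(2, 2)),
               rbind(c(1, 2), c(2, 2)))
  gt <- make_gt(c("p1", "p1", "p2"), geno)
  X <- dosage_matrix(gt)
  expect_equal(ncol(X), 2)                 # 2 alleles per locus -> 1 column each
  expect_equal(unname(X[1, 1]), 0.5)       # heterozygote: half dosage
  expect_equal(unname(X[2, 1]), 0)
  expect_equal(unname(X[3, 1]), 0.5)
})

test_that("partial correlations match the regression-residual oracle", {
  set.seed(81)
  for (rep in 1:10) {
    n <- 60; p <- 5
    X <- matrix(rnorm(n * p), n, p) %*% matrix(rnorm(p * p, sd = 0.5), p, p)
    X <- X + matrix(rnorm(n * p, sd = 0.5), n, p)
    R <- cor(X)
    pc <- rarecomp:::.partial_cor(R)
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      expect_equal(pc[i, j], oracle_partial_cor(X, i, j), tolerance = 1e-6)
    }
  }
})

test_that("a pair independent given a third population loses its edge", {
  # chain structure: A <- C -> B at the allele-frequency level
  set.seed(82)
  L <- 150; n <- 40
  pc <- 0.5 + runif(L, -0.2, 0.2)
  pa <- pmin(pmax(pc + rnorm(L, 0, 0.08), 0.05), 0.95)
  pb <- pmin(pmax(pc + rnorm(L, 0, 0.08), 0.05), 0.95)
  draw <- function(p) {
    a1 <- matrix(rbinom(n * L, 1, rep(p, each = n)) + 1L, n, L)
    a2 <- matrix(rbinom(n * L, 1, rep(p, each = n)) + 1L, n, L)
    list(a1 = a1, a2 = a2)
  }
  A <- draw(pa); B <- draw(pb); C <- draw(pc)
  gt <- genotype_table(sprintf("i%03d", 1:(3 * n)),
                       rep(c("A", "B", "C"), each = n), NULL,
                       rbind(A$a1, B$a1, C$a1), rbind(A$a2, B$a2, C$a2))
  pg <- build_popgraph(gt)
  e <- pg$edges
  ab <- e$retained[(e$pop_i == "A" & e$pop_j == "B") |
                     (e$pop_i == "B" & e$pop_j == "A")]
  expect_false(ab)
  expect_true(all(e$retained[!((e$pop_i == "A" & e$pop_j == "B") |
                                 (e$pop_i == "B" & e$pop_j == "A"))]))
})

test_that("relabeling populations permutes but preserves EED and modularity", {
  gt <- simulate_genotypes(sim_config(n_pops = 6, inds_per_pop = 20,
                                      n_loci = 10, target_fst = 0.3,
                                      seed = 83))
  pg1 <- build_popgraph(gt)
  gt2 <- gt
  map <- setNames(sprintf("z%02d", 6:1), unique(gt$population))
  gt2$population <- unname(map[gt$population])
  pg2 <- build_popgraph(gt2)
  expect_equal(sort(pg1$edges$eed), sort(pg2$edges$eed), tolerance = 1e-10)
  expect_equal(sum(pg1$edges$retained), sum(pg2$edges$retained))
  expect_equal(pg1$modularity, pg2$modularity, tolerance = 1e-10)
})

test_that("retained edge sets are nested in alpha", {
  gt <- simulate_genotypes(sim_config(n_pops = 8, inds_per_pop = 20,
                                      n_loci = 12, target_fst = 0.25,
                                      seed = 84))
  key <- function(pg) with(pg$edges[pg$edges$retained, ],
                           paste(pop_i, pop_j))
  e05 <- key(build_popgraph(gt, alpha = 0.05))
  e01 <- key(build_popgraph(gt, alpha = 0.01))
  e001 <- key(build_popgraph(gt, alpha = 0.001))
  expect_true(all(e01 %in% e05))
  expect_true(all(e001 %in% e01))
})

test_that("distinct allele pools split into two communities with no bridge", {
  cfgA <- sim_config(n_pops = 4, inds_per_pop = 25, n_loci = 10,
                     alleles_per_locus = 4, target_fst = 0.15,
                     null_allele_rate = 0, missing_rate = 0, seed = 21)
  cfgB <- sim_config(n_pops = 4, inds_per_pop = 25, n_loci = 10,
                     alleles_per_locus = 4, target_fst = 0.15,
                     null_allele_rate = 0, missing_rate = 0, seed = 22)
  A <- simulate_genotypes(cfgA); B <- simulate_genotypes(cfgB)
  gt <- genotype_table(c(A$individual, paste0("b", B$individual)),
                       c(A$population, sub("pop", "bpop", B$population)),
                       NULL, rbind(A$a1, B$a1 + 10L), rbind(A$a2, B$a2 + 10L),
                       loci = A$loci)
  pg <- build_popgraph(gt)
  e <- pg$edges
  between <- xor(grepl("^bpop", e$pop_i), grepl("^bpop", e$pop_j))
  expect_equal(sum(e$retained & between), 0)
  memb <- pg$membership
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[grepl("^bpop", names(memb))])), 1)
})

test_that("a panmictic pool yields a dense graph with near-zero modularity", {
  gt <- simulate_genotypes(sim_config(n_pops = 8, inds_per_pop = 25,
                                      n_loci = 12, alleles_per_locus = 6,
                                      target_fst = 0, null_allele_rate = 0,
                                      missing_rate = 0, seed = 33))
  pg <- build_popgraph(gt)
  expect_gt(mean(pg$edges$retained), 0.3)
  expect_lt(pg$modularity, 0.1)
})

test_that("analytic modularity cases are exact", {
  tri2 <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4),
                             directed = FALSE)
  expect_equal(graph_modularity(tri2)$modularity, 0.5)
  expect_equal(graph_modularity(igraph::make_full_graph(6))$modularity, 0)
  edgeless <- igraph::make_empty_graph(4, directed = FALSE)
  expect_message(m <- graph_modularity(edgeless), "edgeless")
  expect_equal(m$modularity, 0)
})

test_that("returned modularity never exceeds the exhaustive maximum", {
  set.seed(85)
  for (case in 1:40) {
    nv <- sample(4:7, 1)
    pairs <- t(combn(nv, 2))
    keep <- runif(nrow(pairs)) < runif(1, 0.3, 0.7)
    if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
    el <- pairs[keep, , drop = FALSE]
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nv - igraph::vcount(g)))
    got <- graph_modularity(g)$modularity
    best <- oracle_max_modularity(el, nv)
    expect_lte(got, best + 1e-12)
    expect_gte(got, 0)   # the one-community partition scores exactly 0
    # the dendrogram's own partition reproduces its score
    memb <- graph_modularity(g)$membership
    expect_equal(modularity_of(el, as.integer(memb)), got, tolerance = 1e-12)
  }
})

test_that("duplicate populations and tiny designs are rejected", {
  geno <- replicate(4, rbind(c(1, 2), c(2, 1)), simplify = FALSE)
  gt <- make_gt(c("p1", "p1", "p2", "p2"), geno)
  expect_error(build_popgraph(gt), "3 populations")
  # identical populations: centroid collision
  g2 <- make_gt(rep(c("p1", "p2", "p3"), each = 2),
                replicate(6, rbind(c(1, 2), c(2, 1)), simplify = FALSE))
  expect_error(build_popgraph(g2), "duplicate")
})
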