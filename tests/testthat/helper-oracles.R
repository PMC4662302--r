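# Independent oracles and fixture builders. Everything here is deliberately
# naive (loops, enumeration) and written against the definitions, not
# against the package internals.

# Build a genotype table from explicit per-individual allele pairs.
# geno: list of rbind(a1, a2) matrices (2 x n_loci), one per individual.
make_gt <- function(pops, geno, fam = NULL, loci = NULL) {
  a1 <- t(vapply(geno, function(g) g[1, ], numeric(ncol(geno[[1]]))))
  a2 <- t(vapply(geno, function(g) g[2, ], numeric(ncol(geno[[1]]))))
  if (ncol(geno[[1]]) == 1) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  genotype_table(sprintf("i%03d", seq_along(pops)), pops, fam, a1, a2,
                 loci = loci %||% sprintf("L%02d", seq_len(ncol(a1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small genotype table for fuzzing (not via simulate_genotypes).
random_gt <- function(n_pops = 3, inds = 6, loci = 2, K = 3,
                      miss = 0.1, seed = 1) {
  set.seed(seed)
  n <- n_pops * inds
  a1 <- matrix(sample.int(K, n * loci, TRUE), n, loci)
  a2 <- matrix(sample.int(K, n * loci, TRUE), n, loci)
  m <- matrix(runif(n * loci) < miss, n, loci)
  a1[m] <- NA; a2[m] <- NA
  genotype_table(sprintf("i%03d", 1:n),
                 rep(sprintf("p%d", 1:n_pops), each = inds),
                 NULL, a1, a2)
}

# Brute-force plain Nei statistics, one locus at a time, straight from the
# definitions (loops over populations; no shared code with the package).
oracle_basic_stats <- function(gt) {
  pops <- unique(gt$population)
  out <- data.frame(locus = gt$loci, Ho = NA_real_, Hs = NA_real_,
                    Ht = NA_real_, Fst = NA_real_, Fis = NA_real_)
  for (l in seq_along(gt$loci)) {
    ho_p <- hs_p <- c(); freqs <- list()
    for (p in pops) {
      rows <- which(gt$population == p & !is.na(gt$a1[, l]))
      if (!length(rows)) next
      x1 <- gt$a1[rows, l]; x2 <- gt$a2[rows, l]
      ho_p <- c(ho_p, mean(x1 != x2))
      alle <- c(x1, x2)
      tab <- table(alle) / length(alle)
      hs_p <- c(hs_p, 1 - sum(tab^2))
      freqs[[length(freqs) + 1]] <- tab
    }
    if (!length(ho_p)) next
    all_alleles <- sort(unique(unlist(lapply(freqs, names))))
    fm <- sapply(freqs, function(f) {
      v <- setNames(rep(0, length(all_alleles)), all_alleles)
      v[names(f)] <- f
      v
    })
    if (is.null(dim(fm))) fm <- matrix(fm, nrow = length(all_alleles))
    pbar <- rowMeans(fm)
    ho <- mean(ho_p); hs <- mean(hs_p); ht <- 1 - sum(pbar^2)
    mono <- length(all_alleles) <= 1
    out$Ho[l] <- if (mono) 0 else ho
    out$Hs[l] <- if (mono) 0 else hs
    out$Ht[l] <- if (length(ho_p) >= 2) (if (mono) 0 else ht) else NA
    out$Fst[l] <- if (!mono && length(ho_p) >= 2 && ht > 0) (ht - hs) / ht else NA
    out$Fis[l] <- if (!mono && hs > 0) 1 - ho / hs else NA
  }
  out
}

# All set partitions of 1..n as membership vectors (restricted growth).
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, maxb) {
    k <- length(memb)
    if (k == n) { out[[length(out) + 1]] <<- memb; return(invisible()) }
    for (b in seq_len(maxb + 1)) rec(c(memb, b), max(maxb, b))
  }
  rec(1L, 1L)
  out
}

# Newman-Girvan modularity of a partition, from the definition.
modularity_of <- function(el, memb) {
  m <- nrow(el)
  if (m == 0) return(0)
  e_same <- mean(memb[el[, 1]] == memb[el[, 2]])
  ends <- c(el[, 1], el[, 2])
  a <- tabulate(memb[ends], max(memb)) / (2 * m)
  e_same - sum(a^2)
}

# Exhaustive maximum modularity over all partitions of an edge list.
oracle_max_modularity <- function(el, n) {
  parts <- all_partitions(n)
  max(vapply(parts, function(p) modularity_of(el, p), numeric(1)))
}

# Partial correlation of variables i and j given the rest, by the
# regression-residual route.
oracle_partial_cor <- function(X, i, j) {
  rest <- setdiff(seq_len(ncol(X)), c(i, j))
  if (!length(rest)) return(cor(X[, i], X[, j]))
  ri <- resid(lm(X[, i] ~ X[, rest]))
  rj <- resid(lm(X[, j] ~ X[, rest]))
  cor(ri, rj)
}
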