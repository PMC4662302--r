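#' Multilocus allele-dosage encoding
#'
#' Encodes each individual as a vector of half allele dosages, one
#' coordinate per allele class and locus, values in `{0, 0.5, 1}`. One
#' reference class per locus (the last) is dropped, since within-locus
#' frequencies sum to one and would otherwise be exactly collinear. Missing
#' calls yield `NA` coordinates at that locus.
#'
#' @param gt a [genotype_table()].
#' @return Numeric matrix, individuals x retained allele coordinates.
#' @export
dosage_matrix <- function(gt) {
  prep <- .gt_prep(gt)
  cols <- list()
  for (l in seq_along(prep$codes)) {
    cc <- prep$codes[[l]]
    if (cc$K < 2) next                       # monomorphic: no information
    for (a in seq_len(cc$K - 1L)) {          # drop reference class
      v <- ((cc$c1 == a) + (cc$c2 == a)) / 2
      cols[[paste(gt$loci[l], cc$alleles[a], sep = ".")]] <- v
    }
  }
  if (!length(cols)) stop("no polymorphic loci to encode")
  do.call(cbind, cols)
}

# Partial correlations from a correlation matrix via its (pseudo)inverse.
.partial_cor <- function(R, ridge = 1e-8) {
  Pm <- tryCatch({
    if (rcond(R) < 1e-10) stop("near-singular")
    solve(R)
  }, error = function(e) MASS::ginv(R + diag(ridge, nrow(R))))
  d <- sqrt(abs(diag(Pm)))
  pc <- -Pm / tcrossprod(d)
  diag(pc) <- 1
  pmin(pmax(pc, -1), 1)
}

#' Population genetic graph by conditional-independence pruning
#'
#' Populations are nodes. Individuals are encoded as multilocus allele
#' dosages ([dosage_matrix()]); population centroids are the mean dosage
#' vectors; the among-population covariance of centroids (populations as
#' variables, allele coordinates as observations) is converted to a
#' correlation matrix, inverted (pseudo-inverse with a ridge of `1e-8` on
#' the diagonal when near-singular, which is logged), and partial
#' correlations `r_ij.rest = -prec_ij / sqrt(prec_ii prec_jj)` are derived.
#' The edge-exclusion deviance `EED_ij = -n ln(1 - r_ij.rest^2)` (with `n`
#' the total number of individuals) is compared to the chi-square(1 df)
#' critical value at `alpha`: edges whose absence cannot be justified are
#' retained. Retained edges carry a conditional genetic distance weight
#' `1 - |r_ij.rest|` (any monotone variant leaves the unweighted community
#' analysis unchanged). Community structure and maximum modularity are
#' computed on the retained, unweighted topology ([graph_modularity()]).
#'
#' @param gt a [genotype_table()] with at least 3 populations and 2
#'   polymorphic loci.
#' @param alpha edge retention level (default 0.05). Smaller `alpha`
#'   retains a subset of the edges retained at larger `alpha` (nested sets).
#' @param ridge diagonal ridge used by the pseudo-inverse fallback.
#' @return Object of class `popgraph`: `graph` (igraph, retained edges),
#'   `edges` (all pairs: `pop_i`, `pop_j`, `partial_r`, `eed`, `retained`,
#'   `weight`), `modularity`, `membership`, `alpha`, `n`.
#' @export
build_popgraph <- function(gt, alpha = 0.05, ridge = 1e-8) {
  pops <- unique(gt$population)
  np <- length(pops)
  if (np < 3) stop("at least 3 populations are required")
  X <- dosage_matrix(gt)
  poly <- length(unique(sub("\\.[^.]*$", "", colnames(X))))
  if (poly < 2) stop("at least 2 polymorphic loci are required")
  cent <- rowsum(ifelse(is.na(X), 0, X), gt$population, reorder = FALSE) /
    rowsum((!is.na(X)) * 1, gt$population, reorder = FALSE)
  cent <- cent[pops, , drop = FALSE]
  dup <- which(as.dist(as.matrix(dist(cent))) < 1e-12)
  if (length(dup)) {
    pairs <- which(as.matrix(dist(cent)) < 1e-12 &
                     upper.tri(matrix(0, np, np)), arr.ind = TRUE)
    stop("duplicate (collinear) populations: ",
         paste(pops[pairs[1, 1]], pops[pairs[1, 2]], sep = " and "))
  }
  S <- cov(t(cent))                 # among-population covariance of centroids
  R <- cov2cor(S)
  pc <- .partial_cor(R, ridge = ridge)
  n <- n_individuals(gt)
  crit <- qchisq(1 - alpha, df = 1)

  idx <- which(upper.tri(pc), arr.ind = TRUE)
  r <- pc[idx]
  r2 <- pmin(r^2, 1 - 1e-12)
  eed <- -n * log(1 - r2)
  retained <- eed > crit
  edges <- data.frame(pop_i = pops[idx[, 1]], pop_j = pops[idx[, 2]],
                      partial_r = r, eed = eed, retained = retained,
                      weight = 1 - abs(r), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[retained, c("pop_i", "pop_j", "weight", "partial_r", "eed")],
    directed = FALSE,
    vertices = data.frame(name = pops, stringsAsFactors = FALSE))
  mod <- graph_modularity(g)
  structure(list(graph = g, edges = edges, alpha = alpha, n = n,
                 populations = pops, modularity = mod$modularity,
                 membership = mod$membership),
            class = "popgraph")
}

#' Maximum modularity over edge-betweenness communities
#'
#' Runs divisive edge-betweenness community detection (betweenness
#' recomputed after each removal) on the unweighted retained topology and
#' returns the maximum Newman-Girvan modularity
#' `Q = sum_c (e_c - a_c^2)` over all levels of the resulting dendrogram,
#' with its partition. An edgeless graph has `Q` defined as 0 (logged).
#'
#' @param g a `popgraph` or an igraph object.
#' @return List with `modularity` (max Q) and `membership` (community id
#'   per population).
#' @export
graph_modularity <- function(g) {
  if (inherits(g, "popgraph")) g <- g$graph
  stopifnot(igraph::is_igraph(g))
  nv <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) {
    message("graph_modularity: edgeless graph, modularity defined as 0")
    memb <- seq_len(nv)
    names(memb) <- igraph::V(g)$name
    return(list(modularity = 0, membership = memb))
  }
  if ("weight" %in% igraph::edge_attr_names(g))
    g <- igraph::delete_edge_attr(g, "weight")   # unweighted topology
  ceb <- igraph::cluster_edge_betweenness(g)
  memb <- igraph::membership(ceb)
  list(modularity = max(ceb$modularity), membership = memb)
}

#' @export
print.popgraph <- function(x, digits = 3, ...) {
  cat(sprintf("Population graph: %d populations, %d/%d edges retained (alpha = %g)\n",
              length(x$populations), sum(x$edges$retained),
              nrow(x$edges), x$alpha))
  cat(sprintf("  max modularity Q = %.*f over %d communities\n",
              digits, x$modularity, length(unique(x$membership))))
  invisible(x)
}

#' Export a population graph
#'
#' Writes the retained graph as GraphML, the full edge table as CSV
#' (`pop_i`, `pop_j`, `partial_r`, `eed`, `retained`, `weight`), the
#' community assignments as CSV, and a JSON summary with the modularity.
#'
#' @param pg a [build_popgraph()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_popgraph <- function(pg, dir, prefix = "popgraph") {
  stopifnot(inherits(pg, "popgraph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".graphml", "_edges.csv",
                                           "_communities.csv", ".json")))
  igraph::write_graph(pg$graph, paths[1], format = "graphml")
  write.csv(pg$edges, paths[2], row.names = FALSE)
  write.csv(data.frame(population = names(pg$membership),
                       community = as.integer(pg$membership)),
            paths[3], row.names = FALSE)
  jsonlite::write_json(list(alpha = pg$alpha, n = pg$n,
                            n_edges_retained = sum(pg$edges$retained),
                            modularity = pg$modularity),
                       paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
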