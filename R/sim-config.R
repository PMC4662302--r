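#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators: the island-model
#' genotype simulator, the nested population/family phenotype simulator, and
#' the two-environment growth-rate model. A single `sim_config` plus its
#' `seed` fully determines all simulated tables.
#'
#' The defaults emulate the sampling design of a selfing, perennial mustard
#' surveyed at 15 SSR-like loci: moderate island-model differentiation,
#' near-complete selfing, a handful of null-allele loci, ~2% missing calls,
#' and eight correlated rosette/leaf traits driven by one genetic latent
#' factor under a population/family nested variance model.
#'
#' @param n_pops number of populations (>= 1).
#' @param inds_per_pop genotyped individuals per population.
#' @param n_families_per_pop maternal (selfed) seed families per population.
#' @param sibs_per_family replicate sibs grown per family.
#' @param n_loci number of codominant loci.
#' @param alleles_per_locus ancestral allele classes per locus (< 99; the
#'   code 99 is reserved for the null-allele class).
#' @param target_fst island-model differentiation parameter in `[0, 1)`.
#'   `0` means every population shares the ancestral frequencies exactly.
#' @param selfing_rate selfing probability `s` in `[0, 1]`; genotypes are
#'   drawn at inbreeding equilibrium, `F_IS = s / (2 - s)`.
#' @param null_allele_rate per-locus probability that one allele class is
#'   masked as a null (scorable) allele.
#' @param missing_rate per-call probability of a missing (unscored) genotype.
#' @param v_pop,v_fam,v_err variance components of the latent genetic trait
#'   (among populations, among families within populations, residual).
#' @param trait_loading_matrix numeric matrix of log-scale loadings mapping
#'   latent factors to the six measured traits (rows: height_21, leafarea_21,
#'   leafnum_21, height_55, leafarea_55, leafnum_55). Column 1 is the genetic
#'   latent factor; any further columns are i.i.d. standard-normal
#'   environmental factors shared across traits.
#' @param trait_noise_sd trait-specific log-scale measurement noise SD.
#' @param plasticity_sd target SD, across families, of the absolute
#'   winter-spring growth-rate difference `|dGR|` (per day).
#' @param env_mean_gr length-2 named vector of mean growth rates per day in
#'   the winter and spring conditions.
#' @param seed integer RNG seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_pops = 4, inds_per_pop = 8, n_loci = 5, seed = 1)
#' cfg
#' @export
sim_config <- function(n_pops = 10,
                       inds_per_pop = 20,
                       n_families_per_pop = 8,
                       sibs_per_family = 4,
                       n_loci = 15,
                       alleles_per_locus = 8,
                       target_fst = 0.3,
                       selfing_rate = 0.95,
                       null_allele_rate = 0.2,
                       missing_rate = 0.02,
                       v_pop = 1,
                       v_fam = 1,
                       v_err = 1,
                       trait_loading_matrix = default_trait_loadings(),
                       trait_noise_sd = 0.05,
                       plasticity_sd = 0.01,
                       env_mean_gr = c(winter = 0.02, spring = 0.06),
                       seed = 1L) {
  counts <- c(n_pops = n_pops, inds_per_pop = inds_per_pop,
              n_families_per_pop = n_families_per_pop,
              sibs_per_family = sibs_per_family, n_loci = n_loci,
              alleles_per_locus = alleles_per_locus)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  if (alleles_per_locus >= .NULL_ALLELE_CODE)
    stop("alleles_per_locus must be < ", .NULL_ALLELE_CODE,
         " (code reserved for null alleles)")
  props <- c(selfing_rate = selfing_rate, null_allele_rate = null_allele_rate,
             missing_rate = missing_rate)
  if (any(props < 0) || any(props > 1))
    stop("selfing_rate, null_allele_rate and missing_rate must lie in [0, 1]")
  if (target_fst < 0 || target_fst >= 1)
    stop("target_fst must lie in [0, 1); target_fst = 1 is a degenerate Beta")
  if (any(c(v_pop, v_fam, v_err) < 0)) stop("variances must be >= 0")
  if (trait_noise_sd < 0 || plasticity_sd < 0) stop("SDs must be >= 0")
  tl <- as.matrix(trait_loading_matrix)
  if (nrow(tl) != 6L)
    stop("trait_loading_matrix must have 6 rows (one per measured trait)")
  if (is.null(rownames(tl))) rownames(tl) <- .measured_traits()
  if (length(env_mean_gr) != 2L)
    stop("env_mean_gr must have two entries (winter, spring)")
  if (is.null(names(env_mean_gr))) names(env_mean_gr) <- c("winter", "spring")

  structure(list(
    n_pops = as.integer(n_pops), inds_per_pop = as.integer(inds_per_pop),
    n_families_per_pop = as.integer(n_families_per_pop),
    sibs_per_family = as.integer(sibs_per_family),
    n_loci = as.integer(n_loci),
    alleles_per_locus = as.integer(alleles_per_locus),
    target_fst = target_fst, selfing_rate = selfing_rate,
    null_allele_rate = null_allele_rate, missing_rate = missing_rate,
    v_pop = v_pop, v_fam = v_fam, v_err = v_err,
    trait_loading_matrix = tl, trait_noise_sd = trait_noise_sd,
    plasticity_sd = plasticity_sd, env_mean_gr = env_mean_gr,
    seed = as.integer(seed)), class = "sim_config")
}

.measured_traits <- function() {
  c("height_21", "leafarea_21", "leafnum_21",
    "height_55", "leafarea_55", "leafnum_55")
}

#' Default trait loading matrix
#'
#' One genetic latent factor loading on all six measured traits on the log
#' scale. Magnitudes around 0.1 keep the traits close to linear in the latent
#' factor after exponentiation, so the variance structure of the latent trait
#' passes through to the composite phenotype essentially undistorted.
#'
#' @return A 6 x 1 numeric matrix.
#' @export
default_trait_loadings <- function() {
  matrix(c(0.14, 0.12, 0.08, 0.15, 0.13, 0.09), ncol = 1,
         dimnames = list(.measured_traits(), "genetic"))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d populations x %d individuals; %d families x %d sibs\n",
              x$n_pops, x$inds_per_pop, x$n_families_per_pop,
              x$sibs_per_family))
  cat(sprintf("  %d loci, %d alleles each; target Fst %.3g; selfing %.3g\n",
              x$n_loci, x$alleles_per_locus, x$target_fst, x$selfing_rate))
  cat(sprintf("  null-allele rate %.3g, missing rate %.3g\n",
              x$null_allele_rate, x$missing_rate))
  cat(sprintf("  variances (pop/fam/err): %.3g / %.3g / %.3g; seed %d\n",
              x$v_pop, x$v_fam, x$v_err, x$seed))
  invisible(x)
}

#' Read a simulation configuration from a key-value file
#'
#' Accepts a two-column `key,value` CSV or a `key: value` YAML-like text
#' file. Unknown keys are an error; missing keys fall back to the
#' [sim_config()] defaults.
#'
#' @param path file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  sep <- if (all(grepl(":", lines))) ":" else ","
  kv <- strsplit(lines, sep, fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[[1]]), "")
  vals <- vapply(kv, function(p) trimws(paste(p[-1], collapse = sep)), "")
  known <- names(formals(sim_config))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(vals[i], ";")[[1]]))
    if (anyNA(v)) vals[i] else v
  })
  names(args) <- keys
  do.call(sim_config, args)
}
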