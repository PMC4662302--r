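#' Simulate nested population/family phenotypes with two-environment growth
#'
#' The genetic latent trait follows the nested random-effects model
#' `y_ijk = P_i + F_ij + e_ijk` with `P_i ~ N(0, v_pop)`,
#' `F_ij ~ N(0, v_fam)` and `e_ijk ~ N(0, v_err)`. The six measured rosette
#' traits (height, leaf area, leaf number at days 21 and 55) are linear
#' combinations of the latent factor(s) on the log scale via the configured
#' loading matrix, plus trait-specific log-normal noise; sizes are
#' exponentiated, so they are strictly positive by construction (leaf
#' numbers are additionally rounded to whole leaves, minimum 1).
#'
#' Height and leaf area are also produced at days 28 and 63 from
#' family-by-environment growth rates: `GR_family,env = env_mean_gr[env]
#' +/- d_ij / 2`, where the family plasticity contrast `d_ij` is normal with
#' SD chosen so that `SD(|GR_winter - GR_spring|) = plasticity_sd` across
#' families (half-normal scaling `sd(|d|) = sd(d) * sqrt(1 - 2/pi)`). Winter
#' growth spans days 21 to 28 and spring growth days 55 to 63.
#'
#' @param config a [sim_config()].
#' @param labels optional `genotype_table` (or data.frame with `population`
#'   and `family` columns) supplying the population/family structure;
#'   defaults to the balanced design in `config`.
#' @return A data.frame (`individual`, `population`, `family`, measured
#'   traits at days 21/28/55/63). The generating latent values and family
#'   growth rates are attached as attributes `"latent"` and `"growth"`.
#' @examples
#' pt <- simulate_phenotypes(sim_config(n_pops = 3, seed = 2))
#' head(pt)
#' @export
simulate_phenotypes <- function(config, labels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  if (is.null(labels)) {
    P <- config$n_pops; Fm <- config$n_families_per_pop
    S <- config$sibs_per_family
    population <- rep(sprintf("pop%02d", seq_len(P)), each = Fm * S)
    family <- paste(population,
                    rep(rep(sprintf("fam%02d", seq_len(Fm)), each = S), P),
                    sep = "_")
    individual <- paste0(family, "_s", rep(seq_len(S), P * Fm))
  } else {
    if (inherits(labels, "genotype_table")) {
      population <- labels$population; family <- labels$family
      individual <- labels$individual
    } else {
      population <- as.character(labels$population)
      family <- as.character(labels$family)
      individual <- if (!is.null(labels$individual))
        as.character(labels$individual) else paste0(family, "_", seq_along(family))
    }
    if (anyNA(family)) stop("labels must provide family identifiers")
  }
  N <- length(individual)
  pops <- unique(population); fams <- unique(family)

  p_eff <- rnorm(length(pops), 0, sqrt(config$v_pop))
  f_eff <- rnorm(length(fams), 0, sqrt(config$v_fam))
  e_eff <- rnorm(N, 0, sqrt(config$v_err))
  latent <- p_eff[match(population, pops)] +
    f_eff[match(family, fams)] + e_eff

  tl <- config$trait_loading_matrix
  n_fac <- ncol(tl)
  fac <- cbind(latent,
               if (n_fac > 1)
                 matrix(rnorm(N * (n_fac - 1)), N, n_fac - 1))
  mu_log <- c(height_21 = log(30), leafarea_21 = log(300),
              leafnum_21 = log(8), height_55 = log(60),
              leafarea_55 = log(800), leafnum_55 = log(15))
  logT <- matrix(mu_log, N, 6, byrow = TRUE) + fac %*% t(tl) +
    matrix(rnorm(N * 6, 0, config$trait_noise_sd), N, 6)
  colnames(logT) <- .measured_traits()
  traits <- exp(logT)
  stopifnot(all(traits > 0))  # sizes built on the log scale: always positive
  traits[, "leafnum_21"] <- pmax(1, round(traits[, "leafnum_21"]))
  traits[, "leafnum_55"] <- pmax(1, round(traits[, "leafnum_55"]))

  # family-by-environment growth rates for stem elongation and leaf area
  gr <- config$env_mean_gr
  sd_d <- .plasticity_contrast_sd(gr[["winter"]] - gr[["spring"]],
                                  config$plasticity_sd)
  d_se <- rnorm(length(fams), 0, sd_d)
  d_la <- rnorm(length(fams), 0, sd_d)
  fam_growth <- data.frame(
    family = fams,
    gr_se_winter = gr[["winter"]] + d_se / 2,
    gr_se_spring = gr[["spring"]] - d_se / 2,
    gr_la_winter = gr[["winter"]] + d_la / 2,
    gr_la_spring = gr[["spring"]] - d_la / 2,
    stringsAsFactors = FALSE)
  gidx <- match(family, fams)

  out <- data.frame(individual = individual, population = population,
                    family = family, stringsAsFactors = FALSE)
  out$height_21 <- traits[, "height_21"]
  out$height_28 <- out$height_21 * exp(fam_growth$gr_se_winter[gidx] * 7)
  out$leafarea_21 <- traits[, "leafarea_21"]
  out$leafarea_28 <- out$leafarea_21 * exp(fam_growth$gr_la_winter[gidx] * 7)
  out$leafnum_21 <- traits[, "leafnum_21"]
  out$height_55 <- traits[, "height_55"]
  out$height_63 <- out$height_55 * exp(fam_growth$gr_se_spring[gidx] * 8)
  out$leafarea_55 <- traits[, "leafarea_55"]
  out$leafarea_63 <- out$leafarea_55 * exp(fam_growth$gr_la_spring[gidx] * 8)
  out$leafnum_55 <- traits[, "leafnum_55"]

  attr(out, "latent") <- latent
  attr(out, "growth") <- fam_growth
  attr(out, "truth") <- list(v_pop = config$v_pop, v_fam = config$v_fam,
                             v_err = config$v_err,
                             qst = if (config$v_pop + config$v_fam > 0)
                               config$v_pop / (config$v_pop + config$v_fam)
                             else NA_real_)
  out
}

# SD of the family contrast d such that SD(|mu + d|) = target when
# d ~ N(0, sd^2): the folded-normal SD equation, solved exactly. The
# solution is bracketed by [target, target / sqrt(1 - 2/pi)].
.plasticity_contrast_sd <- function(mu, target) {
  if (target <= 0) return(0)
  mu <- abs(mu)
  folded_sd <- function(sig) {
    e <- sig * sqrt(2 / pi) * exp(-mu^2 / (2 * sig^2)) +
      mu * (1 - 2 * stats::pnorm(-mu / sig))
    sqrt(max(mu^2 + sig^2 - e^2, 0))
  }
  stats::uniroot(function(s) folded_sd(s) - target,
                 lower = target * 0.999,
                 upper = target / sqrt(1 - 2 / pi) * 1.001,
                 tol = .Machine$double.eps^0.5)$root
}

#' Simulate georeferenced occurrence points
#'
#' Population centroids are placed uniformly in a bounding box and
#' occurrence points are jittered around them; coordinates are decimal
#' degrees.
#'
#' @param n_pops number of population centroids.
#' @param extent numeric length-4 bounding box
#'   `c(lon_min, lon_max, lat_min, lat_max)` with positive width and height.
#' @param points_per_pop occurrence points per population.
#' @param jitter_sd SD (degrees) of the normal jitter around centroids;
#'   `0` puts all of a population's points at its centroid.
#' @param seed RNG seed.
#' @return A data.frame with columns `population`, `lon`, `lat`.
#' @export
simulate_occurrences <- function(n_pops, extent, points_per_pop = 5,
                                 jitter_sd = 0.02, seed = 1L) {
  if (length(extent) != 4) stop("extent must be c(lon_min, lon_max, lat_min, lat_max)")
  if (extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must have positive width and height")
  if (n_pops < 1 || points_per_pop < 1) stop("counts must be >= 1")
  set.seed(seed)
  cx <- runif(n_pops, extent[1], extent[2])
  cy <- runif(n_pops, extent[3], extent[4])
  n <- n_pops * points_per_pop
  data.frame(
    population = rep(sprintf("pop%02d", seq_len(n_pops)),
                     each = points_per_pop),
    lon = rep(cx, each = points_per_pop) + rnorm(n, 0, jitter_sd),
    lat = rep(cy, each = points_per_pop) + rnorm(n, 0, jitter_sd),
    stringsAsFactors = FALSE)
}
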