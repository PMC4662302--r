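#' Relative growth rate per day
#'
#' `GR = (ln size_t2 - ln size_t1) / (days_t2 - days_t1)`, the log-difference
#' form used for both stem elongation (heights) and leaf-area growth, so
#' both traits share per-day units. Vectorized.
#'
#' @param size_t1,size_t2 strictly positive sizes (mm or mm^2).
#' @param days_t1,days_t2 measurement days, `days_t2 > days_t1`.
#' @return Growth rate(s) per day.
#' @examples
#' growth_rate(10, 20, 21, 28)  # ln(2)/7 = 0.09902
#' @export
growth_rate <- function(size_t1, size_t2, days_t1, days_t2) {
  if (any(size_t1 <= 0, na.rm = TRUE) || any(size_t2 <= 0, na.rm = TRUE))
    stop("sizes must be strictly positive")
  if (any(days_t2 <= days_t1, na.rm = TRUE))
    stop("days_t2 must exceed days_t1")
  (log(size_t2) - log(size_t1)) / (days_t2 - days_t1)
}

#' Extract two-environment growth records from a phenotype table
#'
#' Builds the long growth-record table: stem elongation (heights) and leaf
#' area, each in the winter window (days 21 to 28) and the spring window
#' (days 55 to 63) that bracket vernalization.
#'
#' @param pt phenotype data.frame with the day-21/28/55/63 height and
#'   leaf-area columns.
#' @return Data.frame with columns `individual`, `population`, `family`,
#'   `environment`, `trait`, `size_t1`, `size_t2`, `day_t1`, `day_t2`.
#' @export
growth_records <- function(pt) {
  need <- c("height_21", "height_28", "height_55", "height_63",
            "leafarea_21", "leafarea_28", "leafarea_55", "leafarea_63")
  if (!all(need %in% names(pt)))
    stop("phenotype table must contain: ", paste(need, collapse = ", "))
  one <- function(env, trait, c1, c2, d1, d2)
    data.frame(individual = pt$individual, population = pt$population,
               family = pt$family, environment = env, trait = trait,
               size_t1 = pt[[c1]], size_t2 = pt[[c2]],
               day_t1 = d1, day_t2 = d2, stringsAsFactors = FALSE)
  rbind(one("winter", "stem_elongation", "height_21", "height_28", 21, 28),
        one("spring", "stem_elongation", "height_55", "height_63", 55, 63),
        one("winter", "leaf_area", "leafarea_21", "leafarea_28", 21, 28),
        one("spring", "leaf_area", "leafarea_55", "leafarea_63", 55, 63))
}

#' Family-level plasticity breeding values
#'
#' Per individual and trait, the plasticity contrast is
#' `delta = |GR_winter - GR_spring|`; the family breeding value is the mean
#' of `delta` over sibs, computed separately for leaf area (`plast_la`) and
#' stem elongation (`plast_se`). Individuals lacking either environment for
#' a trait are excluded (ids in the `"excluded"` attribute). The
#' cross-trait `mean_plast` averages the two traits after z-standardization
#' within the analysis set (they are on different per-day scales); set
#' `standardize = FALSE` for the raw average.
#'
#' @param records growth records as from [growth_records()].
#' @param standardize z-standardize the two traits before averaging.
#' @return Data.frame: `family`, `population`, `plast_la`, `plast_se`,
#'   `mean_plast`, `n_sibs`.
#' @export
family_plasticity <- function(records, standardize = TRUE) {
  records$gr <- growth_rate(records$size_t1, records$size_t2,
                            records$day_t1, records$day_t2)
  key <- paste(records$individual, records$trait)
  w <- records$environment == "winter"
  s <- records$environment == "spring"
  gw <- setNames(records$gr[w], key[w])
  gs <- setNames(records$gr[s], key[s])
  common <- intersect(names(gw), names(gs))
  incomplete <- setdiff(union(names(gw), names(gs)), common)
  if (length(incomplete))
    message("family_plasticity: excluded ", length(incomplete),
            " individual x trait record(s) lacking one environment")
  first <- records[!duplicated(key), ]
  rownames(first) <- paste(first$individual, first$trait)
  delta <- abs(gw[common] - gs[common])
  info <- first[common, ]
  agg <- function(tr) {
    sel <- info$trait == tr
    if (!any(sel)) return(NULL)
    v <- tapply(delta[sel], info$family[sel], mean)
    n <- tapply(delta[sel], info$family[sel], length)
    data.frame(family = names(v), value = as.numeric(v),
               n = as.integer(n), stringsAsFactors = FALSE)
  }
  la <- agg("leaf_area"); se <- agg("stem_elongation")
  fams <- unique(info$family)
  fam_pop <- tapply(info$population, info$family, `[`, 1)
  out <- data.frame(family = fams,
                    population = as.character(fam_pop[fams]),
                    plast_la = if (!is.null(la))
                      la$value[match(fams, la$family)] else NA_real_,
                    plast_se = if (!is.null(se))
                      se$value[match(fams, se$family)] else NA_real_,
                    stringsAsFactors = FALSE)
  out$n_sibs <- if (!is.null(la)) la$n[match(fams, la$family)]
               else se$n[match(fams, se$family)]
  z <- function(v) {
    if (!standardize) return(v)
    sdv <- sd(v, na.rm = TRUE)
    if (is.na(sdv) || sdv == 0) return(v - mean(v, na.rm = TRUE))
    (v - mean(v, na.rm = TRUE)) / sdv
  }
  out$mean_plast <- rowMeans(cbind(z(out$plast_la), z(out$plast_se)),
                             na.rm = TRUE)
  attr(out, "excluded") <- incomplete
  out
}

#' Species-level mixed model for plasticity
#'
#' Fits `plasticity ~ 0 + species + (1 | population)` by REML — species is
#' the only fixed effect and population (nested in species) the random
#' effect — returning per-species estimated means, a parametric bootstrap of
#' the fixed effects, and pairwise significance by the shared
#' confidence-interval non-overlap rule.
#'
#' @param values data.frame of family plasticity values (one row per
#'   family) with a `population` column and the response named by
#'   `response`.
#' @param species species label per row.
#' @param response response column name (default `"mean_plast"`).
#' @param n_boot parametric-bootstrap replicates.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return Object of class `plasticity_fit`: `means` (per species),
#'   `boot` (list of [bootstrap_dist()]), `significant` (logical matrix),
#'   and the underlying `fit`.
#' @export
species_plasticity_model <- function(values, species,
                                     response = "mean_plast",
                                     n_boot = 1000, seed = NULL,
                                     level = 0.95) {
  d <- data.frame(y = values[[response]],
                  species = factor(species),
                  pop = factor(paste(species, values$population, sep = "/")))
  d <- d[complete.cases(d), ]
  if (nlevels(droplevels(d$species)) < 2)
    stop("at least 2 species are required")
  pops_per_sp <- tapply(as.character(d$pop), d$species,
                        function(p) length(unique(p)))
  if (any(pops_per_sp < 2))
    warning("species with a single population: the population random ",
            "effect is degenerate for ",
            paste(names(pops_per_sp)[pops_per_sp < 2], collapse = ", "))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressMessages(
    lme4::lmer(y ~ 0 + species + (1 | pop), data = d, REML = TRUE,
               control = ctrl))
  means <- lme4::fixef(fit)
  names(means) <- sub("^species", "", names(means))

  sims <- simulate(fit, nsim = n_boot, seed = seed)
  reps <- matrix(NA_real_, n_boot, length(means),
                 dimnames = list(NULL, names(means)))
  for (b in seq_len(n_boot)) {
    fe <- tryCatch(
      lme4::fixef(suppressMessages(lme4::refit(fit, newresp = sims[[b]]))),
      error = function(e) rep(NA_real_, length(means)))
    reps[b, ] <- fe
  }
  boot <- lapply(names(means), function(sp)
    bootstrap_dist(paste0("plasticity:", sp), reps[, sp],
                   unname(means[sp]), level = level,
                   seed = if (is.null(seed)) NA_integer_ else seed))
  names(boot) <- names(means)
  k <- length(means)
  sig <- matrix(NA, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    sig[i, j] <- ci_nonoverlap(
      bootstrap_dist("plasticity", reps[, i], means[i], level = level),
      bootstrap_dist("plasticity", reps[, j], means[j], level = level))
  structure(list(means = means, boot = boot, significant = sig,
                 fit = fit, level = level, response = response),
            class = "plasticity_fit")
}

#' @export
print.plasticity_fit <- function(x, digits = 4, ...) {
  cat("Species plasticity model (species fixed, population random)\n")
  cat("Estimated species means:\n")
  print(round(x$means, digits))
  cat(sprintf("Pairwise %g%% CI non-overlap:\n", 100 * x$level))
  print(x$significant)
  invisible(x)
}

#' @export
coef.plasticity_fit <- function(object, ...) object$means
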