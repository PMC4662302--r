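#' Grid-cell range size
#'
#' Counts the distinct 0.1-degree x 0.1-degree grid cells occupied by at
#' least one occurrence point and multiplies by a fixed 123 km^2 per cell.
#' Cells are half-open with the lower-left corner inclusive:
#' `cell = (floor(lon / 0.1), floor(lat / 0.1))`. The constant per-cell area
#' reproduces the standard occupancy convention; latitude-corrected areas
#' (`111.32 km x 0.1` by `111.32 cos(lat) km x 0.1`) are available behind a
#' flag.
#'
#' @param occ data.frame with `lon` and `lat` columns (decimal degrees), or
#'   a two-column matrix.
#' @param cell_deg cell edge in degrees (default 0.1).
#' @param cell_area_km2 fixed area per occupied cell (default 123).
#' @param latitude_correct use per-cell cosine-corrected areas instead of
#'   the fixed constant.
#' @return List with `n_cells` and `area_km2` (class `range_size`).
#' @examples
#' range_size(data.frame(lon = c(0.05, 0.15), lat = c(0.05, 0.05)))
#' @export
range_size <- function(occ, cell_deg = 0.1, cell_area_km2 = 123,
                       latitude_correct = FALSE) {
  occ <- as.data.frame(occ)
  if (!all(c("lon", "lat") %in% names(occ))) {
    if (ncol(occ) >= 2) names(occ)[1:2] <- c("lon", "lat")
    else stop("occ must have lon and lat columns")
  }
  if (!nrow(occ)) stop("empty occurrence set")
  if (any(occ$lon < -180 | occ$lon > 180 | occ$lat < -90 | occ$lat > 90))
    stop("coordinates out of range [-180,180] x [-90,90]")
  cx <- floor(occ$lon / cell_deg)
  cy <- floor(occ$lat / cell_deg)
  cells <- unique(paste(cx, cy))
  if (latitude_correct) {
    first <- !duplicated(paste(cx, cy))
    lat_mid <- (cy[first] + 0.5) * cell_deg
    areas <- (111.32 * cell_deg)^2 * cos(lat_mid * pi / 180)
    area <- sum(areas)
  } else {
    area <- cell_area_km2 * length(cells)
  }
  structure(list(n_cells = length(cells), area_km2 = area,
                 cell_deg = cell_deg), class = "range_size")
}

#' @export
print.range_size <- function(x, ...) {
  cat(sprintf("Range size: %d occupied %.3g-degree cells = %g km^2\n",
              x$n_cells, x$cell_deg, x$area_km2))
  invisible(x)
}

#' Fst/Qst ratio against the drift expectation
#'
#' A ratio of 1 is expected when populations diverge by drift alone; values
#' above 1 point to stabilizing selection or a lack of additive variance,
#' values below 1 to diversifying selection. The point ratio is the ratio of
#' the two point estimates; the ratio distribution pairs replicate `r` of
#' each bootstrap (independent resampling when lengths differ). Replicates
#' with `Qst` below `min_qst` are dropped and counted. Two significance
#' rules are provided: the default percentile-CI rule (the CI excludes 1)
#' and the mean +/- SD rule; both summaries are returned.
#'
#' @param fst,qst [bootstrap_dist()] objects for Fst and Qst.
#' @param level confidence level.
#' @param min_qst Qst replicates below this are dropped (default 1e-6).
#' @param seed RNG seed (used only when replicate lengths differ).
#' @return Object of class `fst_qst_ratio`: `point`, `replicates`, `ci`,
#'   `mean`, `sd`, `drift_rejected_ci`, `drift_rejected_sd`, `n_dropped`.
#' @export
fst_qst_ratio <- function(fst, qst, level = 0.95, min_qst = 1e-6,
                          seed = NULL) {
  stopifnot(inherits(fst, "bootstrap_dist"), inherits(qst, "bootstrap_dist"))
  f <- fst$replicates; q <- qst$replicates
  if (!length(f) || !length(q)) stop("empty bootstrap distributions")
  if (length(f) != length(q)) {
    if (!is.null(seed)) set.seed(seed)
    n <- max(length(f), length(q))
    f <- sample(f, n, replace = TRUE)
    q <- sample(q, n, replace = TRUE)
  }
  drop <- is.na(q) | q < min_qst | is.na(f)
  n_dropped <- sum(drop)
  if (all(drop)) stop("all Qst replicates are (near) zero")
  ratio <- f[!drop] / q[!drop]
  point <- fst$point / qst$point
  ci <- .percentile_ci(ratio, level)
  m <- mean(ratio); s <- sd(ratio)
  structure(list(point = point, replicates = ratio, ci = ci, level = level,
                 mean = m, sd = s,
                 drift_rejected_ci = ci[1] > 1 || ci[2] < 1,
                 drift_rejected_sd = (m - s) > 1 || (m + s) < 1,
                 n_dropped = n_dropped),
            class = "fst_qst_ratio")
}

#' @export
print.fst_qst_ratio <- function(x, digits = 3, ...) {
  cat(sprintf("Fst/Qst ratio: point %.*f, mean %.*f +/- %.*f, %g%% CI [%.*f, %.*f]\n",
              digits, x$point, digits, x$mean, digits, x$sd,
              100 * x$level, digits, x$ci[1], digits, x$ci[2]))
  cat(sprintf("  drift (ratio = 1) rejected: CI rule %s, SD rule %s (%d replicates dropped)\n",
              x$drift_rejected_ci, x$drift_rejected_sd, x$n_dropped))
  invisible(x)
}

#' Spatially explicit population subsampling
#'
#' Draws groups of populations that mimic a rare species' spatial extent:
#' each group starts from a random seed population and accretes
#' nearest neighbors (great-circle distance) until a uniform-random size in
#' `group_size` is reached. The convex-hull area of the member coordinates
#' is reported so groups can be screened against a target extent window.
#'
#' @param coords data.frame with `pop`, `lon`, `lat` (one row per
#'   population).
#' @param group_size inclusive size range, default `c(5, 7)`.
#' @param n_draws number of groups.
#' @param seed RNG seed.
#' @param extent_window optional `c(min_km2, max_km2)`; draws whose hull
#'   falls outside are rejected and redrawn (up to `max_tries` attempts).
#' @param max_tries rejection-sampling cap per draw.
#' @return List of groups, each `list(pops, hull_km2, seed_pop)`.
#' @export
spatial_subsample <- function(coords, group_size = c(5, 7), n_draws = 20,
                              seed = NULL, extent_window = NULL,
                              max_tries = 200) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("pop", "lon", "lat") %in% names(coords)))
  coords <- coords[!duplicated(coords$pop), ]
  np <- nrow(coords)
  if (np < min(group_size))
    stop("species has fewer populations (", np,
         ") than the minimum group size (", min(group_size), ")")
  if (!is.null(seed)) set.seed(seed)
  D <- geosphere::distm(cbind(coords$lon, coords$lat)) / 1000  # km
  draws <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    for (try in seq_len(max_tries)) {
      sp <- sample.int(np, 1)
      sizes <- group_size[1]:group_size[2]
      size <- min(np, sizes[sample.int(length(sizes), 1)])
      members <- order(D[sp, ])[seq_len(size)]
      hull <- .hull_area_km2(coords$lon[members], coords$lat[members])
      if (is.null(extent_window) ||
          (hull >= extent_window[1] && hull <= extent_window[2])) break
      if (try == max_tries)
        stop("no subsample group fits the extent window [",
             extent_window[1], ", ", extent_window[2], "] km^2")
    }
    draws[[d]] <- list(pops = coords$pop[members], hull_km2 = hull,
                       seed_pop = coords$pop[sp])
  }
  draws
}

# Convex-hull area of lon/lat points in km^2; degenerate hulls (fewer than
# 3 distinct points, or collinear) have area 0.
.hull_area_km2 <- function(lon, lat) {
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  if (length(h) < 3) return(0)
  abs(geosphere::areaPolygon(pts[h, , drop = FALSE])) / 1e6
}

#' Regression of species means on log10 range size
#'
#' Ordinary least squares of one value per species on `log10(area km^2)`;
#' returns the slope, `r^2` and the two-sided `P` on `n - 2` degrees of
#' freedom. With only four species the test has very low power, so `r^2`
#' should be treated as the primary summary; the returned object carries a
#' `low_power` flag.
#'
#' @param values one (typically bootstrap-mean) value per species.
#' @param area_km2 range sizes in km^2, same order.
#' @return List with `slope`, `intercept`, `r2`, `p`, `n`, `low_power`.
#' @export
range_regression <- function(values, area_km2) {
  if (length(values) != length(area_km2)) stop("length mismatch")
  ok <- complete.cases(values, area_km2)
  values <- values[ok]; area_km2 <- area_km2[ok]
  if (length(values) < 3) stop("at least 3 species are required")
  if (any(area_km2 <= 0)) stop("areas must be positive for log10")
  x <- log10(area_km2)
  if (var(x) == 0) stop("zero variance in log10 range size")
  fit <- lm(values ~ x)
  sm <- summary(fit)
  constant <- var(values) == 0
  list(slope = unname(coef(fit)[["x"]]),
       intercept = unname(coef(fit)[[1]]),
       r2 = if (constant) 0 else sm$r.squared,
       p = if (constant) 1 else unname(sm$coefficients["x", "Pr(>|t|)"]),
       n = length(values),
       low_power = length(values) <= 4)
}

#' Median regression diagnostics over spatial subsample draws
#'
#' For each of `n_draws` draws, one random subsample group per widespread
#' species is evaluated: the statistic is recomputed on the group, the
#' group's convex-hull area stands in for that species' range size, rare
#' species contribute their full-sample value and range size, and
#' [range_regression()] is run across species. The medians of `r^2` and `P`
#' over draws are reported. Draws where the statistic is undefined for some
#' group are skipped and logged; more than 50% skipped is an error.
#'
#' @param widespread named list; each element is
#'   `list(coords = data.frame(pop, lon, lat), data = <anything>)`.
#' @param rare named list; each element is `list(value, area_km2)`.
#' @param statistic `function(data, pops)` returning the species value for a
#'   population subset.
#' @param n_draws number of draws (default 20).
#' @param seed RNG seed.
#' @param group_size,extent_window passed to [spatial_subsample()].
#' @return List with `median_r2`, `median_p`, `draws` (per-draw table) and
#'   `n_skipped`.
#' @export
subsample_analysis <- function(widespread, rare, statistic, n_draws = 20,
                               seed = NULL, group_size = c(5, 7),
                               extent_window = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- lapply(widespread, function(w)
    spatial_subsample(w$coords, group_size = group_size, n_draws = n_draws,
                      extent_window = extent_window))
  rare_vals <- vapply(rare, function(r) r$value, numeric(1))
  rare_area <- vapply(rare, function(r) r$area_km2, numeric(1))
  r2 <- p <- rep(NA_real_, n_draws)
  skipped <- logical(n_draws)
  for (d in seq_len(n_draws)) {
    vals <- areas <- numeric(0)
    for (i in seq_along(widespread)) {
      grp <- groups[[i]][[d]]
      v <- tryCatch(statistic(widespread[[i]]$data, grp$pops),
                    error = function(e) NA_real_)
      vals <- c(vals, v); areas <- c(areas, grp$hull_km2)
    }
    if (anyNA(vals) || any(areas <= 0)) { skipped[d] <- TRUE; next }
    reg <- tryCatch(range_regression(c(rare_vals, vals),
                                     c(rare_area, areas)),
                    error = function(e) NULL)
    if (is.null(reg)) { skipped[d] <- TRUE; next }
    r2[d] <- reg$r2; p[d] <- reg$p
  }
  if (sum(skipped) > n_draws / 2)
    stop("more than half of the subsample draws were skipped (",
         sum(skipped), "/", n_draws, ")")
  if (any(skipped))
    message("subsample_analysis: skipped ", sum(skipped), " draw(s)")
  list(median_r2 = stats::median(r2, na.rm = TRUE),
       median_p = stats::median(p, na.rm = TRUE),
       draws = data.frame(draw = seq_len(n_draws), r2 = r2, p = p,
                          skipped = skipped),
       n_skipped = sum(skipped))
}
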