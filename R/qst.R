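#' Derive ratio traits at day 55
#'
#' Adds `internode_55 = leafnum_55 / height_55` (leaves per mm, as
#' conventionally printed for this trait set, dimensional inversion and all)
#' and `leafsize_55 = leafarea_55 / leafnum_55` (mm^2 per leaf). Individuals
#' with zero leaf number get `NA` leaf size (excluded later by the
#' complete-case principal-component step) and are reported in the
#' `"derive_excluded"` attribute.
#'
#' @param pt phenotype data.frame with positive `height_55`, `leafarea_55`
#'   and `leafnum_55`.
#' @param invert_internode if `TRUE`, compute height/leaf-number instead
#'   (the dimensionally conventional "internode distance").
#' @return `pt` with the two derived columns appended.
#' @export
derive_traits <- function(pt, invert_internode = FALSE) {
  need <- c("height_55", "leafarea_55", "leafnum_55")
  if (!all(need %in% names(pt)))
    stop("phenotype table must contain: ", paste(need, collapse = ", "))
  if (any(pt$height_55 <= 0, na.rm = TRUE))
    stop("height_55 must be strictly positive")
  pt$internode_55 <- if (invert_internode) pt$height_55 / pt$leafnum_55
                     else pt$leafnum_55 / pt$height_55
  zero_leaf <- !is.na(pt$leafnum_55) & pt$leafnum_55 == 0
  pt$leafsize_55 <- ifelse(zero_leaf, NA_real_,
                           pt$leafarea_55 / pt$leafnum_55)
  if (invert_internode) pt$internode_55[zero_leaf] <- NA_real_
  if (any(zero_leaf))
    message("derive_traits: ", sum(zero_leaf),
            " individual(s) with zero leaf number flagged (derived traits NA)")
  attr(pt, "derive_excluded") <- pt$individual[zero_leaf]
  pt
}

#' Composite phenotype from weighted principal components
#'
#' Rows with any missing trait are dropped (complete-case analysis, logged in
#' the returned object). Traits are centered and, by default, scaled to unit
#' variance (correlation-matrix PCA — the defensible default for traits on
#' incommensurable scales; covariance-matrix PCA is available via
#' `scale = FALSE`). Each individual's composite score is the mean of its
#' first `n_axes` principal-component scores weighted by the percent
#' variance explained by each axis:
#' `score_i = sum_k w_k PC_ki / sum_k w_k`, `w_k = %variance of axis k`.
#'
#' @param pt phenotype data.frame (see [simulate_phenotypes()] /
#'   [derive_traits()]).
#' @param traits trait columns to use; defaults to the eight rosette/leaf
#'   traits when present.
#' @param n_axes number of leading axes in the weighted mean (default 3).
#' @param scale scale traits to unit variance before the decomposition.
#' @return An object of class `composite_score`: `score` (named vector),
#'   `population`, `family`, `pct_var` (per-axis percent variance),
#'   `loadings`, and `dropped` (ids of incomplete rows).
#' @export
composite_phenotype <- function(pt, traits = NULL, n_axes = 3, scale = TRUE) {
  if (is.null(traits)) {
    traits <- intersect(c("height_21", "leafarea_21", "leafnum_21",
                          "height_55", "leafarea_55", "leafnum_55",
                          "internode_55", "leafsize_55"), names(pt))
  }
  if (!length(traits)) stop("no trait columns found")
  if (n_axes > length(traits)) stop("n_axes exceeds the number of traits")
  X <- as.matrix(pt[, traits, drop = FALSE])
  ok <- complete.cases(X)
  if (sum(ok) < length(traits))
    stop("fewer complete rows (", sum(ok), ") than traits (",
         length(traits), ")")
  dropped <- pt$individual[!ok]
  if (length(dropped))
    message("composite_phenotype: dropped ", length(dropped),
            " incomplete row(s)")
  X <- X[ok, , drop = FALSE]
  constant <- apply(X, 2, function(v) var(v) == 0)
  if (scale && any(constant))
    stop("constant trait(s) cannot be scaled: ",
         paste(traits[constant], collapse = ", "))
  pc <- prcomp(X, center = TRUE, scale. = scale)
  pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  w <- pct[seq_len(n_axes)]
  score <- as.vector(pc$x[, seq_len(n_axes), drop = FALSE] %*% w) / sum(w)
  names(score) <- pt$individual[ok]
  structure(list(score = score,
                 population = pt$population[ok],
                 family = pt$family[ok],
                 pct_var = pct, n_axes = n_axes,
                 loadings = pc$rotation, traits = traits,
                 dropped = dropped),
            class = "composite_score")
}

#' @export
print.composite_score <- function(x, ...) {
  cat(sprintf("Composite phenotype: %d individuals, %d traits\n",
              length(x$score), length(x$traits)))
  cat("  %variance by axis:",
      paste(sprintf("%.1f", x$pct_var[seq_len(min(5, length(x$pct_var)))]),
            collapse = ", "), "...\n")
  cat(sprintf("  weighted mean of first %d axes (weight sum %.1f%%)\n",
              x$n_axes, sum(x$pct_var[seq_len(x$n_axes)])))
  invisible(x)
}

#' Nested variance components, Qst and broad-sense heritability
#'
#' Fits the nested random-effects model `y_ijk = mu + P_i + F_ij + e_ijk`
#' (population, family-within-population, residual) and derives
#' `Qst = V_POP / (V_POP + V_FAM)` — the selfing-appropriate form, which
#' omits the outcrossing factor of 2 on the family variance — and
#' broad-sense heritability `H2 = V_FAM / V_TOT` with
#' `V_TOT = V_POP + V_FAM + V_ERR` (note the denominator includes `V_POP`).
#'
#' `method = "reml"` maximizes the restricted likelihood (via a tightly
#' converged nested mixed-model fit; non-negativity is intrinsic to the
#' parameterization). `method = "anova_mom"` is the closed-form nested
#' ANOVA method-of-moments estimator with Searle's coefficients for
#' unbalanced designs, negative solutions truncated at zero; on balanced
#' designs with interior solutions the two estimators coincide, which is the
#' package's cross-check.
#'
#' @param score numeric response (e.g. the composite phenotype), or a
#'   [composite_phenotype()] object carrying its own labels.
#' @param population,family grouping labels (ignored when `score` is a
#'   `composite_score`).
#' @param method `"reml"` (default) or `"anova_mom"`.
#' @return An object of class `qst_fit` with components `vc`
#'   (`V_POP`, `V_FAM`, `V_ERR`, `V_TOT`), `qst`, `h2`, the underlying
#'   mixed-model `fit` (REML only) and the model frame `data`. Supports
#'   `print()`, `summary()`, `coef()`, `simulate()` and `residuals()`.
#' @examples
#' pt <- simulate_phenotypes(sim_config(n_pops = 6, seed = 4))
#' cs <- composite_phenotype(derive_traits(pt))
#' fit <- variance_components(cs)
#' coef(fit)
#' @export
variance_components <- function(score, population = NULL, family = NULL,
                                method = c("reml", "anova_mom")) {
  method <- match.arg(method)
  if (inherits(score, "composite_score")) {
    population <- score$population; family <- score$family
    score <- score$score
  }
  y <- as.numeric(score)
  d <- data.frame(y = y, population = factor(population),
                  fam = factor(paste(population, family, sep = "/")))
  d <- d[complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$population)) < 2)
    stop("at least 2 populations are required")
  if (nlevels(droplevels(d$fam)) < 2)
    stop("singular design: only one family in total")
  fams_per_pop <- tapply(as.character(d$fam), d$population,
                         function(f) length(unique(f)))
  if (max(fams_per_pop, na.rm = TRUE) < 2)
    stop("singular design: no population has 2 or more families")

  if (var(d$y) == 0) {
    vc <- c(V_POP = 0, V_FAM = 0, V_ERR = 0, V_TOT = 0)
    return(structure(list(vc = vc, qst = NA_real_, h2 = NA_real_,
                          method = method, fit = NULL, data = d,
                          converged = TRUE),
                     class = "qst_fit"))
  }

  if (method == "reml") {
    ctrl <- lme4::lmerControl(
      optimizer = "bobyqa",
      optCtrl = list(rhobeg = 0.2, rhoend = 1e-10),
      calc.derivs = FALSE,
      check.conv.singular = "ignore")
    fit <- suppressMessages(
      lme4::lmer(y ~ 1 + (1 | population) + (1 | fam), data = d,
                 REML = TRUE, control = ctrl))
    vcs <- as.data.frame(lme4::VarCorr(fit))
    v_pop <- vcs$vcov[vcs$grp == "population"]
    v_fam <- vcs$vcov[vcs$grp == "fam"]
    v_err <- vcs$vcov[vcs$grp == "Residual"]
  } else {
    fit <- NULL
    mom <- .nested_anova_mom(d$y, d$population, d$fam)
    v_pop <- mom["V_POP"]; v_fam <- mom["V_FAM"]; v_err <- mom["V_ERR"]
  }
  vc <- c(V_POP = unname(v_pop), V_FAM = unname(v_fam),
          V_ERR = unname(v_err))
  vc <- pmax(vc, 0)
  vc["V_TOT"] <- sum(vc)
  qst <- if (vc[["V_POP"]] + vc[["V_FAM"]] > 0)
    vc[["V_POP"]] / (vc[["V_POP"]] + vc[["V_FAM"]]) else NA_real_
  h2 <- if (vc[["V_TOT"]] > 0) vc[["V_FAM"]] / vc[["V_TOT"]] else NA_real_
  structure(list(vc = vc, qst = qst, h2 = h2, method = method, fit = fit,
                 data = d, converged = TRUE),
            class = "qst_fit")
}

# Closed-form nested ANOVA estimator with Searle's unbalanced coefficients.
.nested_anova_mom <- function(y, pop, fam) {
  pop <- as.character(pop); fam <- as.character(fam)
  N <- length(y)
  n_ij <- tapply(y, fam, length)                  # per family
  fam_pop <- tapply(pop, fam, `[`, 1)
  n_i <- tapply(y, pop, length)                   # per population
  P <- length(n_i); Fn <- length(n_ij)
  ybar <- mean(y)
  ybar_fam <- tapply(y, fam, mean)
  ybar_pop <- tapply(y, pop, mean)

  ss_err <- sum((y - ybar_fam[fam])^2)
  ss_fam <- sum(n_ij * (ybar_fam - ybar_pop[fam_pop])^2)
  ss_pop <- sum(n_i * (ybar_pop - ybar)^2)
  df_err <- N - Fn; df_fam <- Fn - P; df_pop <- P - 1
  if (df_fam < 1 || df_err < 1 || df_pop < 1)
    stop("design too small for the nested ANOVA estimator")
  ms_err <- ss_err / df_err
  ms_fam <- ss_fam / df_fam
  ms_pop <- ss_pop / df_pop

  sum_nij2_ni <- sum(tapply(seq_along(y), pop, function(idx) {
    nn <- tapply(y[idx], fam[idx], length)
    sum(nn^2) / length(idx)
  }))
  sum_nij2_N <- sum(n_ij^2) / N
  sum_ni2_N <- sum(n_i^2) / N
  k1 <- (N - sum_nij2_ni) / df_fam      # sigma_fam coef in MS_fam
  k2 <- (sum_nij2_ni - sum_nij2_N) / df_pop
  k3 <- (N - sum_ni2_N) / df_pop

  v_err <- ms_err
  v_fam <- (ms_fam - ms_err) / k1
  v_pop <- (ms_pop - ms_err - k2 * max(v_fam, 0)) / k3
  c(V_POP = max(v_pop, 0), V_FAM = max(v_fam, 0), V_ERR = v_err)
}

#' @export
print.qst_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Nested variance components (%s)\n", x$method))
  print(round(x$vc, digits))
  cat(sprintf("Qst = %s   H2 = %s\n",
              format(round(x$qst, digits)), format(round(x$h2, digits))))
  invisible(x)
}

#' @export
summary.qst_fit <- function(object, ...) {
  d <- object$data
  cat(sprintf("Nested variance-component fit (%s)\n", object$method))
  cat(sprintf("  %d observations, %d populations, %d families\n",
              nrow(d), nlevels(droplevels(d$population)),
              nlevels(droplevels(d$fam))))
  print(object)
  invisible(object)
}

#' @export
coef.qst_fit <- function(object, ...) {
  c(object$vc, Qst = object$qst, H2 = object$h2)
}

#' @export
residuals.qst_fit <- function(object, ...) {
  if (!is.null(object$fit)) residuals(object$fit)
  else object$data$y - mean(object$data$y)
}

#' Simulate responses from a fitted nested variance-component model
#'
#' Draws new population effects, family effects and residuals from the
#' fitted normal components on the original design (the parametric-bootstrap
#' generator).
#'
#' @param object a `qst_fit`.
#' @param nsim number of response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return A data.frame with `nsim` columns of simulated responses.
#' @export
simulate.qst_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(object$fit))
    return(simulate(object$fit, nsim = nsim, seed = seed))
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  vc <- object$vc
  mu <- mean(d$y)
  out <- replicate(nsim, {
    p <- rnorm(nlevels(d$population), 0, sqrt(vc[["V_POP"]]))
    f <- rnorm(nlevels(d$fam), 0, sqrt(vc[["V_FAM"]]))
    mu + p[as.integer(d$population)] + f[as.integer(d$fam)] +
      rnorm(nrow(d), 0, sqrt(vc[["V_ERR"]]))
  })
  as.data.frame(out)
}

#' Parametric bootstrap of variance components, Qst and H2
#'
#' Per replicate: simulate responses from the fitted model (normal random
#' effects and residuals on the original design), refit, and record
#' `V_POP`, `V_FAM`, `V_ERR`, `V_TOT`, `Qst` and `H2`; percentile intervals
#' at `level`. More than `max_fail` non-converging replicates is an error.
#'
#' @param fit a [variance_components()] REML fit (a degenerate all-zero fit
#'   yields zero-width intervals at 0).
#' @param n_boot replicates (default 1000).
#' @param seed RNG seed.
#' @param level confidence level.
#' @param max_fail tolerated fraction of failed refits (default 0.05).
#' @return Named list of [bootstrap_dist()] for the six quantities
#'   (class `vc_bootstrap`), with the failure count in attribute `n_fail`.
#' @export
parametric_bootstrap_vc <- function(fit, n_boot = 1000, seed = NULL,
                                    level = 0.95, max_fail = 0.05) {
  stopifnot(inherits(fit, "qst_fit"))
  qnames <- c("V_POP", "V_FAM", "V_ERR", "V_TOT", "QST", "H2")
  points <- c(fit$vc, QST = fit$qst, H2 = fit$h2)
  names(points) <- qnames
  if (is.null(fit$fit)) {
    if (any(fit$vc > 0))
      stop("parametric bootstrap needs a REML fit (method = 'reml')")
    reps <- matrix(0, n_boot, 6, dimnames = list(NULL, qnames))
  } else {
    sims <- simulate(fit$fit, nsim = n_boot, seed = seed)
    reps <- matrix(NA_real_, n_boot, 6, dimnames = list(NULL, qnames))
    fails <- 0L
    for (b in seq_len(n_boot)) {
      rb <- tryCatch({
        rf <- suppressMessages(lme4::refit(fit$fit, newresp = sims[[b]]))
        vcs <- as.data.frame(lme4::VarCorr(rf))
        v <- c(vcs$vcov[vcs$grp == "population"],
               vcs$vcov[vcs$grp == "fam"],
               vcs$vcov[vcs$grp == "Residual"])
        v <- pmax(v, 0)
        c(v, sum(v),
          if (v[1] + v[2] > 0) v[1] / (v[1] + v[2]) else NA_real_,
          if (sum(v) > 0) v[2] / sum(v) else NA_real_)
      }, error = function(e) NULL)
      if (is.null(rb)) fails <- fails + 1L else reps[b, ] <- rb
    }
    if (fails > max_fail * n_boot)
      stop("parametric bootstrap: ", fails, "/", n_boot,
           " replicates failed to converge")
    attr(reps, "n_fail") <- fails
  }
  out <- lapply(qnames, function(q)
    bootstrap_dist(q, reps[, q], unname(points[q]), level = level,
                   seed = if (is.null(seed)) NA_integer_ else seed))
  names(out) <- qnames
  attr(out, "n_fail") <- attr(reps, "n_fail")
  class(out) <- "vc_bootstrap"
  out
}

#' @export
print.vc_bootstrap <- function(x, ...) {
  cat("Parametric bootstrap of variance components\n")
  for (d in x) print(d)
  invisible(x)
}
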