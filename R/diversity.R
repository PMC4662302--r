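#' Nei gene-diversity statistics
#'
#' Per-locus and across-loci observed heterozygosity (`Ho`), mean
#' within-population gene diversity (`Hs`), total gene diversity (`Ht`),
#' absolute differentiation (`Dst = Ht - Hs`), the among-population fraction
#' (`Fst = Dst / Ht`) and the inbreeding coefficient (`Fis = 1 - Ho / Hs`).
#'
#' With `estimator = "plain"` the statistics are the uncorrected definitions
#' computed from sample allele frequencies: `Ho` is the mean over populations
#' of the heterozygote fraction, `Hs` the mean over populations of
#' `1 - sum(p_a^2)`, and `Ht` uses the unweighted average of population
#' frequency vectors (Nei's convention). The plain identities
#' `Dst = Ht - Hs`, `Fst * Ht = Dst` and `Fis = 1 - Ho/Hs` then hold exactly
#' per locus.
#'
#' With `estimator = "sample_corrected"` the Nei & Chesser small-sample
#' corrections are applied using the harmonic mean `nh` of per-population
#' sample sizes at the locus:
#' \deqn{\hat H_S = \frac{nh}{nh - 1}\Big(\tilde H_S - \frac{\hat H_O}{2 nh}\Big)}
#' \deqn{\hat H_T = \tilde H_T + \frac{\hat H_S}{nh\,s} - \frac{\hat H_O}{2 nh\,s}}
#' where `s` is the number of populations scored at the locus and the tilde
#' quantities are the plain values. The corrected `Hs` is unbiased for the
#' generating-model gene diversity even under inbreeding, which makes it the
#' right plug-in inside bootstrap confidence intervals.
#'
#' Individuals missing at a locus are excluded at that locus only. Null
#' alleles are a scorable allele class (null/null homozygotes count as
#' homozygous). Monomorphic loci report `Ho = Hs = Ht = 0` with `Fst` and
#' `Fis` undefined (`NA`); across-loci values are means over the loci where
#' each statistic is defined. `Fis` is clamped to `[-1, 1]` for reporting;
#' the raw value is kept in the `Fis_raw` column.
#'
#' @param gt a [genotype_table()].
#' @param estimator `"plain"` (default) or `"sample_corrected"`.
#' @return An object of class `diversity_stats`: a list with `perloc` (one
#'   row per locus: `n`, `A`, `pct_na`, `Ho`, `Hs`, `Ht`, `Dst`, `Fst`,
#'   `Fis`, `Fis_raw`) and `overall` (across-loci means).
#' @examples
#' gt <- simulate_genotypes(sim_config(n_pops = 4, seed = 3))
#' basic_stats(gt)
#' @export
basic_stats <- function(gt, estimator = c("plain", "sample_corrected")) {
  estimator <- match.arg(estimator)
  prep <- .gt_prep(gt)
  scored_any <- rowsum(as.numeric(rowSums(!is.na(gt$a1))), gt$population)
  if (any(scored_any == 0))
    stop("population(s) with zero scored individuals at every locus: ",
         paste(rownames(scored_any)[scored_any == 0], collapse = ", "))
  per <- t(vapply(prep$codes, function(cc)
    .locus_stats(cc$c1, cc$c2, prep$ip, prep$np, cc$K, estimator),
    numeric(10)))
  perloc <- data.frame(locus = gt$loci, per, stringsAsFactors = FALSE,
                       row.names = NULL)
  defined <- colSums(!is.na(per)) > 0
  overall <- ifelse(defined, colMeans(per, na.rm = TRUE), NA_real_)
  names(overall) <- colnames(per)
  structure(list(perloc = perloc, overall = overall,
                 estimator = estimator, n_pops = prep$np),
            class = "diversity_stats")
}

# Recode each locus to contiguous codes 1..K once; reused by the bootstrap.
.gt_prep <- function(gt) {
  pops <- unique(gt$population)
  ip <- match(gt$population, pops)
  codes <- lapply(seq_along(gt$loci), function(l) {
    x1 <- gt$a1[, l]; x2 <- gt$a2[, l]
    alleles <- sort(unique(c(x1, x2)))
    alleles <- alleles[!is.na(alleles)]
    list(c1 = match(x1, alleles), c2 = match(x2, alleles),
         K = length(alleles), alleles = alleles)
  })
  names(codes) <- gt$loci
  list(codes = codes, ip = ip, np = length(pops), pops = pops)
}

# Single-locus statistics from recoded alleles. Returns a fixed-order
# numeric(10): n, A, pct_na, Ho, Hs, Ht, Dst, Fst, Fis, Fis_raw.
.locus_stats <- function(c1, c2, ip, np, K, estimator = "plain",
                         rows = NULL) {
  if (!is.null(rows)) { c1 <- c1[rows]; c2 <- c2[rows]; ip <- ip[rows] }
  out <- c(n = NA_real_, A = NA_real_, pct_na = NA_real_, Ho = NA_real_,
           Hs = NA_real_, Ht = NA_real_, Dst = NA_real_, Fst = NA_real_,
           Fis = NA_real_, Fis_raw = NA_real_)
  scored <- !is.na(c1)
  ns <- sum(scored)
  out["pct_na"] <- 100 * (length(c1) - ns) / length(c1)
  out["n"] <- ns
  if (ns == 0 || K == 0) { out["A"] <- 0; return(out) }
  ip_s <- ip[scored]
  n_p <- tabulate(ip_s, np)
  use <- n_p > 0
  het_p <- tabulate(ip_s[c1[scored] != c2[scored]], np)
  cnt <- tabulate(c((ip_s - 1L) * K + c1[scored],
                    (ip_s - 1L) * K + c2[scored]), np * K)
  Pm <- matrix(cnt, nrow = K)                  # K x np allele counts
  Pm <- Pm[, use, drop = FALSE]
  freq <- sweep(Pm, 2, colSums(Pm), "/")
  present <- rowSums(Pm) > 0
  out["A"] <- sum(present)
  ho_p <- het_p[use] / n_p[use]
  hs_p <- 1 - colSums(freq^2)
  pbar <- rowMeans(freq)
  ho <- mean(ho_p)
  hs <- mean(hs_p)
  ht <- 1 - sum(pbar^2)
  s <- sum(use)
  if (estimator == "sample_corrected") {
    nh <- 1 / mean(1 / n_p[use])               # harmonic mean sample size
    if (nh > 1) {
      hs <- nh / (nh - 1) * (hs - ho / (2 * nh))
      ht <- ht + hs / (nh * s) - ho / (2 * nh * s)
    }
  }
  mono <- out["A"] <= 1
  out["Ho"] <- ho; out["Hs"] <- hs
  if (s >= 2) {
    out["Ht"] <- ht
    out["Dst"] <- ht - hs
    out["Fst"] <- if (!mono && ht > 0) (ht - hs) / ht else NA_real_
  }
  if (mono) { out["Ho"] <- 0; out["Hs"] <- 0; if (s >= 2) out["Ht"] <- 0
    out["Dst"] <- if (s >= 2) 0 else NA_real_
    out["Fst"] <- NA_real_
  }
  fis_raw <- if (!mono && hs > 0) 1 - ho / hs else NA_real_
  out["Fis_raw"] <- fis_raw
  out["Fis"] <- if (is.na(fis_raw)) NA_real_ else max(-1, min(1, fis_raw))
  out
}

#' @export
print.diversity_stats <- function(x, digits = 4, ...) {
  cat(sprintf("Nei diversity statistics (%s estimator, %d populations, %d loci)\n",
              x$estimator, x$n_pops, nrow(x$perloc)))
  ov <- x$overall[c("Ho", "Hs", "Ht", "Dst", "Fst", "Fis")]
  cat("Across-loci means:\n")
  print(round(ov, digits))
  invisible(x)
}

#' Effective number of alleles
#'
#' `A_e = 1 / sum(p_a^2)` from within-population allele frequencies, per
#' population and locus; the species-level value per locus is the mean over
#' populations scored at that locus. Unscored population x locus cells are
#' `NA`.
#'
#' @param gt a [genotype_table()].
#' @return A list with `per_pop` (populations x loci matrix), `per_locus`
#'   (species-level mean over populations) and `overall` (mean over loci).
#' @examples
#' # a locus with k equifrequent alleles has A_e = k
#' @export
effective_alleles <- function(gt) {
  prep <- .gt_prep(gt)
  ae <- matrix(NA_real_, prep$np, length(prep$codes),
               dimnames = list(prep$pops, names(prep$codes)))
  for (l in seq_along(prep$codes)) {
    cc <- prep$codes[[l]]
    scored <- !is.na(cc$c1)
    if (!any(scored) || cc$K == 0) next
    ip_s <- prep$ip[scored]
    cnt <- tabulate(c((ip_s - 1L) * cc$K + cc$c1[scored],
                      (ip_s - 1L) * cc$K + cc$c2[scored]),
                    prep$np * cc$K)
    Pm <- matrix(cnt, nrow = cc$K)
    tot <- colSums(Pm)
    ok <- tot > 0
    freq <- sweep(Pm[, ok, drop = FALSE], 2, tot[ok], "/")
    ae[ok, l] <- 1 / colSums(freq^2)
  }
  per_locus <- colMeans(ae, na.rm = TRUE)
  per_locus[is.nan(per_locus)] <- NA_real_
  list(per_pop = ae, per_locus = per_locus,
       overall = mean(per_locus, na.rm = TRUE))
}
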