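#' Construct a codominant genotype table
#'
#' The central molecular container: individuals x loci diploid integer allele
#' calls with population (and optionally maternal family) labels. Missing
#' calls are `NA` in both allele slots; null alleles are an ordinary,
#' scorable allele class identified by the `null_allele` code.
#'
#' @param individual character vector of unique individual ids.
#' @param population population label per individual.
#' @param family optional family label per individual.
#' @param a1,a2 integer matrices (individuals x loci) of allele codes;
#'   `NA` marks a missing call. If one slot of a call is `NA` the whole call
#'   is treated as missing.
#' @param loci locus names; defaults to the column names of `a1`.
#' @param null_allele integer code of the null-allele class (default 99).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individual, population, family = NULL,
                           a1, a2, loci = colnames(a1),
                           null_allele = .NULL_ALLELE_CODE) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(individual)
  if (nrow(a1) != n || nrow(a2) != n || ncol(a1) != ncol(a2))
    stop("allele matrices must be individuals x loci and conformable")
  if (anyDuplicated(individual))
    stop("duplicated individual ids: ",
         paste(unique(individual[duplicated(individual)]), collapse = ", "))
  if (length(population) != n) stop("one population label per individual")
  if (any(!nzchar(as.character(population))))
    stop("population labels must be non-empty")
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(ncol(a1)))
  # a call is missing as a unit: propagate NA across both slots
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  colnames(a1) <- colnames(a2) <- loci
  if (is.null(family)) family <- rep(NA_character_, n)
  structure(list(individual = as.character(individual),
                 population = as.character(population),
                 family = as.character(family),
                 a1 = a1, a2 = a2, loci = loci,
                 null_allele = as.integer(null_allele)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  np <- length(unique(x$population))
  nmiss <- sum(is.na(x$a1))
  cat(sprintf("Genotype table: %d individuals, %d populations, %d loci\n",
              length(x$individual), np, length(x$loci)))
  cat(sprintf("  missing calls: %d (%.2f%%); null-allele code: %d\n",
              nmiss, 100 * nmiss / length(x$a1), x$null_allele))
  invisible(x)
}

#' Number of loci / individuals / populations of a genotype table
#' @param gt a `genotype_table`.
#' @return An integer.
#' @export
n_loci <- function(gt) length(gt$loci)

#' @rdname n_loci
#' @export
n_individuals <- function(gt) length(gt$individual)

#' @rdname n_loci
#' @export
n_populations <- function(gt) length(unique(gt$population))

#' Subset a genotype table by individuals
#' @param gt a `genotype_table`.
#' @param rows integer or logical index of individuals to keep.
#' @return A `genotype_table`.
#' @export
subset_individuals <- function(gt, rows) {
  genotype_table(gt$individual[rows], gt$population[rows], gt$family[rows],
                 gt$a1[rows, , drop = FALSE], gt$a2[rows, , drop = FALSE],
                 loci = gt$loci, null_allele = gt$null_allele)
}

#' Exclude individuals with too many missing loci
#'
#' Drops every individual whose genotype is missing at more than
#' `max_missing_loci` loci (default 4, the usual screening rule for a
#' 15-locus SSR panel). The removed individuals and their missing-locus
#' counts are attached as the `"removed"` attribute and reported via a
#' message.
#'
#' @param gt a `genotype_table`.
#' @param max_missing_loci maximum tolerated number of missing loci.
#' @return The filtered `genotype_table`.
#' @export
filter_individuals <- function(gt, max_missing_loci = 4) {
  nmiss <- rowSums(is.na(gt$a1))
  keep <- nmiss <= max_missing_loci
  if (!any(keep))
    stop("no individuals remain after excluding those missing at more than ",
         max_missing_loci, " loci")
  removed <- data.frame(individual = gt$individual[!keep],
                        population = gt$population[!keep],
                        n_missing_loci = nmiss[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(removed))
    message("filter_individuals: removed ", nrow(removed),
            " individual(s) missing at more than ", max_missing_loci,
            " loci: ", paste(removed$individual, collapse = ", "))
  out <- subset_individuals(gt, keep)
  attr(out, "removed") <- removed
  attr(out, "sim") <- attr(gt, "sim")
  out
}
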