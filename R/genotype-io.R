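#' Read a genotype table from GenePop or tidy CSV
#'
#' The GenePop dialect is version 4 with 3-digit allele codes: a title line,
#' one locus name per line (or a single comma-separated line), `POP` records
#' delimiting populations, and individual lines `id , 001002 003003 ...`
#' where `000` encodes a missing allele. Two-digit (4-character) genotypes
#' are also accepted. Population labels are taken from the id of the first
#' individual in each `POP` block (the GenePop convention), falling back to
#' `pop1`, `pop2`, ... when ids repeat across blocks.
#'
#' The CSV dialect is the tidy long format written by [write_genotypes()]:
#' columns `individual`, `population`, `family`, `locus`, `allele1`,
#' `allele2`, one row per individual x locus, blank/NA alleles = missing.
#'
#' @param path file path.
#' @param format `"genepop"` or `"csv"`.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("genepop", "csv")) {
  format <- match.arg(format)
  switch(format,
         genepop = .read_genepop(path),
         csv = .read_genotypes_csv(path))
}

.read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a GenePop file: too few lines")
  body <- lines[-1]                       # drop title
  is_pop <- tolower(trimws(body)) %in% c("pop")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a GenePop file: no POP record")
  loci_lines <- body[seq_len(first_pop - 1)]
  loci <- trimws(unlist(strsplit(loci_lines, ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  if (L == 0) stop("no locus names before the first POP record")

  ind <- character(); popn <- integer(); genos <- list()
  pop_block <- 0L
  for (ln in body[first_pop:length(body)]) {
    if (tolower(trimws(ln)) == "pop") { pop_block <- pop_block + 1L; next }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed individual line: ", ln)
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop("individual '", id, "' has ", length(toks),
           " genotypes but ", L, " loci are declared")
    w <- nchar(toks[1]) / 2
    if (!w %in% c(2, 3)) stop("allele codes must be 2 or 3 digits wide")
    g1 <- as.integer(substr(toks, 1, w))
    g2 <- as.integer(substr(toks, w + 1, 2 * w))
    g1[g1 == 0L] <- NA_integer_; g2[g2 == 0L] <- NA_integer_
    ind <- c(ind, id); popn <- c(popn, pop_block)
    genos[[length(genos) + 1L]] <- rbind(g1, g2)
  }
  if (!length(ind)) stop("no individuals found")
  a1 <- t(vapply(genos, function(g) g[1, ], integer(L)))
  a2 <- t(vapply(genos, function(g) g[2, ], integer(L)))
  if (L == 1) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  # population label = first id of the block, unless that collides
  firsts <- ind[!duplicated(popn)]
  labels <- if (anyDuplicated(firsts)) sprintf("pop%d", seq_along(firsts))
            else firsts
  genotype_table(ind, labels[popn], NULL, a1, a2, loci = loci)
}

.read_genotypes_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "locus", "allele1", "allele2")
  if (!all(need %in% names(d)))
    stop("genotype CSV must have columns: ",
         paste(c(need, "family (optional)"), collapse = ", "))
  loci <- unique(d$locus)
  inds <- unique(d$individual)
  per_ind <- table(d$individual)
  if (any(per_ind != length(loci)))
    stop("locus count mismatch: every individual needs one row per locus")
  i <- match(d$individual, inds); l <- match(d$locus, loci)
  a1 <- matrix(NA_integer_, length(inds), length(loci))
  a2 <- a1
  a1[cbind(i, l)] <- as.integer(d$allele1)
  a2[cbind(i, l)] <- as.integer(d$allele2)
  first <- !duplicated(d$individual)
  fam <- if ("family" %in% names(d)) as.character(d$family[first]) else NULL
  genotype_table(inds, d$population[first], fam, a1, a2, loci = loci)
}

#' Write a genotype table as GenePop or tidy CSV
#'
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @param format `"genepop"` (3-digit codes, `000` = missing, populations
#'   delimited by `POP` records) or `"csv"` (tidy long format).
#' @param title title line for GenePop output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, format = c("genepop", "csv"),
                            title = "rarecomp genotype export") {
  format <- match.arg(format)
  if (format == "csv") {
    L <- n_loci(gt); n <- n_individuals(gt)
    d <- data.frame(
      individual = rep(gt$individual, each = L),
      population = rep(gt$population, each = L),
      family = rep(gt$family, each = L),
      locus = rep(gt$loci, n),
      allele1 = as.integer(t(gt$a1)),
      allele2 = as.integer(t(gt$a2)), stringsAsFactors = FALSE)
    write.csv(d, path, row.names = FALSE, na = "")
    return(invisible(path))
  }
  code <- function(a) { a[is.na(a)] <- 0L; sprintf("%03d", a) }
  out <- c(title, gt$loci)
  for (p in unique(gt$population)) {
    out <- c(out, "POP")
    rows <- which(gt$population == p)
    for (r in rows) {
      out <- c(out, paste0(gt$individual[r], " ,  ",
                           paste0(code(gt$a1[r, ]), code(gt$a2[r, ]),
                                  collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
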