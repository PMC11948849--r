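#' Genotype table
#'
#' Container for a matrix of biallelic genotype calls with per-call read
#' depths and variant coordinates. Calls are diploid dosages of the
#' alternate allele (0, 1, 2) with \code{NA} for missing; rows are
#' individuals and columns are variants. Positions are 1-based and must be
#' strictly increasing within each chromosome (VCF convention).
#'
#' @param calls integer matrix, individuals x variants, values 0/1/2/NA.
#' @param chrom character vector of chromosome names, one per variant.
#' @param pos integer vector of 1-based positions, one per variant.
#' @param depths optional integer matrix of per-call read depths, same
#'   shape as \code{calls}.
#' @param ref,alt optional reference/alternate allele strings per variant;
#'   default single-nucleotide placeholders. A comma in \code{alt} marks a
#'   multi-allelic record.
#' @param individuals character vector of individual identifiers; defaults
#'   to \code{rownames(calls)}.
#'
#' @return An object of class \code{genotype_table}.
#' @export
genotype_table <- function(calls, chrom, pos, depths = NULL,
                           ref = NULL, alt = NULL, individuals = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  m <- ncol(calls)
  n <- nrow(calls)
  if (length(chrom) != m || length(pos) != m) {
    stop("chrom and pos must have one entry per variant column")
  }
  if (is.null(individuals)) {
    individuals <- rownames(calls)
    if (is.null(individuals)) individuals <- sprintf("ind%03d", seq_len(n))
  }
  if (length(individuals) != n) stop("individuals must match nrow(calls)")
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    storage.mode(depths) <- "integer"
    if (!all(dim(depths) == dim(calls))) {
      stop("depths must have the same shape as calls")
    }
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("calls must be 0, 1, 2 or NA")
  }
  pos <- as.integer(pos)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0L)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  rownames(calls) <- individuals
  if (!is.null(depths)) rownames(depths) <- individuals
  structure(
    list(individuals = individuals, chrom = as.character(chrom), pos = pos,
         ref = as.character(ref), alt = as.character(alt),
         calls = calls, depths = depths),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$individuals), "individuals x",
      length(x$pos), "variants on", length(unique(x$chrom)),
      "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Number of variants / individuals in a genotype table
#' @param geno a \code{genotype_table}.
#' @return integer count.
#' @export
n_variants <- function(geno) length(geno$pos)

#' @rdname n_variants
#' @export
n_individuals <- function(geno) length(geno$individuals)

#' Alternate-allele frequency per site
#'
#' Computed from called genotypes only; missing calls are excluded from
#' both numerator and denominator.
#'
#' @param geno a \code{genotype_table}.
#' @return numeric vector of length \code{n_variants(geno)}; \code{NaN}
#'   where no genotype is called.
#' @export
allele_freq <- function(geno) {
  colMeans(geno$calls, na.rm = TRUE) / 2
}

#' Dosage matrix with missing-call imputation
#'
#' @param geno a \code{genotype_table}.
#' @param impute \code{"mean"} replaces missing calls by the site mean
#'   dosage 2p; \code{"none"} leaves \code{NA}.
#' @return numeric matrix, individuals x variants.
#' @export
dosage_matrix <- function(geno, impute = c("mean", "none")) {
  impute <- match.arg(impute)
  x <- geno$calls
  storage.mode(x) <- "double"
  if (impute == "mean" && anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2L]]
  }
  x
}

#' Subset a genotype table
#'
#' @param geno a \code{genotype_table}.
#' @param individuals indices or identifiers of individuals to keep.
#' @param variants indices of variant columns to keep.
#' @return a \code{genotype_table}.
#' @export
subset_genotypes <- function(geno, individuals = NULL, variants = NULL) {
  if (is.null(individuals)) individuals <- seq_along(geno$individuals)
  if (is.character(individuals)) {
    individuals <- match(individuals, geno$individuals)
    if (anyNA(individuals)) stop("unknown individual identifier")
  }
  if (is.null(variants)) variants <- seq_along(geno$pos)
  genotype_table(
    calls = geno$calls[individuals, variants, drop = FALSE],
    chrom = geno$chrom[variants], pos = geno$pos[variants],
    depths = if (!is.null(geno$depths))
      geno$depths[individuals, variants, drop = FALSE],
    ref = geno$ref[variants], alt = geno$alt[variants],
    individuals = geno$individuals[individuals]
  )
}
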