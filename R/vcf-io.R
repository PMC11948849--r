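#' Write a genotype table to a VCF 4.2 file
#'
#' Emits GT and DP FORMAT fields; missing calls are written as \code{./.}.
#' The file round-trips losslessly through \code{\link{read_vcf}}.
#'
#' @param geno a \code{\link{genotype_table}}.
#' @param path output file path (plain text \code{.vcf}).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(geno, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ryepollen",
    sprintf("##contig=<ID=%s>", unique(geno$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$individuals), collapse = "\t")
  ), con)
  m <- length(geno$pos)
  if (m == 0L) return(invisible(path))
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(geno$calls), ncol = m)
  ok <- !is.na(geno$calls)
  gt[ok] <- gt_code[geno$calls[ok] + 1L]
  if (!is.null(geno$depths)) {
    dp <- ifelse(is.na(geno$depths), ".", as.character(geno$depths))
    gt <- matrix(paste(gt, dp, sep = ":"), nrow = nrow(gt))
  }
  lines <- vapply(seq_len(m), function(j) {
    paste(c(geno$chrom[j], geno$pos[j], sprintf("snp%d", j),
            geno$ref[j], geno$alt[j], ".", "PASS", ".",
            if (is.null(geno$depths)) "GT" else "GT:DP",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF file into a genotype table
#'
#' Parses via \pkg{vcfR}. Genotypes are converted to alternate-allele
#' dosages 0/1/2 (phased or unphased); records whose GT is not a diploid
#' biallelic-style call (e.g. \code{1/2}) are set missing at that call.
#'
#' @param path VCF file (plain or gzipped).
#' @return a \code{\link{genotype_table}}.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  m <- nrow(fix)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dp_raw <- if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  } else NULL
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  calls <- matrix(code(gt_raw), nrow = m)
  genotype_table(
    calls = t(calls),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    depths = if (!is.null(dp_raw)) {
      d <- t(matrix(as.integer(dp_raw), nrow = m))
      d
    },
    ref = fix[, "REF"], alt = fix[, "ALT"],
    individuals = colnames(v@gt)[-1]
  )
}
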