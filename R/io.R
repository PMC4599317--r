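# Readers and writers for the pipeline's on-disk formats. Matrices travel
# as TSV with samples as rows; interval files as BED (0-based half-open on
# disk, converted to the package's 1-based inclusive convention in memory);
# interactions as BEDPE.

#' Write a samples x features matrix as TSV
#'
#' @param x numeric matrix with sample ids as rownames.
#' @param path output file.
#' @param id_column name of the first (sample id) column.
#' @export
write_matrix_tsv <- function(x, path, id_column = "sample_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a samples x features TSV matrix
#'
#' @param path TSV written by [write_matrix_tsv()] (first column = ids).
#' @return numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write gene models as BED6
#'
#' Converts the in-memory 1-based inclusive spans to BED's 0-based
#' half-open convention.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `gene_id`,
#'   `strand` (and optional `score`).
#' @param path output file.
#' @export
write_bed6 <- function(genes, path) {
  score <- if ("score" %in% names(genes)) genes$score else 0
  write.table(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
               score, genes$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a BED6 file of gene models
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return data.frame with 1-based inclusive `start`/`end`, `gene_id`,
#'   `strand`.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             gene_id = gr$name,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a chromatin-state segmentation as BED4
#'
#' @param seg data.frame with `chrom`, `start`, `end`, `category`
#'   (1-based inclusive).
#' @param path output file.
#' @export
write_bed4 <- function(seg, path) {
  write.table(
    data.frame(seg$chrom, seg$start - 1L, seg$end, seg$category),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a BED4 segmentation (name column = state or category label)
#'
#' @param path BED4 file.
#' @return data.frame with 1-based inclusive intervals and `category`.
#' @export
read_bed4 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             category = gr$name, stringsAsFactors = FALSE)
}

#' Write interaction anchors as BEDPE
#'
#' @param anchors data.frame with `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2` (1-based inclusive) and optional `strength`.
#' @param path output file.
#' @export
write_bedpe <- function(anchors, path) {
  df <- data.frame(anchors$chrom1, anchors$start1 - 1L, anchors$end1,
                   anchors$chrom2, anchors$start2 - 1L, anchors$end2)
  if ("strength" %in% names(anchors)) {
    df$name <- "."
    df$score <- anchors$strength
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read interaction anchors from BEDPE
#'
#' Validates each record and reports the offending line on malformed
#' pairs (end <= start in the half-open convention).
#'
#' @param path BEDPE file (6 mandatory columns, optional name/score).
#' @return data.frame with 1-based inclusive anchors and `strength` (NA
#'   when absent).
#' @export
read_bedpe <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 6) stop("BEDPE needs at least 6 columns")
  names(raw)[1:6] <- c("chrom1", "start1", "end1",
                       "chrom2", "start2", "end2")
  bad <- which(raw$end1 <= raw$start1 | raw$end2 <= raw$start2)
  if (length(bad))
    stop("malformed BEDPE pair (end <= start) at line ", bad[1])
  data.frame(chrom1 = raw$chrom1, start1 = raw$start1 + 1L, end1 = raw$end1,
             chrom2 = raw$chrom2, start2 = raw$start2 + 1L, end2 = raw$end2,
             strength = if (ncol(raw) >= 8) as.numeric(raw[[8]]) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Read a genotype dosage matrix from TSV
#'
#' Rows are samples, columns SNPs, values risk-allele dosages 0/1/2 or NA.
#'
#' @param path TSV with a leading sample id column.
#' @return numeric matrix.
#' @export
read_genotype_tsv <- function(path) read_matrix_tsv(path)

#' Extract risk-allele dosages from a VCF
#'
#' Reads GT fields and counts copies of the declared risk allele per
#' sample, so dosages are oriented to the risk allele regardless of which
#' of REF/ALT it is.
#'
#' @param path VCF file.
#' @param risk_alleles named character vector, SNP id -> risk allele base.
#' @return numeric matrix samples x SNPs with NA for missing genotypes.
#' @export
read_genotypes_vcf <- function(path, risk_alleles) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF genotypes")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  ref <- vcfR::getREF(v); alt <- vcfR::getALT(v)
  out <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), ids))
  for (i in seq_along(ids)) {
    ra <- unname(risk_alleles[ids[i]])
    if (is.null(ra) || is.na(ra))
      stop("no risk allele declared for ", ids[i])
    alleles <- c(ref[i], strsplit(alt[i], ",")[[1]])
    risk_idx <- which(alleles == ra) - 1L
    if (length(risk_idx) == 0)
      stop("risk allele ", ra, " absent from VCF alleles for ", ids[i])
    g <- gt[i, ]
    split_g <- strsplit(g, "[/|]")
    out[, i] <- vapply(split_g, function(a) {
      if (any(is.na(a)) || any(a == ".")) return(NA_real_)
      sum(as.integer(a) == risk_idx)
    }, numeric(1))
  }
  out
}
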