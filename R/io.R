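# Readers/writers for the plain-text interchange formats the pipeline uses.
# FASTA goes through Biostrings; VCF reading (round-trips, report assembly)
# goes through VariantAnnotation; the two simple VCF record shapes we emit
# (bi-allelic SNVs with GT, sequence-resolved deletions) are written by a
# small emitter below.

#' Write / read a samples-by-amplicons mean-depth table
#'
#' The TSV has samples as rows and amplicon ids as columns (header), matching
#' the layout exported by per-region depth tools.
#'
#' @param dm a [DepthMatrix-class].
#' @param path output TSV path.
#' @export
writeDepthTsv <- function(dm, path) {
  d <- t(SummarizedExperiment::assay(dm, "depth"))
  df <- data.frame(sample = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDepthTsv
#' @param panel amplicon panel `GRanges` (with `amplicon_id`, `exon`) giving
#'   the coordinates for the amplicons named in the TSV header.
#' @return `readDepthTsv` returns a [DepthMatrix-class].
#' @export
readDepthTsv <- function(path, panel) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$sample
  DepthMatrix(m[match(panel$amplicon_id, rownames(m)), , drop = FALSE], panel)
}

#' Write an amplicon panel as BED
#'
#' BED is 0-based half-open; closed 1-based amplicon coordinates are shifted
#' accordingly. Column 4 is the amplicon id, column 5 the exon label.
#' @param panel amplicon panel `GRanges`.
#' @param path output path.
#' @export
writeBedPanel <- function(panel, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(panel)),
                   GenomicRanges::start(panel) - 1L, GenomicRanges::end(panel),
                   panel$amplicon_id, panel$exon)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeBedPanel
#' @export
readBedPanel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE)
  gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  gr$amplicon_id <- df[[4]]
  gr$exon <- df[[5]]
  gr
}

#' Write / read a pedigree in PED format
#'
#' Six whitespace-separated columns: family, individual, father, mother, sex,
#' phenotype (`0` = missing parent).
#' @param ped data.frame with columns `fam,id,father,mother,sex,phenotype`.
#' @param path file path.
#' @export
writePed <- function(ped, path) {
  utils::write.table(ped[, c("fam", "id", "father", "mother", "sex", "phenotype")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writePed
#' @export
readPed <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("fam", "id", "father", "mother",
                                        "sex", "phenotype"),
                          colClasses = "character")
  df$sex <- as.integer(df$sex); df$phenotype <- as.integer(df$phenotype)
  df
}

# Minimal VCF 4.2 emitter for bi-allelic substitution records with per-sample
# GT. `variants`: data.frame(chrom, pos, id, ref, alt); `gt`: character matrix
# variants x samples of "0/0"-style genotypes.
writeSnvVcf <- function(variants, gt, path) {
  stopifnot(nrow(variants) == nrow(gt))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(variants$chrom), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], format(variants$pos[i], scientific = FALSE),
            variants$id[i], variants$ref[i], variants$alt[i], ".", "PASS",
            ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
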