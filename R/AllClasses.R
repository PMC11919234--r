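#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits
NULL

#' Transcript model anchored on genomic exon coordinates
#'
#' A minimal transcript model: an ordered set of genomic exons (1-based, fully
#' closed, listed 5'\eqn{\to}3' in transcription order), a strand, and the CDS
#' span in cDNA coordinates. It anchors HGVS-style c./g. coordinate mapping
#' (including intronic offsets such as c.304+941) and exon-overlap queries used
#' by the CNV caller.
#'
#' @slot transcriptId single string, e.g. an RefSeq-style accession.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [GenomicRanges::GRanges] of exons in transcription order
#'   (genomic coordinates ascend on `+`, descend on `-`).
#' @slot cdsStart,cdsEnd CDS boundaries in cDNA coordinates; the CDS length
#'   must be a multiple of 3.
#'
#' @seealso [loadTranscript()], [cToG()], [gToC()], [exonsOverlapped()]
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    chrom = "character",
    strand = "character",
    exons = "GRanges",
    cdsStart = "numeric",
    cdsEnd = "numeric"
  )
)

setValidity("TranscriptModel", function(object) {
  msgs <- character()
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L) msgs <- c(msgs, "model has no exons")
  s <- GenomicRanges::start(ex)
  e <- GenomicRanges::end(ex)
  if (any(e < s)) msgs <- c(msgs, "exon end < start")
  if (length(ex) > 1L) {
    # transcription order: strictly separated, ascending (+) / descending (-)
    if (object@strand == "+") {
      if (any(s[-1] <= e[-length(ex)]))
        msgs <- c(msgs, "exons overlap or are unsorted 5'->3' (+ strand)")
    } else {
      if (any(e[-1] >= s[-length(ex)]))
        msgs <- c(msgs, "exons overlap or are unsorted 5'->3' (- strand)")
    }
  }
  len <- sum(GenomicRanges::width(ex))
  if (object@cdsStart < 1 || object@cdsEnd > len || object@cdsEnd < object@cdsStart)
    msgs <- c(msgs, "CDS boundaries outside the cDNA")
  if ((object@cdsEnd - object@cdsStart + 1) %% 3 != 0)
    msgs <- c(msgs, "CDS length not divisible by 3")
  if (length(msgs)) msgs else TRUE
})

#' A genomic interval with an explicit length convention
#'
#' Published deletion coordinates mix two conventions: some pairs are the
#' first/last deleted base (closed; length = end - start + 1), others flank the
#' breakpoints (breakpoint-exclusive; length = end - start). The convention is
#' carried as a tag so both lengths stay representable.
#'
#' @slot chrom chromosome name.
#' @slot start,end 1-based positions, `start <= end`.
#' @slot convention `"closed"` or `"breakpoint-exclusive"`.
#'
#' @seealso [genomicInterval()], [intervalLength()]
#' @export
setClass("GenomicInterval",
  representation(chrom = "character", start = "numeric", end = "numeric",
                 convention = "character")
)

setValidity("GenomicInterval", function(object) {
  msgs <- character()
  if (!object@convention %in% c("closed", "breakpoint-exclusive"))
    msgs <- c(msgs, "convention must be 'closed' or 'breakpoint-exclusive'")
  if (object@end < object@start) msgs <- c(msgs, "end < start")
  if (length(msgs)) msgs else TRUE
})

#' HGVS-style cDNA position with intronic offset
#'
#' `exonicBase` is the cDNA (c.) coordinate; `intronOffset` 0 means exonic,
#' positive means downstream of a donor (c.N+M), negative upstream of an
#' acceptor (c.N-M).
#'
#' @slot exonicBase integer cDNA coordinate.
#' @slot intronOffset signed integer offset into the flanking intron.
#' @seealso [cPosition()], [parseCPosition()], [cToG()]
#' @export
setClass("CPosition",
  representation(exonicBase = "numeric", intronOffset = "numeric"))

#' Samples-by-amplicons mean-depth container
#'
#' Wraps a [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' panel amplicons (a `GRanges` with `amplicon_id` and `exon` metadata) and
#' whose columns are samples; the single assay `"depth"` holds the mean
#' sequencing depth of each amplified region in each sample.
#'
#' @seealso [DepthMatrix()], [normalizeDepth()], [depthRatios()]
#' @export
setClass("DepthMatrix", contains = "RangedSummarizedExperiment")

#' An exonized intronic segment (pseudoexon)
#'
#' Describes an intronic segment spliced into the mRNA as a novel exon after a
#' splice-site-creating variant: the acceptor/donor genomic positions (closed;
#' acceptor is the first and donor the last included base on the + strand), the
#' host intron index, and optionally the included sequence.
#'
#' @slot intron index of the host intron (between exons `intron` and
#'   `intron + 1`).
#' @slot acceptor,donor genomic positions of the first/last included base.
#' @slot sequence included sequence (may be empty; when set its length must
#'   equal `donor - acceptor + 1`).
#' @seealso [pseudoexonEvent()], [applyPseudoexon()], [frameConsequence()]
#' @export
setClass("PseudoexonEvent",
  representation(intron = "numeric", acceptor = "numeric", donor = "numeric",
                 sequence = "character"))

setValidity("PseudoexonEvent", function(object) {
  msgs <- character()
  if (object@donor < object@acceptor) msgs <- c(msgs, "donor < acceptor")
  len <- object@donor - object@acceptor + 1
  if (nzchar(object@sequence) && nchar(object@sequence) != len)
    msgs <- c(msgs, "sequence length disagrees with acceptor/donor span")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel", object@transcriptId, "\n")
  cat(" ", length(object@exons), "exons on", object@chrom,
      paste0("(", object@strand, ")"), "| cDNA",
      sum(GenomicRanges::width(object@exons)), "bp | CDS c.",
      object@cdsStart, "-", object@cdsEnd, "\n", sep = " ")
})

setMethod("show", "GenomicInterval", function(object) {
  cat(sprintf("%s:%d-%d [%s, %d bp]\n", object@chrom, object@start,
              object@end, object@convention, intervalLength(object)))
})

setMethod("show", "PseudoexonEvent", function(object) {
  cat(sprintf("PseudoexonEvent: intron %d, %d-%d (%d bp)%s\n",
              object@intron, object@acceptor, object@donor,
              object@donor - object@acceptor + 1,
              if (nzchar(object@sequence)) ", sequence attached" else ""))
})
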