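#' Construct a TranscriptModel
#'
#' Exons are given in transcription order as parallel vectors of genomic start
#' and end (1-based, fully closed). On the minus strand, transcription order
#' means descending genomic coordinates.
#'
#' @param transcriptId transcript accession string.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exonStart,exonEnd integer vectors of exon boundaries.
#' @param cdsStart,cdsEnd CDS boundaries in cDNA coordinates. Defaults to a
#'   CDS covering the cDNA trimmed to a multiple of 3.
#' @return a [TranscriptModel-class] object.
#' @examples
#' toy <- TranscriptModel("TOY1", "chr1", "+", c(100, 300), c(199, 399))
#' cdnaLength(toy)
#' @export
TranscriptModel <- function(transcriptId, chrom, strand, exonStart, exonEnd,
                            cdsStart = 1L, cdsEnd = NULL) {
  stopifnot(length(exonStart) == length(exonEnd))
  ex <- GenomicRanges::GRanges(chrom, IRanges::IRanges(exonStart, exonEnd),
                               strand = strand)
  len <- sum(GenomicRanges::width(ex))
  if (is.null(cdsEnd)) cdsEnd <- len - (len - cdsStart + 1) %% 3
  new("TranscriptModel", transcriptId = as.character(transcriptId),
      chrom = as.character(chrom), strand = strand, exons = ex,
      cdsStart = as.numeric(cdsStart), cdsEnd = as.numeric(cdsEnd))
}

#' @describeIn TranscriptModel total cDNA length (sum of exon widths).
#' @param model a `TranscriptModel`.
#' @export
cdnaLength <- function(model) sum(GenomicRanges::width(model@exons))

#' @describeIn TranscriptModel exon `GRanges` in transcription order.
#' @export
exonRanges <- function(model) model@exons

# cDNA coordinates of each exon's first/last base (transcription order).
cumBoundaries <- function(model) {
  w <- GenomicRanges::width(model@exons)
  ce <- cumsum(w)
  list(start = ce - w + 1, end = ce)
}

# Length of the intron following exon k in transcription order.
intronLength <- function(model, k) {
  s <- GenomicRanges::start(model@exons)
  e <- GenomicRanges::end(model@exons)
  if (k < 1 || k >= length(model@exons)) stop("no intron after exon ", k)
  if (model@strand == "+") s[k + 1] - e[k] - 1 else s[k] - e[k + 1] - 1
}

#' Load a transcript model from GFF3, JSON, or the packaged fixture
#'
#' `"slc26a4_fixture"` names the packaged synthetic SLC26A4-like model (21
#' exons on the + strand of chr7, exon 3 ending at c.304, with the published
#' deletion windows covering exons 1-3, 5-6 and 9-10). A user-supplied GFF3
#' (exon and optional CDS features of one transcript) or a JSON file in the
#' fixture's format overrides it.
#'
#' @param x path to a `.gff3`/`.gff` or `.json` file, or the tag
#'   `"slc26a4_fixture"`.
#' @return a [TranscriptModel-class].
#' @examples
#' m <- loadTranscript("slc26a4_fixture")
#' length(exonRanges(m))
#' @export
loadTranscript <- function(x) {
  if (identical(x, "slc26a4_fixture")) {
    return(modelFromJson(system.file("extdata", "slc26a4_model_synthetic.json",
                                     package = "EVAdx", mustWork = TRUE)))
  }
  if (!file.exists(x)) stop("no such file or fixture tag: ", x)
  if (grepl("\\.json$", x, ignore.case = TRUE)) return(modelFromJson(x))
  modelFromGff3(x)
}

modelFromJson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  TranscriptModel(j$transcript_id, j$chrom, j$strand, j$exon_start, j$exon_end,
                  j$cds_start, j$cds_end)
}

modelFromGff3 <- function(path) {
  # Light structural pre-scan so malformed input fails with the line number.
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8))
    stop("GFF3 parse error at line ", body[which(nf < 8)[1]],
         ": expected >= 8 tab-separated fields")
  g <- rtracklayer::import(path, format = "gff3")
  ex <- g[tolower(as.character(g$type)) == "exon"]
  if (length(ex) == 0L) stop("GFF3 contains no exon features")
  strand <- as.character(GenomicRanges::strand(ex)[1])
  if (!strand %in% c("+", "-")) strand <- "+"
  ord <- order(GenomicRanges::start(ex), decreasing = (strand == "-"))
  ex <- ex[ord]
  id <- if (!is.null(ex$transcript_id)) ex$transcript_id[1]
        else if (!is.null(ex$Parent) && length(ex$Parent[[1]])) as.character(ex$Parent[[1]][1])
        else if (!is.null(ex$ID)) as.character(ex$ID[1]) else "transcript"
  model <- TranscriptModel(id, as.character(GenomicRanges::seqnames(ex))[1],
                           strand, GenomicRanges::start(ex), GenomicRanges::end(ex))
  cds <- g[tolower(as.character(g$type)) == "cds"]
  if (length(cds)) {
    b1 <- gToC(model, if (strand == "+") min(GenomicRanges::start(cds))
                      else max(GenomicRanges::end(cds)))
    b2 <- gToC(model, if (strand == "+") max(GenomicRanges::end(cds))
                      else min(GenomicRanges::start(cds)))
    model@cdsStart <- b1@exonicBase
    model@cdsEnd <- b2@exonicBase
    methods::validObject(model)
  }
  model
}

#' Construct a GenomicInterval
#'
#' @param chrom chromosome name.
#' @param start,end 1-based positions.
#' @param convention `"closed"` (start/end are the first/last base of the
#'   segment) or `"breakpoint-exclusive"` (start/end flank the segment).
#' @return a [GenomicInterval-class].
#' @examples
#' intervalLength(genomicInterval("chr7", 107300016, 107307681))  # 7666
#' @export
genomicInterval <- function(chrom, start, end,
                            convention = c("closed", "breakpoint-exclusive")) {
  convention <- match.arg(convention)
  new("GenomicInterval", chrom = as.character(chrom), start = as.numeric(start),
      end = as.numeric(end), convention = convention)
}

#' Parse a "chrN:start-end" region string into a GenomicInterval
#'
#' Commas in positions are tolerated (published tables print them).
#' @param x region string such as `"chr7:107,300,698-107,303,849"`.
#' @inheritParams genomicInterval
#' @export
parseRegion <- function(x, convention = "closed") {
  x <- gsub(",", "", x)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)[-–]([0-9]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse region string: ", x)
  genomicInterval(m[2], as.numeric(m[3]), as.numeric(m[4]), convention)
}

#' Length of a genomic interval under its convention
#'
#' Closed intervals span `end - start + 1` bases; breakpoint-exclusive pairs
#' (coordinates flanking the lost segment) give `end - start`.
#'
#' @param iv a [GenomicInterval-class].
#' @return length in bp.
#' @export
intervalLength <- function(iv) {
  stopifnot(methods::is(iv, "GenomicInterval"))
  if (iv@convention == "closed") iv@end - iv@start + 1 else iv@end - iv@start
}

#' Construct / parse an HGVS-style cDNA position
#'
#' @param exonicBase integer cDNA coordinate.
#' @param intronOffset signed intronic offset (0 = exonic).
#' @return a [CPosition-class].
#' @examples
#' parseCPosition("c.304+941")
#' @export
cPosition <- function(exonicBase, intronOffset = 0) {
  new("CPosition", exonicBase = as.numeric(exonicBase),
      intronOffset = as.numeric(intronOffset))
}

#' @rdname cPosition
#' @param x string such as `"c.304+941"`, `"304+941"`, `"c.919-2"` or `"c.946"`;
#'   a trailing substitution (`C>T`) is ignored.
#' @export
parseCPosition <- function(x) {
  x <- sub("^c\\.", "", x)
  m <- regmatches(x, regexec("^([0-9]+)([+-][0-9]+)?", x))[[1]]
  if (length(m) < 2 || !nzchar(m[2])) stop("cannot parse cDNA position: ", x)
  cPosition(as.numeric(m[2]), if (nzchar(m[3])) as.numeric(m[3]) else 0)
}

#' Map a cDNA position (with optional intronic offset) to a genomic position
#'
#' Positive offsets hang off an exon's 3' (donor) boundary, negative offsets
#' off an exon's 5' (acceptor) boundary; the offset must fit inside the
#' flanking intron.
#'
#' @param model a [TranscriptModel-class].
#' @param pos a [CPosition-class] (or string accepted by [parseCPosition()]).
#' @return genomic position (numeric scalar).
#' @examples
#' m <- loadTranscript("slc26a4_fixture")
#' cToG(m, "c.304+941")
#' @export
cToG <- function(model, pos) {
  if (is.character(pos)) pos <- parseCPosition(pos)
  e <- pos@exonicBase; d <- pos@intronOffset
  cb <- cumBoundaries(model)
  if (e < 1 || e > cdnaLength(model)) stop("cDNA position ", e, " outside transcript")
  k <- which(e >= cb$start & e <= cb$end)
  s <- GenomicRanges::start(model@exons); ge <- GenomicRanges::end(model@exons)
  plus <- model@strand == "+"
  if (d == 0) {
    return(if (plus) s[k] + (e - cb$start[k]) else ge[k] - (e - cb$start[k]))
  }
  if (d > 0) {
    if (e != cb$end[k]) stop("positive intronic offset from non-boundary base c.", e)
    if (k >= length(model@exons)) stop("no intron after the terminal exon")
    if (d > intronLength(model, k))
      stop("offset +", d, " exceeds intron ", k, " length ", intronLength(model, k))
    if (plus) ge[k] + d else s[k] - d
  } else {
    if (e != cb$start[k]) stop("negative intronic offset from non-boundary base c.", e)
    if (k <= 1) stop("no intron before the first exon")
    if (-d > intronLength(model, k - 1))
      stop("offset ", d, " exceeds intron ", k - 1, " length ", intronLength(model, k - 1))
    if (plus) s[k] + d else ge[k] - d
  }
}

#' Map a genomic position to a cDNA position
#'
#' Exonic positions map to plain c. coordinates. Intronic positions map to the
#' nearer exon boundary with a signed offset (ties go to the upstream donor,
#' following the usual HGVS midpoint split).
#'
#' @inheritParams cToG
#' @param g genomic position.
#' @return a [CPosition-class].
#' @export
gToC <- function(model, g) {
  s <- GenomicRanges::start(model@exons); ge <- GenomicRanges::end(model@exons)
  cb <- cumBoundaries(model)
  plus <- model@strand == "+"
  k <- which(g >= s & g <= ge)
  if (length(k) == 1) {
    return(cPosition(if (plus) cb$start[k] + (g - s[k]) else cb$start[k] + (ge[k] - g)))
  }
  n <- length(model@exons)
  for (k in seq_len(n - 1)) {
    inIntron <- if (plus) g > ge[k] && g < s[k + 1] else g < s[k] && g > ge[k + 1]
    if (inIntron) {
      dDon <- if (plus) g - ge[k] else s[k] - g
      dAcc <- if (plus) s[k + 1] - g else g - ge[k + 1]
      return(if (dDon <= dAcc) cPosition(cb$end[k], dDon)
             else cPosition(cb$start[k + 1], -dAcc))
    }
  }
  stop("genomic position ", g, " outside the transcript span")
}

#' Exons overlapped by a genomic interval
#'
#' Returns the (contiguous) run of exons intersecting the interval, with each
#' endpoint flagged full (exon entirely inside the interval) or partial. An
#' interval overlapping no exon returns a zero-row result, not an error.
#'
#' @inheritParams cToG
#' @param iv a [GenomicInterval-class] (its closed span is used for overlap).
#' @return `data.frame(exon, full)` in exon-number order.
#' @examples
#' m <- loadTranscript("slc26a4_fixture")
#' exonsOverlapped(m, genomicInterval("chr7", 107314217, 107316062))
#' @export
exonsOverlapped <- function(model, iv) {
  stopifnot(methods::is(iv, "GenomicInterval"))
  if (iv@chrom != model@chrom)
    return(data.frame(exon = integer(), full = logical()))
  s <- GenomicRanges::start(model@exons); e <- GenomicRanges::end(model@exons)
  hit <- which(e >= iv@start & s <= iv@end)
  if (length(hit) == 0) return(data.frame(exon = integer(), full = logical()))
  if (!all(diff(sort(hit)) == 1)) stop("overlapped exons are not contiguous")
  hit <- sort(hit)
  data.frame(exon = hit, full = s[hit] >= iv@start & e[hit] <= iv@end)
}
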