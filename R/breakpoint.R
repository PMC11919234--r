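# Deletion breakpoint resolution from long reads: the computational
# counterpart of long-distance PCR + Sanger/SMRT validation. A read spanning a
# deletion junction decomposes into two colinear reference segments; the
# deleted interval is placed at its leftmost equivalent position across any
# microhomology tract (VCF normalisation practice).

#' Locate a deletion junction in a single long read
#'
#' Anchors the read prefix and suffix in the reference with exact k-mer seeds
#' (`k = minAnchor`; several seed windows are tried so occasional substitution
#' errors do not unseat the anchor), derives the two diagonal offsets, and --
#' when the suffix offset exceeds the prefix offset -- picks the split point
#' maximising reference agreement on both sides. The maximiser is a plateau
#' across any microhomology; the lowest-coordinate (left-aligned) placement is
#' reported with the tract length.
#'
#' @param read,reference [Biostrings::DNAString] or character.
#' @param minAnchor minimum anchor/seed length in bp (default 30).
#' @param maxSeedWindows how many successive seed windows to try per end.
#' @param verbose message the reason when no candidate is returned.
#' @return `NULL` for fully matching or unanchorable reads, otherwise a
#'   one-row data.frame: `read_gap_start`/`read_gap_end` flanking read
#'   positions, `del_start`, `del_end` (closed deleted reference interval),
#'   `del_length`, `microhomology`.
#' @export
findGap <- function(read, reference, minAnchor = 30, maxSeedWindows = 20,
                    verbose = FALSE) {
  none <- function(reason) {
    if (verbose) message("findGap: ", reason)
    NULL
  }
  read <- as.character(read); reference <- as.character(reference)
  if (!nchar(read) || !nchar(reference)) stop("empty read or reference")
  n <- nchar(read)
  if (n < 2 * minAnchor) return(none("read shorter than two anchors"))
  refSS <- Biostrings::DNAString(reference)
  o1 <- seedOffset(read, refSS, minAnchor, maxSeedWindows, fromEnd = FALSE)
  if (is.null(o1)) return(none("no unique prefix anchor"))
  o2 <- seedOffset(read, refSS, minAnchor, maxSeedWindows, fromEnd = TRUE)
  if (is.null(o2)) return(none("no unique suffix anchor"))
  if (o2 == o1) return(none("read matches the reference contiguously"))
  if (o2 < o1) return(none("offsets imply an insertion, not a deletion"))
  rb <- strsplit(read, "")[[1]]
  refb <- strsplit(reference, "")[[1]]
  idx1 <- seq_len(n) + o1
  idx2 <- seq_len(n) + o2
  m1 <- idx1 >= 1 & idx1 <= length(refb) & rb == refb[pmin(pmax(idx1, 1), length(refb))]
  m2 <- idx2 >= 1 & idx2 <= length(refb) & rb == refb[pmin(pmax(idx2, 1), length(refb))]
  # split after read position j: prefix matches on diagonal o1, suffix on o2
  score <- cumsum(m1) + sum(m2) - cumsum(m2)
  jRange <- minAnchor:(n - minAnchor)
  best <- max(score[jRange])
  plateau <- jRange[score[jRange] == best]
  j <- min(plateau)                              # left-aligned placement
  data.frame(read_gap_start = j, read_gap_end = j + 1,
             del_start = j + o1 + 1, del_end = j + o2,
             del_length = o2 - o1,
             microhomology = max(plateau) - min(plateau))
}

# Offset (ref position - read position) of a unique exact seed near one end
# of the read; NULL when no window yields a unique hit.
seedOffset <- function(read, refSS, k, windows, fromEnd) {
  n <- nchar(read)
  for (w in seq_len(windows)) {
    s <- if (!fromEnd) (w - 1) * k + 1 else n - w * k + 1
    if (s < 1 || s + k - 1 > n) break
    kmer <- substr(read, s, s + k - 1)
    hits <- Biostrings::matchPattern(kmer, refSS)
    if (length(hits) == 1) return(BiocGenerics::start(hits)[1] - s)
    if (length(hits) > 1) next
  }
  NULL
}

#' Consensus deletion call from per-read candidates
#'
#' The modal left-aligned interval wins; ties between modes are an error (no
#' silent choice). Discordant reads are reported alongside. Because published
#' coordinate pairs mix conventions, both are emitted: `pair_closed` is the
#' first/last deleted base (closed; length = end - start + 1), and
#' `pair_exclusive` is the last retained base before the gap with the last
#' deleted base (its end - start equals the same physical length).
#'
#' @param candidates data.frame of [findGap()] rows (rbind of candidates).
#' @return list: `del_start`, `del_end`, `length` (deleted bases),
#'   `pair_closed`, `pair_exclusive` (2-vectors), `support`, `discordant`
#'   (data.frame of non-modal candidates).
#' @export
consensusDeletion <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0)
    stop("no breakpoint candidates")
  key <- paste(candidates$del_start, candidates$del_end)
  tab <- sort(table(key), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) {
    ties <- names(tab)[tab == tab[1]]
    stop("tie between candidate intervals: ", paste(ties, collapse = " vs "))
  }
  win <- names(tab)[1]
  parts <- as.numeric(strsplit(win, " ")[[1]])
  list(del_start = parts[1], del_end = parts[2],
       length = parts[2] - parts[1] + 1,
       pair_closed = c(parts[1], parts[2]),
       pair_exclusive = c(parts[1] - 1, parts[2]),
       support = unname(tab[1]),
       discordant = candidates[key != win, , drop = FALSE])
}

#' Render a consensus deletion as a VCF 4.2 record
#'
#' Sequence-resolved style: POS is the base before the deletion, REF is that
#' base plus the deleted sequence, ALT is the anchor base, with
#' `SVTYPE=DEL`, `END` and `SVLEN` in INFO. A deletion starting at the first
#' reference base falls back to a symbolic `<DEL>` allele.
#'
#' @param call a [consensusDeletion()] result.
#' @param reference the reference sequence the call's coordinates refer to.
#' @param chrom chromosome name for the record.
#' @param path optional path; when given a single-record VCF is written.
#' @return one-row data.frame of VCF fields (invisibly writes `path`).
#' @export
deletionToVcf <- function(call, reference, chrom = "chr7", path = NULL) {
  reference <- as.character(reference)
  len <- call$length
  if (call$del_start <= 1) {
    rec <- data.frame(chrom = chrom, pos = call$del_start, id = ".",
                      ref = substr(reference, call$del_start, call$del_start),
                      alt = "<DEL>",
                      info = sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d",
                                     call$del_end, len))
  } else {
    p <- call$del_start - 1
    rec <- data.frame(chrom = chrom, pos = p, id = ".",
                      ref = substr(reference, p, call$del_end),
                      alt = substr(reference, p, p),
                      info = sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d",
                                     call$del_end, len))
  }
  if (!is.null(path)) {
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", chrom, ">"),
             "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
             "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
             "##ALT=<ID=DEL,Description=\"Deletion\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"))
    body <- paste(rec$chrom, format(rec$pos, scientific = FALSE), rec$id,
                  rec$ref, rec$alt, ".", "PASS", rec$info, sep = "\t")
    writeLines(c(hdr, body), path)
  }
  rec
}

#' Resolve a deletion from a read set
#'
#' Runs [findGap()] over every read and [consensusDeletion()] over the
#' resulting candidates.
#'
#' @param reads [Biostrings::DNAStringSet] (or character vector).
#' @param reference reference sequence.
#' @param ... passed to [findGap()].
#' @return a [consensusDeletion()] result with an extra `candidates` element.
#' @export
resolveBreakpoints <- function(reads, reference, ...) {
  reads <- as.character(reads)
  cands <- lapply(reads, findGap, reference = reference, ...)
  keep <- !vapply(cands, is.null, logical(1))
  if (!any(keep)) stop("no read yielded a breakpoint candidate")
  cand <- do.call(rbind, Map(function(x, id) cbind(read = id, x),
                             cands[keep], names(reads)[keep]))
  out <- consensusDeletion(cand)
  out$candidates <- cand
  out
}
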