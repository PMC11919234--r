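#' Construct a DepthMatrix
#'
#' @param depth numeric matrix, amplicons (rows) by samples (columns); row
#'   names must match `panel$amplicon_id` when set.
#' @param panel amplicon panel `GRanges` (with `amplicon_id`, `exon`).
#' @return a [DepthMatrix-class].
#' @export
DepthMatrix <- function(depth, panel) {
  stopifnot(nrow(depth) == length(panel), all(depth >= 0, na.rm = TRUE))
  if (is.null(rownames(depth))) rownames(depth) <- panel$amplicon_id
  stopifnot(identical(rownames(depth), panel$amplicon_id))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(depth = depth), rowRanges = panel)
  new("DepthMatrix", se)
}

#' @describeIn DepthMatrix per-sample total sequenced bases
#'   (\eqn{\sum_a depth \times length}).
#' @param dm a `DepthMatrix`.
#' @export
sampleTotals <- function(dm) {
  colSums(SummarizedExperiment::assay(dm, "depth") *
            GenomicRanges::width(SummarizedExperiment::rowRanges(dm)))
}

#' Normalise depths to a fixed per-sample data amount
#'
#' Scales each sample's depths so its total data amount (mean depth times
#' amplicon length, summed over amplicons) equals `targetTotal` -- the
#' "assume 10 Mbp of data per sample" normalisation that makes depths
#' comparable across samples regardless of sequencing throughput.
#'
#' @param dm a [DepthMatrix-class].
#' @param targetTotal target total bases per sample (default 1e7).
#' @return a [DepthMatrix-class] with rescaled depths.
#' @export
normalizeDepth <- function(dm, targetTotal = 1e7) {
  tot <- sampleTotals(dm)
  if (any(tot <= 0))
    stop("sample(s) with zero total depth: ",
         paste(colnames(dm)[tot <= 0], collapse = ", "))
  d <- sweep(SummarizedExperiment::assay(dm, "depth"), 2, targetTotal / tot, "*")
  DepthMatrix(d, SummarizedExperiment::rowRanges(dm))
}

#' Cross-sample per-amplicon depth ratios and robust z-scores
#'
#' Each normalised depth is divided by a per-amplicon reference (the cohort
#' median by default, or a supplied vector) so unequal amplification shows up
#' as a ratio departing from 1; the z-score measures that departure against
#' the robust cross-sample spread (1.4826 x MAD) of the amplicon's ratios.
#' Amplicons with a zero reference are masked (`NA`) and listed in the
#' `masked` element rather than silently dropped.
#'
#' @param dm a normalised [DepthMatrix-class].
#' @param reference `"cohort_median"` (requires >= 3 samples) or a numeric
#'   vector of per-amplicon reference depths.
#' @param diploidBand ratio band treated as apparently diploid when
#'   estimating the per-amplicon spread. Copy-number carriers sit far from 1
#'   and would inflate a spread taken over all samples (several samples can
#'   share one founder deletion), so the robust SD is the 1.4826 x MAD of the
#'   in-band samples; the full-cohort MAD is the fallback when fewer than 3
#'   samples fall in the band.
#' @return list with matrices `ratio` and `z` (amplicons x samples), the
#'   `reference` vector used, and `masked` amplicon ids.
#' @export
depthRatios <- function(dm, reference = "cohort_median",
                        diploidBand = c(0.7, 1.3)) {
  d <- SummarizedExperiment::assay(dm, "depth")
  if (is.character(reference) && identical(reference, "cohort_median")) {
    if (ncol(d) < 3)
      stop("cohort_median reference needs at least 3 samples")
    ref <- apply(d, 1, stats::median)
  } else {
    ref <- as.numeric(reference)
    stopifnot(length(ref) == nrow(d))
  }
  masked <- ref == 0
  ratio <- d / ifelse(masked, NA, ref)
  # median-of-ratios recentring per sample: a sample carrying a multi-exon
  # deletion has its remaining amplicons inflated by the fixed-total
  # normalisation; dividing by the sample's median ratio (driven by its
  # diploid majority) removes that baseline shift
  centre <- apply(ratio, 2, stats::median, na.rm = TRUE)
  ratio <- sweep(ratio, 2, ifelse(centre > 0, centre, 1), "/")
  med <- numeric(nrow(ratio)); s <- numeric(nrow(ratio))
  for (a in seq_len(nrow(ratio))) {
    r <- ratio[a, ]
    inBand <- r[!is.na(r) & r >= diploidBand[1] & r < diploidBand[2]]
    pool <- if (length(inBand) >= 3) inBand else r[!is.na(r)]
    med[a] <- stats::median(pool)
    s[a] <- stats::mad(pool)                  # 1.4826 * MAD
  }
  z <- (ratio - med) / ifelse(s == 0, NA, s)
  z[s == 0 & !is.na(ratio) & ratio == med] <- 0
  z[is.na(z) & !is.na(ratio)] <- ifelse(
    (ratio - med)[is.na(z) & !is.na(ratio)] > 0, Inf, -Inf)
  list(ratio = ratio, z = z, reference = ref,
       masked = rownames(d)[masked])
}

#' Call per-amplicon copy-number states from ratios
#'
#' Ratio bands map to states (CN0 below `thresholds[1]`, CN1 up to
#' `thresholds[2]`, CN2 up to `thresholds[3]`, CN3+ above); a non-diploid band
#' additionally requires `|z| >= minZ`, otherwise the amplicon is kept at CN2
#' and flagged suspect.
#'
#' @param rz result of [depthRatios()].
#' @param thresholds strictly increasing ratio cut-points
#'   `c(CN0 = 0.2, CN1 = 0.7, CN3 = 1.3)`.
#' @param minZ robust z magnitude required to leave CN2.
#' @return list of matrices `state` (`"CN0"/"CN1"/"CN2"/"CN3+"`, `NA` for
#'   masked amplicons), `rawState` (the ratio band before the z gate) and
#'   logical `suspect` (non-diploid band downgraded for weak z).
#' @export
callStates <- function(rz, thresholds = c(CN0 = 0.2, CN1 = 0.7, CN3 = 1.3),
                       minZ = 3) {
  stopifnot(all(diff(thresholds) > 0))
  r <- rz$ratio; z <- rz$z
  state <- matrix(NA_character_, nrow(r), ncol(r), dimnames = dimnames(r))
  ok <- !is.na(r)
  band <- findInterval(r[ok], thresholds)     # 0..3
  state[ok] <- c("CN0", "CN1", "CN2", "CN3+")[band + 1]
  rawState <- state
  suspect <- matrix(FALSE, nrow(r), ncol(r), dimnames = dimnames(r))
  weak <- ok & state != "CN2" & abs(z) < minZ
  suspect[weak] <- TRUE
  state[weak] <- "CN2"
  list(state = state, rawState = rawState, suspect = suspect)
}

#' Merge per-amplicon states into exon-range CNV calls
#'
#' Maximal runs of panel-adjacent amplicons sharing a non-diploid state become
#' one call spanning the run; the exon range comes from [exonsOverlapped()] on
#' the spanned interval. Single-amplicon calls are flagged low-confidence
#' rather than suppressed. Before segmenting, a suspect amplicon (ratio band
#' non-diploid but z below the gate) is rescued into its neighbours' state
#' when an adjacent amplicon of the same sample carries the same state
#' confidently -- a mid-run z blip must not split a multi-amplicon deletion --
#' while isolated suspects still call nothing.
#'
#' @param st result of [callStates()].
#' @param rz result of [depthRatios()] (supplies mean ratio / z per call).
#' @param panel amplicon panel `GRanges` in panel order.
#' @param model the [TranscriptModel-class] for exon labelling.
#' @return `GRanges` of calls with metadata `sample`, `state`, `exonFrom`,
#'   `exonTo`, `meanRatio`, `meanZ`, `nAmplicons`, `lowConfidence`,
#'   `inheritance` (initialised `"unknown"`).
#' @export
segmentCalls <- function(st, rz, panel, model) {
  calls <- list()
  for (smp in colnames(st$state)) {
    s <- st$state[, smp]
    raw <- st$rawState[, smp]
    susp <- st$suspect[, smp]
    repeat {                                  # rescue band-consistent suspects
      fix <- which(susp & s == "CN2" &
                     (c(s[-1], "CN2") == raw | c("CN2", s[-length(s)]) == raw))
      if (!length(fix)) break
      s[fix] <- raw[fix]
      susp[fix] <- FALSE
    }
    s[is.na(s)] <- "CN2"                     # masked amplicons break no runs
    r <- rle(s)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in which(r$values != "CN2")) {
      idx <- starts[i]:ends[i]
      iv <- genomicInterval(model@chrom,
                            min(GenomicRanges::start(panel[idx])),
                            max(GenomicRanges::end(panel[idx])))
      exr <- exonsOverlapped(model, iv)
      gr <- GenomicRanges::GRanges(model@chrom,
                                   IRanges::IRanges(iv@start, iv@end))
      gr$sample <- smp
      gr$state <- r$values[i]
      gr$exonFrom <- if (nrow(exr)) min(exr$exon) else NA_integer_
      gr$exonTo <- if (nrow(exr)) max(exr$exon) else NA_integer_
      gr$meanRatio <- mean(rz$ratio[idx, smp], na.rm = TRUE)
      gr$meanZ <- mean(rz$z[idx, smp], na.rm = TRUE)
      gr$nAmplicons <- length(idx)
      gr$lowConfidence <- length(idx) < 2
      gr$inheritance <- "unknown"
      calls[[length(calls) + 1]] <- gr
    }
  }
  if (!length(calls))
    return(GenomicRanges::GRanges(
      sample = character(), state = character(), exonFrom = integer(),
      exonTo = integer(), meanRatio = numeric(), meanZ = numeric(),
      nAmplicons = integer(), lowConfidence = logical(),
      inheritance = character()))
  do.call(c, calls)
}

#' Annotate trio inheritance of CNV calls
#'
#' Child calls are matched to parental calls over the same exon range: a
#' heterozygous-deletion child call supported by one parent is labelled
#' paternal/maternal; a CN0 child call with both parents CN1 over the range is
#' `homozygous_biparental`; no parental support is `de_novo`; missing parent
#' samples give `unknown`.
#'
#' @param calls `GRanges` from [segmentCalls()] covering children and parents.
#' @param ped pedigree data.frame (`fam,id,father,mother,...`).
#' @param samples ids of all samples that were analysed (parents with no call
#'   are still "present"); defaults to the pedigree's ids, so pass the depth
#'   matrix's column names when some pedigree members were not sequenced.
#' @return `calls` with the `inheritance` column filled for child calls.
#' @export
annotateInheritance <- function(calls, ped, samples = ped$id) {
  if (!length(calls)) return(calls)
  key <- function(i) paste(calls$exonFrom[i], calls$exonTo[i])
  hasRange <- function(smp, k, st)
    any(calls$sample == smp & calls$state == st &
        paste(calls$exonFrom, calls$exonTo) == k)
  for (i in seq_along(calls)) {
    smp <- calls$sample[i]
    row <- ped[ped$id == smp, , drop = FALSE]
    if (nrow(row) == 0 || row$father == "0" || row$mother == "0") next
    fa <- row$father; mo <- row$mother
    if (!all(c(fa, mo) %in% samples)) next   # parent data missing -> unknown
    k <- key(i)
    if (calls$state[i] == "CN0") {
      if (hasRange(fa, k, "CN1") && hasRange(mo, k, "CN1"))
        calls$inheritance[i] <- "homozygous_biparental"
      else calls$inheritance[i] <- "de_novo"
    } else if (calls$state[i] == "CN1") {
      faC <- hasRange(fa, k, "CN1"); moC <- hasRange(mo, k, "CN1")
      calls$inheritance[i] <-
        if (faC && !moC) "paternal"
        else if (moC && !faC) "maternal"
        else if (faC && moC) "unknown"
        else "de_novo"
    }
  }
  calls
}

#' One-step CNV calling on a depth matrix
#'
#' Convenience pipeline: [normalizeDepth()] then [depthRatios()],
#' [callStates()], [segmentCalls()] and (when a pedigree is given)
#' [annotateInheritance()].
#'
#' @param dm a raw [DepthMatrix-class].
#' @param model the [TranscriptModel-class].
#' @param ped optional pedigree data.frame.
#' @param ... passed to [callStates()].
#' @return `GRanges` of annotated calls.
#' @export
callCnv <- function(dm, model, ped = NULL, ...) {
  rz <- depthRatios(normalizeDepth(dm))
  st <- callStates(rz, ...)
  calls <- segmentCalls(st, rz, SummarizedExperiment::rowRanges(dm), model)
  if (!is.null(ped)) calls <- annotateInheritance(calls, ped, colnames(dm))
  calls
}
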