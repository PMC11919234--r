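# Functional consequence of pseudoexon inclusion: frame arithmetic, protein
# consequence of splicing an intronic segment into the mRNA, splice-site
# context checks, and RT-PCR product-size prediction on cDNA.

#' Reading-frame consequence of an inserted segment
#'
#' An insertion whose length is a multiple of 3 preserves the reading frame
#' and adds `length/3` residues unless the inserted sequence carries a stop
#' codon in the junction frame; any other length shifts the frame. Only full
#' codons lying inside the insertion are scanned here -- hybrid codons
#' straddling the junction need genomic context and are handled by
#' [applyPseudoexon()].
#'
#' @param length insertion length in bp (>= 1).
#' @param sequence optional inserted sequence (enables the stop scan).
#' @param junctionPhase 0, 1 or 2: how many bases of the interrupted codon lie
#'   upstream of the junction.
#' @return list: `in_frame`, `inserted_residues` (`NA` unless in frame and
#'   stop-free), `introduces_stop`.
#' @examples
#' frameConsequence(126)          # in frame, 42 residues
#' frameConsequence(125)$in_frame # frameshift
#' @export
frameConsequence <- function(length, sequence = NULL, junctionPhase = 0) {
  stopifnot(length >= 1, junctionPhase %in% 0:2)
  inFrame <- length %% 3 == 0
  stop <- FALSE
  if (!is.null(sequence) && nzchar(sequence)) {
    stopifnot(nchar(sequence) == length)
    skip <- (3 - junctionPhase) %% 3      # bases completing the open codon
    if (length - skip >= 3) {
      starts <- seq.int(skip + 1, length - 2, by = 3)
      starts <- starts[starts + 2 <= length]
      codons <- substring(sequence, starts, starts + 2)
      stop <- any(codons %in% c("TAA", "TAG", "TGA"))
    }
  }
  list(in_frame = inFrame,
       inserted_residues = if (inFrame && !stop) length / 3 else NA_real_,
       introduces_stop = stop)
}

#' Splice a pseudoexon into a transcript and call the protein consequence
#'
#' Builds the mutant cDNA (the event sequence inserted between the flanking
#' exons), translates the mutant CDS, and classifies the consequence as an
#' in-frame insertion of k residues, a premature termination codon (PTC)
#' within or downstream of the insertion (frameshift), flagging
#' nonsense-mediated-decay candidacy when a PTC appears.
#'
#' @param model a [TranscriptModel-class].
#' @param event a [PseudoexonEvent-class] inside one of the model's introns.
#' @param genome locus sequence (a [fixtureLocus()]-style list, or a sequence
#'   plus `offset`).
#' @param offset genomic coordinate of `genome` base 1 when `genome` is a bare
#'   sequence.
#' @return list: `transcripts` (wild-type + mutant
#'   [Biostrings::DNAStringSet]), `consequence` (`"in_frame_insertion"`,
#'   `"ptc_in_insertion"` or `"frameshift_ptc"`), `inserted_residues`,
#'   `ptc_position` (residue index, `NA` if none), `nmd_candidate`.
#' @examples
#' loc <- fixtureLocus()
#' res <- applyPseudoexon(loc$model, fixturePseudoexon(loc), loc)
#' res$consequence; res$inserted_residues
#' @export
applyPseudoexon <- function(model, event, genome, offset = 1) {
  tx <- simulateTranscripts(model, event, genome, offset)
  L <- event@donor - event@acceptor + 1
  cb <- cumBoundaries(model)
  junction <- cb$end[event@intron]           # last wild-type base before insert
  if (junction < model@cdsStart || junction >= model@cdsEnd)
    stop("insertion point outside the CDS; protein consequence undefined")
  mutant <- as.character(tx[["mutant"]])
  cdsLen <- model@cdsEnd - model@cdsStart + 1
  mutCds <- substr(mutant, model@cdsStart, model@cdsEnd + L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(mutCds, 1, 3 * (nchar(mutCds) %/% 3))),
    if.fuzzy.codon = "X"))
  stopAt <- regexpr("*", aa, fixed = TRUE)
  expectedStop <- (cdsLen + ifelse(L %% 3 == 0, L, NA)) / 3
  inFrame <- L %% 3 == 0
  if (inFrame && stopAt == expectedStop) {
    out <- list(consequence = "in_frame_insertion",
                inserted_residues = L / 3, ptc_position = NA_real_,
                nmd_candidate = FALSE)
  } else if (inFrame) {
    out <- list(consequence = "ptc_in_insertion",
                inserted_residues = NA_real_, ptc_position = as.numeric(stopAt),
                nmd_candidate = TRUE)
  } else {
    out <- list(consequence = "frameshift_ptc",
                inserted_residues = NA_real_,
                ptc_position = if (stopAt > 0) as.numeric(stopAt) else NA_real_,
                nmd_candidate = stopAt > 0)
  }
  c(list(transcripts = tx), out)
}

#' Check canonical splice dinucleotides around a pseudoexon
#'
#' An acceptor needs AG immediately 5' of the included segment and a donor GT
#' immediately 3'. Non-canonical context is a warning (returned, not thrown);
#' coordinates outside the supplied genome are an error.
#'
#' @inheritParams applyPseudoexon
#' @return list with `ok` (logical) and `warnings` (character).
#' @export
validateSpliceSites <- function(event, genome, offset = 1) {
  if (is.list(genome)) { offset <- genome$offset; genome <- genome$sequence }
  genome <- as.character(genome)
  a <- event@acceptor - offset + 1
  d <- event@donor - offset + 1
  if (a - 2 < 1 || d + 2 > nchar(genome))
    stop("event coordinates (with 2 bp context) outside the genome")
  warnings <- character()
  if (substr(genome, a - 2, a - 1) != "AG")
    warnings <- c(warnings, "non-canonical acceptor (expected AG)")
  if (substr(genome, d + 1, d + 2) != "GT")
    warnings <- c(warnings, "non-canonical donor (expected GT)")
  list(ok = length(warnings) == 0, warnings = warnings)
}

#' Predict RT-PCR product sizes on cDNA templates
#'
#' Each primer (forward as given; reverse matched as its reverse complement)
#' must occur exactly once per transcript; the product size is the distance
#' between the primers' 5' ends, inclusive. On a heterozygote (wild-type +
#' pseudoexon transcript) the two product sizes differ by the pseudoexon
#' length -- the two-band gel pattern.
#'
#' @param transcripts [Biostrings::DNAStringSet] (or named character vector).
#' @param forward,reverse primer sequences, 5'->3'.
#' @return named integer vector of product sizes, one per transcript.
#' @examples
#' loc <- fixtureLocus()
#' tx <- simulateTranscripts(loc$model, fixturePseudoexon(loc), loc)
#' pr <- fixturePrimers(loc)
#' rtpcrProducts(tx, pr$forward, pr$reverse)
#' @export
rtpcrProducts <- function(transcripts, forward, reverse) {
  txs <- as.character(transcripts)
  revc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(reverse)))
  vapply(seq_along(txs), function(i) {
    tx <- Biostrings::DNAString(txs[i])
    nm <- if (!is.null(names(txs))) names(txs)[i] else as.character(i)
    f <- Biostrings::matchPattern(forward, tx)
    r <- Biostrings::matchPattern(revc, tx)
    if (length(f) == 0) stop("forward primer absent from transcript ", nm)
    if (length(f) > 1) stop("forward primer multi-maps in transcript ", nm)
    if (length(r) == 0) stop("reverse primer absent from transcript ", nm)
    if (length(r) > 1) stop("reverse primer multi-maps in transcript ", nm)
    as.integer(BiocGenerics::end(r)[1] - BiocGenerics::start(f)[1] + 1)
  }, integer(1), USE.NAMES = FALSE) |> stats::setNames(names(txs))
}
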