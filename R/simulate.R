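#' Deterministic synthetic locus for the packaged transcript model
#'
#' Builds the genomic sequence of the synthetic SLC26A4-like locus from a
#' fixed seed: random intergenic/intronic background, a stop-free coding
#' sequence written into the exons, canonical GT/AG dinucleotides at every
#' intron boundary, a 126-bp stop-free pseudoexon with canonical AG/GT context
#' planted in intron 3 at the c.304+941 region, and the cohort's reference
#' alleles at the published variant positions.
#'
#' @param seed integer seed; `NULL` uses the packaged fixture seed so every
#'   caller sees the same locus.
#' @return list with `sequence` ([Biostrings::DNAString]), `offset` (genomic
#'   coordinate of base 1), and `model` (the fixture [TranscriptModel-class]).
#' @examples
#' loc <- fixtureLocus()
#' nchar(as.character(loc$sequence))
#' @export
fixtureLocus <- function(seed = NULL) {
  meta <- fixtureMeta()
  model <- loadTranscript("slc26a4_fixture")
  if (is.null(seed)) seed <- meta$locus_seed
  set.seed(seed)
  offset <- meta$locus_start
  n <- meta$locus_end - meta$locus_start + 1
  seqc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)

  # spliced cDNA: stop-free CDS (sense codons + terminal TAA), random 3' UTR
  nCodon <- (model@cdsEnd - model@cdsStart + 1) / 3
  sense <- senseCodons()
  cds <- c(sample(sense, nCodon - 1, replace = TRUE), "TAA")
  cdna <- strsplit(paste0(paste(cds, collapse = ""),
                          randomDna(cdnaLength(model) - model@cdsEnd)), "")[[1]]
  # published substitution refs that fall in the cDNA
  for (v in fixtureVariantTable()$id) {
    p <- parseCPosition(v)
    if (p@intronOffset == 0) cdna[p@exonicBase] <- sub(".*([ACGT])>.*", "\\1", v)
  }
  # repair any stop the forced refs created upstream of the terminal codon
  for (i in seq_len(nCodon - 1)) {
    cod <- (3 * i - 2):(3 * i)
    if (paste(cdna[cod], collapse = "") %in% c("TAA", "TAG", "TGA"))
      cdna[cod[1]] <- "C"
  }

  s <- GenomicRanges::start(model@exons); e <- GenomicRanges::end(model@exons)
  cb <- cumBoundaries(model)
  for (k in seq_along(s)) {
    seqc[(s[k]:e[k]) - offset + 1] <- cdna[cb$start[k]:cb$end[k]]
  }
  # canonical splice dinucleotides in every intron
  for (k in seq_len(length(s) - 1)) {
    seqc[(e[k] + 1:2) - offset + 1] <- c("G", "T")
    seqc[(s[k + 1] - 2:1) - offset + 1] <- c("A", "G")
  }
  # pseudoexon: stop-free body (C-padded ends so junction-spanning codons
  # cannot form stops), canonical AG acceptor / GT donor context
  px <- meta$pseudoexon
  body <- strsplit(stopFreeDna(px$donor - px$acceptor + 1), "")[[1]]
  body[c(1, 2)] <- "C"
  body[length(body) - c(1, 0)] <- "C"
  seqc[(px$acceptor:px$donor) - offset + 1] <- body
  seqc[(px$acceptor - 2:1) - offset + 1] <- c("A", "G")
  seqc[(px$donor + 1:2) - offset + 1] <- c("G", "T")
  # intronic published refs (the exonic ones are already in the cDNA)
  for (v in fixtureVariantTable()$id) {
    p <- parseCPosition(v)
    if (p@intronOffset != 0) {
      ref <- sub(".*([ACGT])>.*", "\\1", v)
      seqc[cToG(model, p) - offset + 1] <- ref
    }
  }
  list(sequence = Biostrings::DNAString(paste(seqc, collapse = "")),
       offset = offset, model = model)
}

fixtureMeta <- function() {
  jsonlite::read_json(system.file("extdata", "slc26a4_model_synthetic.json",
                                  package = "EVAdx", mustWork = TRUE),
                      simplifyVector = TRUE)
}

senseCodons <- function() {
  all <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                               paste0), c("T", "C", "A", "G"), paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# The cohort's substitution variants with their parent-of-origin, mirroring
# the published genotype table (deletion alleles are handled separately).
fixtureVariantTable <- function() {
  data.frame(
    patient = c("3312024-1", "3312061-1", "3312177-1", "3312180-1",
                "3312189-1", "3312305-1", "3312305-1", "3312396-1",
                "3312396-1", "3312635-1", "3312757-1"),
    id = c("c.279T>A", "c.1264-6T>G", "c.919-2A>G", "c.1667A>G",
           "c.1614+1G>A", "c.304+941C>T", "c.946G>T", "c.1315G>A",
           "c.304+941C>T", "c.2168A>G", "c.919-2A>G"),
    origin = c("paternal", "paternal", "paternal", "maternal", "maternal",
               "paternal", "maternal", "paternal", "maternal", "paternal",
               "maternal"),
    stringsAsFactors = FALSE)
}

# Deletion events of the published genotype table at exon resolution.
fixtureDeletionTable <- function() {
  data.frame(
    patient = c("3312024-1", "3312061-1", "3312177-1", "3312180-1",
                "3312189-1", "3312285-1", "3312757-1"),
    exonFrom = c(1, 1, 5, 1, 9, 5, 1),
    exonTo = c(3, 3, 6, 3, 10, 6, 3),
    zygosity = c("het", "het", "het", "het", "het", "hom", "het"),
    origin = c("maternal", "maternal", "maternal", "paternal", "paternal",
               "biparental", "paternal"),
    stringsAsFactors = FALSE)
}

#' Build an amplicon panel tiling a transcript's exons
#'
#' Each exon is covered by `perExon` abutting amplicons spanning the exon plus
#' `flank` bases on each side, emulating a multiplex-PCR design targeting
#' exonic and flanking regions.
#'
#' @param model a [TranscriptModel-class].
#' @param perExon amplicons per exon (default 2).
#' @param flank flanking bases included on each side of the exon.
#' @return `GRanges` sorted by position with `amplicon_id` and `exon` metadata.
#' @export
ampliconPanel <- function(model, perExon = 2, flank = 50) {
  s <- GenomicRanges::start(model@exons); e <- GenomicRanges::end(model@exons)
  ord <- order(s)
  rows <- do.call(rbind, lapply(seq_along(s)[ord], function(k) {
    lo <- s[k] - flank; hi <- e[k] + flank
    cuts <- round(seq(lo - 1, hi, length.out = perExon + 1))
    data.frame(exon = k, start = cuts[-length(cuts)] + 1, end = cuts[-1],
               part = seq_len(perExon))
  }))
  gr <- GenomicRanges::GRanges(model@chrom,
                               IRanges::IRanges(rows$start, rows$end))
  gr$amplicon_id <- sprintf("e%02d%s", rows$exon, letters[rows$part])
  gr$exon <- rows$exon
  gr
}

#' Specify a simulated trio cohort
#'
#' Collects the generator's stated world: trio count, amplicon panel, planted
#' copy-number events, the 10-Mbp expected per-sample data amount, and the
#' noise model (negative-binomial depth dispersion, lognormal amplicon
#' efficiency, lognormal per-sample throughput, optional background rate for
#' homozygously deleted amplicons).
#'
#' @param nTrios number of trios (proband + both parents).
#' @param panel amplicon panel `GRanges` from [ampliconPanel()].
#' @param events data.frame of planted deletions with columns
#'   `patient` (proband id), `exonFrom`, `exonTo`, `zygosity` (`"het"`/`"hom"`),
#'   `origin` (`"paternal"`, `"maternal"`, `"biparental"`); may have 0 rows.
#' @param families family name per trio; proband/father/mother sample ids are
#'   `<fam>-1`, `<fam>-2`, `<fam>-3`.
#' @param meanTotalBases expected total sequenced bases per sample (1e7).
#' @param dispersion negative-binomial size parameter of per-amplicon depth
#'   (larger = less noise; `Inf` = Poisson). Default 100 (~10% CV).
#' @param efficiencySd log-scale SD of per-amplicon amplification efficiency.
#' @param throughputSd log-scale SD of per-sample total throughput.
#' @param contamination background depth fraction on CN0 amplicons.
#' @param seed master seed; all stage seeds derive from it.
#' @return object of class `"CohortSpec"` (a validated list).
#' @export
cohortSpec <- function(nTrios, panel, events = NULL,
                       families = sprintf("FAM%02d", seq_len(nTrios)),
                       meanTotalBases = 1e7, dispersion = 100,
                       efficiencySd = 0.4, throughputSd = 0.2,
                       contamination = 0, seed = 1) {
  stopifnot(nTrios >= 1, dispersion > 0, length(families) == nTrios)
  if (is.null(events))
    events <- data.frame(patient = character(), exonFrom = numeric(),
                         exonTo = numeric(), zygosity = character(),
                         origin = character())
  probands <- paste0(families, "-1")
  if (!all(events$patient %in% probands))
    stop("planted events name unknown probands: ",
         paste(setdiff(events$patient, probands), collapse = ", "))
  if (nrow(events) &&
      (min(events$exonFrom) < min(panel$exon) || max(events$exonTo) > max(panel$exon)))
    stop("planted event exon range outside the amplicon panel")
  structure(list(nTrios = nTrios, panel = panel, events = events,
                 families = families, meanTotalBases = meanTotalBases,
                 dispersion = dispersion, efficiencySd = efficiencySd,
                 throughputSd = throughputSd, contamination = contamination,
                 seed = seed),
            class = "CohortSpec")
}

#' The 13-trio cohort mirroring the published genotype table
#'
#' Convenience wrapper: fixture panel plus the seven published deletion events
#' (heterozygous Exons 1-3 in four probands, heterozygous Exons 5-6 and 9-10,
#' homozygous Exons 5-6) with their parental origins.
#'
#' @param seed master seed.
#' @param ... further arguments passed to [cohortSpec()].
#' @export
tableMirrorSpec <- function(seed = 1, ...) {
  model <- loadTranscript("slc26a4_fixture")
  fams <- sub("-1$", "", buildTableFixtures()$genotypes$patient_id)
  cohortSpec(13, ampliconPanel(model), fixtureDeletionTable(),
             families = fams, seed = seed, ...)
}

#' Pedigree of a simulated cohort
#'
#' @param spec a [cohortSpec()].
#' @return data.frame in PED column order (`fam,id,father,mother,sex,phenotype`).
#' @export
cohortPedigree <- function(spec) {
  do.call(rbind, lapply(seq_len(spec$nTrios), function(i) {
    f <- spec$families[i]
    data.frame(fam = f,
               id = paste0(f, c("-1", "-2", "-3")),
               father = c(paste0(f, "-2"), "0", "0"),
               mother = c(paste0(f, "-3"), "0", "0"),
               sex = c(0L, 1L, 2L), phenotype = c(2L, 1L, 1L))
  }))
}

# Per-sample, per-amplicon copy-number truth implied by the planted events.
truthCopyNumber <- function(spec) {
  nAmp <- length(spec$panel)
  ped <- cohortPedigree(spec)
  cn <- matrix(2L, nrow = nAmp, ncol = nrow(ped),
               dimnames = list(spec$panel$amplicon_id, ped$id))
  ev <- spec$events
  for (i in seq_len(nrow(ev))) {
    amps <- which(spec$panel$exon >= ev$exonFrom[i] &
                  spec$panel$exon <= ev$exonTo[i])
    child <- ev$patient[i]
    fam <- sub("-1$", "", child)
    father <- paste0(fam, "-2"); mother <- paste0(fam, "-3")
    if (ev$zygosity[i] == "hom") {
      cn[amps, child] <- cn[amps, child] - 2L
      cn[amps, father] <- cn[amps, father] - 1L
      cn[amps, mother] <- cn[amps, mother] - 1L
    } else {
      cn[amps, child] <- cn[amps, child] - 1L
      carrier <- if (ev$origin[i] == "paternal") father else mother
      cn[amps, carrier] <- cn[amps, carrier] - 1L
    }
  }
  if (any(cn < 0)) stop("planted events stack below copy number 0")
  cn
}

#' Simulate a per-sample, per-amplicon mean-depth matrix
#'
#' Forward model: amplicon efficiencies are lognormal (shared across samples,
#' as a multiplex-PCR panel behaves), each sample's total throughput is a
#' lognormal multiple of `meanTotalBases`, and the mean depth of amplicon *a*
#' in sample *s* is negative-binomially distributed with mean proportional to
#' efficiency x copy number / 2, scaled so the expected per-sample total bases
#' (depth x amplicon length summed) matches the sample throughput.
#'
#' @param spec a [cohortSpec()].
#' @return list with `dm` (a [DepthMatrix-class]) and `truth` (list holding the
#'   copy-number matrix `cn`, the planted `events`, and the `pedigree`).
#' @examples
#' m <- loadTranscript("slc26a4_fixture")
#' sp <- cohortSpec(2, ampliconPanel(m), seed = 7)
#' sim <- simulateDepthMatrix(sp)
#' dim(SummarizedExperiment::assay(sim$dm))
#' @export
simulateDepthMatrix <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(deriveSeed(spec$seed, 1))
  panel <- spec$panel
  len <- GenomicRanges::width(panel)
  nAmp <- length(panel)
  cn <- truthCopyNumber(spec)
  nS <- ncol(cn)
  eff <- stats::rlnorm(nAmp, 0, spec$efficiencySd)
  thr <- stats::rlnorm(nS, 0, spec$throughputSd)
  baseMu <- eff / sum(eff * len)           # depth share per amplicon at CN2
  depth <- matrix(0, nrow = nAmp, ncol = nS, dimnames = dimnames(cn))
  for (s in seq_len(nS)) {
    mu <- spec$meanTotalBases * thr[s] * baseMu *
      (cn[, s] / 2 + ifelse(cn[, s] == 0, spec$contamination, 0))
    depth[, s] <- if (is.infinite(spec$dispersion)) stats::rpois(nAmp, mu)
                  else stats::rnbinom(nAmp, size = spec$dispersion, mu = mu)
  }
  list(dm = DepthMatrix(depth, panel),
       truth = list(cn = cn, events = spec$events,
                    pedigree = cohortPedigree(spec)))
}

#' Simulate long reads over a locus, optionally from a deletion haplotype
#'
#' Reads are uniform substrings of the haplotype (the reference with the
#' deleted segment excised, when a deletion is given) with lengths drawn
#' uniformly from `readLenRange` -- the 1-6 kb fragment range of sheared
#' long-read libraries -- and independent substitution errors at `errorRate`.
#' Reads sampled across the excision point carry the deletion junction.
#'
#' @param reference [Biostrings::DNAString] or character scalar.
#' @param deletion `NULL`, or `c(start, end)` -- the first and last deleted
#'   base in reference coordinates (closed).
#' @param nReads number of reads.
#' @param readLenRange min/max read length (clamped to the haplotype length).
#' @param errorRate per-base substitution probability.
#' @param seed RNG seed.
#' @return list with `reads` ([Biostrings::DNAStringSet]) and `truth`
#'   (data.frame: read id, haplotype start, length, `spans_junction`).
#' @export
simulateLongReads <- function(reference, deletion = NULL, nReads = 50,
                              readLenRange = c(1000, 6000), errorRate = 0,
                              seed = 1) {
  ref <- as.character(reference)
  n <- nchar(ref)
  if (!is.null(deletion)) {
    if (deletion[1] < 1 || deletion[2] > n || deletion[2] < deletion[1])
      stop("deletion outside the reference")
    hap <- paste0(substr(ref, 1, deletion[1] - 1),
                  substr(ref, deletion[2] + 1, n))
    junction <- deletion[1] - 1          # haplotype position left of the gap
  } else {
    hap <- ref
    junction <- NA_real_
  }
  hn <- nchar(hap)
  if (hn < readLenRange[1]) stop("haplotype shorter than the minimum read length")
  set.seed(seed)
  lens <- pmin(round(stats::runif(nReads, readLenRange[1], readLenRange[2])), hn)
  starts <- floor(stats::runif(nReads, 1, hn - lens + 1 + 1))
  seqs <- substring(hap, starts, starts + lens - 1)
  if (errorRate > 0) {
    seqs <- vapply(seqs, function(s) {
      b <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(b)) < errorRate)
      for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  ids <- sprintf("read%04d", seq_len(nReads))
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read = ids, start = starts, length = lens,
                          spans_junction = !is.na(junction) &
                            starts <= junction & starts + lens - 1 > junction))
}

#' Simulate wild-type (and pseudoexon-bearing) cDNA
#'
#' The wild-type transcript is the spliced exon sequence; when a pseudoexon
#' event is given, the mutant transcript additionally includes the event's
#' sequence between the flanking exons, so the mutant is exactly the event
#' length longer.
#'
#' @param model a [TranscriptModel-class].
#' @param pseudoexon `NULL` or a [PseudoexonEvent-class] lying inside one of
#'   the model's introns.
#' @param genome locus sequence covering the model (and event), as returned by
#'   [fixtureLocus()] (a list with `sequence` and `offset`), or a
#'   [Biostrings::DNAString] with `offset` given separately.
#' @param offset genomic coordinate of `genome` base 1 (ignored when `genome`
#'   is a `fixtureLocus()` list).
#' @return named [Biostrings::DNAStringSet] (`wildtype`, and `mutant` when an
#'   event is given).
#' @examples
#' loc <- fixtureLocus()
#' tx <- simulateTranscripts(loc$model, fixturePseudoexon(loc), loc)
#' Biostrings::width(tx)
#' @export
simulateTranscripts <- function(model, pseudoexon = NULL, genome, offset = 1) {
  if (is.list(genome)) { offset <- genome$offset; genome <- genome$sequence }
  genome <- as.character(genome)
  s <- GenomicRanges::start(model@exons); e <- GenomicRanges::end(model@exons)
  exSeq <- substring(genome, s - offset + 1, e - offset + 1)
  if (model@strand == "-")
    exSeq <- vapply(exSeq, function(x)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
      character(1), USE.NAMES = FALSE)
  wt <- paste(exSeq, collapse = "")
  out <- c(wildtype = wt)
  if (!is.null(pseudoexon)) {
    k <- pseudoexon@intron
    if (k < 1 || k >= length(s)) stop("event intron index outside the model")
    lo <- if (model@strand == "+") e[k] + 1 else e[k + 1] + 1
    hi <- if (model@strand == "+") s[k + 1] - 1 else s[k] - 1
    if (pseudoexon@acceptor < lo || pseudoexon@donor > hi)
      stop("pseudoexon overlaps an exon or lies outside intron ", k)
    ins <- if (nzchar(pseudoexon@sequence)) pseudoexon@sequence
           else substring(genome, pseudoexon@acceptor - offset + 1,
                          pseudoexon@donor - offset + 1)
    if (model@strand == "-")
      ins <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ins)))
    cb <- cumBoundaries(model)
    out <- c(out, mutant = paste0(substr(wt, 1, cb$end[k]),
                                  ins, substr(wt, cb$end[k] + 1, nchar(wt))))
  }
  Biostrings::DNAStringSet(out)
}

#' Construct a PseudoexonEvent
#'
#' @param intron host intron index.
#' @param acceptor,donor genomic positions of the first/last included base.
#' @param sequence optional included sequence.
#' @export
pseudoexonEvent <- function(intron, acceptor, donor, sequence = "") {
  new("PseudoexonEvent", intron = as.numeric(intron),
      acceptor = as.numeric(acceptor), donor = as.numeric(donor),
      sequence = as.character(sequence))
}

#' The fixture's planted 126-bp pseudoexon
#'
#' @param locus a [fixtureLocus()] result; built fresh when omitted.
#' @return a [PseudoexonEvent-class] with sequence attached.
#' @export
fixturePseudoexon <- function(locus = fixtureLocus()) {
  px <- fixtureMeta()$pseudoexon
  seq <- substring(as.character(locus$sequence),
                   px$acceptor - locus$offset + 1, px$donor - locus$offset + 1)
  pseudoexonEvent(px$intron, px$acceptor, px$donor, seq)
}

#' Junction-flanking RT-PCR primers for the fixture transcripts
#'
#' A forward primer inside exon 3 and a reverse primer inside exon 4 of the
#' fixture cDNA, flanking the intron-3 pseudoexon insertion point, so the
#' wild-type and mutant products differ by exactly the pseudoexon length.
#'
#' @inheritParams fixturePseudoexon
#' @return list with `forward` and `reverse` primer strings (5'->3').
#' @export
fixturePrimers <- function(locus = fixtureLocus()) {
  wt <- as.character(simulateTranscripts(locus$model, NULL, locus)[["wildtype"]])
  fwd <- substr(wt, 260, 279)
  revTarget <- substr(wt, 433, 452)
  list(forward = fwd,
       reverse = as.character(Biostrings::reverseComplement(
         Biostrings::DNAString(revTarget))))
}

#' Load the published cohort genotype and variant evidence tables
#'
#' Structured transcriptions of the study's per-patient genotype table (13
#' probands, paternal/maternal allele columns) and per-variant ACMG evidence
#' table (13 classified variants), plus the supplementary classification for
#' the one allele the evidence table omits.
#'
#' @return list with `genotypes` (data.frame), `evidence` (data.frame; the
#'   `printed_criteria` column is a list of character vectors), and
#'   `supplementary` (data.frame of supplied classifications).
#' @export
buildTableFixtures <- function() {
  gt <- utils::read.table(system.file("extdata", "cohort_genotypes.tsv",
                                      package = "EVAdx", mustWork = TRUE),
                          sep = "\t", header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "")
  ev <- jsonlite::read_json(system.file("extdata", "variant_evidence.json",
                                        package = "EVAdx", mustWork = TRUE),
                            simplifyVector = TRUE)
  list(genotypes = gt, evidence = ev$variants,
       supplementary = ev$supplementary_classifications)
}

#' Write the cohort's planted substitution variants as a trio VCF
#'
#' Emits one bi-allelic record per published substitution with trio genotypes
#' (proband and the transmitting parent heterozygous), mirroring the cohort
#' genotype table, for the report module to phase by transmission.
#'
#' @param spec the cohort spec (supplies sample ids; typically
#'   [tableMirrorSpec()]).
#' @param locus a [fixtureLocus()] result (supplies coordinates and refs).
#' @param path output VCF path.
#' @return the path, invisibly.
#' @export
writeCohortSnvVcf <- function(spec, locus = fixtureLocus(), path) {
  vt <- fixtureVariantTable()
  vt <- vt[vt$patient %in% paste0(spec$families, "-1"), , drop = FALSE]
  model <- locus$model
  uniq <- !duplicated(vt$id)
  variants <- data.frame(
    chrom = model@chrom,
    pos = vapply(vt$id[uniq], function(v) cToG(model, parseCPosition(v)),
                 numeric(1)),
    id = vt$id[uniq],
    ref = sub(".*([ACGT])>.*", "\\1", vt$id[uniq]),
    alt = sub(".*>([ACGT]).*", "\\1", vt$id[uniq]))
  samples <- cohortPedigree(spec)$id
  gt <- matrix("0/0", nrow = nrow(variants), ncol = length(samples),
               dimnames = list(variants$id, samples))
  for (i in seq_len(nrow(vt))) {
    fam <- sub("-1$", "", vt$patient[i])
    carrier <- paste0(fam, if (vt$origin[i] == "paternal") "-2" else "-3")
    gt[vt$id[i], c(vt$patient[i], carrier)] <- "0/1"
  }
  writeSnvVcf(variants, gt, path)
}
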