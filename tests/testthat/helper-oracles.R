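# Shared fixtures and independent oracles used across the suite.

# Small + or - strand toy transcript with given exon count; exons of length
# exonLen separated by intronLen.
toyModel <- function(nExons = 4, exonLen = 60, intronLen = 200, strand = "+",
                     chrom = "chrT", origin = 1000) {
  if (strand == "+") {
    starts <- origin + (seq_len(nExons) - 1) * (exonLen + intronLen)
    ends <- starts + exonLen - 1
  } else {
    # transcription order descends genomically
    ends <- origin + (nExons - seq_len(nExons) + 1) * (exonLen + intronLen)
    starts <- ends - exonLen + 1
    ord <- order(starts, decreasing = TRUE)
    starts <- starts[ord]; ends <- ends[ord]
  }
  TranscriptModel("TOY", chrom, strand, starts, ends)
}

# Intron length after exon k (transcription order), computed from the public
# exon accessor so it stays independent of the package internals.
intronLengthForTest <- function(model, k) {
  ex <- exonRanges(model)
  s <- GenomicRanges::start(ex); e <- GenomicRanges::end(ex)
  if (model@strand == "+") s[k + 1] - e[k] - 1 else s[k] - e[k + 1] - 1
}

randomDnaStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force oracle for findGap: every two-segment colinear decomposition of
# an error-free read against the reference, with both segments at least
# minAnchor long. Returns a data.frame of deleted closed intervals.
bruteGapOracle <- function(read, ref, minAnchor = 30) {
  n <- nchar(read)
  refSS <- Biostrings::DNAString(ref)
  out <- list()
  for (s in minAnchor:(n - minAnchor)) {
    pre <- Biostrings::matchPattern(substr(read, 1, s), refSS)
    suf <- Biostrings::matchPattern(substr(read, s + 1, n), refSS)
    if (!length(pre) || !length(suf)) next
    for (i in BiocGenerics::end(pre)) {
      for (j in BiocGenerics::start(suf)) {
        if (j >= i + 2)
          out[[length(out) + 1]] <- c(del_start = i + 1, del_end = j - 1)
      }
    }
  }
  if (!length(out))
    return(data.frame(del_start = numeric(), del_end = numeric()))
  unique(as.data.frame(do.call(rbind, out)))
}

# Truth keys ("sample|state|exonFrom|exonTo") for every planted deletion in a
# simulated cohort, including the carrier parents implied by the events.
truthEventKeys <- function(events) {
  keys <- character()
  for (i in seq_len(nrow(events))) {
    fam <- sub("-1$", "", events$patient[i])
    ef <- events$exonFrom[i]; et <- events$exonTo[i]
    if (events$zygosity[i] == "hom") {
      keys <- c(keys,
                paste(events$patient[i], "CN0", ef, et, sep = "|"),
                paste(paste0(fam, "-2"), "CN1", ef, et, sep = "|"),
                paste(paste0(fam, "-3"), "CN1", ef, et, sep = "|"))
    } else {
      carrier <- paste0(fam, if (events$origin[i] == "paternal") "-2" else "-3")
      keys <- c(keys,
                paste(events$patient[i], "CN1", ef, et, sep = "|"),
                paste(carrier, "CN1", ef, et, sep = "|"))
    }
  }
  keys
}

callKeys <- function(calls, confidentOnly = TRUE) {
  df <- as.data.frame(calls)
  if (confidentOnly) df <- df[!df$lowConfidence, , drop = FALSE]
  paste(df$sample, df$state, df$exonFrom, df$exonTo, sep = "|")
}

# Reference with a 4-bp microhomology tract flanking a planted deletion:
# deleting [delStart, delEnd] or any placement shifted left by up to 4 bases
# yields the same haplotype.
microhomologyRef <- function(n = 2000, delStart = 801, delEnd = 1200,
                             mh = "ACGT", seed = 42) {
  set.seed(seed)
  b <- strsplit(randomDnaStr(n), "")[[1]]
  k <- nchar(mh)
  b[(delStart - k):(delStart - 1)] <- strsplit(mh, "")[[1]]
  b[(delEnd - k + 1):delEnd] <- strsplit(mh, "")[[1]]
  # break any accidental extension of the tract
  b[delStart - k - 1] <- "A"; b[delEnd - k] <- "C"
  b[delStart] <- "G"; b[delEnd + 1] <- "T"
  paste(b, collapse = "")
}
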