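model <- loadTranscript("slc26a4_fixture")
panel <- ampliconPanel(model)

test_that("depth simulation honours the noiseless limit and planted events", {
  # Poisson limit with flat efficiencies and throughput: depths agree with the
  # equal-share expectation to within counting noise
  sp <- cohortSpec(1, panel, dispersion = Inf, efficiencySd = 0,
                   throughputSd = 0, seed = 5)
  sim <- simulateDepthMatrix(sp)
  d <- SummarizedExperiment::assay(sim$dm, "depth")
  mu <- 1e7 / sum(GenomicRanges::width(panel))
  expect_true(all(abs(d - mu) < 6 * sqrt(mu)))
  expect_true(all(sim$truth$cn == 2))

  # homozygous Exons 5-6 deletion: zero depth over those amplicons
  ev <- data.frame(patient = "FAM01-1", exonFrom = 5, exonTo = 6,
                   zygosity = "hom", origin = "biparental")
  sim2 <- simulateDepthMatrix(cohortSpec(1, panel, ev, seed = 5))
  amps <- panel$amplicon_id[panel$exon %in% 5:6]
  d2 <- SummarizedExperiment::assay(sim2$dm, "depth")
  expect_true(all(d2[amps, "FAM01-1"] == 0))
  expect_true(all(sim2$truth$cn[amps, "FAM01-1"] == 0))
  expect_true(all(sim2$truth$cn[amps, c("FAM01-2", "FAM01-3")] == 1))

  # identical seed, identical matrix
  simA <- simulateDepthMatrix(cohortSpec(3, panel, seed = 17))
  simB <- simulateDepthMatrix(cohortSpec(3, panel, seed = 17))
  expect_identical(SummarizedExperiment::assay(simA$dm),
                   SummarizedExperiment::assay(simB$dm))

  # events outside the panel are rejected
  expect_error(cohortSpec(1, panel,
                          data.frame(patient = "FAM01-1", exonFrom = 22,
                                     exonTo = 23, zygosity = "het",
                                     origin = "paternal")),
               "outside the amplicon panel")
})

test_that("cohort mirror plants the published deletion burden", {
  sp <- tableMirrorSpec(seed = 17)
  sim <- simulateDepthMatrix(sp)
  expect_equal(length(unique(sim$truth$events$patient)), 7)
  # Mendelian consistency: child copy number never exceeds what the parents
  # can transmit (child CN at an amplicon >= father CN/2 floor + mother CN/2
  # floor and <= ceil halves summed)
  cn <- sim$truth$cn
  for (fam in sp$families) {
    ch <- cn[, paste0(fam, "-1")]
    fa <- cn[, paste0(fam, "-2")]; mo <- cn[, paste0(fam, "-3")]
    expect_true(all(ch >= floor(fa / 2) + floor(mo / 2)))
    expect_true(all(ch <= ceiling(fa / 2) + ceiling(mo / 2)))
  }
})

test_that("simulated depth means match the forward model within 3 SE", {
  # one amplicon per CN state, many replicates via many trios at dispersion
  # default; flat efficiencies/throughput isolate the CN factor
  nRep <- 2000
  ev <- data.frame(patient = "FAM01-1", exonFrom = 5, exonTo = 6,
                   zygosity = "hom", origin = "biparental")
  sp <- cohortSpec(1, panel, ev, efficiencySd = 0, throughputSd = 0, seed = 1)
  ampDel <- panel$amplicon_id[panel$exon == 5][1]
  ampDip <- panel$amplicon_id[panel$exon == 12][1]
  mu <- 1e7 / sum(GenomicRanges::width(panel))
  vals <- matrix(NA_real_, nRep, 2)
  set.seed(99)
  seeds <- sample(1e6, nRep)
  for (r in seq_len(nRep)) {
    sp$seed <- seeds[r]
    d <- SummarizedExperiment::assay(simulateDepthMatrix(sp)$dm, "depth")
    vals[r, ] <- c(d[ampDel, "FAM01-2"], d[ampDip, "FAM01-1"])
  }
  # CN1 parent: mean mu/2; CN2: mean mu
  for (col in 1:2) {
    expected <- c(mu / 2, mu)[col]
    se <- stats::sd(vals[, col]) / sqrt(nRep)
    expect_lt(abs(mean(vals[, col]) - expected), 3 * se)
  }
})

test_that("long-read simulation emits exact substrings and junction gaps", {
  set.seed(2)
  ref <- randomDnaStr(9000)
  sim <- simulateLongReads(ref, NULL, nReads = 20, readLenRange = c(1000, 3000),
                           errorRate = 0, seed = 3)
  for (r in as.character(sim$reads)) expect_true(grepl(r, ref, fixed = TRUE))

  # a planted 1845-bp deletion produces reads whose reference gap equals the
  # planted span (brute-force two-anchor check on an error-free read)
  del <- c(4001, 4000 + 1845)
  sim2 <- simulateLongReads(ref, del, nReads = 40, readLenRange = c(1500, 3000),
                            errorRate = 0, seed = 4)
  spanning <- which(sim2$truth$spans_junction)
  expect_gt(length(spanning), 0)
  cand <- findGap(sim2$reads[[spanning[1]]], ref)
  expect_equal(cand$del_length, 1845)
  # the reported interval may sit left of the planted one by the natural
  # microhomology at the junction, but excising it must recreate the haplotype
  hap <- paste0(substr(ref, 1, del[1] - 1), substr(ref, del[2] + 1, nchar(ref)))
  expect_identical(paste0(substr(ref, 1, cand$del_start - 1),
                          substr(ref, cand$del_end + 1, nchar(ref))), hap)
  expect_lte(cand$del_start, del[1])

  # determinism: identical call, byte-identical FASTA
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(simulateLongReads(ref, del, 10, seed = 9)$reads, f1)
  Biostrings::writeXStringSet(simulateLongReads(ref, del, 10, seed = 9)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulateLongReads(ref, c(8000, 9500), 5), "outside")
})

test_that("transcript simulation inserts the pseudoexon exactly", {
  loc <- fixtureLocus()
  wtOnly <- simulateTranscripts(model, NULL, loc)
  expect_equal(unname(Biostrings::width(wtOnly)), cdnaLength(model))

  px <- fixturePseudoexon(loc)
  tx <- simulateTranscripts(model, px, loc)
  w <- stats::setNames(Biostrings::width(tx), names(tx))
  expect_equal(unname(w["mutant"] - w["wildtype"]), 126)

  # a 125-bp event shifts the length by 125
  px125 <- pseudoexonEvent(3, px@acceptor, px@acceptor + 124)
  tx125 <- simulateTranscripts(model, px125, loc)
  w125 <- stats::setNames(Biostrings::width(tx125), names(tx125))
  expect_equal(unname(w125["mutant"] - w125["wildtype"]), 125)

  # an event overlapping an exon is rejected
  e4 <- GenomicRanges::start(exonRanges(model))[4]
  expect_error(simulateTranscripts(model, pseudoexonEvent(3, e4 - 10, e4 + 10), loc),
               "overlaps an exon|outside intron")
})

test_that("published table fixtures decode as printed", {
  fx <- buildTableFixtures()
  gt <- fx$genotypes
  expect_equal(nrow(gt), 13)
  r <- gt[gt$patient_id == "3312285-1", ]
  expect_equal(r$paternal_allele, "Exons 5-6 deletion (1845 bp)")
  expect_equal(r$maternal_allele, "Exons 5-6 deletion (1845 bp)")
  empty <- gt[gt$patient_id == "3310066-1", ]
  expect_equal(empty$paternal_allele, "")
  expect_equal(empty$maternal_allele, "")
  ev <- fx$evidence
  expect_equal(nrow(ev), 13)
  expect_setequal(unlist(ev$printed_criteria[ev$id == "c.946G>T"]),
                  c("PVS1", "PM2", "PM3_VeryStrong", "PP4"))
})

test_that("emitted files round-trip through the package readers", {
  sp <- cohortSpec(2, panel, seed = 21)
  sim <- simulateDepthMatrix(sp)
  tsv <- tempfile(fileext = ".tsv")
  writeDepthTsv(sim$dm, tsv)
  back <- readDepthTsv(tsv, panel)
  expect_equal(SummarizedExperiment::assay(back, "depth"),
               SummarizedExperiment::assay(sim$dm, "depth"))

  bed <- tempfile(fileext = ".bed")
  writeBedPanel(panel, bed)
  p2 <- readBedPanel(bed)
  expect_equal(GenomicRanges::start(p2), GenomicRanges::start(panel))
  expect_equal(p2$amplicon_id, panel$amplicon_id)

  pedf <- tempfile(fileext = ".ped")
  ped <- cohortPedigree(sp)
  writePed(ped, pedf)
  back <- readPed(pedf)
  expect_equal(back$id, ped$id)
  expect_equal(back$father, ped$father)
})
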