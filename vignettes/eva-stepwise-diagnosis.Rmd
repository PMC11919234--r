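---
title: "Stepwise genetic diagnosis of enlarged vestibular aqueduct: models and methods"
author: "EVAdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise genetic diagnosis of EVA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EVAdx)
```

# The problem

Enlarged vestibular aqueduct (EVA) is an inner-ear malformation associated
with sensorineural hearing loss; biallelic pathogenic variants of *SLC26A4*
(DFNB4 / Pendred syndrome) are its dominant genetic cause. Routine panels that
sequence the exonic and flanking regions of *SLC26A4* by multiplex PCR leave a
minority of patients with one (M1) or zero (M0) identified alleles. This
package implements the computational side of the stepwise strategy used to
resolve such patients:

1. **CNV calling** on the per-amplicon read depths of the existing multiplex
   panel, to find multi-exon deletions invisible to SNV/indel calling;
2. **breakpoint resolution** of those deletions from long reads spanning the
   locus;
3. **pseudoexon consequence prediction** for deep intronic variants that
   create new splice sites and exonize intronic (Alu) sequence;
4. **ACMG/AMP classification** of every candidate allele, specialised with
   hearing-loss-specific PM3 point scaling;
5. **cohort reporting**: trio phasing, M0/M1/M2 diagnostic status, diagnostic
   yield and screening arithmetic.

A first-class synthetic-data generator produces every input the pipeline
consumes, so all stages are testable without access to patient data.

# The synthetic locus and transcript model

Real GRCh37 *SLC26A4* exon coordinates are not shipped; the packaged model
(`loadTranscript("slc26a4_fixture")`) is a *synthetic* 21-exon, plus-strand
transcript whose geometry reproduces every containment relation the analysis
depends on: exon 3 ends at c.304 (so c.304+941 is a deep intron-3 position),
exon boundaries fall at c.919, c.1264 and c.1614 (the cohort's intronic and
canonical-splice variants are valid HGVS positions), and the three published
deletion windows cover exactly exons 1–3, 5–6 and 9–10. A user-supplied GFF3
overrides the fixture throughout.

`fixtureLocus()` generates the genomic sequence deterministically from a
packaged seed: random background, a stop-free coding sequence written into the
exons (so translation-based consequence calls are meaningful), canonical GT/AG
dinucleotides at every intron boundary, the published reference alleles at the
cohort's variant positions, and a 126-bp stop-free pseudoexon with canonical
AG/GT context planted at the c.304+941 region of intron 3.

Coordinate arithmetic is exact and convention-tagged. Published deletion
coordinate pairs mix two conventions — the 7666-bp and 3152-bp pairs are
first/last deleted base (closed; length `end - start + 1`), while the 1845-bp
and 4979-bp pairs only reproduce under `end - start` — so `GenomicInterval`
carries a convention tag, both lengths are representable, and the consensus
breakpoint caller reports both coordinate-pair styles rather than guessing
which the authors intended.

`gToC()` maps intronic positions to the *nearer* exon boundary (HGVS midpoint
split); consequently `gToC(cToG(p)) = p` holds for exonic positions and for
intronic offsets within the proximal half of an intron — a distal-half offset
is, by definition, represented from the other boundary.

# The depth model and the CNV caller

**Forward model.** For sample $s$ and amplicon $a$ the simulated mean depth is

$$ D_{sa} \sim \mathrm{NB}\!\left(\mu_{sa},\ \theta\right), \qquad
   \mu_{sa} = T\,t_s\,\frac{e_a}{\sum_b e_b \ell_b}\cdot\frac{c_{sa}}{2}, $$

with $T = 10^7$ expected total bases per sample, $t_s$ a lognormal per-sample
throughput factor (log-SD 0.2), $e_a$ a lognormal amplicon efficiency shared
across samples (log-SD 0.4, as a multiplex panel behaves), $\ell_a$ the
amplicon length, $c_{sa}$ the integer copy number and $\theta$ the
negative-binomial size. Defaults were chosen once as a realistic stated world:
$\theta = 100$ gives a ~10% coefficient of variation per amplicon, typical of
replicate scatter in deep multiplex amplicon assays. Homozygously deleted
amplicons draw depth 0 (an optional contamination rate $\varepsilon$ adds
background). All randomness flows from one master seed through per-stage
derived seeds, so each stage is independently reproducible.

**Calling.** `normalizeDepth()` rescales each sample so
$\sum_a D_{sa}\ell_a = 10^7$ exactly — the "assume 10 Mbp of data per sample"
normalisation. `depthRatios()` divides by a per-amplicon reference (cohort
median by default, parents included; configurable) and additionally recentres
each sample by its median ratio: with a fixed-total normalisation, a carrier
of a multi-exon deletion has every *other* amplicon inflated by the deleted
footprint share (~10% for the homozygous exons 5–6 carrier), and the
median-of-ratios correction removes that baseline shift, exactly as
size-factor normalisation does in count models. The robust z-score uses
$1.4826 \times \mathrm{MAD}$ of the *apparently diploid* samples (ratio in
[0.7, 1.3)) per amplicon: several samples can share one founder deletion, and
a spread taken over all samples would be inflated by the carriers themselves.

States follow fixed ratio bands — CN0 below 0.2, CN1 in [0.2, 0.7), CN2 in
[0.7, 1.3), CN3+ above — with a $|z| \ge 3$ gate; a non-diploid band failing
the gate is kept diploid and flagged *suspect*. The bands sit midway between
copy-number expectations (0.5 per allele) and the gate guards against
amplicon-level noise; the source analysis states only "high or low depth", so
these defaults are this package's stated world. Segmentation merges maximal
runs of adjacent same-state amplicons; a suspect amplicon flanked by a
confident call of the same band state is rescued into the run (a mid-run z
blip must not split a six-amplicon deletion), while an isolated suspect still
calls nothing. Single-amplicon calls are emitted but flagged low-confidence.
Trio inheritance is annotated by matching child calls to parental calls over
the same exon range (paternal / maternal / homozygous biparental / de novo).

**What a green test establishes.** The recovery criterion (exon-range-exact
recall and precision $\ge$ 0.95 over 100 simulated 13-trio cohorts; precision
over confident calls, since every plantable event spans $\ge 4$ amplicons and
the low-confidence flag exists precisely to quarantine singleton blips) shows
the caller is sharp *under the stated noise model*: negative-binomial depth
with sample- and amplicon-level lognormal factors. Real panels add GC bias,
batch effects and occasional failed amplifications that this generator
deliberately does not model; the scale-invariance and conservation invariants
still hold for arbitrary inputs, but the 95% figures do not transfer to real
data unexamined.

# Breakpoint resolution

`findGap()` anchors a long read's prefix and suffix in the locus with exact
30-mer seeds (several windows are tried, so occasional substitution errors do
not unseat an anchor), yielding two alignment diagonals. A suffix diagonal
offset exceeding the prefix diagonal implies a deletion; the split point is
chosen to maximise total reference agreement, and the maximiser is a plateau
whose width is the junctional microhomology. The lowest-coordinate placement
is reported (left alignment, matching VCF normalisation practice; the source
does not state its convention). `consensusDeletion()` takes the modal
interval across reads, errors on modal ties rather than choosing silently,
and reports both coordinate-pair conventions. `deletionToVcf()` emits a
sequence-resolved VCF 4.2 deletion record (symbolic `<DEL>` fallback at the
contig start).

Anchoring is exact-seed plus bounded-mismatch scoring rather than full
alignment: the read simulator emits substitution-only errors (indel errors
are excluded so the breakpoint oracle stays exact), and for that error model
two-diagonal decomposition is complete. The brute-force oracle — exhaustive
enumeration of all two-segment colinear decompositions with both segments
$\ge$ 30 bp — is kept in the test suite and the resolver must match it,
modulo left-alignment, on references up to 5 kb.

# Pseudoexon consequence

`frameConsequence()` is pure arithmetic: an insertion of length $L$ is
in-frame iff $L \equiv 0 \pmod 3$, contributing $L/3$ residues when stop-free
(126 bp → 42 residues); full codons inside the insertion are scanned for
stops in the junction frame (all three phases supported and tested), while
hybrid junction-spanning codons are resolved by `applyPseudoexon()`, which
splices the event into the transcript, translates the mutant CDS, and
classifies the outcome as in-frame insertion, PTC-within-insertion, or
frameshift with the PTC residue reported — any PTC sets the
nonsense-mediated-decay candidate flag. NMD efficiency itself is out of
scope. Splice-site context is checked (AG acceptor / GT donor) as warnings,
not errors: whether a user-supplied pseudoexon is genuinely stop-free is
flagged, never assumed.

`rtpcrProducts()` predicts RT-PCR product sizes as the inclusive distance
between primer 5' ends, requiring each primer to map uniquely; on a
heterozygote the wild-type and mutant products differ by exactly the
pseudoexon length — the two-band gel pattern. The fixture primers flank the
exon 3/4 junction from within the synthetic cDNA; the published primer
sequences target the real transcript, which is not shipped.

# ACMG engine

Criteria carry an *effective strength* (Supporting/Moderate/Strong/
VeryStrong), defaulting to the code prefix. PM2 uses the hearing-loss
subpopulation threshold $7\times10^{-5}$ (Moderate) with a Supporting tier
below $7\times10^{-4}$. PM3 follows the ClinGen-SVI-style point scale — 1.0
per confirmed in-trans observation, 0.5 per homozygous or phase-unknown
observation, thresholds 0.5/1/2/4 for Supporting/Moderate/Strong/VeryStrong,
with no per-variant cap on phase-unknown points (configurable weights). PVS1
applies to nonsense, frameshift, canonical-splice and exonic-deletion classes;
PP3 consumes REVEL (> 0.7) or dbscSNV ADA (> 0.957) scores as annotations
only; PS3 takes the stated functional-evidence strength; PP4 is a
phenotype-specificity flag. `combineCriteria()` implements the standard
combining rules down to VUS; benign-side criteria are out of scope.

Two deliberate non-matches with the published table are surfaced, not
special-cased: the point scale gives c.1614+1G>A PM3\_Strong where the table
printed default Moderate (final class unchanged), and c.1667A>G shares its
entire criteria profile with c.1315G>A yet the table prints Pathogenic for
one and Likely Pathogenic for the other — the engine returns
LikelyPathogenic for both, so exactly 12 of 13 classifications are
concordant and the discrepancy appears in the concordance report.

# Reporting

`assembleGenotypes()` phases proband variants onto parental alleles by trio
transmission (untransmitted or doubly-carried variants stay unphased and are
flagged; two variants on one parental allele are recorded together and never
counted biallelic). `diagnosticStatus()` yields M2/M1/M0 by counting parental
alleles bearing a Pathogenic or Likely Pathogenic variant — VUS alleles never
count. `cohortYield()` rounds half-up (69 from 9/13), and `screenFrequency()`
reports per-mille carrier rates to two decimals (5 in 20,666 → 0.24‰).

Two cohort alleles are absent from the published evidence table
(c.919-2A>G and c.2168A>G); the fixtures supply their classifications
(flagged `source = "supplied"`) so the printed genotype table is scoreable —
without them the published 9/13 yield is unreachable from the printed tables
alone.

# Numerical and scope notes

* Runtime scaling: the acceptance suite runs the full 100-cohort CNV sweep;
  the unit suite runs the same generative checks at reduced replicate counts
  (e.g. 2,000 draws for the 3-SE forward-model mean check, 10 seeds for the
  end-to-end status reproduction) with bands recomputed for the smaller n.
* Degenerate inputs: all-zero samples, zero-reference amplicons, modal ties
  in consensus, deletions at the contig start, primers that are absent or
  multi-map, unclassified variants referenced by a genotype — each is a
  defined error or a masked-and-reported condition, never a silent choice.
* Out of scope: wet-lab procedure modelling, WES/WGS alignment and variant
  calling, computation of SpliceAI/varSEAK/REVEL/dbscSNV scores, Alu-family
  annotation, benign-side ACMG criteria, digenic analyses.
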