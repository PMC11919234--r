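{
  "comment": "Synthetic SLC26A4-like transcript model. Real GRCh37 exon coordinates for NM_000441.2 are not redistributable here; these 21 exons are placed so that every published containment relation holds: exon 3 ends at c.304 (the c.304+941 variant lies in intron 3), the chr7:107300016-107307681 window contains exons 1-3, the chr7:107300698-107303849 window contains exons 1-2 fully and exon 3 partially, the chr7:107314217-107316062 window covers exactly exons 5-6, the chr7:107329303-107334282 window covers exactly exons 9-10, exon boundaries fall at c.919 (acceptor), c.1264 (acceptor) and c.1614 (donor).",
  "transcript_id": "NM_000441.2-synthetic",
  "chrom": "chr7",
  "strand": "+",
  "exon_start": [107301000, 107302000, 107303800, 107309000, 107314300, 107315800,
                 107317000, 107319000, 107330000, 107332000, 107336000, 107338000,
                 107340000, 107341000, 107342000, 107343000, 107344000, 107345000,
                 107346000, 107347000, 107348000],
  "exon_end":   [107301139, 107302109, 107303853, 107309179, 107314449, 107315999,
                 107317083, 107319099, 107330119, 107332124, 107336129, 107338220,
                 107340149, 107341149, 107342149, 107343149, 107344149, 107345149,
                 107346149, 107347149, 107348685],
  "cds_start": 1,
  "cds_end": 2445,
  "locus_start": 107299000,
  "locus_end": 107350000,
  "locus_seed": 1070441,
  "pseudoexon": {
    "intron": 3,
    "acceptor": 107304794,
    "donor": 107304919,
    "variant": "c.304+941C>T"
  }
}
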