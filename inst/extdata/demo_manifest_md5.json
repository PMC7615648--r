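{
  "backgrounds.fa": "c393e13f0fc00a81859a7c2914e96f41",
  "blacklist.txt": "0481974e20162b591f89cff42d983052",
  "genes.bed": "5f8d8f5bf25833bc15a179f2b0db0d4e",
  "genes.gff3": "ace6d6555b76b723ea8d2b35b311a39e",
  "genome.fa": "486d493e7be54018a561b59d98054247",
  "islands.tsv": "48860a4e390588d8039c016c4ef3bf50",
  "metagene_matrix.tsv": "529699a60e2820508e1921dac768c99a",
  "metagene_profile.tsv": "8fe270cc8993e9e0933753084297f588",
  "motifs.tsv": "e060b27d27ea5673b34e7df4081d8bfc",
  "polya_assigned.tsv": "5e5d49f26312712600a62d66d7216f93",
  "polya.minus.bedgraph": "0578aed84a4e9b22e924cf9add7d33d0",
  "polya.plus.bedgraph": "74f753d16da360ad541c5c293047b6c7",
  "qc_WT.tsv": "264bec4efb8d26515168d984b3a6a0a7",
  "qc_Ysh1AA.tsv": "35511ed12a44d318e2f9036dbeedcb30",
  "targets.fa": "ee34c28d4e96246c8557965cc9492f73",
  "terminator_tracts.tsv": "61f040f3696e297cc87f158c56c14330",
  "truth_points.tsv": "8be8696e5d8d0373fa3d317c529c5af9",
  "truth_tracts.tsv": "9850101dc7b8f5a97b521ebe281ab23e",
  "WT_merged.minus.bedgraph": "ed537496aaccda5e9c9e803819710bce",
  "WT_merged.plus.bedgraph": "5468bcd6c1df2a1aebeada048aea9a60",
  "WT_rep1.minus.bedgraph": "e8ca5458f02c28f503b0c2510d2b3f74",
  "WT_rep1.plus.bedgraph": "58812293954ecec5df222c2909c99f60",
  "WT_rep2.minus.bedgraph": "7142e66d17a148c4efb4c05c89c02d33",
  "WT_rep2.plus.bedgraph": "dc91f60b6e776ebf78266377eacbfb73",
  "Ysh1AA_merged.minus.bedgraph": "8b68b0c4c32c38add31ce5fbad0a4458",
  "Ysh1AA_merged.plus.bedgraph": "dc513c2b473f0741373353a7c9c08088",
  "Ysh1AA_rep1.minus.bedgraph": "c13597e10fe898f5f6b8c885134b4851",
  "Ysh1AA_rep1.plus.bedgraph": "fb33382dfd21ac860c649e7804dda805",
  "Ysh1AA_rep2.minus.bedgraph": "8cfa76a23cb68ef150e9cb9965456b6c",
  "Ysh1AA_rep2.plus.bedgraph": "24410bc37961351514825b6e13a3f5ac"
}
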