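{
  "de_total": 568,
  "ng14_specific": 319,
  "rutc30_specific": 62,
  "clustered": 532,
  "unclustered": 36,
  "up_cluster_genes": 256,
  "down_cluster_genes": 276,
  "basal_different": 23,
  "q_bradford_ng14": 1.2,
  "q_bradford_rutc30": 3.98
}
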