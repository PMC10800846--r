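{
  "title": "linesig run report",
  "required": [
    "manifest",
    "samples",
    "otus",
    "presence_partition",
    "alpha_diversity",
    "pcoa",
    "permanova",
    "diff_abundance",
    "signature",
    "class_grid",
    "gene_lists",
    "controls",
    "flags"
  ]
}
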