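[
  {
    "contig_id": "ctg01",
    "span": [9, 19],
    "anchors": [
      ["ctg01_g0014", "ctg01_g0015"]
    ],
    "gene_ids": ["ctg01_g0009", "ctg01_g0010", "ctg01_g0011", "ctg01_g0012", "ctg01_g0013", "ctg01_g0014", "ctg01_g0015", "ctg01_g0016", "ctg01_g0017", "ctg01_g0018", "ctg01_g0019"],
    "cazyme_calls": [
      {
        "gene_id": "ctg01_g0009",
        "family": "GH130"
      },
      {
        "gene_id": "ctg01_g0010",
        "family": "GH26"
      },
      {
        "gene_id": "ctg01_g0012",
        "family": "GH26"
      },
      {
        "gene_id": "ctg01_g0013",
        "family": "GH27"
      },
      {
        "gene_id": "ctg01_g0017",
        "family": "GH26"
      },
      {
        "gene_id": "ctg01_g0018",
        "family": "GH5"
      },
      {
        "gene_id": "ctg01_g0019",
        "family": "CE2"
      }
    ],
    "family_set": ["CE2", "GH130", "GH26", "GH27", "GH5"],
    "n_genes": 11,
    "merged": false
  }
]
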