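{
  "true_labels": {
    "ctg01_g0000": "NONE",
    "ctg01_g0001": "NONE",
    "ctg01_g0002": "NONE",
    "ctg01_g0003": "NONE",
    "ctg01_g0004": "NONE",
    "ctg01_g0005": "NONE",
    "ctg01_g0006": "NONE",
    "ctg01_g0007": "NONE",
    "ctg01_g0008": "NONE",
    "ctg01_g0009": "GH130",
    "ctg01_g0010": "GH26",
    "ctg01_g0011": "NONE",
    "ctg01_g0012": "GH26",
    "ctg01_g0013": "GH27",
    "ctg01_g0014": "SUSC",
    "ctg01_g0015": "SUSD",
    "ctg01_g0016": "NONE",
    "ctg01_g0017": "GH26",
    "ctg01_g0018": "GH5",
    "ctg01_g0019": "CE2",
    "ctg01_g0020": "NONE",
    "ctg01_g0021": "NONE",
    "ctg01_g0022": "NONE",
    "ctg01_g0023": "NONE",
    "ctg01_g0024": "NONE",
    "ctg01_g0025": "NONE",
    "ctg01_g0026": "NONE",
    "ctg01_g0027": "NONE",
    "ctg01_g0028": "NONE",
    "ctg01_g0029": "NONE",
    "ctg01_g0030": "SUSC",
    "ctg01_g0031": "SUSD",
    "ctg01_g0032": "NONE",
    "ctg01_g0033": "NONE",
    "ctg01_g0034": "NONE",
    "ctg01_g0035": "NONE",
    "ctg01_g0036": "NONE",
    "ctg01_g0037": "NONE",
    "ctg01_g0038": "NONE",
    "ctg01_g0039": "NONE"
  },
  "planted_puls": {
    "contig_id": ["ctg01"],
    "start_index": [9],
    "end_index": [19],
    "architecture": ["planted"]
  }
}
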