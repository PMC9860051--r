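seed: 1
stages:
- simulate
- annotate
- mine
- compare
simulate:
  genome:
    n_contigs: 1
    n_genes_per_contig: 40
    n_puls: 1
    n_decoys: 1
  noise:
    fp_rate: 0.0
    fn_rate: 0.0
    near_threshold_fraction: 0.0
  proteome:
    n_proteins: 200
    n_reps: 3
    n_effect: 10
    effect_fold: 8.0
    cv: 0.2
    missing_rate: 0.0
  arrays:
    n_extracts: 3
    n_probes: 2
    deletion_depth: 1.0
    n_spots: 2
    noise_cv: 0.0
annotate:
  mode: confirmed
mine:
  frame: 7
  max_gap: 1
  require_same_strand: yes
  require_gh26: yes
proteomics:
  alpha: 0.05
  n_perm: 250
  conditions:
  - galactomannan
  - pectin
  reference: galactomannan
arrays:
  control: buffer
  treatment: GH26C

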