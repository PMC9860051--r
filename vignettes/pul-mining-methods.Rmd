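---
title: "Mining beta-mannan polysaccharide utilization loci: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining beta-mannan polysaccharide utilization loci: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulcascade)
```

## What the package computes

Marine *Bacteroidetes* organise carbohydrate catabolism in polysaccharide
utilization loci (PULs): gene clusters coding for a TonB-dependent
transporter / surface glycan-binding protein tandem (SusC/SusD), the
carbohydrate-active enzymes (CAZymes) that depolymerize one substrate
class, and associated regulators and transporters. `pulcascade` implements
the computational workflow used to characterize a beta-mannan PUL and its
distribution across marine genomes and metagenome-assembled genomes
(MAGs):

1. **dual-evidence CAZyme annotation** — HMM domain hits against CAZy
   family profiles, filtered by the dbCAN parser rules, optionally
   confirmed by protein sequence-search hits against a family-tagged
   database;
2. **PUL mining** — detection of SusC/D tandem anchors and extension of
   cluster boundaries by a seven-gene frame, excluding glycosyl
   transferases;
3. **comparative analysis** — modularity classification against the
   reference beta-mannan locus (GH26, GH5, GH27, GH130, CE2 + SusC/D),
   family co-occurrence, intersection counts, MAG repertoire matching,
   and reciprocal-best-hit synteny maps;
4. **proteome semiquantification** — %riBAQ, a detection filter, Welch
   tests with permutation-based FDR, and condition fold changes;
5. **microarray epitope-deletion analysis** — replicate means, max-to-100
   normalization per dataset, and percent signal reduction against a
   buffer control.

Every stage can be exercised on seeded synthetic data with planted ground
truth, which is how the package validates itself.

## Annotation model

Domain hits are filtered with the dbCAN parser's documented rules, kept as
configurable defaults in `annotation_rules()`: e-value `< 1e-5` for
alignments longer than 80 residues, `< 1e-3` otherwise; profile coverage
`> 0.30`; and hits on one protein whose envelopes overlap by more than half
of the shorter envelope are resolved by keeping the lower e-value (ties:
higher coverage, then profile name — a deterministic greedy pass ordered by
e-value). Overlap resolution runs before thresholding, as in the original
parser; the filter is idempotent.

SusC is called from the TIGR04056 profile and SusD from the PF12741,
PF12771, PF14322 and PF07980 profiles; version suffixes such as `.10` are
stripped before matching. A protein hitting both classes is flagged and
resolved by the lower e-value.

Confirmation requires a search hit at e-value `<= 1e-20`, query coverage
`>= 40%` and identity `>= 30%`. Two readings of "confirmed" are possible
and both are provided: the default requires the search hit to carry the
*same family label* as the domain call (`confirm_rules(scope = "family")`),
the alternative accepts any qualifying hit for the protein
(`scope = "protein"`). All three bounds are inclusive: wording like
"threshold of E-20" and "at least 30%" is read as closed intervals, so
boundary values pass (`test-acceptance.R` probes one ulp on each side).
SusC/SusD calls are HMM-only by definition and glycosyl transferase
families bypass confirmation, since they are excluded from all downstream
context scans anyway. Confirmed-mode calls are provably a subset of
HMM-only calls, and tightening any confirmation threshold never adds a
call; both properties are tested.

## The seven-gene frame

A "seven-gene frame" around a SusC/D anchor admits at least two readings.
A single fixed window of seven genes on each side cannot produce the large
multi-CAZyme clusters that the mining is meant to recover, so the default
is an *iterative* window: from each side of the anchor span, examine the
next seven genes; if any carries a non-GT CAZyme call, move the boundary to
the farthest such gene within the window and re-examine from there; stop
when a window holds no CAZyme or the contig ends. The final span is trimmed
so each terminus is a CAZyme, SusC or SusD gene. The fixed-window reading
remains available (`window = "fixed"`). Frames count genes, not base pairs;
contig ends truncate windows.

This greedy boundary walk is equivalent to a fixed-point closure (absorb
any CAZyme within seven genes of the current span edge until nothing
changes). The test suite exploits the equivalence: an independent closure
implementation is the oracle, and because extension is one-sided, checking
every one-sided flank of length 0–13 over {no label, CAZyme, GT} — about
4.8 million arrangements, both code paths — covers *every* arrangement of
up to 15 genes around one anchor. Side independence is additionally
spot-checked through the full gene-table path.

Anchor pairing defaults (the underlying screen defines only the pair
concept): SusC and SusD in either order, at most one intervening gene, same
strand, each gene in at most one pair, candidate pairs taken greedily left
to right with the closest pair winning ties. All of this is configurable
(`max_gap`, `require_same_strand`). Overlapping spans grown from distinct
anchors are merged into one PUL and flagged `merged`. The assembly screen
keeps clusters whose family set contains GH26 (any subfamily); it can be
disabled to inspect all anchored clusters.

## Comparative definitions

"Same modularity" is taken as *family-set equality* with the reference
(multiplicity ignored, extra families disqualify), at (sub)family level
with GH5 subfamilies collapsed to GH5 — this matches a presence/absence
depiction of cluster content. A superset mode is exposed for the more
permissive reading, and multiplicity-aware comparisons can be emulated from
`cazyme_calls`. Co-occurrence fractions use an inclusive retention
threshold ("at least 5%" keeps a family in exactly 5% of clusters). MAG
repertoire matching deliberately ignores genetic context: the minimal
criterion is one SusC, one SusD and one GH26 anywhere in the genome; the
full criterion requires every reference family.

Synteny maps pair genes by reciprocal best hits at e-value `<= 1e-5` (ties
broken by lower e-value then lexicographic subject id — the underlying
screen states only the threshold, so the standard deterministic pairing was
chosen). Conservation is the fraction of reference genes matched; the order
score is the longest increasing subsequence of target positions in
reference order, divided by the number of matched pairs.

## Proteomics model

%riBAQ rescales each sample so protein intensities sum to 100; missing
values count zero in the denominator and stay missing. Proteins are
"identified" when detected in at least two replicates of at least one
condition. Welch's two-sided t statistic with Welch–Satterthwaite degrees
of freedom is the test statistic; when both groups have zero variance and
equal means, `t = 0` by convention.

The test is applied to `log2(%riBAQ)` with missing values excluded
groupwise (a raw-scale mode exists); the quantification scale was not
prescribed, and the log scale is where lognormal intensity noise is
homoscedastic. FDR control is permutation-based with null statistics pooled
across proteins: for each candidate cutoff c (the observed |t| values),

    FDR(c) = mean over permutations of #{null |t| >= c} / max(1, #{observed |t| >= c})

and the significant set is the largest set with `FDR <= alpha`. All
distinct group-label assignments are enumerated when there are at most
`n_perm` (default 250) of them — a 3 vs 3 design has 20, so the default is
exhaustive and deterministic; otherwise `n_perm` distinct assignments are
sampled with the given seed. The observed assignment and its group-swap
complement reproduce the observed statistics exactly and are excluded from
the null pool; counting them would bound the estimated FDR below by 2/20 at
any cutoff covering the true effects and zero out the procedure's power at
`alpha = 0.05`.

### Calibration and power, measured

Two properties of this estimator are worth stating plainly, since the
acceptance script measures both:

* **Null calibration.** On all-null data the realized false-discovery
  proportion sits near, and slightly above, the nominal 5% (the largest
  observed |t| beats every pooled null statistic with probability roughly
  1/19 under exchangeability with 18 null assignments). The null-control
  check passes within 3 Monte-Carlo standard errors of its 200
  repetitions.
* **Power at n = 3.** With 22 planted 8-fold effects among 1000 proteins
  (replicate CV 0.2), each effect's t statistic is noncentral with only
  ~4 degrees of freedom for the variance estimate, while the pooled null
  cutoff for FDR 0.05 sits around |t| ≈ 8. The chance that the *weakest*
  of 22 such statistics clears the cutoff is only ~40–55% per experiment,
  even though the *average* fraction of effects recovered is ~95%. The
  all-or-nothing recovery check in `test-acceptance.R` therefore fails by
  design of the statistics, not of the code: with three replicates and a
  plain per-protein Welch test there is no seed-independent way to recover
  every planted effect in 95% of experiments at FDR 0.05. Variance
  moderation across proteins would change this, but is a different test
  than the one implemented here.

Fold changes are reported as mean(reference)/mean(other) on the
quantification scale, flagged infinite when the denominator mean is zero;
only ratios above one are marked positive.

## Microarray model

Replicate spot signals are averaged per (extract, probe, treatment); cells
with fewer than two spots violate the replicate rule and are excluded (and
reported). Normalization sets the highest mean signal of each *dataset* to
100; a dataset defaults to one treatment block — one physical array /
sub-heatmap — with a global mode available. The epitope-deletion score is
`100 × (1 − treated/control)` on the same extract and probe, floored at
zero (signal increases keep their raw ratio), undefined and flagged when
the control is zero. Because treated and control blocks are normalized
separately, a deletion that removes the *maximum* cell of the treated block
rescales that block and compresses scores; the deletion-depth *ranking* is
preserved (tested), and exact `100 × depth` scores hold whenever an
untargeted cell anchors both maxima.

## Synthetic data: what it emulates, and what it does not

`generate_genome()` plants PULs with the reference architecture — SusC/D
pair, three GH26, GH5, GH27, GH130, CE2, with regulator/transporter genes
interspersed and CAZymes at both termini — on a fixed 1 kb coordinate grid
(only gene order matters downstream). Decoys cycle through lone SusC/D
pairs (no CAZyme within seven genes), CAZyme runs without an anchor, and
GT-only clusters beside an anchor. Features are placed best-fit with at
least eight background genes of padding, so planted features cannot
interact; impossible requests raise a capacity error.

`generate_hit_tables()` writes hit scores that always satisfy their
pass/fail intent: true labels get filter-passing domain hits (dropped with
probability `fn_rate`) and confirmation-passing search hits; spurious hits
(per-protein probability `fp_rate`) pass the HMM filter but never carry
confirming search evidence, so dual-evidence annotation rejects them while
HMM-only annotation keeps them. A `near_threshold_fraction` places scores
within an order of magnitude (or a few points) of the cutoffs, on the
correct side.

`generate_proteome()` draws lognormal intensities around per-protein base
abundances (natural-log spread 1.5, roughly four orders of magnitude of
dynamic range); `cv` sets replicate scatter; effect proteins are multiplied
by `effect_fold` in the first condition; missingness is uniform at random —
deliberately the simplest testable model, *not* intensity-dependent
missingness as in real label-free data. `generate_arrays()` multiplies
targeted cells by `1 − deletion_depth` before replicate noise; the buffer
control is never deleted.

None of the generators simulate sequences, spectra, or biologically
structured noise. Passing tests therefore demonstrate that the *rules* are
implemented exactly and behave correctly under controlled violations; they
do not demonstrate robustness to the error modes of real annotation
pipelines (fragmented assemblies, chimeric proteins, intensity-dependent
missingness, antibody cross-reactivity).

## Numerical and engineering choices

* All generators restore the caller's RNG state; identical configuration
  and seed give byte-identical outputs (tested).
* Deterministic tie-breaks everywhere: e-value then coverage then profile
  name in overlap resolution; left-most then closest in anchor pairing;
  e-value then lexicographic subject id in best-hit selection; radix
  ordering avoids locale-dependent sorts.
* Zero intensities are treated as missing before log transform (with the
  raw-scale mode untouched); all-zero samples and all-zero array datasets
  are errors naming the offender.
* Problem sizes in the checks — 100 seeded genomes of 2 × 60 genes, 4.8 M
  exhaustive flank arrangements, 200 null and 50 power repetitions of
  1000 × 6 matrices — run in roughly three minutes in total and were
  chosen as the smallest sizes at which the estimates stabilize.
* Exchange formats: flat TSV gene tables (GFF3 via `rtracklayer`
  available), HMMER3 `--domtblout` dialect, BLAST tabular (`6 std qcovs`
  plus a subject-family column), TSV matrices with a sample-metadata
  sidecar, truth and manifests as JSON, configurations as YAML.

## Known limitations

* The mining operates on gene order; base-pair distances, operon structure
  and regulator binding sites are out of scope.
* Synteny conservation is directional (fraction of *reference* genes
  matched); swap the arguments for the reverse view.
* The permutation FDR is the plain pooled estimator; no variance
  moderation (S0-style fudge factors) is applied, with the power
  consequences quantified above.
* Full-scale database screens (hundreds of assemblies, real dbCAN/CAZy
  runs) are supported through the hit-table interfaces but are not part of
  the test surface.
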