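# thyt1

Copy-number profiling and the THYT1 prognostic signature in papillary
thyroid carcinoma (PTC).

Most PTCs are indolent, but the subset that develops distant metastases
(DM) carries most of the disease's mortality. Genome-wide SNP-array
profiling of DM versus non-metastatic control tumors shows that DM PTCs
carry a moderately elevated copy-number alteration (CNA) burden and,
above all, three recurrent lesions: duplication of the Chr1q arm,
duplication of a Chr5p region harboring the *TERT* locus, and *TERT*
promoter hotspot mutations (C228T/C250T). The presence of **any one** of
these three alterations defines positivity for the **THYT1** signature
(*Thyroid TERT Chr1q*), which is strongly associated with metastatic
behavior and independently predicts shorter overall survival
(hazard ratio ≈ 7.3 in the metastatic group).

This package re-implements that analysis as a tested pipeline:

- **Segmentation** — per-chromosome Gaussian-emission HMM over
  copy-number levels (Viterbi decoding in C++), per-probe breakpoint
  prior 10⁻⁷, minimum 10 probes per segment, and iterative quadratic
  wave correction.
- **Calling** — segment mean-LRR bands (> 0.1 duplication, > 0.7
  amplification, < −0.15 hemizygous deletion, < −1.1 homozygous
  deletion); allelic ratio r = |2·BAF − 1| with heterozygous imbalance
  at r > 0.4 and LOH when ≥ 85% of probes have r > 0.8 over ≥ 500 kb.
- **Burden** — per-class relative length (% of covered autosomal
  genome) and event counts per sample.
- **Differential regions** — per-probe Fisher exact tests between
  groups with Benjamini–Hochberg adjustment (adjusted p < 0.05),
  frequency ≥ 25% in the more frequent group, and between-group
  difference ≥ 15%, gains and losses tested separately.
- **Signature & statistics** — THYT1 scoring with explicit handling of
  unassessed features; variant-support filtering (both strands, ≥ 10
  reads, ≥ 5% of reads); MSI classification (MSS / MSI-L / MSI-H at the
  30% unstable-marker rule on a 13-marker panel); Fisher/chi-square
  contingency tests; Kaplan–Meier, log-rank, and Cox proportional
  hazards (Efron ties) with stage/histology/gender adjustment.
- **Synthetic cohorts** — a first-class generator that plants arm and
  locus events at the published group frequencies (DM: 35.3% Chr1q
  dup, 23.5% TERT dup, 40.6% TERT mutation; controls: 3.3%, 0%, 3.4%),
  couples Chr9q loss to Chr1q duplication, emulates probe-level
  LRR/BAF with Gaussian noise, and draws survival times with a
  7.29-fold hazard for THYT1-positive samples — so every stage of the
  pipeline is testable without any external data. An ingest path for
  SEG-format segment tables (e.g. TCGA level-3 copy number) is
  included.

## Worked example

The numbered drivers under `analysis/` run the full study emulation on
a desk-scale mini-genome (300 Mb, 6 chromosomes with analogues of
1, 5, 9 and 17; ~30,000 probes at 10 kb spacing; 34 DM + 61 controls):

```sh
Rscript analysis/01_simulate.R        # cohort tables under results/analysis/
Rscript analysis/02_segment_call.R    # calls.seg, burden.tsv, signature.tsv
Rscript analysis/03_differential.R    # regions.tsv / regions.bed
Rscript analysis/04_signature_stats.R # contingency.tsv
Rscript analysis/05_survival.R        # survival.tsv, KM tables
```

A run prints, among other things:

```
gain chr1:30.0-60.0 Mb  DM 42% vs control 3% (adj p <= 1.2e-05)
gain chr5:0.0-25.0 Mb   DM 37% vs control 3% (adj p <= 1.2e-05)
loss chr9:20.0-50.0 Mb  DM 36% vs control 2% (adj p <= 0.00015)

thyt1_positive  DM 27/34 (79.4%)  control  4/61 ( 6.6%)  p = 2.88e-13

log-rank THYT1 +/-: chi2 = 8.69, p = 0.003208
thyt1_positive  univariate   HR  5.39 (95% CI  1.57-18.48)  p = 0.00742
thyt1_positive  multivariate HR  8.16 (95% CI  2.11-31.65)  p = 0.00238
```

i.e. the differential analysis recovers exactly the three planted
loci (1q gain, 5p gain spanning TERT, 9q loss) and nothing else; THYT1
separates the groups; and the Cox model recovers a hazard ratio
consistent with the generating value of 7.29 (sampling noise at
n = 34 moves individual estimates; the acceptance script quantifies
recovery over 100 replicates). Equivalent programmatic entry points:
`run_pipeline()` for the whole chain and `make_report()` for a text
summary.

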