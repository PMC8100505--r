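# hlaRemodel

Cytokine stimulation — interferon-γ in particular — remodels which peptides a
tumor cell displays on its HLA molecules: more peptides, longer class I
ligands, a shift toward HLA-B allotypes, class II display switched on, and
broader coverage of individual source antigens, none of it well predicted by
transcript or protein abundance. `hlaRemodel` implements that comparative
analysis as a tested R pipeline for untreated-vs-treated immunopeptidome
studies (two conditions, replicated, with matched transcriptome and
proteome), paired with a synthetic-data generator that emits complete study
inputs with ground-truth labels so every stage is validated by parameter
recovery.

It is written for computational immunologists / proteomics analysts working
with post-identification artifacts: per-replicate peptide tables (PEAKS-style
TSV/CSV exports), a proteome FASTA, feature × sample quantification matrices,
an antigen panel and an optional protein half-life table.

## What it computes

* **Presence and overlap** — replicate-aware presence calls per distinct
  sequence; union-based partition into *common* / *unique to untreated* /
  *unique to treated* (the three percentages sum to 100), plus the shared
  fraction relative to each condition's own repertoire.
* **Length statistics** — class I (8–12) and class II (13+) length
  distributions; two-way fixed-effects ANOVA of per-replicate proportions,
  length × condition, with Bonferroni per-length contrasts.
* **Binding** — a pluggable predictor. Built-in: per-allele, per-length PSSM
  with log₂ odds `log2(((c + κ·b)/(n + κ))/b)` and percentile rank
  `100·(1 + #{background > score})/(1 + N)` against a calibrated background
  sample; binder at rank ≤ 2; best-allele (argmin rank) attribution with
  per-locus shares. External predictor ranks can be supplied as TSV and give
  identical calls.
* **Motif deconvolution** — annealed Gibbs sampling of 9-mers into motif
  clusters, maximizing summed Kullback–Leibler information of cluster PSSMs
  against background.
* **Source proteins and antigens** — exact substring mapping (I/L
  equivalent) with 0-based half-open match intervals; per-protein distinct
  peptide counts, interval-union coverage %, and
  `mean over replicates of log2(1 + Σ MS1 intensity)`; peptides-per-protein
  histogram (bins 1, 2, 3, 4, 5, 6–20, 21+); source-protein overlap; antigen
  panel cross-reference with per-antigen `log2((n_treated+1)/(n_untreated+1))`.
* **Multi-omics integration** — simple differential expression (log₂ CPM +
  0.5 offset or log₂(1+intensity), pooled-variance t, Benjamini–Hochberg,
  FDR < 0.05); peptides-per-protein fold change with +1 pseudocount binned
  into *decreased* (< 0.5), *unchanged* (0.5–1.5), *increased* (> 1.5);
  Pearson correlations between peptidome, transcript and protein fold
  changes; protein half-life correlations including the 100 fastest-degrading
  and 100 most stable proteins.

## Worked example

```r
library(hlaRemodel)

rc <- make_fixtures("paper_like", seed = 20210422, dir = "results/inputs")
report <- run_pipeline(rc)       # writes TSVs + summary.json to rc$out_dir
s <- report$summary
```

The `paper_like` preset simulates ~15,000 class I peptides per untreated
replicate with a 1.85-fold treated increase, 37.5 % of the class I union
shared, an HLA-B share rising from 0.33 to 0.60, and weak omics couplings
(r = 0.2 transcript, 0.08 protein, 0.275 transcript–protein). The run above
prints, via the numbered drivers in `analysis/`:

```
distinct class I sequences: 34525
common 37.4% | unique treated 51.8% | unique untreated 10.8%
class I treated/untreated per-replicate ratio: 1.85
treated locus shares:   A 0.242   B 0.599   C 0.159
mean coverage of shared proteins: 8.33% -> 15.04% (1.81-fold)
significant at FDR < 0.05: 2797 transcripts, 2602 proteins
transcript vs protein fold-change correlation:      r = 0.262
peptidome vs transcriptome / proteome correlations: r = 0.202 / 0.093
half-life vs peptide count (all, untreated):        r = 0.005, p = 0.72
```

Read: the generator's planted effects come back out of the full pipeline —
the shared fraction (37.4 vs 37.5), the count multiplier (1.85), the treated
HLA-B share (0.599 vs 0.60), the omics couplings (0.202/0.093 vs 0.2/0.08,
0.262 vs 0.275) — and the half-life correlation is null because the
generator draws half-lives independently of presentation. `summary.json`
holds every headline number, all recomputable from the stage TSVs, which
carry a config-hash header; re-running with the same config and inputs is
byte-identical.

The numbered scripts under `analysis/` run the same stages step by step
(`01_simulate_inputs.R` … `06_full_report.R`), each writing its tables under
`results/`.

## Layout

```
R/                  implementation (io, synthetic generator, overlap/lengths,
                    motifs + Gibbs, mapping/antigens, multi-omics, pipeline)
src/                C++ multi-pattern substring search (Rcpp)
analysis/           numbered narrative drivers over the package
scripts/            acceptance.R
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (models, assumptions, design choices)
```
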