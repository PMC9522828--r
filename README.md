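# cfalpha

Read-level methylation marker discovery and stacked-ensemble
classification for cell-free DNA (cfDNA) liquid biopsies.

## The problem

Tumors shed DNA into blood plasma, but tumor-derived fragments are a small
minority of circulating cfDNA. Conventional differential-methylation
analysis compares the population-average methylation rate at a CpG site
(the β-value) between groups and loses sensitivity exactly when the tumor
fraction is low. This package implements the read-level alternative: each
sequenced fragment gets an **α-value** — the fraction of methylated CpGs
among all CpG sites the read covers,

α(read) = #methylated CpGs / #covered CpGs,

and tumor signal is sought as a *well-separated component* of the per-region
α distribution rather than as a shift of its mean. Because methylation is
pervasive along a DNA molecule, a read from a hypermethylated tumor allele
has α near 1 even when 99% of overlapping reads are unmethylated background.

The package is aimed at method developers and computational biologists who
need a complete, testable desk-scale implementation of this pipeline:

1. **Marker unit regions** — in-silico MspI digestion (`C|CGG`) of a
   reference; regions are the intervals between adjacent cut sites shorter
   than 350 bp, the natural units of an RRBS-style assay.
2. **Marker discovery** — for a candidate region and direction, a grid
   search learns the α threshold (α_hyper or α_hypo) that maximises the
   number of case/control pairs whose directional read counts are enriched
   by a one-sided Fisher exact test; candidates must be supported by at
   least 2/3 of pairs and survive filtration against reserved reference
   noncancer plasma. Four marker families are built: cancer-specific
   hyper/hypomethylation (tumor vs adjacent-normal tissue, merged across
   cancer types) and tissue-specific hyper/hypomethylation (normal tissue
   vs normal tissue).
3. **Feature profiles** — per sample and marker, the directional read count
   at the marker's own learned threshold, normalised and log-transformed:
   `value = ln(1e9 · count / raw_read_count + 1)`.
4. **Stacked ensemble** — level 1: one linear SVM (L2 penalty, C = 1) per
   marker family; level 2: a 2000-tree random forest on the stacked,
   cross-fitted level-1 outputs. Detection is binary; tissue-of-origin
   (TOO) is one-vs-rest with a confidence gate: a type is called only when
   the fold change between the top two membership probabilities is ≥ 2.5.
5. **Evaluation protocol** — 10 random 75/25 splits with 30 noncancer
   plasma samples re-reserved per run for marker filtration; AUROC,
   sensitivity at one false positive, TOO accuracy and accumulated
   confusion matrices, with percentile 95% CIs across runs.
6. **Synthetic methylomes** — a beta-binomial generator plants
   differentially methylated regions into paired tumor/normal tissues and
   builds plasma as tumor/background read mixtures, so every stage is
   testable without restricted patient data.

## Worked example

```r
library(cfalpha)

# a synthetic study: 4 cancer types, 20 tissue pairs each, 200 regions,
# plasma at 10% tumor fraction
cohort <- simulate_cohort(sim_config(seed = 42))

# full random-split validation (marker re-discovery per run)
res <- run_pipeline(cohort, n_runs = 3, seed = 11)
res$runs
#>      run     auroc sensitivity_at_fp specificity too_accuracy too_no_call_frac
#>    <int>     <num>             <num>       <num>        <num>            <num>
#> 1:     1 1.0000000         1.0000000        0.95    0.8571429        0.5333333
#> 2:     2 1.0000000         1.0000000        0.95    1.0000000        0.6000000
#> 3:     3 0.9466667         0.9333333        0.95    1.0000000        0.8000000
```

Per run: `auroc` is the test-set area under the ROC curve of the detection
ensemble; `sensitivity_at_fp` the fraction of test cancer plasma detected
while allowing a single false positive among the test noncancer samples
(`specificity` = 19/20 here since one of 20 test negatives is conceded);
`too_accuracy` the fraction of confidence-gated tissue-of-origin calls that
name the correct cancer type, and `too_no_call_frac` the fraction of test
cancer samples the 2.5-fold confidence gate leaves uncalled.

Lower-level entry points mirror the pipeline stages: `digest_reference()`,
`build_distributions()`, `discover_markers()` / `build_marker_panels()`,
`build_profile_views()`, `train_stacked()`, `predict_detection()`,
`predict_too()`. A thin command-line wrapper with `digest`, `simulate`,
`discover` and `pipeline` subcommands is installed at
`inst/cli/cfalpha.R`.

## Scope

Upstream read processing (trimming, bisulfite alignment, UMI
deduplication, methylation calling) is out of scope: the package consumes
per-read methylation summaries (sample, fragment interval, methylated /
total CpG counts) in a plain TSV, one row per deduplicated fragment.
β-value analyses, annotation enrichment, and cross-platform transfer are
likewise out of scope. See the methods vignette
(`vignettes/cfalpha-methods.Rmd`) for the model, its assumptions, and the
design decisions.
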