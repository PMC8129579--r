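# patternseq

Function-based temporal pattern analysis of staged RNA-seq time courses.

`patternseq` is for researchers studying how a cell type matures through an
ordered series of developmental stages — the motivating system is pancreatic
β-cell maturation, profiled from sorted embryonic endocrine progenitors
(the baseline population, which expresses no β-cell genes) through neonatal
stages to adulthood, with a few biological replicates per stage. It answers
two questions: *which genes change relative to the progenitor baseline*,
and *when and how, organized by biological function*.

## The method

1. **Selection.** After filtering (replicate-averaged count ≥ 10 in at
   least one stage) and log2 transformation (zeros kept at 0), each gene's
   baseline-subtracted mean profile d(x₁..x_T) is scored by its **bounded
   area** A = ∫|d(x)|dx on the unit-spaced stage axis. A is tested against
   a **log-normal null** ln A ~ N(μ, σ) fitted from replicate-vs-mean
   deviation areas (published values: μ = 1.09, σ = 0.44). Genes with
   Bonferroni-adjusted p < 1% are **seeds**; unadjusted p < 1% gives
   **candidates**.
2. **Temporal Patterns (TPs).** Within each functional term (GO/pathway,
   GMT input), seed and candidate profiles are clustered by template
   regression (join when R² ≥ 0.8 with positive slope). Every TP keeps at
   least one seed; candidates are rescued into the DE list only through a
   TP. GO terms are processed leaves-first, removing clustered genes from
   ancestor terms (redundancy reduction).
3. **Time breaks and Main Patterns (MPs).** A stage is a TP's break when
   the change to an adjacent stage exceeds 20% of the pattern mean
   |TP|; the main break maximizes |TP(x)|. TPs sharing a break are
   summarized into MPs, classified **positive/negative** by the sign at
   the break.
4. **Enrichment.** One-sided Fisher tests of category membership for MP
   gene groups — by sign alone and by sign × break group (embryonic /
   nascent / older) — with Benjamini–Hochberg FDR within each case family,
   significant at q < 5%.

A synthetic-data module plants step/ramp/pulse/decay genes with known break
stages and signs, with replicate noise calibrated so deviation areas follow
the log-normal null exactly, making the whole pipeline testable end to end.

## Worked example

```r
library(patternseq)
cfg <- sim_config(n_genes = 500, frac_de = 0.25, effect_log2 = 8,
                  shape_mix = c(step = 1, ramp = 0, pulse = 0, decay = 0),
                  n_terms = 12, term_size = 10, term_purity = 1, seed = 42)
fix <- simulate_to_dir(cfg, "fix")
res <- run_pipeline(pipeline_config(
  counts = fix$counts, gmt = fix$gmt, hierarchy = fix$hierarchy,
  category_map = fix$category_map, out_dir = "out", seed = 42))
#> [patternseq] 500 of 500 genes pass the expression filter
#> [patternseq] 70 seeds, 37 candidates
#> [patternseq] 10 temporal pattern(s), 79 DE gene(s)
#> [patternseq] 6 main pattern(s), 0 unclassified TP(s)
res$null
#> null_model: ln(area) ~ Normal(1.0536, 0.4790), n = 1500
```

The fitted null recovers the generating parameters (1.09, 0.44) from 1,500
replicate deviation areas. `out/mps.tsv` shows the planted structure — MPs
split by break stage and sign, e.g.:

```
mp_id  time_break  sign      tp_count  gene_count
MP001  2           negative  2         11
MP002  2           positive  1         10
MP003  3           negative  3         11
...
```

and `out/enrichment.tsv` recovers the planted category signal: the step-up
category is enriched among positive-MP genes (a = 30 of the 30 recovered
members, p = 1.8e-22, q = 5.4e-22), the step-down category among negative
(p = 7.6e-23), with timing resolved by break group (e.g.
`positive_nascent × CAT_step_pos`, p = 1.1e-11).

Interpretation: seeds/candidates are the area-significant genes; each TP is
one term's coherent expression program; an MP is a maturation-stage-anchored
program across terms — "positive, break at stage 5" reads as *activated in
older β cells*.

## Command line

```sh
Rscript -e 'patternseq::patternseq_cli()' simulate --out fix --seed 1
Rscript -e 'patternseq::patternseq_cli()' run --counts fix/counts.tsv \
    --gmt fix/annotations.gmt --hierarchy fix/hierarchy.tsv \
    --category-map fix/categories.tsv --out out
```

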