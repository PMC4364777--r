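---
title: "Calling escape from X inactivation: model, thresholds and validation"
author: "xciescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling escape from X inactivation: model, thresholds and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciescape)
```

## The problem

In female mammals one X chromosome is transcriptionally silenced (X
chromosome inactivation, XCI), but a minority of X-linked genes keep
expressing from the inactive X (Xi). In an F1 cross between two mouse
species - or in a cell line selected for a fixed inactivation pattern -
XCI is completely skewed and the two parental alleles differ at dense
SNPs, so an RNA-seq read carrying diagnostic SNPs can be assigned to the
Xi or the Xa. The question "does gene *i* escape XCI?" then becomes a
question about the proportion of its allele-specific reads that come from
the Xi.

## The model

For gene $i$, let $n_{i0}$ and $n_{i1}$ be the allele-specific read
counts assigned to the Xi and Xa, $n_i = n_{i0} + n_{i1}$. We model

$$n_{i0} \sim \mathrm{Binomial}(n_i,\; p_i),$$

where $p_i$ is the expected Xi read proportion, estimated by
$\hat p_i = n_{i0}/n_i$ with the Wald interval
$\hat p_i \pm z_{\alpha/2}\sqrt{\hat p_i(1-\hat p_i)/n_i}$ and
$z_{\alpha/2}$ the $100(1-\alpha/2)$-th standard-normal percentile.

Alignment to the two parental genomes is not perfectly symmetric. The
residual **mapping bias** is measured per experiment on the autosomes,
which are biallelically expressed: $r_m = N_{A0}/N_{A1}$, the ratio of
autosomal allele-specific reads mapped to the Xi-containing versus the
Xa-containing genome. The bias-corrected estimate is

$$\bar p_i = \frac{n_{i0}}{n_{i0} + r_m\, n_{i1}}
          = \frac{\hat p_i}{\hat p_i + r_m\,(1-\hat p_i)} = f(\hat p_i),$$

and the confidence limits are corrected with the same map $f$. Since $f$
is strictly increasing for every $r_m > 0$ and fixes 0 and 1, the
transformed limits remain ordered and the sign of the lower limit is
unchanged; at $r_m = 1$ everything reduces to the uncorrected form.
Reported limits are clipped to $[0,1]$, but the pre-clip lower limit is
kept for the escape test below, which compares it strictly against zero.

A gene is called **escape** in a sample when all three criteria hold:

1. the $99\%$ lower confidence limit of $p_i$ is greater than zero
   ($\alpha = 0.01$) - significant Xi contribution;
2. diploid expression RPKM $\ge 1$ - the gene is expressed at all;
3. Xi-SRPM $\ge 2$ (allele-specific Xi reads per 10 million uniquely
   mapped reads) - enough absolute Xi evidence.

Threshold ties are inclusive. Biological replicates are analysed
separately and reconciled afterwards: escape in every assessable
replicate gives the tissue status *escape*, escape in a strict subset
gives *variable*, in none *subject*. Across tissues, genes escaping in
at least two tissues form **group 1** (common escape); genes escaping in
exactly one tissue with no escape (not even variable) anywhere else form
**group 2** (tissue-specific escape); variable genes join neither group.

```{r}
fit <- xci_fit(table1_counts(), r_m = 1)
summary(fit)
```

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `alpha` | 0.01 | - | 99% interval; only the lower limit is tested, but $z_{\alpha/2}$ uses the two-sided convention of the interval definition |
| `rpkm_min` | 1 | RPKM | expression floor; below it the escape question is moot |
| `xi_srpm_min` | 2 | reads / 10M | guards against calls driven by one or two stray Xi reads |
| `mapq_min` | 30 | MAPQ | read-segregation quality floor ("uniquely mapped, high quality") |
| `r_m` | estimated | ratio | autosomal allelic ratio; near but rarely equal to 1 |
| peak `alpha` / `both_min` | 0.05 / 0.25 | - | exact binomial tail cutoffs for allelic peak preference |
| `window`, `step` | 500 kb, 1 kb | bp | sliding-window scan geometry for Xi-peak clusters |
| scan `cutoff` | 0.01 | - | per-window Poisson upper-tail cutoff |
| promoter flanks | ±1 kb / ±500 bp | bp | promoter-peak exclusion / promoter signal windows |

Two per-gene overrides mirror cases that arise in practice and are
applied only to the genes named in an `overrides` table: counting
intronic allele-specific reads for genes whose exons are SNP-poor
(`count_scope = "exonic+intronic"`, e.g. a lncRNA with mostly intronic
SNPs), and relaxing the MAPQ floor for genes whose exons are shadowed by
a near-identical paralogous region, which depresses MAPQ without making
the reads ambiguous at diagnostic SNPs.

## Decisions where the design was open

* **"Corrected accordingly".** The confidence limits are corrected by
  applying $f$ to the uncorrected Wald limits. $f$ is the model's own
  correction map and is order-preserving, so the corrected interval is
  exactly the image of the uncorrected one; in particular the escape
  decision "lower limit $> 0$" is invariant under the correction.
* **Wald, not exact.** The interval is the Wald form by construction of
  the model; a Clopper-Pearson option (`exact = TRUE`) exists for
  sensitivity analysis and is off by default. With $n = 0$ a gene is
  *unassessable* rather than an error, and `min_n` can raise that bar.
* **The unnamed tail gap in peak classification.** BL6-preferred needs an
  upper tail $< 0.05$, spretus-preferred a lower tail $< 0.05$, and
  both-preferred needs *both* tails $\ge 0.25$. A peak whose minimum tail
  falls in $[0.05, 0.25)$ satisfies none of the three definitions; such
  peaks are labelled `ambiguous` and kept out of the preferred sets
  rather than silently dropped, so downstream densities are computed on
  an explicitly defined set.
* **Chromosome-appropriate backgrounds.** X-linked peaks are tested
  against the pooled X background $p_X$ (skewed XCI makes the X unlike
  autosomes); autosomal peaks against the autosomal analogue.
* **Which peaks the cluster scan sees.** Xi-preferred and both-preferred
  peaks jointly, since both carry Xi binding; a `faces` argument selects
  other sets.
* **Cluster boundaries.** Significant windows (500 kb wide at 1 kb
  steps) are merged by overlap into runs; the run's window union
  necessarily overhangs the enriched region by up to half a window on
  each side. Because the object of interest is the merged set of
  *peaks*, the default cluster interval is trimmed to the span of the
  peaks inside the run (`bounds = "peaks"`); `bounds = "windows"`
  reports the raw union. The scan's $\lambda$ is the mean window count
  (Poisson MLE over all windows of the scanned chromosome).
* **No multiple-testing correction across windows.** The scan applies a
  plain per-window cutoff of 0.01. This controls no family-wise rate;
  on long chromosomes occasional false windows are expected, which is
  why the toy validation chromosome is kept short (below). An optional
  Benjamini-Hochberg flag is deliberately absent from the default path.
* **Co-localization background.** The deterministic default compares
  escape genes against *all* supplied non-escape X genes; a
  `mode = "sampled"` draws a fixed-size random background under a
  recorded seed. Overlap means gene body intersects a cluster interval.
* **Single-replicate tissues.** A tissue with one (possibly pooled)
  sample takes that sample's call directly as escape/subject; *variable*
  requires at least two assessable replicates disagreeing.
* **Mapping-bias inputs.** `compute_mapping_bias()` uses every autosomal
  allele-specific count it is given; restricting to exonic counts is the
  caller's choice of input rows.
* **Reads spanning several genes** count for each overlapped gene; the
  multi-gene fraction is logged. Conflicting-SNP reads (matching both
  parents) indicate mismapping or genotyping error and are excluded from
  allele-specific counts.

## Numerical conventions

Coordinates are 0-based half-open internally; SNP tables are 1-based
(VCF-like); BED output is 0-based half-open. Promoter and metagene
windows are half-open, $[\mathrm{TSS}-f, \mathrm{TSS}+f)$ in the
direction of transcription and mirrored exactly for minus-strand genes,
so boundary cases are bit-reproducible and profiles are invariant under
mirroring the coordinate system. Window membership in the scan is by
peak midpoint, so a peak is counted at most once per window despite the
500:1 window/step overlap. All report tables are written with 6
significant digits and a header naming the configuration hash.

## What the synthetic generator emulates

`sim_config()` / `sim_xci_dataset()` generate toy data with known ground
truth under one master seed, each stage drawing from a sub-stream keyed
by `(seed, stage)` so outputs are byte-stable and adding a stage never
perturbs another.

* **Expression:** per-gene expected allele-specific depth log-uniform
  over `n_range` (default 100-10,000 reads), Poisson totals, binomial
  Xi counts. Escape genes (default 10% of X genes) draw
  $p_i \in [0.03, 0.5]$ - a few percent to half of the Xa level -
  silenced genes have $p_i = 0$ exactly.
* **Mapping bias** acts on the odds scale: the observed proportion is
  $p' = r_m p/(r_m p + 1 - p)$ (default $r_m = 1.1$). On autosomes
  ($p = 0.5$) this reproduces an observed ratio of $r_m$, so the
  estimator closes the loop; at $p = 0$ it leaves $n_0 = 0$, so bias
  alone can never fabricate Xi expression.
* **ChIP peaks:** a uniform background at 8 peaks per 500 kb (about
  genome-wide CTCF peak density) on a 1.75-Mb toy chromosome, with one
  planted 500-kb cluster at 6x density whose peaks carry Xi-skewed
  allele counts (0.9) against a balanced (0.5) background. The toy
  chromosome is short on purpose: the uncorrected 0.01-cutoff scan
  spans only a few window-widths there, keeping its family-wise
  false-cluster rate under the nominal level so a null dataset cleanly
  yields zero clusters.
* **Promoter signal:** Gaussian read pile-ups (sd 300 bp) at each TSS,
  Xa at a common depth and Xi scaled by $p_i$.

Passing tests on these data show that the estimator, the calling rules,
the peak tests and the scan behave as designed under the assumed model.
They do not show robustness to what the generator omits: overdispersion
beyond binomial/Poisson, allelic mapping artefacts localised to
particular SNPs, gene-length and GC effects, correlated replicates, or
reference/annotation errors - on real data those enter through `r_m`,
the filters, and upstream alignment quality.

## Validation problem sizes

The shipped test-suite and acceptance script validate at sizes chosen to
make the statistical checks sharp yet quick: 10,000 binomial draws for
interval coverage ($n = 500$, $p = 0.2$; observed coverage about 98.9%
against the 98% floor the Wald form is held to); 10,000 null peaks for
test-level calibration; 100 generator seeds each for planted-cluster
recovery (Jaccard $\ge 0.5$ against truth) and for null scans; and an
end-to-end dataset of 200 X genes, 100 autosomal genes, two replicates
at $r_m = 1.1$, on which escape sensitivity is measured over truth
escapers with $p_i \ge 0.05$ and $n \ge 500$ and specificity over
silenced genes. A 500-gene closure check verifies that the corrected
interval covers the true simulated $p_i$ for at least 97% of genes with
$n \ge 200$ and $p_i \in [0.05, 0.95]$.

## Known limitations

* The Wald interval is anti-conservative at small $n$ and extreme $p$;
  the SRPM filter removes most such cases from calling, and the exact
  option quantifies the remainder.
* $r_m$ is a single per-experiment scalar; locus-specific mapping bias
  is not modelled.
* The scan fits one global Poisson rate per chromosome; a locally
  varying background (e.g. mappability) would need a covariate-aware
  rate.
* Group classification takes tissue statuses at face value; it does not
  propagate per-call uncertainty.
* The packaged three-tissue table carries replicate-averaged SRPM
  values, so refitting it reproduces the published per-gene worked
  examples but not per-replicate bookkeeping (e.g. variable-escape
  labels that depended on individual replicates).
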