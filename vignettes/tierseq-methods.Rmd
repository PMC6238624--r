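---
title: "Mapping endoribonuclease cleavage sites from differential 5' end coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endoribonuclease cleavage sites from differential 5' end coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experimental logic

RNase E is the essential single-strand-specific endoribonuclease that
initiates most mRNA decay in Gram-negative bacteria. Every internal cut it
makes leaves a new monophosphorylated 5' end, so in 5'-end sequencing data
(one count per read at the genomic coordinate of the read's biological 5'
end, "first-base-in-read coverage") cleavage products appear as sharp
single-nucleotide signals. Transiently inactivating the enzyme — here via a
temperature-sensitive allele shifted to the nonpermissive temperature —
inverts the signal in two informative directions:

* **cleavage sites**: 5' ends *depleted* in the mutant relative to the wild
  type. These positions exist because the nuclease cuts there.
* **enriched sites**: 5' ends *enriched* in the mutant. These are primary
  transcript 5' ends, or products of other nucleases, that are normally
  consumed by 5'-end-dependent RNase E decay and become stabilized when the
  enzyme is off.

`tierseq` implements the complete desk-scale analysis of such an
experiment, from per-library coverage tracks to annotated, motif-summarized
site catalogs, together with a synthetic-data generator that provides
ground truth for every stage.

## The statistical model

Let $K_{ij}$ be the 5'-end count at position $i$ in library $j$, with
condition labels wild type / mutant and $\ge 2$ replicates each.

**Normalization.** Median-of-ratios size factors:
$s_j = \mathrm{median}_{i \in I}\, K_{ij} / g_i$ with
$g_i = (\prod_j K_{ij})^{1/n}$ and $I = \{i : g_i > 0\}$. Normalized counts
are $K_{ij}/s_j$; the *base mean* is their average over all libraries.

**Dispersion.** Counts are modelled as negative binomial with
$\mathrm{Var} = \mu + \alpha\mu^2$. Per position a method-of-moments
estimate $\hat\alpha_i = \max\{0, (v_i - m_i)/m_i^2\}$ is computed from the
grand mean $m_i$ of normalized counts and the replicate-df-weighted pooled
within-condition variance $v_i$ (the standard pooled estimator; the
within-condition pooling keeps genuine condition effects out of the
variance). A mean-dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ is fitted
by least squares over positions with $m_i > 0$, $\hat\alpha_i > 0$, and the
working dispersion is the fixed-weight blend
$\tilde\alpha_i = w\,\alpha(m_i) + (1-w)\hat\alpha_i$ with $w = 0.5$,
floored at $10^{-8}$. This is a deliberate, documented simplification of
the Cox–Reid/MAP machinery in DESeq2-class tools: at three replicates per
condition the moment estimator is noisy and the trend supplies the
stabilization; exact parity with any specific tool is a non-goal, and the
package is validated instead by calibration and recovery on data with known
truth.

**Test.** The effect is
$\log_2\!\mathrm{FC}_i = \log_2(\bar\mu^{WT}_i / \bar\mu^{mut}_i)$
(wild type over mutant, so cleavage sites come out positive). A
pseudocount of $0.5$ enters *both* condition means only when either mean is
zero, keeping single-strain positions finite without perturbing the rest.
The standard error comes from the NB delta method,
$\mathrm{Var}(K_j/s_j) = \mu/s_j + \tilde\alpha\mu^2$, propagated through
the log ratio, and $p$ is two-sided normal on
$\log_2\!\mathrm{FC}/\mathrm{SE}$. Benjamini–Hochberg step-up adjustment is
applied jointly across all filtered positions of all replicons.

## From positions to sites

1. **Coverage filter**: keep positions with raw coverage $\ge$ `min_cov`
   (default 10) in at least one library.
2. **Candidate selection**: fold change $\ge$ `fc_min` (default 2, i.e.
   $|\log_2\!\mathrm{FC}| \ge 1$) and padj < `alpha` (default 0.05); the
   sign selects the class.
3. **Clustering**: endoribonucleases cut imprecisely, especially in
   homopolymer stretches, so candidates of one class on one strand within
   `proximity` = 3 nt are chained (single linkage, `bedtools cluster -d`
   semantics) and each chain is represented by a center.
4. **Annotation**: the center is assigned to one RNA category by
   containment with precedence rRNA > tRNA > sRNA > CDS > 5'UTR > 3'UTR >
   other, densities are reported per feature in sites/kb (zero-site genes
   included), and site frequencies are profiled relative to start and stop
   codons in transcript orientation.
5. **Motif**: ±5 nt windows around centers (reverse-complemented on the
   minus strand) are summarized as count/frequency matrices with per-column
   information content computed as relative entropy against the *genome*
   composition — in a 68.8% GC genome a uniform background would fabricate
   AU enrichment. An iterative ±1-shift alignment ("one base of shifting
   allowed") maximizes the summed log-likelihood ratio; iterations that
   would decrease the objective are rejected, so the trace is monotone and
   termination is guaranteed. Full motif discovery is out of scope: windows
   are exported as FASTA (plus a MEME-minimal matrix) for external tools.

### Design choices the contract left open

* **Cluster center tie-breaks.** The upstream description fixes only "the
  center position of the cluster". We take the member nearest the
  arithmetic mean; ties go to the larger base mean (the strongest signal is
  the best single representative), then leftmost for determinism.
* **Category precedence.** Single-category accounting is implied but the
  rule is not stated. Structural RNAs win over CDS over UTRs so that, e.g.,
  a site in a UTR-derived sRNA is counted as sRNA — consistent with how
  UTR-processed regulators are usually reported.
* **Joint BH.** Adjustment is applied once across all replicons per
  contrast, matching a single significance set per temperature; a
  two-temperature design is two independent runs.
* **Overlapping significance classes.** Wild-type- and mutant-enriched
  candidates often interleave at neighboring nucleotides; the two classes
  are clustered independently and clusters never span classes or strands.
* **Size-factor scale invariance.** Scaling one library by $c$ multiplies
  its size factor by $c$ *relative to every other library*, and leaves all
  fold changes exactly unchanged. The absolute factor moves by
  $c^{(n-1)/n}$ because the geometric-mean reference absorbs $c^{1/n}$ —
  a property of the median-of-ratios definition itself (DESeq2 behaves
  identically); p-values shift only through the weak scale dependence of
  the moment dispersions, bounded in the tests at 2%.

## The synthetic world

The generator states one fixed world per configuration; its defaults
restate the design of the motivating experiment rather than tunable knobs:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 200 kb | one replicon at desk scale |
| `gc_content` | 0.688 | the organism's GC fraction |
| `n_replicates` | 3 | replicates per strain |
| `n_cleavage_sites`, `n_enriched_sites` | 200 / 200 | implanted truth |
| `cleavage_log2fc`, `enriched_log2fc` | 2.5 | true log2 effects |
| `site_mean_wt` | 80 | NB mean on the enriched side of a site |
| `dispersion` | 0.1 | NB $\alpha$ |
| `size_factors` | 1.0, 1.2, 0.8, 1.1, 0.9, 1.05 | true library scales |
| `background_rate` | 0.01/nt/strand | non-differential background ends |
| `noise_rate` | 0.02/nt/strand | 0–2-count noise positions |
| `motif_prob` | 0.8 | AU written at cut offsets 0/+1 |

Genes (optional 5'UTR + CDS + optional 3'UTR) plus sRNA and rRNA features
are placed without overlap on both strands. Cleavage sites are uniform
within transcribed features; enriched sites preferentially sit at feature
5' ends (a stabilized primary 5' end is the canonical mutant-enriched
signal). All sites are $\ge 10$ nt apart so that truth sites map 1:1 to
called clusters. Counts are drawn directly at the 5'-end position level —
the unit under test is the coverage-table-to-sites path, and a read-level
emitter with mapping biases is a declared non-goal. Background positions
follow a spatial Poisson scatter with log-normal NB means (median 20, so a
realistic fraction passes the coverage filter); noise positions draw
uniform 0–2 counts and are mostly removed by the filter, exercising it.

What a green test therefore establishes: calibration (null FDR within the
BH bound), recovery (≥ 80% recall / ≥ 90% precision per class at 2-nt
center tolerance under the stated effects), and motif detection (IC maxima
and AU enrichment at the cut). What it does not establish: robustness to
mapping artifacts, rRNA depletion effects, multi-mapping, secondary
structure, or any claim about counts in the real deposited data set, whose
reproduction requires an external read-mapping stack.

## Numerical notes and limitations

* Coordinates are 1-based inclusive everywhere; only the BED writer
  converts to 0-based half-open.
* The 5' end of a minus-strand read is its rightmost aligned coordinate;
  alignment clipping must be resolved upstream.
* Wiggle I/O is restricted to the `variableStep` dialect with the
  `_forward`/`_reverse` track-name convention; negative values are read as
  reverse-strand magnitudes. `fixedStep` input is rejected.
* With fewer than two usable (mean, dispersion) points the trend fit falls
  back to a flat line at the median raw dispersion (0.01 when none exist);
  this only occurs on degenerate toy tables.
* The Wald test is a plug-in z-test; at two replicates per condition it is
  anticonservative in the extreme tails. The three-replicate default is
  calibrated (empirically $P(p<0.05) \approx 0.03$–$0.07$ under the null).
* `evaluate_recovery` reports precision 1.0 with a flag when nothing is
  called, so downstream tooling need not special-case the zero
  denominator.

## A worked run

```{r, eval = FALSE}
library(tierseq)

sim <- simulate_experiment(sim_config(seed = 7), dir = "sim")
res <- run_all(file.path("sim", "manifest.json"))
ev  <- evaluate_recovery(res$clusters, sim$truth)
ev$summary
```

The same pipeline is available from the command line via
`Rscript inst/cli/tierseq run --manifest sim/manifest.json`.
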