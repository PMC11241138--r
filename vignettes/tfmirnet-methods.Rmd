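---
title: "Methods: TF-rooted miRNA regulatory network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF-rooted miRNA regulatory network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfmirnet)
```

## Scope and model

`tfmirnet` reconstructs how a transcription factor (TF) regulates
genes indirectly through miRNAs. The procedure integrates four layers:

1. **Promoters.** Each transcript or pri-miRNA TSS defines a
   symmetric window `[pos − h, pos + h)` with half-width `h = 2500`
   bp, clipped at chromosome bounds. The window is strand-independent
   and windows are kept per transcript — a gene is "bound" if *any*
   of its transcript promoters is; merging happens on hits, not on
   windows. Mature miRNAs inherit the union of the promoters of all
   their precursors (a mature processed from two pri-transcripts has
   two chances to be bound).

2. **Binding.** A ChIP-seq peak counts for a promoter iff its score
   exceeds `−log10(p) = 3` *and* its overlap exceeds 100 bp, both
   strictly — a peak at exactly 3.0 or exactly 100 bp never counts.
   The per-peak filter is applied before gene-level merging: this is
   the conservative reading where the order of merge and refine is
   ambiguous, and it makes the bound set monotone in both thresholds.
   Histone marks (H3K27ac, H3K4me3) are called by any (≥ 1 bp)
   overlap, since no mark threshold is part of the procedure.

3. **Expression.** Genes pass the expressed filter with TPM > 1 in at
   least one replicate; matures with a normalized count > 1 in at
   least one sample, after per-sample averaging across precursors.
   DE classification is strict on both axes: genes `|log2FC| > 1`
   and `FDR < 0.05`, matures `|log2FC| > 0.5` and `FDR < 0.1`, with
   Benjamini–Hochberg adjustment. Fold changes are oriented silenced
   vs control, so a miRNA "up upon silencing" has positive log2FC.

4. **Network.** For TF-bound differentially expressed miRNAs (DEMs),
   target-map pairs survive iff the fold-change signs oppose
   (`(+,−)` or `(−,+)`; an exact 0 on either side never forms an
   edge). Two networks are emitted: `network_all` keeps all
   sign-opposed differentially expressed targets; `network_bound`
   restricts genes to TF-bound promoters and adds direct TF→gene
   edges. Three strata are reported: the anti-correlated target set
   against *all expressed genes* (any sign-opposed fold change), its
   intersection with classified DEGs, and the TF-bound part of that
   intersection — the second and third are the node sets of the two
   networks.

## The stand-in differential-expression test

The pipeline deliberately does not re-implement a count-model DE
tool; external DE tables are accepted as drop-in inputs. For the
self-contained synthetic path, `de_test()` offers:

* `lognormal_t` — median-of-ratios normalization (per sample, the
  median ratio to each feature's geometric mean, zeros excluded),
  then a pooled two-sample t-test on `log2(normalized + c0)` with
  pseudo-count `c0 = 0.5`. `log2FC` is always
  `log2((mean_sil + c0)/(mean_ctl + c0))` on normalized counts.
* `lognormal_limma` — the same transform, with limma's moderated t.

`run_pipeline()` defaults to the moderated test for **both**
contrasts. The rationale is power at the study's replicate counts:
with 2 replicates per condition a per-feature t has 2 degrees of
freedom, and even 3-vs-3 (4 df) both misses large planted effects and
admits the BH-expected tail of false calls when only ~10 of 200
features carry signal. Moderation shares variance information across
features — the same reason dedicated count-model tools pool
dispersion estimates — and is the honest small-sample stand-in. The
plain `lognormal_t` remains the `de_test()` default and is the method
whose null calibration the test suite checks (raw p < 0.05 fraction
within [0.03, 0.07] on 2000 null NB features at dispersion 0.1).

Degenerate cases are fixed by contract: identical groups give
log2FC = 0 and p = 1; zero within-group variance with distinct means
gives p = NA (no within-group evidence); fewer than 2 replicates in a
group yields fold changes only.

## Motif scanning

PFMs are converted to log2-odds with the pseudocount distributed by
background: `log2((n_bj + s·bg_b)/(N_j + s)/bg_b)` with `s = 0.8`.
Windows on both strands are scored by summation; the **relative
score** rescales between the minimum and maximum attainable matrix
scores, the usual PWM-scan convention, so it lies in [0, 1] and the
consensus scores exactly 1 (a plain score/max ratio can go negative
and cannot serve as a bounded threshold). The default hit threshold
is a relative score of 0.80 — a common scanning convention, exposed
in the thresholds object because no scanning scheme is prescribed by
the procedure itself. Windows containing `N` are skipped. The
bundled matrix `SYNTH.CLEAR.1` is a *synthetic* CLEAR-like E-box
palindrome (consensus `GTCACGTGAC`), constructed for simulation and
examples; it is not a database matrix.

## The synthetic study and what it does (not) emulate

`simulate_study()` plants a known network and generates every input
file the pipeline consumes. Defaults encode the study design being
emulated:

| knob | default | why |
|---|---|---|
| replicates | 2 mRNA / 3 miRNA per condition | the emulated design |
| counts | NB, `var = μ + αμ²`, `α = 0.1` | typical bulk RNA-seq dispersion |
| baseline means | log-normal, `meanlog = log 300`, `sdlog = 1.2` | spans silent to abundant |
| silent genes | 10% near-zero baseline | exercises the TPM filter |
| DE fractions | 4% of genes, 5% of matures | matches the reported strata ratios (~424/11451, 33/657) |
| planted effects | uniform 1.2–3 log2 units, signed | detectable but not trivial |
| bound fractions | 50% genes, 45% pri-miRNAs | matches reported bound ratios |
| repression coupling | 1.5 log2 units on the target, sign-opposed | makes anti-correlation detectable by construction |
| decoys | 0.5 decoy peaks per true peak; 20 decoy target pairs per mature | peaks that fail exactly one rule; target-map noise |

Every bound promoter receives one peak centred on its TSS (width 400
bp, score uniform 6–60), so binding recovery is exact by
construction; decoy peaks either score ≤ 3 on a promoter, overlap a
promoter by ≤ 100 bp (hung off the left edge of a gene's leftmost
window so they cannot graze a sibling window), or carry a passing
score on a dedicated promoter-free chromosome. Planted effects are
drawn only among features with baseline mean ≥ 20, since DE at lower
counts is not expected to be detectable at these replicate numbers.
Repression targets are drawn from TF-bound, expression-eligible genes
without their own planted effect, so each target's fold change comes
solely from the coupling. One global seed drives a named substream
per generator, so each layer regenerates independently.

What the simulation does *not* emulate: real promoter architecture
(no overlapping genes, no alternative or intronic miRNA promoters),
peak shape and signal-to-noise structure, GC/sequence composition
beyond the embedded motif, correlated library composition effects,
and the heavy-tailed dispersion of real data. Passing recovery tests
therefore validates the *integration logic and thresholds*, not
performance on real sequencing data.

## Numerical and design choices

* All internal coordinates are 0-based half-open; 1-based TSS tables
  convert at the reader boundary (`coordinate_base`), and chromosome
  naming clashes are handled by an explicit rename map at load time.
  The `[−h, +h)` window has length exactly `2h`.
* Interval intersection is delegated to GenomicRanges/IRanges; the
  elementary overlap is `max(0, min(ends) − max(starts))` on matching
  chromosomes, strand ignored.
* Best peak per gene: highest score, then largest overlap, then
  leftmost start — a total order making annotations deterministic.
* BH adjustment wraps the stock step-up implementation; NAs pass
  through.
* miRNA DE runs on per-mature aggregated **raw** counts rounded to
  the nearest integer (the averaging step precedes the DE hand-off);
  the normalized matrix is used only for the expressed filter.
* Mature miRNAs with no precursor in the TSS catalog are flagged and
  treated as unbound rather than dropped.
* Network exports order nodes and edges lexicographically so repeated
  runs are byte-identical; GraphML round-trips through igraph.
* Pipeline test problem sizes: the bundled checks run at 300–2000
  genes and 40–100 pri-miRNAs, sizes at which every stage's behaviour
  (filters, merging, recovery) is already fully exercised.

## Known limitations

Distal (enhancer) binding is out of scope — only promoter windows are
annotated, although in real data most TF peaks fall outside
promoters. The anti-correlation rule is sign-only; it does not weigh
effect sizes or target-site strength. The stand-in DE test is not a
dispersion-modelled count test and should be replaced by DESeq2-style
output (via `gene_de`/`mirna_de`) for real data. miRNAs with
alternative promoters are represented only through the precursors
present in the TSS catalog.
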