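---
title: "Detecting hierarchical DCC recruitment sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hierarchical DCC recruitment sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dccrex)
```

## The scientific problem

In *C. elegans* hermaphrodites the dosage compensation complex (DCC), a
condensin-containing complex, binds both X chromosomes and halves their
transcriptional output. Binding is organized as recruitment plus spreading:
a limited set of *recruitment sites* (rex sites) nucleates binding, and the
complex then spreads in cis, confined within chromosomal domains delimited
by TAD boundaries. Recruitment sites form a hierarchy of strong,
intermediate and weak classes; strong sites carry homotypic clusters of a
12-bp sequence motif and act first, enabling binding at weaker sites.
`dccrex` implements the computational side of that analysis: ChIP
enrichment processing, recruitment-site detection and classification, motif
affinity scanning, deletion-effect statistics, and the supporting
permutation and qPCR statistics, together with a synthetic-data generator
that makes every stage testable without external data.

## ChIP enrichment model

Per-base coverage from ChIP and matched input is each divided by its own
genome-wide median (mitochondrial chromosome excluded), and enrichment is
the difference of the normalized tracks; values can be negative where input
exceeds ChIP. For strains whose X-to-autosome coverage ratio is altered,
medians are computed separately for the X and the pooled autosomes
(`separate_x = TRUE`) and recombined after normalization. Replicates are
merged by the positionwise arithmetic mean.

Peak sets pass a strict majority rule: a pooled-replicate peak is kept only
when it overlaps (at least 1 bp) a peak in strictly more than half of the
individual replicate sets — for duplicates this means both. Long
multi-summit peaks are split: local maxima at or above a minimum height are
candidate sub-summits, and a cut is placed at the lowest valley between two
candidates whenever the valley drops below a *separation float* (default
0.85) times the smaller summit. When a candidate pair fails the valley
test the pair merges into its taller member before the walk continues;
without this, base-level jitter would nominate spurious adjacent candidates
and true valleys would never be compared between true summits. On noisy
per-base tracks the profile can additionally be smoothed (51-bp running
mean in the pipeline) before candidates are located. The default minimum
height is the median summit height of the peak set; the pipeline instead
uses a floor above the spreading plateau (see below), because
threshold-called peaks on synthetic tracks merge whole domains into single
runs, a regime the median rule was not designed for.

## Recruitment sites

Summit heights of the recruiter protein SDC-2 are modeled as a
two-component univariate Gaussian mixture fitted by
expectation-maximization; the high component captures the small set of
summits with extreme coverage ("foci"). Initialization uses the 25th/90th
percentile split of the data, the likelihood trace is monotone by
construction, and foci are observations with posterior probability of the
high component above 0.5 (ties excluded). As an alternative selection the
`n_top` strongest summits can be taken directly.

Each selected summit nominates a 400-bp window centered on it. The window
becomes a recruitment site when it overlaps at least one SDC-3, one DPY-30,
and one DPY-27 peak, and overlaps no H3K4me3 peak. "No significant H3K4me3
enrichment" is operationalized as zero overlap with the H3K4me3 peak set; a
mean-enrichment threshold over the window is available as a configuration
alternative. The first failing filter is recorded for every excluded
candidate.

Sites are characterized by the mean enrichment of SDC-2, SDC-3, DPY-30 and
DPY-27 over a 3-kb window centered on the summit. k-means with k = 3 and a
fixed seed assigns the strong/intermediate/weak classes, labeled by
descending cluster-mean SDC-2 feature. Whether the original analysis
clustered summary scores or full per-base profiles is not determinate; the
four-feature summary is this package's contract because it is stable at
small site counts and directly interpretable. Ranks order sites by the
descending sum of the four features — a simple symmetric aggregate chosen
so that ranking is reproducible from the exported feature columns.

Windowed comparisons between strains use 200-bp windows at 100-bp steps
across a chromosome, or 40-bp windows centered on site summits; window
means are floored at a pseudo-level (default `1e-3`) before log2 ratios,
and windows clipped at chromosome ends keep their true extent and are
flagged.

## Motif model

The 12-bp recruitment motif is represented as a position weight matrix
built from user-supplied aligned occurrences with a pseudocount (default
0.01); motif discovery itself is out of scope. Scanning uses a biophysical
mismatch-energy occupancy model: for a site $s$,

$$E(s) = \frac{1}{\lambda} \sum_i \ln\frac{p_i(\mathrm{cons}_i)}{p_i(s_i)},
\qquad a(s) = \frac{R_0 e^{-E(s)}}{1 + R_0 e^{-E(s)}},$$

with $\lambda = 0.7$ and $R_0 = \exp(0.584\,w - 5.66)$ for width $w$ —
standard settings for this family of occupancy models. Scores are
standardized to a 0–10 scale by min–max over the analytic extremes, so the
consensus scores exactly 10 and the per-position worst 12-mer exactly 0,
without requiring a genome-wide pass; an empirical mode standardizing over
the scores observed in a scan is provided as an alternative. Both strands
are scored at every start position; the better strand is reported, ties
going to plus, and windows containing N are skipped.

A homotypic cluster is a hit scoring at least 7 flanked within 200 bp
(start-to-start, a determinate and symmetric choice) by at least one other
hit scoring at least 5; clusters sharing members merge. X-versus-autosome
enrichment curves report, per score cutoff, the fraction of hits on the X
divided by the X's share of genome length. Occupancy comparisons average an
intrinsic nucleosome-occupancy track over 150-bp windows centered on group
members and compare groups with one-tailed Welch t-tests; when both groups
are constant and equal the p-value is 0.5 by convention.

## Deletion-effect statistics

For a deletion strain, the log2 ratio of deletion to wild-type mean
enrichment is computed per binding peak (means floored at `1e-3`). A
window (2 Mb at full chromosome scale; 500 kb in the desk-scale pipeline)
is stepped across each peak center; the window mean log2 ratio is
normalized by subtracting the ratio at a designated anchor site — the
strongest recruitment site outside the deleted domain, playing the role of
a positive control — so the anchor's own window sits at exactly 0.
Subtraction in log space is the only normalization that achieves that.
Percent deviation from wild type is $100\,(2^{m'} - 1)$, mapping a log2
ratio of $\log_2 0.8$ to exactly −20%. Each window's member ratios are
compared with the ratios of all X peaks by a one-tailed Welch t-test
(window lower); members stay in the chromosome-wide reference by default,
with exclusion available as a flag. Maximal runs of significant windows
become depleted regions whose edges are the outermost significant window
centers — window extents overlap by construction, so centers give the only
determinate boundary.

Two resolution facts shape how these calls behave. First, a detected
region's edge is blurred by roughly $(q - \tfrac12)\,W$ for window size
$W$ when a fraction $q$ of all X peaks is depleted, because windows mixing
depleted and intact peaks sit between the window mean and the
chromosome-wide reference; edge recovery at peak-spacing resolution
therefore requires a window commensurate with the peak spacing, and the
package's edge-recovery checks run a 20-kb window over a 10-kb peak grid.
Second, with an uncorrected per-window threshold of $p < 0.05$, isolated
significant windows arise by construction at rate $\alpha$ under the null;
a negative-control comparison of two independent wild-type simulations
therefore shows occasional regions *narrower than one window*, but no
window-scale region. The package's null check asserts exactly that, rather
than the absence of any region, which no uncorrected per-window test can
deliver.

The TAD-boundary proximity test sums, over all depleted-region edges, the
distance to the nearest boundary, and compares it with a null in which each
region is independently relocated uniformly at random preserving its length
(the standard region-randomization contract); the empirical p-value uses
the +1 correction and the null distribution of log10 summed distance is
reported without assuming normality. Expression response is tested per
contiguous 500-kb window with a one-sided Fisher exact test of up-regulated
(log2 ratio > 0) genes in the window against the rest of the chromosome.

## Cooperativity statistics

ChIP-qPCR quantification follows
$\Delta\Delta C_t = (C_t^{exp} - C_t^{ctrl})_{ChIP} -
(C_t^{exp} - C_t^{ctrl})_{input}$, enrichment $2^{-\Delta\Delta C_t}$, and
percent endogenous recruitment $100 \times$ ectopic over endogenous
enrichment, computed per biological replicate before summarizing, because
background enrichment varies between replicates. Conditions are compared
with one-tailed unequal-variance t-tests.

The region-overlap permutation test counts annotation elements overlapping
at least one query region and relocates queries uniformly within their own
chromosomes (lengths preserved, collisions permitted, 100 permutations by
default, +1-corrected p-value). Contact-matrix analysis thresholds at a
quantile (default 99%) of the upper-triangle off-diagonal entries — zeros
included and strict inequality at the threshold, the conservative
determinate reading; a nonzero-only flag is available. Two sites interact
when any bin pair between them exceeds the threshold.

## The synthetic-data generator

The generator defines the study conditions under which every downstream
claim is tested. Defaults: five 0.5-Mb autosomes, one 2-Mb X, one 15-kb
mitochondrial chromosome; 16 recruitment sites on the X (4 strong, 4
intermediate, 8 weak) with tier amplitudes 10/5/2 and per-protein
multipliers (SDC-2 1.0, SDC-3 0.8, DPY-30 0.7, DPY-27 1.2); Gaussian peak
kernels (sd 75 bp) plus exponential spreading (decay 50 kb, half the peak
amplitude) truncated at domain boundaries placed every 500 kb; mean-one
log-normal noise (sd 0.2) independent per replicate, three replicates; a
high H3 landscape dipping at sites and H3K4me3 peaks at designated non-site
loci, two of which also carry DCC-like binding to exercise the H3K4me3
exclusion, plus autosomal recruiter-only loci that exercise the DPY-27
filter. Motif instances are planted per tier — scores 10/8/6 within 200 bp
at strong sites, 8/6 at intermediate sites, a single 7.5 at weak sites — by
a dynamic program over per-position substitutions that hits each target
standardized score as closely as the PWM's granularity allows. Peak shape,
spreading form and noise family are the simplest choices with the
qualitative properties the analysis assumes (localized summits, distance
decay confined by boundaries, overdispersed strictly positive coverage);
none is fit to data. Deletion strains multiply DCC signal inside the
deleted site's domain by $1 - d(x)$ with $d$ falling linearly from
`d_max = 0.2` at the site to 0 at the domain edges (a uniform profile is
available for closed-form checks) and remove the deleted site's own peak
and spreading contribution.

What the generator does not emulate: read-level artifacts (mappability,
GC bias, fragment-length effects), sequence-dependent background, biological
replicate correlation, or realistic TAD structure in the contact matrix
beyond power-law decay with site–site bonuses. Passing tests therefore
demonstrate the correctness and internal consistency of the statistics, not
performance on real sequencing data.

## Numerical choices and degenerate inputs

Internal coordinates are 0-based half-open everywhere; conversion happens
only at format boundaries (BED native, wiggle shifted by one). Tracks are
dense per-base vectors, acceptable at desk scale and chosen for the
simplicity of window statistics; absent bases are 0, matching coverage
semantics. Summit and valley ties resolve to the leftmost base. The
mixture EM floors component standard deviations at $10^{-6}$ of the data
standard deviation so point-mass components cannot collapse the
likelihood; all-equal heights are a reported degeneracy, as are fewer than
three distinct feature vectors for k-means. Log2 ratios floor window and
peak means at a configurable pseudo-level ($10^{-3}$) so empty windows
cannot produce infinities. Welch tests where both groups are constant
return 0.5 (equal means) or a directional 0/1 and are flagged. Empirical
permutation p-values always use the +1 correction.

## Pipeline and problem sizes

`run_pipeline()` chains simulation, enrichment, consensus peaks, site
definition and classification, motif scanning, deletion-effect and
cooperativity statistics, writing every table with a parameter-and-seed
header; identical seeds give byte-identical outputs. The demonstration
configuration scales the analysis to the desk-scale genome: top-25
candidate summits (top-100 at full chromosome scale), a 500-kb sliding
window (2 Mb at full scale) with 250-kb/100-kb alternates, 100 overlap
permutations, 10000 TAD permutations, and a 10-kb contact bin. The full
demonstration run completes in roughly two minutes on one CPU; the test
suite uses smaller chromosomes (50–400 kb) for the per-module checks and
the defaults for the end-to-end recovery check.

```{r, eval = FALSE}
res <- run_pipeline(sim_config(), pipeline_config(), outdir = "demo")
res$evaluation
```

## Known limitations

Peak calling on synthetic tracks is threshold-based by design; calling
peaks from read pileups against a background model is out of scope, and
consensus/splitting logic consumes externally called peaks in real
applications. The mixture model is univariate and two-component; heavier
tailed summit distributions would need a different family. k-means with
k = 3 presumes three classes rather than estimating their number. The
region-overlap and TAD-proximity nulls are uniform relocations, which
ignore chromatin-state covariates a real analysis might condition on. The
published site catalog for the real X chromosome (64 sites on 17.7 Mb) is
not reproducible here because it derives from deposited sequencing data;
all quantitative checks run against planted ground truth instead.
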