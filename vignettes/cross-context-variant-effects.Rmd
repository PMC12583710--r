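---
title: "Scoring cross-context variant effects on chromatin accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cross-context variant effects on chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(sitefx)
library(dplyr)
```

## The problem

Most disease-associated variants from genome-wide association studies are
non-coding, and their effect on regulatory activity can depend not only on
cell type but on finer conditioning labels — here called *contexts*, after
the motivating case of vascular anatomical sites (ascending versus
descending aorta) within one vascular cell type. `sitefx` implements the
downstream analysis that sits on top of any trained sequence-to-profile
accessibility predictor:

1. **Variant effect scoring.** For each SNP, predict base-resolution
   accessibility for the reference and alternate allele over a 1 kb window
   centered on the variant, and summarise the difference as a log2 fold
   change of total predicted coverage (`logFC`, and its magnitude
   `abs_logFC`) plus the Jensen–Shannon distance (`jsd`) between the two
   probability profiles (profile-shape change).
2. **Empirical significance.** Compare each observed score against a null
   of dinucleotide-preserving shuffles of the 2114 bp sequence around the
   variant, with the reference or alternate allele re-inserted at the
   center of each shuffled copy.
3. **Cross-context deviance.** Regress one context's `abs_logFC` on
   another's, studentize the residuals, and select the top quantile of
   variants furthest from the line — variants whose predicted effect is
   context-dependent — then export 200 bp windows around them for de novo
   motif discovery.
4. **GWAS gene-set enrichment.** Test whether GWAS nearest-gene sets are
   over-represented among a cell type's differentially expressed genes,
   against random gene sets drawn from the expressed genes.

A synthetic-data module generates every input with known ground truth, and
a pseudobulk module converts single-cell ATAC fragment files into
per-cluster tagAlign reads (the preprocessing that feeds predictor
training, which is itself out of scope here).

## The predictor contract and the toy grammar

All scoring code depends only on a contract: `predict_accessibility(object,
seq)` must return a per-base probability profile summing to 1 and a finite
natural-log total coverage. A trained convolutional network can stand
behind this contract; the package ships `toy_predictor()`, a deterministic
motif-grammar model that makes hand-derived expectations exact.

The toy predictor scans the window with each motif's log-odds PWM
(forward strand). An offset scoring `s >= tau` is a *hit* with excess
`e = s - tau`. With context activation weight `beta`:

- `log_total = b0 + sum(beta * e)` over hits (`b0` the baseline,
  default `log(10^4)` counts);
- per-base activation is the sum of `beta * e` over hits whose footprint
  covers the base, and the profile is the softmax (temperature 1) of the
  activation vector.

Softmax temperature is fixed at 1 to keep the link monotone with one fewer
free parameter; `log_total` is natural-log internally and converted to
log2 only in scoring, so `logFC` is computed on the log scale and never by
exponentiating counts. Scanning is forward-strand only, matching the
synthetic generator's forward-strand planting — the contract itself is
strand-agnostic, and a strand-aware predictor plugs in without changes
downstream.

## Effect sizes

For a variant at 0-based position `pos`, both allele windows span
`[pos - floor(L/2), pos - floor(L/2) + L)` with the variant base at offset
`floor(L/2)` (`L = 1000` by default; the even-length centering convention
had to be fixed somewhere and this one keeps the arithmetic pure integer).
The two windows differ at exactly the center base, so

- `logFC = (log_total_alt - log_total_ref) / ln 2`,
- `jsd = sqrt(JS divergence)` with base-2 logarithms, so the distance is
  bounded by 1 and reaches 1 exactly for disjoint-support profiles.

```{r closed-form}
m <- motif_model("hit", pwm_consensus_matrix("TGACTCAC"),
                 threshold = 16 - log(2), betas = c(asc = 1))
pred <- toy_predictor(m, "asc")
ref_win <- paste0(strrep("A", 46), "TGACTCAC", strrep("A", 46))
alt_win <- ref_win; substr(alt_win, 50, 50) <- "G"
# destroying a hit with beta * e = ln 2 gives logFC = -1 exactly
score_variant(pred, ref_win, alt_win)$logFC
```

## The dinucleotide-preserving empirical null

Significance is assessed against shuffled versions of the variant's
neighbourhood that keep all 16 adjacent-pair counts (and the terminal
bases) fixed — preserving the low-order composition that accessibility
models are sensitive to, while destroying motif instances. The shuffle
samples uniformly over valid arrangements via the random-arborescence
Euler-path construction: a uniformly random last-exit edge set forming an
arborescence into the terminal base is drawn by rejection, remaining
out-edges are permuted uniformly, and the Euler path is walked. Each
shuffled window is duplicated and the reference or alternate allele
written at the center, and each pair is scored exactly like an observed
variant (the central `L_pred` bases of the `L_shuf = 2114` bp window).

The empirical p-value uses the add-one convention
`p = (1 + #{null >= obs}) / (1 + n_null)`, so `p` is never 0 and the
smallest attainable value is `1/(1 + n_null)`; the literal proportion
is available with `add_one = FALSE`. "More extreme" is one-sided on the
non-negative metrics `abs_logFC` and `jsd` (a signed `logFC` is judged
through its absolute value).

Two pooling conventions are supported. The default builds one null per
(variant, context) — the statistically conservative reading, since each
variant is calibrated against its own sequence composition.
`pool_null = TRUE` shares a single null per context, pooled round-robin
over the observed variants' shuffled backgrounds; this approximates the
one-large-null-per-scored-set economy that makes million-draw nulls
affordable and is the right choice when many variants are scored at desk
scale. Windows containing `N` are rejected rather than shuffled, because
the dinucleotide alphabet is ill-defined with ambiguity codes; failures
are recorded per variant, never silently dropped.

At desk scale the package defaults to `n_null = 10^4` (minimum attainable
p `1/10001`); the calibration tests in this package use `n_null = 999` so
that the minimum attainable p is exactly `1/1000`. Calibration is checked
by drawing observed variants *from the null construction itself* and
requiring their p-values to pass a Kolmogorov–Smirnov uniformity test;
this needs a grammar with effectively continuous scores, so the test
fixture uses a random centered PWM with threshold 0 (about half of all
offsets are hits) rather than a sharp consensus motif, whose score lattice
would collapse the null into ties.

## Cross-context deviance

Scores from two contexts are compared by ordinary least squares of the
second-named context on the first (`y ~ x` with intercept; the direction
is fixed and labeled in the output because swapping axes changes
residuals). Outliers are ranked by externally studentized residuals

`t_i = r_i / (s_(i) * sqrt(1 - h_i))`

with `s_(i)` the leave-one-out residual standard deviation and `h_i` the
leverage; two-sided p-values use the t distribution with `n - 3` degrees
of freedom. Points with leverage numerically 1 are flagged and excluded
from selection rather than given infinite statistics. The deviance is
computed on `abs_logFC` by default (`jsd` is available via the `metric`
argument but is not the default).

Selection takes `k = max(1, floor(q * n))` variants with the largest
`|t|`, ties broken by smaller p then lexicographic variant id, with
`q = 0.01` by default (the top 1% of deviant SNPs). A fixed deterministic
rule was required because floor, ceiling and round all disagree with each
other on real data sizes; `max(1, floor(.))` guarantees a non-empty
selection and never over-selects. Exported windows span
`[pos - flank, pos + flank)` with `flank = 100` — an exact 200 bp
half-open window with the SNP at offset `flank`, chosen over the 201 bp
inclusive reading.

```{r deviance}
sim <- simulate_score_matrix(2000, rho = 0.95, sigma = 0.5,
                             frac_deviant = 0.01, delta = 3, seed = 4)
fit <- context_deviance(score_matrix_to_long(sim$scores),
                        "context_A", "context_B", q = 0.01)
fit
mean(fit$selected %in% sim$truth$variant_id[sim$truth$deviant])
```

```{r deviance-plot, fig.width = 5, fig.height = 4}
autoplot(fit)
```

## GWAS gene-set enrichment

The observed count is the overlap of the GWAS nearest-gene set with genes
at adjusted p < 0.05 (Benjamini–Hochberg column expected; the DE analysis
itself is upstream of this package). The baseline pools `n_draws` random
sets of 100 genes drawn without replacement from the expressed genes, and
the 2x2 table (GWAS versus pooled baseline) is tested with the plain
Pearson chi-squared statistic, df 1, no continuity correction — the large
pooled counts make the correction superfluous, and the uncorrected
statistic is the one that equals the textbook `sum((O - E)^2 / E)` on a
worked table. An `empirical = TRUE` option instead reports the fraction of
draws whose DE proportion reaches the observed one, for users who prefer a
resampling p over the pooled chi-squared framing; pooling is the default
because it matches the chi-squared reporting convention.

## The synthetic-data generator

The generator produces every pipeline input with known truth. What it
emulates, and what it deliberately does not:

- `simulate_genome()` draws i.i.d. bases at a requested GC content
  (default 0.41, mammalian-like). No repeats, isochores or CpG islands.
- `plant_motifs()` writes motif consensus sequences at non-overlapping
  uniform positions, forward strand only, by rejection sampling with a
  1000-retry cap (failure is explicit, never a silent overlap).
- `simulate_variants()` places a fraction of SNPs inside planted
  instances — substituting the sharpest PWM column's consensus base with
  its lowest-scoring alternative, the strongest single-base disruption —
  and the rest uniformly outside instances. Reference alleles always match
  the genome (round-trip checked against the emitted FASTA). SNPs only;
  multi-allelic sites and indels are never generated, and on-disk
  coordinates are 1-based (VCF/TSV) while everything in memory is 0-based
  half-open.
- `simulate_score_matrix()` emulates the two-context `abs_logFC` scatter:
  per-variant latent effect plus independent per-context noise, with the
  noise scaled so the columns have correlation `rho` and per-context SD
  `sigma` (latent SD `sigma * sqrt(rho)`, noise SD `sigma * sqrt(1 -
  rho)`); `sigma` is the marginal SD because that is the quantity read off
  such a scatter plot. Deviants (`round(frac_deviant * n)` of them,
  exactly) receive `+delta` in one random context. Values center on a
  positive mean (default 1) but are not clamped at zero — clamping would
  distort the correlation contract that the generator guarantees.
- `simulate_de_tables()` marks genes DE with probability `frac_de`, GWAS
  genes with `min(1, enrichment_factor * frac_de)` (clamped with a
  warning), and encodes DE status in a `padj` column compatible with the
  enrichment module's threshold.
- `simulate_fragments()` draws fragments uniformly with lengths in
  50–500 bp. No Tn5 insertion bias, peak structure, LD or read-level
  error — so passing tests demonstrate the statistical machinery, not
  robustness to those artefacts of real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen so the full suite completes in a few minutes on one CPU while
keeping every estimate's Monte-Carlo error well inside its tolerance:
1000 random 200-mers for shuffle conservation; exhaustive enumeration of
2-letter sequences up to length 8 for shuffle uniformity (chi-squared
goodness of fit at family-wise alpha 0.01, Bonferroni across enumerable
sequences); 999-draw nulls with 500 observed draws for calibration;
`n = 10^4` variants with 1% deviants at `delta = 6 * sigma` for recovery;
2000 replicates for the enrichment test's type-I error; and an end-to-end
run on a 1 Mb two-context genome with 2000 variants (20% motif-hitting)
and a pooled 1000-draw null. In the end-to-end scenario the shared grammar
spans a range of activation weights (0.3–1.2): a single shared effect
size would make the regression's design degenerate — three point masses —
whereas the spread anchors the fitted line to the cross-context diagonal
the way a real score scatter does.

Other numerical decisions: softmax activations are max-shifted before
exponentiation; the Jensen–Shannon divergence clamps at `[0, 1]` before
the square root to absorb rounding at the boundary; `0 * log(0)` terms
are dropped by restricting KL sums to positive entries; empirical
p-values count ties as "equally high or higher"; and all generators are
bit-reproducible given (parameters, seed), with RNG state restored on
exit so library calls never perturb a caller's stream.

## Known limitations

- The toy predictor is linear in motif excess scores; it cannot represent
  saturation, cooperativity or repression, and it scans one strand.
- Effect sizes from a single predictor per context; if an ensemble of
  models per context exists (e.g. cross-validation folds), combining
  their scores is left to the caller.
- The deviance regression is pairwise by design; multi-context
  comparisons are a sequence of labeled pairs, not a joint model.
- The enrichment test treats genes as exchangeable units; it does not
  model gene length, expression level or LD-induced clustering of GWAS
  nearest-genes.
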