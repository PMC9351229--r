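---
title: "Measuring genotype-imputation accuracy from dosage files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genotype-imputation accuracy from dosage files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosageqc)
```

## The problem

Genome-wide association studies impute millions of untyped variants from a
genotyped scaffold and a reference panel.  Imputation software reports, for
every marker $m$ and individual $i$, a-posteriori probabilities
$p_{g,i}$ for the three genotypes $g \in \{0, 1, 2\}$ (copies of the
counted allele).  Downstream analysis needs to know which markers were
imputed well enough to use, and several accuracy indices are in routine
use but scattered across different tools.  dosageqc computes all of them
in one pass over a standard Oxford-GEN-style dosage file, filters markers
and samples, and flags chromosome segments enriched with poorly imputed
markers.

All indices are built from two per-individual moments of the posterior:
the expected dosage $w_i = p_{1,i} + 2 p_{2,i} \in [0, 2]$ and its second
moment $v_i = p_{1,i} + 4 p_{2,i}$, together with the allele-frequency
estimate $\hat\theta = \sum_i w_i / (2n)$.  The reported MAF is the folded
value $100\,\min(\hat\theta, 1 - \hat\theta)$, but every index uses the
counted allele as read; all of them are invariant under allele
reorientation.  Variances are population (1/n) moments throughout.

## The indices

**info** (IMPUTE2 style) is the share of statistical information about the
allele frequency that survives imputation:

$$\mathrm{info} = 1 - \frac{\sum_i (v_i - w_i^2)}{2 n \hat\theta (1 - \hat\theta)}.$$

It is 1 for fully certain posteriors, can go below 0, and is undefined for
monomorphic markers (reported with the sentinel `-97`).

**MACH r²** compares the observed dosage variance with the binomial
variance implied by the allele frequency,
$r^2_{\mathrm{MACH}} = \mathrm{Var}(w) / (2\hat\theta(1-\hat\theta))$;
**Beagle allelic r²** is the squared correlation between the best-guess
genotype $z_i$ (posterior argmax, ties resolved toward the smaller
genotype) and the unobserved truth, estimated as
$\mathrm{Cov}(z, w)^2 / (\mathrm{Var}(z)\,(\bar v - \bar w^2))$.  The
square root of either scales the effective power of an allelic test.

**Iam** measures how much of an anchor distribution's genotype uncertainty
the imputation has resolved into individual-specific information.  For an
anchor $a$ (either pure chance $(1/3, 1/3, 1/3)$ or Hardy–Weinberg
proportions at $\hat\theta$),

$$\mathrm{Iam}(a) = 1 - \frac{\tfrac1n \sum_i \bigl(1 - \sum_g p_{g,i}^2\bigr)}
                             {1 - \sum_g a_g^2},$$

the complement of the ratio of the mean Gini–Simpson diversity of the
individual posteriors to the anchor's diversity.  With the chance anchor
this is algebraically identical to the mean squared Euclidean distance of
the triplets from the uniform point, normalized by its maximum $2/3$ — 0
for completely uninformative posteriors, 1 for fully certain ones.  The
HWE anchor credits only information beyond what the population allele
frequency already supplies; it degenerates (sentinel) when
$\hat\theta \in \{0, 1\}$.  The recommended filtering threshold for both
anchors is 0.47.

**hiQ** asks the complementary question: are the dosages heterogeneous
enough *across* individuals to support inference?  dosageqc defines it as
the between-individual share of the total variance of a genotype drawn
from the pooled posteriors,

$$\mathrm{hiQ} = \frac{\mathrm{Var}(w)}{\bar v - \bar w^2},$$

an intraclass correlation: 1 when every posterior is certain and all
dosage variation is real inter-individual signal, 0 when the dosages are
identical and any variation is within-individual imputation noise.
Values below the recommended threshold 0.97 flag dosages too similar,
relative to their uncertainty, to be usable in association testing.  The
exact normalization used for this index in the original software's
supplementary material was not available when this package was written;
dosageqc's definition is stated above, reproduces the qualitative
behaviour (direction, thresholds, and the worked example's region labels)
but not the original's printed hiQ values, and should be cited as this
package's definition.

## Regional classification

A marker's indices can fail individually, but poor imputation clusters
along the chromosome (typically near telomeres and assembly gaps).  Each
marker gets a score: the number of failing indices among Iam_chance,
Iam_HWE (threshold 0.47) and hiQ (threshold 0.97), with undefined indices
counting as failures.  Scores 0, 1 and ≥2 map to COLD, TEPID and HOT.  A
run of at least `very_hot_run = 3` consecutive HOT markers, with
consecutive gaps no larger than `window_bp = 10000` base pairs, is
upgraded to VERY_HOT — evidence of a massively misimputed segment rather
than isolated failures.  Consequences of this construction: an isolated
marker keeps the label implied by its own indices and can never be
VERY_HOT; worsening any marker's indices can never move any label toward
COLD.  Both constants are exposed as arguments of `classify_regions()`
because sensible values depend on marker density.

## Worked example

```{r}
paths <- write_worked_example(file.path(tempdir(), "example"))
cfg <- parse_params(readLines(paths[["params"]]))
cfg$probe_exclusions <- NULL    # keep all five individuals
res <- run_accuracy(cfg, quiet = TRUE)
res$table[, c("SNP", "position", "N", "maf_pct", "iam_chance",
              "iam_hwe", "hiq", "info", "r2_mach", "r2_beagle", "Accuracy")]
```

The three markers named in `exclude_SNP.txt` are quality-control markers
and never reach the output.  Of the remaining four, only rs00002 keeps a
TEPID label: its posteriors are individually certain (Iam pair near 1,
info 0.98) but every individual receives the same dosage, so the marker
carries no usable between-individual signal (hiQ 0, MACH r² 0, Beagle r²
undefined).  The other three fail at least two indices and sit in HOT
surroundings.

## The synthetic-data generator

`simulate_markers()` draws true genotypes from Hardy–Weinberg proportions
at a chosen allele frequency $\theta$ and blurs each one toward an anchor:
posterior $= \lambda\,e_{g} + (1-\lambda)\,a$, where $e_g$ is the
degenerate distribution at the true genotype.  This one-parameter model
spans the whole quality range and has exact closed forms the test-suite
exploits: with the chance anchor, $\mathrm{Iam}_{chance} = \lambda^2$ for
*every* genotype configuration; with the HWE anchor at $\lambda = 0$,
info, MACH r² and Iam_HWE are all exactly 0 and Beagle r² is undefined;
at $\lambda = 1$, info $= 1$ and (for non-constant best guesses) Beagle
r² $= 1$.  Defaults are 100 samples, $\theta = 0.3$ and $\lambda = 0.8$ —
a decently but imperfectly imputed common variant.  Marker $m$ uses the
deterministic seed substream `seed + 7919 m`, so any subset of markers
reproduces exactly and identical specifications give byte-identical
files.

What the generator does *not* emulate: linkage disequilibrium between
markers (each marker is independent), reference-panel or strand artefacts,
and posterior shapes that are not mixtures of a vertex and the anchor.
Passing tests therefore validate the estimators and the pipeline
arithmetic, not the behaviour of any particular imputation software on
real haplotypes.

## Numerical choices and edge cases

* Variances use the population (1/n) denominator everywhere; this is what
  reproduces the reference values for the r² family.
* Best-guess ties break deterministically toward the smaller genotype.
* Any negative probability marks that individual missing at that marker
  only; the individual still counts at other markers.  N is the count of
  individuals that are both retained and non-missing.
* Every undefined index (zero-variance denominators, degenerate anchors,
  N = 0) is printed as the single sentinel `-97`.
* Table formatting rounds indices half-to-even at 3 decimals, trims
  trailing zeros but keeps one decimal (`0.720` prints as `0.72`, `0`
  as `0.0`); MAF gets one decimal.  Values are pre-rounded at 9 decimals
  first so accumulated floating-point noise cannot flip a decimal
  boundary (a sum like 26.150000000000006 must round as 26.15).
* Two-probability inputs are amended with $p_2 = 1 - p_0 - p_1$; a
  remainder within $10^{-6}$ below zero is clamped to 0, anything further
  negative is a parse error.
* Gzip input is detected from the two magic bytes, not the file name.
* Files are consumed in bounded chunks (default 512 rows); with the
  callback interface of `read_markers()` memory stays proportional to
  chunk size times sample count, independent of marker count.  The
  test-suite demonstrates this on a 10,000-marker, 50-sample file, which
  processes in seconds on one CPU.

## Known limitations

* hiQ is this package's own definition (see above); comparisons with
  hiQ values produced by other software are not meaningful at the level
  of exact numbers.
* The regional scheme's window and run-length defaults target dense
  imputation output; sparse marker sets should widen `window_bp`.
* One chromosome per input file, as in the underlying format; genome-wide
  orchestration is left to the caller.
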