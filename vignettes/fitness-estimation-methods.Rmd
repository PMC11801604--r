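---
title: "Estimating gene-disruption fitness from transposon insertion libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gene-disruption fitness from transposon insertion libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satayfit)
```

## The estimation problem

A saturated transposon screen pools on the order of 10^5–10^6 insertion
mutants, grows them competitively, and sequences transposon–genome
junctions. The data reaching this package are a map of unique insertion
sites with read counts, a gene annotation, and centromere coordinates. The
quantity of interest is the fitness effect of disrupting each gene, on a
gradual scale rather than a binary essential/non-essential call.

The central statistic is deliberately simple: the mean read count per
insertion site within a gene's coding region. Everything else in the
pipeline exists to make that mean interpretable — deciding which sites to
average, adding back the sites that produced no reads, and attaching an
honest uncertainty.

## Growth model and fitness scales

Each mutant is assumed to start from a single cell (double insertions at
one coordinate are rare enough to ignore) and to grow exponentially for the
duration of library expansion, so the read count at site $i$ of gene $g$ is
$y_{g,i} = 2^{\mu_g t} \pm \epsilon$ with one growth rate $\mu_g$ per gene.
$\mu_g$ is an *effective* rate: lag, stationary phase and death are folded
into it, not modelled. Under a Poisson read model the maximum-likelihood
estimate of the per-mutant read level is the sample mean $\hat y_g$, and

$$w_g = \frac{\log_2 \hat y_g}{\mathrm{median}[\log_2 \hat y_g]}$$

is a time-free fitness (the median gene stands in for the unmutated
ancestor, because most disruptions are near neutral). $\hat y_g < 1$, which
happens when most of a gene's sites are imputed zeros, gives $w_g < 0$:
the mutant is lost from bottlenecks faster than it can be sampled. A second
scale, $w_g = (\hat y_g / \mathrm{median}[\hat y_g])^{1/t}$ with $t = 10$
generations of expansion, matches the per-generation convention of pooled
competition assays and is bounded below by 0. The two scales use
median-of-log and log-of-median references respectively, exactly as their
defining conventions state; these differ slightly for even gene counts.
The median-scale value is invariant to the logarithm base.

Normalizing to the median assumes a unimodal fitness distribution; a
library in which many mutants outgrow the ancestor would need an explicit
growth-trajectory model instead.

## Which sites enter the mean

* **Edge exclusion.** Insertions in the outer 10% of a coding region often
  truncate too little of the protein to abolish function — visibly so for
  essential genes, whose positional read profile is U-shaped
  (`bin_profile()`). Sites with relative position outside $[0.10, 0.90)$
  (measured 5'→3' on the coding strand) are excluded from the read set.
  The interval is half-open: position 0.10 is in, 0.90 is out.
* **Zero-site imputation.** The expected insertion count
  $E(X_g) = \lfloor \lambda(r_c) L_g \rfloor$ uses the full gene length, so
  the observed count $O(X_g)$ it is compared against also counts *all*
  observed insertions in the gene, edge sites included — the two must share
  a denominator. $\max(0, E - O)$ zero-read records are appended; when
  observations exceed expectation, no unobserved sites are assumed.
* **Outlier trim.** After imputation, reads above
  $q_{95} + 1.5 (q_{95} - q_{5})$ are removed once (no iteration).
  Percentiles interpolate linearly between order statistics (type 7, the
  default of the common numerical stats routines); with few sites the
  interpolated $q_{95}$ chases the largest value, so small genes rarely
  lose sites — a property, not a bug, of the published rule. The rule is
  upper-tail only; structural zeros are never outliers.

Genes with fewer than 5 sites after trimming, or all-zero reads, are
`undetermined`. The usable-site count $n$ is also the denominator of the
standard error; edge-excluded sites do not count toward it.

## Centromere bias

The MiniDS transposon excises from a donor locus near the centromere and
reinserts preferentially nearby, so insertion density is elevated within
roughly 200 kb of every centromere (about 0.12/bp against 0.067/bp
elsewhere in the data that motivated the method). The correction fits the
arm-averaged cumulative insertion count with a cubic over 0–400 kb
(unweighted, on a 1 kb grid; arms shorter than a distance simply drop out
of the average there) and takes its derivative as the local rate
$\lambda(r_c)$ for $r_c < 200$ kb, frozen at $\lambda(200\,\mathrm{kb})$
beyond — extrapolated cubics oscillate, and the bias is local, so a
constant distal rate is the right regularization. The fitted rate must be
non-negative over the whole window; if not, the curve itself needs
inspection and the fit errors out rather than clamping.

Numerical choices: the regression runs on a scaled abscissa ($r$ divided by
the fit range) because raw bp powers up to $(4\times10^5)^3$ make the
normal equations singular in double precision; coefficients are rescaled to
bp units afterwards. Sites inside the centromere interval get distance 0
and are counted with the left arm (they are rare; the convention just has
to be fixed). The gene's distance is measured from
$\lfloor(\mathrm{start}+\mathrm{end})/2\rfloor$ to the nearer centromere
edge.

One approximation is intrinsic to the published procedure and worth
stating: a single cubic fitted across 0–400 kb cannot exactly represent a
curve that is genuinely cubic below a 200 kb plateau kink and linear above
it. On simulated data this leaves the rate at $r_c = 0$ a few percent low
and a correspondingly small residual in $E - O$ for the most
centromere-proximal genes (about 5% of the mean expected count across the
genome). With realistic per-gene scatter this residual is invisible; in
near-noiseless simulations a sufficiently powered regression of $E - O$
against centromere distance can detect it.

## Uncertainty

Counts within a gene are modelled negative-binomially,
$\mathrm{Var} = \mu + \alpha\mu^2$, with one $\alpha$ for the whole
dataset: all counts are conditional on the same sequencing depth, and the
mean estimate does not depend on $\alpha$, so the two separate. $\alpha$
is the no-intercept OLS slope of $z_g = (s^2_g - \hat y_g)/\hat y_g$ on
$\hat y_g$ over genes with at least two usable sites and positive mean
($s^2_g$ uses the $n-1$ denominator; imputed zeros are part of the gene's
read distribution and are included; trimmed values are not, matching the
pipeline order). A negative estimate is clamped to the Poisson limit with
a warning. The per-gene variance is
$\max(\hat y_g + \alpha \hat y_g^2,\ s^2_g)$ — genes noisier than the
genome-wide trend keep their own variance — and
$SE_g = \sqrt{V_g / n}$. The error is stated on the read-count scale, as
the defining equation is; it is not propagated through the log/median
scaling.

## What the simulator emulates

`simulate_genome()` + `synthetic_truth()` + `simulate_library()` generate
libraries with known ground truth. Default study conditions, chosen once:

* 3 chromosomes with 500 kb arms (so the cumulative curve covers the full
  400 kb fit window), 300 non-overlapping genes of 300–4000 bp, 20%
  essential — the approximate essential fraction in yeast.
* Placement rate $0.067 + 0.053\,(1 - r_c/200\,\mathrm{kb})^2$ per bp,
  constant beyond 200 kb: the printed near/distal rates, with a smooth
  taper whose cumulative is piecewise cubic. The skew-correction property
  of the bias model is only well-posed if the generating curve lies
  (approximately) in the model family the method fits, which is also what
  the method assumes of real data.
* Per-gene growth rates $\mu_g = \max(0, 1 - s)$ with deleterious effects
  $s \sim \mathrm{Exp}(\mathrm{mean}\ 0.1)$: one near-neutral peak with a
  skewed deleterious tail. Essential genes have $\mu = 0$ in the central
  80% with a linear tolerance ramp over the outer 10% — the minimal
  mechanism reproducing the U-shaped edge profile.
* $t = 10$ generations; bottleneck of 100 cells per site (multinomial);
  read counts negative-binomial with $\alpha = 0.1$ and a mean depth of 25
  reads per site; zero-read sites are dropped, as in real data.

PCR noise is not simulated cycle-by-cycle; the NB dispersion absorbs it,
which is exactly the interpretation the variance model licenses. Replicate
pairs can be split at the expansion, PCR or sequencing stage
(`split_point`), re-randomizing only the stages after the split; their ΔP
divergence orders accordingly. What the simulator does *not* emulate:
read-mapping errors (which smear one insertion over neighbouring
coordinates and are the main motivation for the 2 bp matching window),
sequence-composition insertion preferences, the extreme single-read
skew of undersequenced real libraries, and secondary-site transposon
effects. Passing recovery tests therefore demonstrate correctness of the
estimation machinery under the stated noise model, not robustness to every
artefact of real sequencing.

## Replicates, subsampling, comparisons

`match_insertions()` matches sites across two maps within a 2 bp window.
Matching is greedy over candidate pairs ordered by distance (ties toward
the lower coordinate), which makes it deterministic and exactly symmetric
in the two inputs; with a 2 bp window genuine ambiguity is rare. An
unmatched site counts toward ΔP only with ≥ 2 reads — one stray read is no
evidence a mutant existed. Read differences at matched sites are reported
raw and depth-normalized (per million mapped reads); the paper-style
headline is the absolute difference.

`subsample_reads()` draws reads without replacement under an exact
multivariate hypergeometric scheme (sequential conditional draws per
site), and `saturation_curve()` reruns the whole pipeline per depth. Depth
series are nested by default so the unique-insertion curve is monotone by
construction. Cross-dataset fitness comparisons keep genes determined in
both datasets with $E(X) \ge 5$ in both — below that there is too little
information for a reliable estimate.

## Problem sizes

Simulated analyses in the tests and the acceptance script use the default
3 Mb genome (about 2×10^5 sites, 5×10^6 reads) for pipeline-level
properties, 500 genes × 50 sites for dispersion recovery, and a compact
0.24 Mb single-chromosome genome for the 20-seed replicate-splitting
design, sizes at which every recovery property is comfortably measurable
while a full run stays in the tens of seconds.

## Known limitations

* The single shared $\alpha$ underestimates uncertainty for genes with
  genuinely gene-specific dispersion; the max-rule on the variance is a
  blunt guard, not a shrinkage estimator.
* Domain-level effects (a disruption that inactivates one protein domain
  but not another) are averaged over; the per-gene fitness is an average
  of domain-wise fitness.
* The median normalization fails informatively (an error) when the median
  mean read count is exactly 1, and silently misleads for multimodal
  fitness distributions.
* Coordinates are matched by exact chromosome-name equality; a rename map
  in the readers handles dialect differences, and any reference lift-over
  is upstream of this package.
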