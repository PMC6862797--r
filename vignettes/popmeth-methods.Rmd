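---
title: "popmeth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{popmeth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popmeth)
```

`popmeth` analyzes DNA methylation variation across panels of fully
inbred genotypes.  This vignette is the package's own account of the
models it implements, the parameters that matter, the simulation used to
validate it, and the choices made where the design was genuinely open.

## The data model

Input is one methratio-dialect TSV per line: chromosome, 1-based
position, strand, context (CG/CHG/CHH), methylated and total read
counts per cytosine.  Internally all coordinates are 0-based half-open.
Chromosomes are tiled into non-overlapping 20-bp windows anchored at
coordinate 0.  A cytosine contributes to its window only with at least
2 reads; the window level is read-weighted, i.e. pooled counts
$\sum C / \sum CT$ over contributing cytosines, not an unweighted mean
of per-cytosine ratios.  The read-weighted form matches methratio
semantics and downweights barely covered cytosines; whether the original
analysis weighted by reads is not documented, so this is a stated
package choice.  CG cytosines from both strands pool into the window by
position; no symmetric-CpG pairing is attempted because no pairing rule
is defined for the windowed statistics.

## Two-step DMR calling

Methylation in inbred panels is strongly bimodal at variable loci: most
lines sit near a high or a low epiallele level.  The caller exploits
this with fixed, context-specific contrast rules rather than a
parametric test.

**Step 1 (pairwise).** A reference group of $k = 16$ lines (group I) is
contrasted with every remaining line.  The default selector ranks lines
by fraction of non-missing windows and then greedily maximizes the
minimum kinship distance $d(i,j) = K_{ii} + K_{jj} - 2K_{ij}$ to the
lines already picked — high coverage first, diversity second — with ties
broken by input order.  The reference set is fully overridable because
the original 16 lines of any given study are not derivable from data.
Per window a pair is *significant* when levels differ by more than 0.6
(CG/CHG), or for CHH when the difference exceeds 0.2 with one line below
0.05 and the other above 0.25.  Significant windows of the same
direction chain while the gap between one window's end and the next's
start is at most 50 bp; chains with at least three significant windows
become candidates.  Windows without data do not break a step-1 chain
(they merely do not count toward the three).

**Step 2 (consensus).** Candidates from all comparisons are
union-merged when within 200 bp.  Each merged region is re-divided into
its 20-bp windows; per window, support is the fraction of contrasting
pairs *with data in both lines* that called it significant.  Support is
normalized to the region's own best window (the normalization is
per-region, not global), windows below 0.4 normalized support are
dropped, and every maximal run of at least three consecutive eligible
windows survives, trimmed to the run's span.  When dropping a middle
window splits a region into two runs of three or more, both are kept as
separate regions — the single-run case is the documented one, and
emitting each maximal run is the resolution-preserving extension.

**QC and final call.** The region's cytosine census is the union of
reported positions across the panel (the capture design); a line passes
QC when the census has ≥ 6 sites of the context, at least 2/3 of them
carry ≥ 2 reads in that line (inclusive bound), and the line's mean
per-site coverage over the census is ≥ 2.  The region survives only if
more than 60% of lines pass.  Finally, per-line region levels (pooled
counts over cytosines with ≥ 2 reads) are ranked; CG/CHG regions are
kept when second-highest − second-lowest > 0.6, CHH regions when the
second-highest exceeds 0.25 and the second-lowest is below 0.05.  At
least 4 lines with data are required so the second extremes are distinct
from the extremes; the second-rank form guarantees that no single line
can create a DMR.  The "≥ 2× coverage" QC phrase admits a per-cytosine
and a pooled reading; the per-cytosine reading gates the 2/3 rule and
the pooled reading gates the mean-coverage condition, so both are
enforced.

## Epiallele statistics

**Context classification.**  For a CG DMR, the CHG level over the same
interval is summarized by its second-rank difference and the squared
Pearson correlation with the CG level across lines with data in both
contexts (≥ 4 required): difference > 0.6 and r² > 0.8 gives CG_CHG;
difference < 0.2 and r² < 0.2 gives CG_only; anything else is
unclassified.  CHG DMRs mirror this.

**Minor epiallele frequency.**  The pairwise "> 0.6 difference" rule
does not by itself partition more than two lines, so lines are assigned
by the midpoint of the second-highest and second-lowest levels: a line
is High when it sits on the high side *and* its contrast with the
second-lowest exceeds the context threshold (symmetric for Low; CHH
uses > 0.25 / < 0.05 directly).  On bimodal data this reproduces the
pairwise rule exactly; intermediate lines stay unassigned.  A record is
produced only when more than half the lines with data are assignable,
and MEF = min(High, Low)/(High + Low) ∈ (0, 0.5].

**Subgroup-specific DMRs.**  One-way ANOVA of region methylation on
subgroup (subgroups with fewer than 2 data lines are excluded with a
warning); DMRs with P < 0.001 go to Tukey HSD (Tukey–Kramer for the
unequal group sizes), and a DMR is subgroup-specific when any pair
differs at P < 0.001.  `stats::aov`/`stats::TukeyHSD` provide the
arithmetic; tests cross-check the F statistic against a direct
`pf()` evaluation.

## Relatedness

Relationship matrices use the standardized form $K = ZZ'/m$ over
column-standardized features — the default of the standard GRM tools —
for both SNPs (0/2 codes) and per-DMR methylation levels.  Missing
methylation entries are handled pairwise-complete: $K_{ij}$ averages
$z_i z_j$ over features observed in both lines, which avoids imputation
bias at the cost of not being guaranteed PSD (eigenvalues are clamped at
zero before mixed-model use, and matrices with materially negative
eigenvalues are rejected).  Two matrices are compared by the squared
Pearson correlation of their off-diagonal upper triangles.  When all
three contexts are pooled, features are concatenated (averaging the
per-context matrices is available by computing them separately).

Probabilistic PCA (EM for the isotropic-noise factor model) serves
incomplete methylation matrices; initialization is deterministic (SVD of
the column-mean-imputed matrix), convergence is a relative change below
1e-6 in the expected reconstruction objective, capped at 1000
iterations with a warning (scores are still returned).  Constant
features are removed before fitting; on complete data the fitted scores
span the classical principal subspace.

## Association

Methylation (and trait) values are inverse-normal transformed with the
Blom offset, $\Phi^{-1}((r - 3/8)/(n + 1/4))$, ties sharing average
ranks.  Markers are filtered to MAF strictly above 0.05 computed on the
analysis lines.  The mixed model is EMMAX-style: per trait the variance
ratio $\delta = \sigma^2_e/\sigma^2_g$ is estimated once by REML on the
covariates-only model through a spectral decomposition of $K$, then
every marker is tested by weighted least squares on the spectral axis
with a Wald t-test ($df = n - p - 1$).  With $K = I$ the variance
components are unidentifiable (the REML profile is flat in $\delta$);
the implementation detects the flat profile and takes the homoskedastic
limit, so the model degenerates to exact OLS and the BLUP vanishes.
Structure covariates $Q$ default to the top-3 genotype principal
components (admixture proportions can be supplied instead); marker codes
enter untransformed (0/2).

Significant associations (Bonferroni $\alpha/N$; every threshold is
logged to 3 significant figures) are LD-pruned per DMR — greedy from the
most significant, accepting a marker only when its genotype $r^2$
(squared Pearson correlation of codes, the haplotype $r^2$ for inbred
homozygotes) with every accepted marker is below 0.1, ties on p broken
by ascending position then id — and filtered on the haplotype effect:
the two allele classes must differ by more than 0.05 in median
methylation.  Distance classes: local = same chromosome within 10 Mb of
the DMR midpoint, distal = different chromosome, otherwise unclassified;
a DMR's category is Local_only / Distal_only / Both / None, with any
unclassified-distance marker making the whole DMR Unclassified (the
precedence is a stated choice; the source rule does not order the
categories).

The DMR–trait model is two-step: $Y = Q + K + \varepsilon_1$ by the
mixed model, with $Y' = Y - Q\hat b - \mathrm{BLUP}(u)$, then
$Y' = \beta X + \varepsilon_2$ by OLS per DMR, requiring data in at
least 60% of the shared lines per pair, Bonferroni at $0.01/n$ DMRs of
the context.  The association direction is the sign of $\beta$.

## Mendelian randomization

For each significant DMR–gene pair within 1 Mb, two instrumented models
are fitted.  Causal: candidates are the DMR's significant mQTL SNPs
within 1 Mb; those associated with expression at $P < 0.05/n_{DMR}$ are
excluded, the survivor most significant for methylation is the
instrument, and $\beta_{pred} = \beta_{expr\sim DMR} \times
\beta_{DMR\sim SNP}$ is compared with the observed
$\beta_{expr\sim SNP}$.  Consequential is the mirror image (threshold
$0.05/n_{gene}$, $\beta_{pred} = \beta_{expr\sim SNP} \times
\beta_{DMR\sim expr}$, observed $\beta_{DMR\sim SNP}$).  Component
regressions reuse the mixed/residual machinery with $Q$ and $K$
adjustment, and both exposure and outcome are inverse-normal transformed
so the path product lives on a single scale — on noiseless chains
$\beta_{pred}$ then equals $\beta_{obs}$ to machine precision.  Ties for
"most significant" break by position then id.  Model fit is the Pearson
correlation of predicted and observed effects across pairs, reported per
model (a warning is attached below 10 evaluable pairs).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not the sequencing process.  A panel of inbred lines (default 263, in
three subgroups of proportions 0.25/0.40/0.35) receives homozygous 0/2
genotypes under Balding–Nichols subgroup drift (default divergence
0.15, a moderate crop-panel value; MAF floor 0.05).  Planted regions
carry a binary epiallele per line — high or low methylation level
(defaults 0.85/0.05 for CG/CHG, 0.35/0.02 for CHH, satisfying the
caller's definitional thresholds by construction) — with three kinds:
`genetic_cis` (the epiallele copies a linked SNP, minor allele = low,
mirroring the observation that the lowly methylated state is usually the
rarer epiallele), `pure_epigenetic` (low epiallele assigned i.i.d. with
probability `mef_target`), and `tissue_stable_background` (no
variation; negative control).  Reads per cytosine are negative-binomial
(`mu = coverage_mean`, default 20; `size = coverage_dispersion`, default
5 — chosen for testability, as the empirical coverage distribution of a
capture assay is not published) and methylated counts are binomial at
the line's level; a configurable fraction of lines gets zero coverage
per region to exercise the > 60%-of-lines filters.  Only planted regions
emit reads — the assay being emulated is region capture, not WGBS.

Traits are planted effects + a polygenic term from genome-wide
standardized genotypes + Gaussian noise.  Causal chains route
SNP→DMR→trait through a `genetic_cis` region; consequential chains
route SNP→trait→DMR through a `pure_epigenetic` region whose levels are
overwritten with the downstream effect.  A `beta_direct` field plants an
independent eQTL at the gene (causal truth) or an independent mQTL at
the DMR (consequential truth): real loci carry such independent QTLs,
and without them the mismatched MR model has no surviving instruments
at all — every candidate fails the exclusion filter — so its failure
would be unmeasurable rather than measurably worse.

What the generator does **not** emulate: read-level errors and
bisulfite conversion failure, linkage disequilibrium decay within
regions (each planted region has a single controlling SNP), TE/genic
annotation context, and tissue effects.  Passing tests therefore show
the algorithms implement their stated rules and recover planted truth
under the assumed noise model; they do not certify performance on real
bisulfite data.

## Validation studies and their sizes

The test suite validates each stage at sizes chosen to finish in
minutes on one CPU while leaving no rule unexercised:

* caller vs a brute-force enumerator of the printed rules on 50 random
  instances of ≤ 5 lines × ≤ 30 windows;
* planted-DMR recovery (recall 1.0, zero background calls) on a
  40-line panel, per context;
* mixed-model null calibration on 10,000 tests (100 iid-normal traits ×
  100 markers, 200 lines).  The kinship is estimated from a marker
  panel disjoint from the tested markers: testing the markers that
  built K is known to be conservative (proximal contamination), which
  would contaminate the calibration measurement itself;
* effect recovery (2-SE coverage ≥ 95% over 100 replicates) with the
  polygenic background drawn from the kinship marker panel, so the
  fitted model matches the generative one, and the tested marker
  outside it;
* MR direction recovery on 100 chains per truth model (150 lines,
  planted effect sizes spanning ±0.5 and ±1);
* MEF recovery on 20 planted regions × 100 lines.

## Known limitations

* The consensus step's support normalization makes DMR boundaries
  depend on the best window within each merged region; two studies with
  different group-I sets can trim differently at region edges.
* Pairwise-complete kinship can be slightly non-PSD under heavy
  missingness; eigenvalue clamping is a pragmatic repair.
* EMMAX's fixed variance ratio is an approximation; per-marker REML
  would be better calibrated at strong polygenic signal but is
  quadratically more expensive.
* The MEF High/Low midpoint rule is a deterministic extension of a
  pairwise definition; other extensions (e.g. model-based clustering)
  could assign intermediate lines differently.
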