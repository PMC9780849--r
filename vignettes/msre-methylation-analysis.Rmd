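---
title: "Multi-level differential methylation analysis of MSRE-seq data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level differential methylation analysis of MSRE-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The assay and what the pipeline models

Methyl-sensitive restriction enzyme sequencing (MSRE-seq) digests genomic DNA
with HpaII, which cuts its CCGG recognition site only when the internal CpG
is unmethylated. Methylated sites resist digestion, so after library
preparation and sequencing, the intact-fragment read depth at a CCGG site
increases with the probability that the site was methylated. Throughout this
package "CpG site" means the CpG inside a C(CpG)G HpaII motif, anchored at
the 1-based position of its first C; the motif is its own reverse complement,
so a forward-strand scan of the reference is strand-complete. Sites on chrX
and chrY are excluded by default: with both sexes in a cohort, sex-linked
copy-number and inactivation differences would masquerade as group signal.

The pipeline compares a case cohort (here labelled CP, for the spastic
cerebral palsy myogenic-cell study design it models: 6 cases and 6 controls,
each assayed as proliferating myoblasts, MB, and differentiating myotubes,
MT) against controls at four levels of genomic organization:

1. **Individual sites** — a Gaussian likelihood-ratio test per site with
   Benjamini–Hochberg FDR control, log2 fold change (CP − control, positive
   = hypermethylated in CP), PCA over informative sites, and top-200 heatmap
   selection.
2. **Chromosomes** — one-sided Fisher exact enrichment of significant sites.
3. **1-Mbp segments** — mean logFC per bin, flagged against the genome-wide
   95% interval.
4. **Promoters** — mean methylation load over TSS±1000 bp windows, tested
   like sites.

# Scoring: the log2-CPM stand-in

The study's per-site methylation scores came from a commercial pipeline whose
formula is not public; what is known is that the scores are proportional to
the per-site methylation probability and live on a scale comparable to
log-scaled expression data. `normalize_depth()` therefore uses the standard
construction for such data: counts-per-million per library followed by
`log2(CPM + 0.5)`. This removes library-size differences exactly (scaling a
library's depths by any constant leaves its scores unchanged), is monotone
in depth within a library, and the pseudo-count keeps shallow sites finite.
`score_matrix()` accepts externally computed scores, so the stand-in is
swappable. `common_sites()` first restricts to sites covered (depth ≥
`min_depth`, default 1) in *every* library — whether the study's common-site
intersection used a depth threshold or mere presence is not recoverable, so
the threshold is a reported parameter rather than a constant.

# The site-level test and its null

For scores $y$ at one site with $n$ samples, the LRT compares the two
group-means model against the common-mean model:
$\Lambda = n \ln\!\big((\mathrm{RSS}_0+\varepsilon)/(\mathrm{RSS}_1+\varepsilon)\big)$,
with a variance floor $\varepsilon = 10^{-8}$ so constant-score sites yield
statistic 0 rather than 0/0. $\Lambda$ is a monotone transform of the
one-way ANOVA F statistic, $\Lambda = n\ln(1 + F/(n-2))$.

The p-value default deserves a note. The large-sample reference for an LRT
is $\chi^2_1$, but at $n = 12$ that approximation is visibly miscalibrated:
integrating over the exact F(1, 10) null shows the $\chi^2$ p-values deviate
from uniformity by up to 0.056 in Kolmogorov–Smirnov distance — enough to
distort FDR control at scale. Because the exact finite-sample null of the
same statistic is available (F with 1 and $n-2$ degrees of freedom under the
Gaussian working model), `p_method = "f"` is the default; `"chisq"` gives
the asymptotic form. Both order sites identically (they are monotone in the
same statistic), so informative-site selection and top-200 ranking are
unaffected by the choice; only calibration differs.

No empirical-Bayes variance moderation is applied: the study's exact linear
-model configuration is unstated, and the plain per-site test keeps the null
exactly calibrated, which the validation suite checks.

BH-FDR is the adjustment (the study machinery's default false-discovery
correction), applied through `stats::p.adjust`; a brute-force step-up oracle
in the test suite pins the definition. Significance means $q < \alpha$ with
$\alpha = 0.05$.

# Regional statistics

**Chromosome enrichment** uses the one-sided (greater) Fisher exact test on
the 2×2 table of significant × on-chromosome counts, with the *tested* sites
as universe. One-sided because enrichment is the question — depleted
chromosomes then report p ≈ 1, matching how such tables are conventionally
presented. The p equals a hypergeometric upper tail and is computed by
`stats::phyper`; the suite checks it against direct summation to 1e-10
relative error.

**1-Mbp bins**: a site at 1-based position $p$ maps to bin
$\lfloor (p-1)/10^6 \rfloor$, bins anchored at coordinate 0 per chromosome,
trailing partial bins kept, empty bins omitted. The "95% interval" used for
flagging is ambiguous in the source material between an SD interval of bin
values and a standard error of the mean; an SE interval would flag nearly
every bin at these bin counts, so the default is $\mu \pm 1.96\sigma$ of the
bin-value distribution, with an empirical percentile interval
(`method = "percentile"`) as the alternative.

**Promoter windows** span [TSS − 1000, TSS + 1000] inclusive (2001
positions; symmetric, hence strand-independent). The endpoint convention is
not stated in the source; inclusivity is declared and tested. Windows with
fewer than two member sites are excluded — one site is not a load. At most
one transcript per gene is kept: the window with the most member sites, ties
broken by smaller TSS then lexicographic transcript ID, a deterministic rule
stable under input shuffling. MB and MT are tested separately, mirroring how
the per-condition promoter tables are reported.

**Interval containment** for gene/enhancer annotation uses BED semantics:
features are 0-based half-open, and a site at 1-based $p$ lies in
$[s, e)$ iff $s \le p-1 < e$.

# The synthetic-cohort generator

The study's raw data are access-controlled, so every downstream stage is
validated against a generator that emulates the design: 6 + 6 samples, two
paired cell conditions sharing one ground truth, and planted effects at all
four levels. Defaults (all overridable through `sim_config()`):

| parameter | default | why |
|---|---|---|
| `n_per_group` | 6 | the modelled cohort size |
| `chrom_spec` | 4 autosomes × 12 Mbp | desk-scale genome; ~1.9e4 sites |
| `site_density` | 0.4 /kbp | within ~2× of the genome-wide CCGG density (2.29e6 sites / 3.1 Gbp ≈ 0.74/kbp) while keeping runs fast |
| `baseline_beta` | Beta(2, 5) | right-skewed per-site methylation probabilities, mean ≈ 0.29 |
| `frac_dm` | 0.015 | planted DM sites, exact count (floor), sampled without replacement so recovery denominators are deterministic |
| `delta` | 1.2 | log-odds shift; yields planted \|log2FC\| ≈ 1.2, inside the 0.6–2.4 range the study reports for shared significant sites |
| `enriched_chroms` | chr3 at 4× | chromosome-level concentration of DM sites |
| `block_effect` | ±0.25 logit | 1-Mbp blocks: sub-threshold per site, ≈10σ at bin resolution — reproducing the scale separation between single-site effects (\|logFC\| ≈ 1) and regional bin means (≈ ±0.2–0.3) |
| `promoter_effect` | ±1.2 logit | planted TSS-window shifts |
| `depth_mean` | 300 | expected depth at a fully methylated site; the assay guarantees >20× over captured regions, and means well above the floor are what make \|logFC\| ≈ 1 effects detectable at n = 6 + 6 (a design power analysis, not a fit to data) |
| `nb_dispersion` | 0.02 | negative-binomial dispersion φ (variance μ + φμ²); technical-scale variability appropriate for restriction-digest libraries |
| size factors | log-uniform [0.7, 1.4] | bounded away from 0 so no library is empty |

Coverage links to methylation linearly: depth mean = s · depth_mean · θ.
The true chemistry is closer to all-or-none per allele; since the score is
defined only as proportional to the methylation probability, the linear link
is the simplest faithful stand-in and is isolated in
`simulate_depth_matrix()` so it can be swapped. θ = 0 gives zero coverage
(unmethylated sites are always cut).

All randomness flows from a single integer seed through fixed per-stage
offsets (catalogue +101, truth +202, depth +303, annotations +404), and the
generator restores the caller's RNG state. Planted shifts are applied only
where nonzero, so unaffected sites keep their θ bit-for-bit and the truth
table's DM flags are exact.

What the generator does *not* emulate: correlated methylation of neighbouring
sites, per-allele digestion chemistry, partial digestion efficiency, batch
structure, or sequence-composition coverage bias. Passing recovery tests
therefore demonstrate that the statistics find what they are defined to
find under idealized noise — not that the pipeline is robust to every
artefact of real libraries.

# Validation studies and problem sizes

Three study drivers back both the test suite and `scripts/acceptance.R`:

- `run_calibration()` — null cohorts (δ = 0, no blocks/promoters), ~5,000
  sites, 20 seeds: site p-values uniform (median KS D < 0.05; ≈ 0.012
  observed), site- and promoter-level flagged fractions within 3 binomial
  SEs of nominal.
- `run_recovery()` — default planted conditions (~19,000 sites), 20 seeds:
  site sensitivity ≥ 0.8 with empirical FDR ≤ 0.075; planted enriched
  chromosome flagged; planted blocks flagged with the correct sign; planted
  promoters recovered.
- `run_stability()` — MB and MT simulated from one shared truth with
  independent coverage noise, 20 seeds: Pearson correlation of 1-Mbp bin
  logFCs > 0.9 (≈ 0.99 observed), the regional-stability property.

These problem sizes keep each driver under about a minute on a single core
while leaving binomial noise well inside the asserted margins.

# Degenerate inputs and numerical choices

- Constant score vectors: statistic 0, p = 1 (variance floor).
- All-zero libraries are an error naming the library; zero retained common
  sites is an error suggesting a lower `min_depth`.
- Zero bin variance: all bins neutral, with a warning.
- Chromosomes with zero tested sites are excluded from enrichment, warned.
- Ties in top-n selection break by (q, p, chromosome, position) so output is
  a deterministic function of the data, not of row order.
- Windows overlapping a chromosome start are truncated at position 1 with a
  warning.

# Known limitations

- The scoring stand-in is not the commercial score; only its documented
  qualitative properties (probability-proportional, log scale) are
  reproduced.
- The Gaussian working likelihood is an approximation to log-CPM noise;
  at very low depth its tails are wrong even though calibration holds at
  the simulated depths.
- No covariate adjustment (age, sex, muscle source) and no variance
  moderation.
- Enrichment and bins inherit whatever selection the site-level α induces;
  they are descriptive summaries of the same test, not independent evidence.
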