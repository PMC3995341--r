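---
title: "Methods: homoeolog bias, cis/trans classification, and the synthetic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog bias, cis/trans classification, and the synthetic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeobias)
```

## The measurement and its model

For every gene with at least one homoeolog-diagnostic SNP we observe a
pair of counts per sample: reads supporting the Nipponbare-derived copy
(`n_count`) and reads supporting the 93-11-derived copy (`i_count`).
The analysis treats the allele split as binomial given the total and
asks, per sample, whether the Nipponbare fraction departs from 1/2.

The key identities behind the classification, with `c` the cis effect
and `t` the trans effect of a gene in log2 units:

- in silico hybrid (1:1 parental mix, P): allele ratio `2^(c + t)`;
- true F1 hybrid (H): allele ratio `2^c` — the common trans environment
  acts on both alleles, so trans effects cancel within a nucleus;
- tetraploid: allele ratio `2^(c + w)`, where `w` is a gene- and
  sample-specific ploidy perturbation (see below).

Three FDR-controlled decisions per gene — biased in P (sigP), biased in
H (sigH), P-vs-H ratio change (sigT) — plus the bias directions yield
the seven divergence types. The same ratio-change test against P
defines the regulation groups (convergent/divergent/conserved), and the
cross of bias states in P and in each hybrid/tetraploid gives the nine
inheritance categories.

### Assumptions

* Reads at diagnostic SNPs are exchangeable draws from the allele pool:
  no mapping bias toward the reference allele, no position effects.
  Pileup counting sums per site, so a read covering several SNPs of a
  gene contributes once per site; this inflates totals (and hence
  nominal power) for SNP-dense genes but does not bias the fraction.
* The binomial test conditions on the observed total; totals themselves
  (expression level) carry no information about allelic bias.
* One library per sample: no biological replicates, as in the
  experimental design the pipeline targets. All inference is
  per-gene-within-sample; FDR control is across genes.

## Statistical primitives and numerical choices

* **Exact binomial test** (`binom_exact_two_sided`): two-sided p by the
  minimum-likelihood rule — sum of `dbinom(j; n, 1/2)` over outcomes
  with `pmf(j) <= pmf(k) * (1 + 1e-7)`. The relative tolerance absorbs
  floating-point ties; at `p0 = 0.5` the rule coincides with doubling
  the smaller tail. Totals of zero are untestable and reported as
  `EQUAL` with `q = 1`, flagged, and excluded from the FDR family.
* **Ratio-change test** (`yates_chi2_2x2`): the Yates-corrected
  chi-square statistic `N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2)` with the
  continuity term floored at zero, referred to chi-square(1). The
  two-proportion test with continuity correction is algebraically the
  same statistic, so a single code path serves both the T test of the
  cis/trans classification and the group assignment. Tables with a zero
  margin are untestable: the gene is reported `AMBIGUOUS` (types) or
  Group III with an `untestable` flag, never silently merged.
* **FDR**: Benjamini–Hochberg, one family per test kind and sample
  (pair) across the full gene universe. The T test is adjusted over all
  genes, not only those significant in P or H; restricting the family
  would couple the three decisions and complicate the error model,
  while the rule definitions are unchanged.
* **Group ties**: a gene significant in the ratio-change test whose
  distance to 1:1 is numerically equal in P and S (within 1e-12) must
  have flipped direction; it is assigned to Group II (divergent).
* **Direction**: the sign of `n_count - i_count`, not the bias call, so
  genes significant but near 0.5 are handled deterministically.
* **Log ratios**: `log2((n + 0.5) / (i + 0.5))` for displays and range
  comparisons only; tests always use raw counts. KS p-values use the
  asymptotic distribution (gene-scale n) and are printed exactly, with
  a flag when below 2.2e-16.
* **alpha = 0.05** on q-values everywhere, configurable in one place.

## Diagnostic-SNP selection

Sites diagnostic of the 93-11 homoeolog are selected from the 93-11 RNA
pileup at depth > 10 with the dominant alternative base above 95% of
reads; both inequalities strict. The exclusion list from the Nipponbare
pileup uses the same depth rule with the fraction threshold at 5% — the
depth requirement is taken to carry over since only the fraction is
varied. The final set is (RNA candidates ∩ genomic SNPs) minus
exclusions, keyed by (chrom, pos, alt); conflicting alternative bases
at a position drop the site with a message. SNPs inside the exon span
of two or more gene models are left unassigned rather than multiply
counted, preventing the same reads from being tested twice.

The in silico hybrid scales each parent's diagnostic-site reads to the
smaller of the two library sizes (library size measured on the
diagnostic sites being analysed, so the 1:1 ratio holds on exactly the
reads entering the tests) and rounds to the nearest integer, ties to
even.

The coverage filter keeps genes with total >= `min_total` in every
analysed sample; the default `min_total = 10` matches the depth rule of
site selection and gives the binomial test minimal resolution
(`p = 2/1024` at 10:0). The original study's exact universe-defining
threshold is not recoverable from its description, so no particular
universe size is claimed.

## The synthetic-data generator

Per gene: base expression `mu ~ Lognormal(0, 1)` (a realistic span of
RNA-seq expression levels, CV ≈ 1.3); an architecture drawn from the
configured proportions (default: all six equal); effect magnitudes
`|c|, |t| ~ Uniform(0.5, 3)` log2 units with random signs constrained
by the architecture (equal-magnitude draws, opposite signs for
antagonistic architectures; `t = -c` exactly for compensatory). Totals
are negative binomial with mean `depth * mu / mean(mu)` and variance
`m + phi m^2` (`phi = 0.05` by default, typical RNA-seq overdispersion;
`phi = 0` gives Poisson); allele splits are binomial at the expected
fraction `r / (1 + r)`.

Two generator choices deserve emphasis:

* **Coupled parental libraries.** The parental mix is realised as one
  stochastic total per gene split binomially at the `2^(c+t)` fraction;
  the Nipponbare share becomes the `parent_N` reads and the 93-11 share
  the `parent_9` reads. Drawing the two parent libraries as independent
  negative binomials would add `sqrt(2 phi) ≈ 0.32` log-units of
  gene-level ratio noise to the in silico hybrid — noise that the
  binomial test would read as spurious parental divergence and that
  represents biological parent-vs-parent variation outside the `c + t`
  model. Coupling keeps the in silico fraction exactly at its expected
  value plus binomial noise, so ground-truth recovery is well defined.
* **The ploidy perturbation `w`.** The divergence amplification seen in
  tetraploids is modelled phenomenologically as an additive log2 term
  `w ~ Normal(0, w_sd)` drawn independently per gene and per tetraploid.
  This is the package's own stand-in — no quantitative model of the
  whole-genome-duplication effect is available to anchor it — and its
  independence across the two reciprocal tetraploids mirrors the low
  overlap of affected genes between them. The default `w_sd = 0` makes
  tetraploids distributionally identical to hybrids; range-expansion
  demonstrations use `w_sd = 1.5`, the smallest round value whose
  variance contribution clearly exceeds the trans-variance removed by
  hybridization under the default architecture mix.

Site-level simulation lays `snps_per_gene` sites per gene on one
pseudo-chromosome, with Poisson per-site depth `depth / snps_per_gene`,
alternative-base fraction `1 - error_rate` in the 93-11 pileup and
`error_rate` in the Nipponbare pileup; configurable fractions of sites
are withheld from the genomic list or given 10% Nipponbare
contamination to exercise the intersection and exclusion rules.

All randomness derives from a single integer seed; each generator stage
uses a fixed offset of it, so identical configs give byte-identical
output.

### What the generator does not emulate

Mapping bias, read-level structure (a read covering several SNPs),
positional or GC effects, replicate structure, expression-level
dependence of effects, correlated `w` across homoeologous networks, and
any genuine biology of genome doubling. Passing recovery tests
demonstrates that the classifier inverts the generative model it was
tested on — it cannot certify behaviour on real data where these
effects exist.

## Problem sizes used by the checks

Architecture-recovery checks run 6,000 genes (about 1,000 per
architecture) at 1,000 reads/gene, dispersion 0.05 and effects of at
least 1 log2 unit — conditions under which cis-only and compensatory
recovery sit around 95% and conserved specificity around 90%, the
residual loss being almost entirely FDR-driven false positives of one
of the three tests (each near `alpha` times the rejection fraction).
Range-ordering checks use 10,000 genes. Both complete in seconds; the
classification itself is linear in genes and dominated by the exact
binomial sums.

## Known limitations

* Significance-pattern classification is threshold-based: genes with
  antagonistic cis/trans effects where cis dominates are operationally
  `CIS_PLUS_TRANS` (direction concordant), so generative antagonism is
  only partially visible; this is a property of the rule set itself.
* Without replicates, overdispersion between biological copies of the
  same sample type is unidentifiable; the binomial test is
  anti-conservative to the extent such variation exists in real data.
* The `AMBIGUOUS` type absorbs both genuinely uninterpretable patterns
  (e.g. sigT alone) and power failures; its rate rises quickly as depth
  falls.
* Pileup-level counting cannot de-duplicate reads spanning multiple
  SNPs; totals are site-sums, not read counts.
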