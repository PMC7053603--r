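---
title: "Inferring lncRNA–miRNA–mRNA ceRNA networks with cernetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA–miRNA–mRNA ceRNA networks with cernetr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernetr)
library(dplyr)
```

## The inference problem

Competing endogenous RNA (ceRNA) regulation rests on a simple titration
model: a long non-coding RNA (lncRNA) carrying a miRNA response element can
sequester a miRNA and thereby de-repress that miRNA's mRNA targets. In a
tumour/normal comparison this predicts a characteristic signature for a
functional lncRNA–miRNA–mRNA axis:

* the lncRNA and the mRNA move in the **same** direction between tumour and
  matched normal tissue, and are **positively** coexpressed;
* the miRNA moves in the **opposite** direction, and is **negatively**
  correlated with its mRNA target;
* sequence- and database-level evidence supports both miRNA–target
  relationships.

`cernetr` implements the full screening cascade that turns several paired
tumour/normal expression studies, a multi-source miRNA-target evidence
table, and miRNA/lncRNA sequences into a ranked ceRNA network:

1. **Differential expression** per dataset, with empirical-Bayes moderated
   paired or group t-statistics and Benjamini–Hochberg adjustment, under
   per-dataset thresholds.
2. **Consensus** across datasets (intersection of significant sets per
   molecule kind), with direction-consistency flags.
3. **Coexpression screens**: lncRNA–mRNA pairs with r > 0.7 and p < 0.05 in
   every dataset; miRNA–mRNA pairs with r < 0 (no p filter).
4. **Target evidence**: predicted miRNA–mRNA pairs supported by at least 6
   of 12 sources, intersected with the negative correlations.
5. **Duplex scan**: miRanda-style local alignment of each miRNA against
   each lncRNA, gated at score > 140 and free energy < −20 kcal/mol.
6. **Triple assembly** under the shared-miRNA and direction rules, network
   construction, unweighted connectivity, and composite axis ranking.

Every stage takes a data frame and returns a tibble, so the screens chain
naturally with the pipe; `run_cerna_pipeline()` wires them together.

## The moderated t-statistic

For each feature the effect is the log2 fold change (tumour − normal; for
paired designs the mean of within-pair differences). With moderation
enabled, the residual variances $s^2_g$ (df $d$) are shrunk towards a prior
$(d_0, s_0^2)$ estimated by fitting a scaled F distribution to the observed
variances (the limma empirical-Bayes model; the hyperparameter fit is
delegated to `limma::fitFDist`). The posterior variance is

$$\tilde{s}^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},$$

and the moderated t refers $\hat\beta_g / (\tilde{s}_g u)$ to a t
distribution on $d_0 + d$ degrees of freedom, where $u$ is the unscaled
standard error factor ($1/\sqrt{n}$ paired, $\sqrt{1/n_1 + 1/n_2}$ group).
Setting `prior_df = Inf` fixes the posterior variance at `prior_var`
(normal reference); `moderation = FALSE` gives the ordinary t-test, in
which zero-variance features are reported with p = 0 when the effect is
non-zero and p = 1 otherwise, with a warning. All threshold comparisons are
strict inequalities, matching the `<`/`>` conventions of the screening
rules.

## The duplex scanner

The scanner aligns the reversed miRNA (3'→5') locally against the target's
5'→3' strand under complementarity scoring: Watson–Crick pairs +5, G:U
wobble +1, mismatch −3, affine gaps (open −9, extend −4), with substitution
scores inside the miRNA seed window (positions 2–8 from the 5' end)
multiplied by 4. These defaults approximate published miRanda conventions;
bit-exact reproduction of the miRanda binary is out of scope, and all
parameters are configurable through `duplex_scoring()`. Hits are extracted
greedily: the best local alignment is reported, its target span masked, and
the alignment repeated, yielding maximal non-overlapping local optima in
non-increasing score order. A perfect 22-nt complement scores
15·5 + 7·5·4 = 215 under the defaults, comfortably above the 140 gate; a
seed-only (7-mer) match scores exactly 140 and is excluded by the strict
inequality — weak sites are detectable but do not pass the screen.

Free energy is computed per hit from a bundled Turner-style
nearest-neighbor stack table over the paired positions, plus a duplex
initiation term (+4.09 kcal/mol) and terminal AU/GU penalties (+0.45). We
additionally charge a fixed +3 kcal/mol for every helix interruption (a
maximal run of mismatched or gapped columns between paired columns). A pure
stack sum ignores the thermodynamic cost of interior loops and bulges
entirely, which lets heavily interrupted chance alignments in random
sequence accumulate enough stacks to pass the −20 kcal/mol gate; the flat
interruption charge restores the qualitative behaviour of the
Vienna-derived energies miRanda uses while keeping the model deterministic
and desk-scale. The model remains an approximation: no loop-size
dependence, no dangling ends, no ensemble folding.

## What the synthetic generator emulates

`simulate_study()` produces multi-dataset bundles with the statistical
structure the analysis assumes, plus ground truth. Expression is
log2-normal around condition means. Planted triples follow a Gaussian
structural chain miRNA → mRNA → lncRNA: the miRNA gets a mean shift of
∓`effect_logfc` in tumour samples, the mRNA is an affine-negative function
of the miRNA plus noise (shift ±`effect_logfc`), and the lncRNA an
affine-positive function of the mRNA plus noise. Noise variances are
calibrated so that each coupled pair's within-condition Pearson correlation
equals ±`coupling_strength` while every planted log2 fold change stays
exactly ±`effect_logfc` in expectation — in the noise-free limit the
empirical logFC is exact. The defaults (200 mRNAs, 50 lncRNAs, 20 miRNAs,
10 planted triples, |logFC| = 2, noise SD 0.5, coupling 0.95, two
pseudo-datasets of 10 tumour/normal pairs) are the study conditions used
throughout the tests; where no value was dictated by the emulated design we
chose once what a microarray meta-analysis of this size would plausibly
show, and froze it.

Evidence tables flag each true miRNA–mRNA pair per source with probability
`evidence_sensitivity` (0.9) and each decoy (5 per true pair, sampled from
the complement) with probability `evidence_fpr` (0.02). Sequences are
random-composition RNA with the reverse complement of the miRNA (full
length for strong sites, seed-only for weak) embedded at recorded 1-based
positions. One master seed drives deterministically derived per-component
streams, so identical configs give byte-identical bundles.

Deliberate simplifications, and hence the limits of what passing tests
show about real data: no probe-level effects, no batch effects, no missing
values, no subject-level random effect (the generator's within-pair
correlation is zero, so paired and group analyses agree in expectation —
real matched designs gain more from pairing), and decoy targets are
sampled uniformly rather than by seed-match frequency. Accession-level
reproduction of real studies additionally depends on probe-collapse,
normalisation and annotation conventions that their methods rarely pin
down; `read_expression_bundle()` documents ours (highest-mean probe per
feature, no re-normalisation).

## Numerical and policy choices

* **Strict thresholds everywhere** (r > 0.7, p < 0.05, support ≥ 6 — the
  "at least" rule is the one inclusive bound —, score > 140,
  energy < −20, |logFC| gates): boundary values fail except the evidence
  support minimum.
* **Correlations over all samples** (tumour + normal) of a dataset, among
  differentially expressed features only; both choices are configurable
  (`features_a`/`features_b`, dataset subsetting) since the emulated design
  is ambiguous on them.
* **Conflicting directions**: an mRNA or lncRNA whose significant
  directions disagree across datasets loses its regulatory role
  (excluded); a conflicting miRNA is retained direction-less and drawn
  grey, and an undetermined miRNA does not block triple assembly. Both
  policies are per-kind configurable in `resolve_directions()`.
* **Degree** counts all edge kinds by default, including the dashed
  lncRNA–mRNA coexpression edges, because connectivity is analysed on the
  drawn network; `degree_edges = "regulatory"` restricts it.
* **Axis ranking** is a composite the package defines: equal-weight mean of
  min-max-normalised node degree, mean |logFC|, and cross-dataset
  direction reproducibility, with lexicographic tie-breaks. Literature
  priors are intentionally not modelled.
* **Ties and degenerate inputs**: ROC ties get half credit (trapezoid AUC
  equals the normalised Mann–Whitney U); single-class ROC input is an
  error; hypergeometric enrichment with zero overlap returns p = 1 under
  EASE; zero-variance features are skipped in correlation with a warning.

## Worked example

```{r example, eval = FALSE}
bundle <- simulate_study(sim_config(seed = 1))
run <- run_cerna_pipeline(bundle)
run
score_against_truth(run, bundle$truth)
head(run$axes[, c("lncrna_id", "mirna_id", "mrna_id", "axis_score", "rank")])
plot_network(run$network)
```

On this seed the pipeline assembles 10 triples covering all 10 planted
axes with no spurious ones; across 100 seeds at the default conditions the
mean recovery is 1.00 and the mean spurious fraction about 0.02 (the
`scripts/acceptance.R` run recomputes both).

## Problem sizes used in the shipped checks

The test suite favours many small, oracle-checked instances over large
simulations: the step-up adjustment and AUC identities are checked on 1000
random inputs each, the duplex scanner against a brute-force
dynamic-programming oracle on 200 random miRNA ≤ 10 nt / target ≤ 30 nt
instances, enrichment tails by exhaustive summation for all universe sizes
up to 60, and the end-to-end recovery on 100 seeded replicates of the
default study conditions; distributional generator properties use 20–40
replicates of a reduced bundle. These sizes are the package's own choices
and are stated here so that reported rates can be read with their Monte
Carlo resolution in mind.

## Known limitations

The duplex energies are approximate and not comparable to Vienna/miRanda
absolute values; the enrichment statistic reproduces the EASE convention
but real DAVID results depend on its (unpublished) background universe;
the ranking composite is a transparent heuristic, not a validated score;
and the pipeline's accession-level counts on real studies are sensitive to
preprocessing conventions outside its scope.
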