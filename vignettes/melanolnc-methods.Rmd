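---
title: "Methods: cell-type-adjusted lncRNA profiling in canine oral melanoma"
author: "melanolnc maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-adjusted lncRNA profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Canine oral mucosal melanoma is a spontaneous cancer arising in breeds with
strong predisposition (golden retrievers, Labrador retrievers, poodles),
and a natural model for the rare human mucosal melanomas. Bulk RNA-seq of
matched normal/tumor oral samples can reveal long non-coding RNAs (lncRNAs)
that are dysregulated in tumors — but two obstacles stand between counts
and biology. First, tumor and normal oral tissue differ massively in cell
composition (normals are keratinocyte- and muscle-rich, tumors
melanocyte-rich), so naive differential expression largely measures cell
mixture, not oncogenic regulation. Second, most canine lncRNAs have no
functional annotation, so candidate lists need orthology to the
better-annotated human genome and guilt-by-association through coding-gene
co-expression before they mean anything.

`melanolnc` implements this analysis end to end: cell-type-score-adjusted
negative-binomial differential expression, signed weighted co-expression
networks with module–trait statistics, CIGAR-based cross-species orthology,
and hypergeometric enrichment with term transfer to lncRNAs — together with
a fully seeded synthetic-cohort generator so that every stage can be
validated against a known ground truth.

# The differential-expression model

Counts for gene $g$ in sample $j$ are modeled as negative binomial,

$$K_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g), \qquad
\mu_{gj} = s_j \exp(x_j^\top \beta_g), \qquad
\mathrm{Var}(K_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2 ,$$

with size factors $s_j$ by the median-of-ratios convention and the design

$$ \sim \text{sex} + \text{cell types} + \text{breed} + \text{condition} $$

(condition last; reference levels: normal condition, alphabetically first
sex and breed). The three cell-type covariates are continuous enrichment
scores in $[0,1]$ (next section), entered unstandardized. The condition
coefficient, divided by $\ln 2$, is the log2 fold change (lFC) of tumor
versus normal *at fixed cell composition* — the quantity of interest.

Choices a user should know about:

* **Dispersion** is estimated per gene by method of moments on
  size-factor-normalized counts residualized on the design
  ($\hat\alpha = \max(\alpha_{\min}, (s^2-\bar m)/\bar m^2)$ with
  $\alpha_{\min} = 10^{-8}$, residual variance on $n-p$ degrees of
  freedom), then shrunk halfway in log space toward a log-log linear trend
  of dispersion on mean fitted across genes. The trend blend stabilizes
  gene-wise noise at $n = 52$ without an empirical-Bayes machinery.
* **Fitting** is iteratively reweighted least squares with a log link and
  $\log s_j$ offset (Fisher scoring weights $\mu/(1+\alpha\mu)$),
  converging when the largest coefficient change falls below $10^{-6}$,
  capped at 100 iterations; coefficients are clamped to $\pm 30$ on the
  natural-log scale to survive quasi-separated genes, and non-converged
  genes get missing p-values.
* **Testing** is a two-sided Wald test, $p = 2\Phi(-|\hat\beta/SE|)$. The
  covariance is the inverse Fisher information scaled by $n/(n-p)$: the
  uncorrected Wald test was measurably anticonservative at this design
  size (null rejection ~0.060 at nominal 0.05 in simulation; ~0.040 with
  the correction), and the scaling is the standard quasi-likelihood-style
  small-sample adjustment.
* **Shrinkage** of lFCs uses a zero-centered normal prior with adaptive
  variance $\tau^2 = \max(0,\ \overline{\mathrm{lFC}^2} - \overline{SE^2})$,
  giving the posterior mode
  $\mathrm{lFC}_{\text{shrunk}} = \mathrm{lFC} \cdot \tau^2/(\tau^2+SE^2)$.
  This is an approximation in the spirit of heavy-tailed-prior shrinkage,
  not a re-implementation of it: a normal prior shrinks extreme outlying
  effects harder than a heavy-tailed prior would, which matters when true
  effects are rare and huge (see Limitations).
* **Calling** uses the strict thresholds $|\mathrm{lFC}_{\text{shrunk}}| >
  1.5$ and BH-adjusted $p < 0.05$; a shrunken lFC of exactly 1.5 is *not*
  significant. Testing is done on the MLE; the shrunken value is used for
  effect-size thresholding and reporting. BH is applied plainly over all
  filtered genes (no independent filtering, no outlier replacement) — less
  powerful than pipelines with those extras, but exactly reproducible.
* **Breed-specific calls** add a `breed:condition` interaction and extract
  the per-breed condition contrast (coefficient plus interaction term, with
  the contrast variance from the full covariance). A gene is
  breed-specific iff it passes both thresholds in the target breed and has
  adjusted $p \ge 0.05$ in the comparison breed. Breeds lacking either
  condition are excluded from the interaction fit with a warning — with
  essentially no Labrador controls, the meaningful contrast is golden
  retriever versus poodle.
* The 13 matched normal/tumor pairs are *not* modeled (no individual
  term), matching the design formula above; p-values are therefore mildly
  conservative for the paired subset.

# Cell-type scores

The cell-type covariates are single-sample signature scores: for a sample
(expression column) and a marker set $S$, the score is the mean
within-sample rank of the marker genes divided by $G+1$. It is invariant
under any strictly increasing transform of the column, lies in $(0,1)$,
equals 0.5 in expectation for a random set, and is rescaled per cell type
to $[0,1]$ across samples before entering the design. Three signatures are
used by default — keratinocyte, melanocyte, skeletal muscle — the cell
types whose mixture differs most between normal oral mucosa and melanoma.
A full signature-enrichment framework with spillover compensation is
deliberately out of scope: the scores serve only as design covariates, and
a rank statistic is transparent, dependency-free, and testable.

# Co-expression networks

Expression (normalized counts or TPM; `log2(x+1)` by default, with a raw
switch, because log correlation is robust to single-sample outliers) is
reduced to the most variable genes (top-$N$ by variance, ties broken by
gene id), then:

1. **Signed adjacency** $a_{ij} = ((1+\mathrm{cor}_{ij})/2)^\beta$ with
   Pearson correlation and soft power $\beta = 7$ by default. The
   scale-free fit table (binned $\log_{10} p(k)$ on $\log_{10} k$
   regression) is reported for a power grid, and an explicit $\beta$
   always wins over the recommendation.
2. **Topological overlap**
   $\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
   (\min(k_i,k_j) + 1 - a_{ij})$.
3. **Modules** are branches of the average-linkage tree of
   $1-\mathrm{TOM}$, cut at a constant height equal to the 0.90 quantile
   of the merge heights; clusters smaller than `minSize` (default 10)
   become grey, and modules whose eigengenes correlate above 0.85 are
   merged. We verified on planted-module simulations that cutting near the
   top of the tree (e.g. the 0.99 quantile) sits *above* the separation
   between module branches and the loose background and fuses distinct
   modules; 0.90 recovers planted modules essentially perfectly across
   seeds. This constant-height procedure deliberately replaces adaptive
   branch-cutting; absolute module counts will therefore differ from
   analyses using the adaptive cutter, and we treat module membership, not
   module count, as the meaningful output.
4. **Eigengenes** are the first principal component of the
   gene-standardized module submatrix (unit norm, sign oriented to
   correlate non-negatively with the mean module profile), and
   module–trait association is the Pearson correlation of the eigengene
   with the trait, $p$ from the $t$ transform on $n-2$ degrees of freedom.
   Per-breed module–trait vectors are obtained by subsetting samples to
   one breed before calling the same functions.
5. **Hubs** are genes with $|GS| > 0.5$ and $|MM| > 0.5$, strictly.

DE lncRNAs are overlaid on the module partition and split by the sign of
their module's significant trait correlation; because rounding and
truncation of the reported percentage differ at the first decimal, both
are returned.

# Orthology

Each query gene is represented by its **meta-transcript**: the interval
union of all exons over all transcripts, with the spliced sequence
(reverse-complemented on the minus strand) when a genome is supplied.
Users align meta-transcripts with any spliced aligner (e.g. `minimap2 -ax
splice`); the package consumes SAM or PAF text and keeps only primary
alignments.

**Identity** is matching bases over alignment columns, computed from the
CIGAR: columns are `{=, X, M, I, D}` — indels are columns of the
alignment; intron skips (`N`) and clips (`S`, `H`) are not. With plain `M`
CIGARs the match count requires the edit-distance tag
(`matches = M + I + D − NM`); without it the call errors rather than
guessing. Identity is computed over the whole primary alignment, not a
best-scoring segment.

**Classification**: queries with no primary alignment are `unaligned`;
identity below the 0.70 screen is `below_identity` (the screen is
inclusive — exactly 70% passes — and is a reporting filter, not a validity
rule: lowering it rescues biologically interesting sub-threshold hits);
otherwise the alignment blocks (`M/=/X/D` extend, `N` splits, `I` is
query-only) are intersected with the target annotation under strand-aware,
split (exon-level) semantics, and the query becomes `annotated_ortholog`
to the gene with maximal exon-overlap bases (ties to the lexicographically
smallest gene id) or `novel_aligned` when no exon is touched. Genes whose
exons span multiple chromosomes or strands (assembly artifacts) are
rejected at annotation load.

# Enrichment and guilt by association

Module mRNAs are tested against gene sets by the upper-tail
hypergeometric, $P(X \ge k)$, over the universe of genes that entered
co-expression, with BH adjustment across terms within a module; lncRNAs
are excluded from the tested sets (the sets describe coding-gene
function). A ranked gene-set statistic is not used because modules are
unordered sets. Each lncRNA then inherits its module's significant terms
($q < 0.05$) together with the module's direction of trait correlation;
grey lncRNAs inherit nothing.

# The synthetic cohort

`simulationConfig()` defaults define the study conditions: 52 samples from
39 dogs — 13 matched normal/tumor pairs plus 26 tumor-only animals across
GRET (16 dogs), LABR (13) and PODL (10), with only one Labrador pair so
that the Labrador-controls scarcity of real cohorts is reproduced; 2000
genes across protein-coding, lincRNA, antisense and sense-intronic
biotypes; NB counts with log-normal dispersions ($\ln \alpha \sim
N(\log 0.1, 0.5)$), log-normal base means, and true size factors uniform
in $[0.5, 2]$ (geometric mean 1).

Planted structure, all recorded in the ground truth:

* **DE genes** (10% by default) with log2 effects uniform in $[1,3]$,
  random sign, or a signed point mass.
* **Cell-type mixing** that confounds condition: per-sample Dirichlet
  proportions around (keratinocyte, melanocyte, muscle) weights of
  (0.5, 0.2, 0.3) in normals and (0.1, 0.8, 0.1) in tumors, concentration
  10 — chosen so that tumor purity varies as widely as it does in real
  resections; much tighter mixing would make melanocyte content collinear
  with condition and the adjusted condition effect unidentifiable. Thirty
  markers per type (disjoint, protein-coding, never planted DE) gain
  `cellEffect = 2` log2 units per unit proportion.
* **Latent modules**: three factors with loadings 0.7 on 50–150 genes
  each; factor–condition correlations (0.7, −0.7, 0) by default, mirroring
  positively and negatively tumor-associated modules. Because a
  condition-correlated factor gives its genes a *real* condition effect
  ($\lambda\rho/\mathrm{sd}(c)$ log2 units), those genes are recorded as
  true DE — planted effects, marker effects and module memberships are
  kept mutually disjoint so every planted fact has a single cause.
* **Orthology**: one third of query lncRNAs get a primary spliced
  alignment whose CIGAR reproduces a drawn identity in $[0.72, 0.98]$
  exactly (mix of `=`, `X`, `I`, `D`, `N`); a fifth of those land on
  annotated target genes; 30% of the rest align below threshold
  ($[0.45, 0.65]$); 10% of aligned queries get a secondary decoy record.

Everything is deterministic given the seed (R Mersenne-Twister with
inversion normals, pinned explicitly), and every planted fact is
re-derivable from the emitted files alone — the consistency the test suite
verifies.

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: no read-level or sequence-content
realism; no isoform structure (gene-level counts only); no within-pair
correlation between a dog's normal and tumor sample; no breed-specific
expression architecture beyond random nuisance shifts; cell-type effects
that are exactly log-linear in proportions (real marker genes saturate);
and GO-like terms that mark planted modules by construction. Passing
recovery tests demonstrates that the estimators invert the generator's
model class at cohort scale, not that the model class captures oral
melanoma biology.

**Calibration conditions.** Type-I error is measured on a null
configuration (no planted DE, no latent modules, cell-type confounding
retained): latent factors are planted structure whose per-seed chance
correlation with condition produces real, correlated shifts, so they
belong in the FDR scenario (where their effects are part of the recorded
truth), not in the null. FDR, power, score recovery and module recovery
(ARI) use the full default configuration.

# Problem sizes and numerical conventions

Validation runs use the cohort at its natural scale — 2000 genes by 52
samples for DE (one seed each for type-I and FDR in the test suite,
pooled seeds in the acceptance script), 600-gene networks for module
recovery over 10 seeds, and 20 replicates of a 370-gene cohort for the
covariate-adjustment sign test. Other conventions: expression filter
keeps genes with ≥ 10 total reads (boundary inclusive) and biotypes
{protein-coding, lincRNA, antisense}; sense-intronic genes are parsed and
carried but excluded by the default filter; TPM requires explicit
effective lengths (no imputation); PCA operates on `log2(x+1)` of
normalized counts; all module/color assignments, variance-filter ties and
ortholog ties have deterministic tie-breaks so that reruns are
byte-identical.

# Known limitations

* The normal shrinkage prior over-shrinks rare extreme effects when the
  overall DE signal is weak ($\tau^2$ collapses); heavy-tailed priors
  degrade more gracefully.
* The Wald test with moment dispersions is approximate; the $n/(n-p)$
  covariance scaling centers its size near nominal at this design but is
  not an exact small-sample theory.
* Constant-height branch cutting trades the adaptive cutter's sensitivity
  on nested modules for reproducibility; module counts are not comparable
  across procedures.
* The rank-based cell score is a monotone, not calibrated, proxy for cell
  proportions; adjustment removes most but not all composition signal.
* Orthology identity treats the primary alignment as a whole; a
  best-segment definition would score chimeric alignments differently.
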