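---
title: "Discriminative sequence models for expression-genotype linking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative sequence models for expression-genotype linking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsmlink)
```

# The model

## Copying-chain backbone

A phased genotype profile over $V$ biallelic sites is a pair of haplotypes
$x = (h^m, h^p)$, $h_s \in \{0, 1\}$. Each haplotype is modelled as an
error-prone mosaic copy of a reference panel of $K$ haplotypes (the
Li–Stephens model): a hidden state $z_s \in \{1, \dots, K\}$ indexes the
panel haplotype being copied at site $s$,

$$p_{\mathrm{HMM}}(h, z) \;=\; \pi(z_1)\,\varepsilon(h_1 \mid z_1)
\prod_{s=2}^{V} \tau(z_s \mid z_{s-1})\,\varepsilon(h_s \mid z_s),$$

with a uniform initial prior $\pi$, a symmetric copying error
$\varepsilon \in (0, 0.5)$ (default 0.01; the source material only calls it
"small"), and the switch transition

$$\tau(z_s \mid z_{s-1}) = (1-\rho_s)\,\mathbf{1}[z_s = z_{s-1}] + \rho_s / K,
\qquad \rho_s = 1 - \exp(-c\,\Delta g_s / K),$$

where $\Delta g_s$ is the genetic-map distance in centimorgans between
consecutive sites and $c$ (`recombScale`, default 1) rescales the map. A
switch re-selects the copied haplotype uniformly, self included. This is the
standard parameterization used by imputation-style copying models; the exact
form used by the original authors is not printed in their main text, so this
is a documented choice, not a claim of equivalence. Degenerate maps
($\Delta g = 0$ everywhere) are legal and collapse the chain to a single
copied haplotype with errors.

All chain computations (`forwardBackward`, `hmmLogLik`, the batched training
passes) use per-site scaled forward–backward recursions, compiled via Rcpp,
and run without underflow for chains of at least $10^5$ sites; a pure-R
path-enumeration oracle (`bruteForceMarginal`, and an internal paired-chain
enumerator for the diploid case) provides the independent reference that the
test suite compares against to $10^{-10}$ in log space.

## eQTL factors and the conditional random field

Each eQTL $s$ (a panel site with an associated eGene set $Q(s)$) carries a
logistic factor shared by the two haplotypes,

$$\phi_s(h_s, e_{Q(s)}) = h_s\,\sigma(\alpha_s + \beta_s^\top e_{Q(s)})
+ (1 - h_s)\,\bigl(1 - \sigma(\alpha_s + \beta_s^\top e_{Q(s)})\bigr),$$

which enters the chain as external per-site evidence (`SiteEvidence`); panel
sites outside the eQTL map carry weight 1. Allowing $|Q(s)| > 1$ lets
correlated eGenes reinforce one another instead of being reduced to the single
most significant gene. The unnormalized conditional over a haplotype is

$$\tilde p_{\mathrm{DSM}}(h \mid e) = \sum_z p_{\mathrm{HMM}}(h, z)
\prod_s \phi_s(h_s, e_{Q(s)}),$$

and the diploid model factorizes across the two haplotypes (the *haplotype
approximation*), which reduces inference from quadratic to linear in $K$.
`dsmExactDiploidLogScore` retains the joint $(z^m, z^p)$ chain with a
genotype-level factor for small instances, to quantify the approximation: with
product-form genotype factors it equals the decoupled score exactly (an
identity the tests assert), and a 3-level cumulative-logit dosage factor
(cutpoints $\pm 1$ by default) provides a genuinely non-factorizable
alternative exercised only in those comparisons.

## Training

Because the evidence factor $\phi_s(h_s, \cdot)$ multiplies every hidden-state
path, $\log \tilde p_{\mathrm{DSM}}(h \mid e) = \log p_{\mathrm{HMM}}(h) +
\sum_s \log \phi_s(h_s, e)$. Maximizing this *unnormalized* quantity therefore
degenerates to independent per-site logistic regression and cannot calibrate
for LD. `trainDSM` instead maximizes the normalized conditional log
likelihood

$$\sum_i \sum_{h \in \{h^m_i, h^p_i\}}
\Bigl[\log p_{\mathrm{HMM}}(h) + \sum_s \log \phi_s(h_s, e_i) - \log Z(e_i)\Bigr],
\qquad
Z(e) = \sum_{h'} p_{\mathrm{HMM}}(h') \prod_s \phi_s(h'_s, e),$$

where $Z(e)$ is computed by a forward pass with the haplotype summed out of
the emission. It is the normalizer that couples the factors across sites:
when two linked sites carry the same eGene signal, inflating both factors
inflates $Z$ as well, so joint training absorbs the redundancy instead of
double-counting it. The test suite checks this directly — the trained model's
held-out joint log loss is no worse than a naive product of independently
fitted per-site logistic factors on an LD-block fixture, and duplicating an
eGene leaves the combined logit $\alpha + \beta^\top e$ at the single-gene
fit's value.

The gradient has the classic observed-minus-expected form: with $q_s(e) =
P(h_s = 1 \mid e)$ the posterior allele probability from the same
forward–backward pass, $\partial \ell_i / \partial l_s = d_{is} - 2 q_s(e_i)$,
where $l_s$ is the factor logit and $d$ the dosage. Analytic gradients are
verified against central finite differences (relative error below $10^{-4}$;
observed around $10^{-8}$) on random instances.

Optimization is full-batch Adam with the published defaults (learning rate
0.025, 50 epochs) from a symmetric start $\alpha = \beta = 0$; chain
parameters are frozen (the source only learns the factors). Fifty Adam steps
bound each coordinate's movement by roughly $50 \times 0.025 = 1.25$, which is
adequate for chromosome-scale windows with hundreds of samples per window but
underfits small, strong-signal fixtures; the parameter-recovery experiment
below therefore trains to convergence (400 epochs). Per-gene expression is
standardized to zero mean and unit variance on the training data and the
standardization is frozen into the model (upstream pipelines are assumed to
have applied their own normalization already). Factor probabilities are
clipped to $[10^{-12}, 1 - 10^{-12}]$ before logs. Training aborts on a
non-finite objective. `trainDSMWindows` partitions the eQTLs into consecutive
windows (published default 750 per window) over contiguous panel segments; a
switch probability of 1 at a window boundary makes windowed and joint training
exactly equal, which the tests verify to $10^{-10}$.

## Match score and P-values

Candidates are ranked by $M(x, e) = \tilde p_{\mathrm{DSM}}(x \mid e) /
p_{\mathrm{HMM}}(x)$; dividing by the chain prior removes the preference for
candidates that are merely common haplotypes (for a fixed query, ranking by
$M$ is equivalent to ranking by $p(e \mid x)$). Under the haplotype-decoupled
factors the chain terms cancel exactly and

$$\log M(x, e) = \sum_s \bigl[d_s \log p_s + (2 - d_s) \log(1 - p_s)\bigr],
\qquad p_s = \sigma(\alpha_s + \beta_s^\top e_{Q(s)}),$$

so `scoreAll` is a single matrix product in the candidate dosage matrix; a
test asserts the identity against the marginal-minus-prior chain route. With
flat factors ($\alpha = \beta = 0$) every candidate ties at $2V \log 0.5$ —
the no-signal degeneracy.

`fitNull` models each query's mismatching scores as a Gaussian (mean and sd of
the off-true row entries; at least 30 mismatches required, zero variance
refused) and `matchPValue` returns the upper-tail probability. The per-query
(row-wise) null follows the per-individual P-value presentation of the source;
a subsampled candidate null of 500 is the default in the CLI
(`--null-subsample`).

# Linking evaluation

`linkForward` assigns each query its row argmax independently (no bipartite
matching), breaking ties deterministically toward the smallest candidate
identifier and flagging them, since ties indicate zero signal. `linkReverse`
reads the transposed matrix. For unknown membership, `thresholdedLinking`
calls links only above a score threshold and sweeps it: TPR is the fraction of
present-match queries called *and* correctly linked; FPR the fraction of
queries without any matching candidate that are called; precision the correct
calls over all calls; AUROC/AUPRC by trapezoid. `holdoutLinking` repeats this
over seeded random holdouts (default: half the queries' true candidates
removed, 100 trials). Note one consequence of the correctness term in TPR:
with many candidates and uninformative scores, chance-level AUROC tracks the
chance linking accuracy (near 0), not 0.5; the chance-level property holds for
the membership signal itself, which the tests probe in a single-candidate
configuration.

# Baselines

`pruneEQTLs` implements greedy correlation pruning: eQTLs in decreasing
significance order, retaining each whose training-dosage Pearson $|r|$ with
all retained eQTLs is at most the threshold (published operating point 0.1);
constant-dosage sites are excluded with a warning. `gnbFit`/`gnbLogScore`
implement Gaussian naive Bayes over dosage classes $\{0, 1, 2\}$ (phase
carries no expression signal): per-class means of the single eGene's
expression with a pooled within-class standard deviation and a smoothed
genotype-frequency prior. Classes with fewer than two samples fall back to a
linear dosage fit for their mean; add-one smoothing keeps unseen classes
finite; zero-variance genes floor the sd at $10^{-6}$ with a warning. The
unpublished "additional normalization heuristics" of the original method are
deliberately omitted.

`eblFit`/`eblLogScore` implement extremity-based linking in its hybrid form:
for eQTLs passing a correlation filter ($|r| \ge$ `corrMin`), query expression
beyond the training extremity quantile (`extremityQ`, two-sided) predicts the
homozygote on the association's side; agreeing candidates contribute 0,
disagreeing ones $-\lambda$ (default 5 nats; $\lambda = \infty$ recovers hard
filtering; the original method counts matches, which a flat per-site penalty
generalizes). Non-extreme genes contribute their Gaussian naive Bayes term,
so with nothing extreme the score collapses to GNB exactly. `tuneEBL` grid
searches both thresholds on training linking accuracy, mirroring the original
protocol of optimizing them; the default grids
($q \in \{0.8, 0.9, 0.95, 0.99\}$, $|r| \in \{0.1, 0.3, 0.5\}$) are this
package's documented choice, as the original ranges are not printed.

# The synthetic-data framework

`simulatePanel` draws sites in consecutive LD blocks (`ldBlockSize`, default
5): each block has its own founder pool (`nFounders`, default 4, kept
polymorphic at every site) that panel haplotypes copy with a small per-site
error (`founderError`, default 0.02), so within-block sites are correlated and
blocks are independent; allele frequencies are nudged into $[0.05, 0.95]$.
Physical spacing is 1 kb; the genetic map is uniform at `cmPerSite` (default
0.02 cM, i.e. sparse recombination across a 300-site window).
`simulateIndividuals` draws each haplotype from the copying process itself
(the model's own switch probabilities and copy error), so the chain prior is
exactly well-specified — deliberate, so that oracle and recovery tests isolate
implementation correctness from model misfit; a `hotspots` argument provides a
misspecified-recombination mode for robustness checks. `simulateExpression`
is the linear-dosage model $e_g = \sum_{s: g \in Q(s)} \mathrm{effect}_{s,g}
\cdot d_s + \text{noise}$ with Gaussian noise of sd `noiseSd` (or Student-t
with `noiseDf` degrees of freedom, the heavy-tailed regime that motivates
extremity-based linking); each eQTL's eGenes share its effect sign, creating
the redundant signals the DSM must calibrate away. `makeLinkingFixture`
assembles disjoint train/test cohorts, decoys from the same panel (optionally
from a frequency-shifted panel, emulating an ancestry-mismatched candidate
pool), and the ground-truth pairing.

What the generator does *not* emulate: realistic allele-frequency spectra and
demography, selection, tissue-dependent expression covariance beyond
shared-eQTL coupling, measurement batch structure, and the scale of real eQTL
maps (tens of thousands of eQTLs per chromosome). Passing tests therefore
demonstrate correctness of the algorithms and the claimed relative behaviour
of the methods under the stated generative assumptions — not linking accuracy
on real cohorts.

# Experimental designs used by the tests and acceptance script

**Standard linking fixture** (`simConfig()` defaults): $K = 60$, $V = 300$ in
blocks of 5, 150 eQTLs $\times$ 3 eGenes plus 50 noise genes, effect 1, noise
sd 1, 300 training and 50 test individuals, 250 decoys. At this scale the DSM
is trained with the published defaults and compared against the baselines over
10 seeds; decoy-set growth is checked for monotone degradation.

**Parameter recovery**: 40 *independent* eQTLs — realized genetically as
unlinked sites (100 cM spacing) at common variants (two balanced founders) —
single eGene each, slope 2 on noise sd 0.25, $n = 500$, trained to
convergence (400 epochs). Two properties of the haplotype-decoupled model
shaped this design: the dosage posterior is Binomial$(2, q)$, so a
heterozygote is called correctly only while $q \in (1/3, 2/3)$; tightly linked
sites let the chain identify one parental panel row and pull heterozygote
posteriors off $1/2$, and skewed allele frequencies do the same through the
frequency prior. Under LD or rare variants this is a genuine accuracy
ceiling of the approximation, not an implementation artifact. The permuted
control shuffles expression against genotypes before training and checks that
held-out allele posteriors collapse to $0.5 \pm 0.1$.

**Null calibration**: one window at the published window scale — $V = 600$,
450 eQTLs in blocks of 2, weak effects (0.2) — the regime in which a Gaussian
null for match scores is justified by aggregation over many weakly correlated
sites. P-value uniformity is checked on 2,000 truly unmatched queries against
500 candidates with the designated "true" candidate rotating across queries
(fixing one candidate for all queries would inject that candidate's random
effect into every P-value); model-based P-values from a 500-candidate
subsample are compared to empirical ranks on 2,000 candidates on the log–log
scale. The weak effects also keep true-match scores inside the empirically
resolvable range ($p \ge 1/2000$), which is what makes the comparison
informative. On the 150-eQTL default fixture the score null is visibly
skewed and the Gaussian P-values are not uniform — a scale effect worth
remembering when applying the null model to small eQTL windows.

# Numerical choices and edge cases

* Scaled linear-space recursions with per-site renormalization; degenerate
  (all-zero) evidence at a site raises an error rather than returning
  $-\infty$.
* Factor probabilities clipped at $10^{-12}$; the clip is outside the range
  gradient tests explore.
* Argmax ties break toward the smallest candidate identifier and are flagged.
* `bruteForceMarginal` refuses instances beyond $10^6$ paths; the exact
  diploid chain refuses joint state spaces beyond $10^4$ (configurable).
* Multiple eQTL records on one variant are merged into a single factor site
  (one site, one factor), pooling their eGene sets.
* VCF input: biallelic, phased records only (strict mode errors, non-strict
  skips with a warning); 0 = REF, 1 = ALT in file orientation, never
  re-polarized; without a genetic map a uniform 1 cM/Mb fallback is applied.
* CLI provenance contains no timestamps, so a fixed `--seed` reproduces every
  output byte for byte; model bundles embed the eQTL-map fingerprint and
  `link` refuses a mismatching map file.

# Known limitations

* The haplotype approximation caps per-site dosage accuracy for heterozygotes
  at linked or frequency-skewed sites (see above); the exact diploid model is
  provided only at oracle scale.
* The Gaussian match-score null is an asymptotic-in-sites approximation; on
  small windows it is visibly miscalibrated.
* Training is full-batch and single-threaded; the intended scale is the
  per-window regime (hundreds of eQTLs), not whole chromosomes at once.
* EBL's original normalization heuristics and exact grid ranges are not
  public; this package's defaults are documented stand-ins.

```{r session}
sessionInfo()
```
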