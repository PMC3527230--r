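---
title: "Modeling codon substitution as a function of solvent accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling codon substitution as a function of solvent accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsaevol)
```

## The model

Residues buried in a protein core evolve more slowly than residues exposed
to solvent. `rsaevol` builds this dependence directly into a codon
substitution model. The substitution process over the 61 sense codons of the
standard genetic code is a reversible Markov process with infinitesimal
generator $Q(r)$ whose off-diagonal entries, for codons $i \neq j$, are

$$
Q_{ij}(r) \;=\;
\begin{cases}
0 & \text{more than one nucleotide differs} \\
\Pi_j & \text{synonymous transversion} \\
\kappa(r)\,\Pi_j & \text{synonymous transition} \\
\omega(r)\,\Pi_j & \text{nonsynonymous transversion} \\
\kappa(r)\,\omega(r)\,\Pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

where $r \in [0,1]$ is the relative solvent accessibility (RSA) of the
residue encoded at the site, $\Pi_j$ is the stationary frequency of the
target codon, $\omega$ is the nonsynonymous/synonymous rate ratio and
$\kappa$ the transition/transversion ratio. The finite-time transition
matrix over an evolutionary distance $t(r)$ is $P(r) = \exp[t(r)\,Q(r)]$.
All three quantities $\omega$, $t$ and $\kappa$ may depend on $r$.

Because a continuous covariate cannot enter the matrix directly, RSA is
discretized into $n$ evenly spaced bins and every value within bin $k$ is
represented by the bin mid-point $r_k$; the continuous model is approximated
by $n$ discrete matrices $Q_k = Q(r_k)$ that share parameters. Each
parameter takes one of three functional forms:

* **constant** — one RSA-independent value (1 degree of freedom);
* **linear** — intercept plus slope, e.g.
  $\omega(r) = \omega_0 + \omega_1 r$ (2 df);
* **per-bin** — an independent value in each bin ($n$ df).

The cross of three forms over three parameters yields 27 GY94-family model
specifications, compared by AIC $= 2\,\mathrm{df} - 2\ln L$. The MG94-family
variant replaces $(\omega, t)$ by a synonymous rate $\alpha$ and a
nonsynonymous rate $\beta$; it is defined here through the correspondence
$\alpha \leftrightarrow t$, $\beta \leftrightarrow t\,\omega$, so both
families share the target-codon-frequency convention above and coincide
whenever all parameters are RSA-independent. A nucleotide-frequency MG94
would give slightly different likelihoods; the correspondence definition is
deliberate, because it makes "is $\omega$ linear in $r$, or are $\alpha$ and
$\beta$ individually linear?" a pure question of parameterization, decidable
by AIC on equal df.

## Likelihood

For two aligned sequences the likelihood uses a stationary root at one tip:
a site in bin $k$ with ordered codon pair $(i, j)$ contributes
$\log(\pi_i P_k[i,j])$. Under reversibility this is equivalent to the
two-branch tree with an unobserved root (pulley principle) and halves the
computation. Sites are independent, so the data reduce to per-bin counts of
ordered codon pairs; `binPairCounts()` builds exactly these sufficient
statistics, and the test suite asserts that the binned likelihood equals a
naive site-by-site evaluation and is invariant to swapping the sequences.

Codon frequencies $\Pi_j$ use the F3×4 construction — products of empirical
nucleotide frequencies at the three codon positions, renormalized over the
61 sense codons. They are estimated once from both sequences of the whole
alignment, held fixed during optimization, and not counted as degrees of
freedom; this is what makes the all-constant GY94 model a 3-df model.

## Parameters, defaults, units

| parameter | meaning | default start | bounds |
|---|---|---|---|
| $\omega$ | nonsynonymous/synonymous rate ratio | 0.2 | $(10^{-6}, 100)$ |
| $\kappa$ | transition/transversion rate ratio | 2 | $(10^{-6}, 500)$ |
| $t$ | branch length, arbitrary rate units | 0.3 | $(10^{-6}, 50)$ |

$t$ is *not* rescaled to one expected substitution per unit time, neither
globally nor per bin. The unit is fixed by the generator itself (a
synonymous transversion to codon $j$ occurs at rate $\Pi_j$). Per-bin
rescaling would silently redefine $t(r)$ bin by bin and destroy the
hypothesis that $t$ is linear in $r$, which is one of the hypotheses the
model space is meant to test.

The default bin count is $n = 20$: large enough to approximate a smooth RSA
dependency, while linear forms keep the df low regardless of $n$.

## Optimization and numerical choices

* $Q$ is reversible, so $P = \exp(tQ)$ is computed through the symmetric
  similarity transform $S = \Pi^{1/2} Q\, \Pi^{-1/2}$ and one
  eigendecomposition of $S$ per distinct $(\omega, \kappa)$; all $t$ values
  reuse the same decomposition. The dense exponential in `ape` serves as an
  independent cross-check in the tests. Round-off negatives in $P$ are
  clamped to zero; codons with zero frequency are isolated as absorbing
  states.
* Fitting uses bounded L-BFGS-B with 5 seeded restarts (first start at the
  defaults above, slopes 0; restarts jittered by ±50%). Restarts guard
  against the roughness that binning-induced aliasing can create in the
  likelihood surface.
* Positivity: every evaluated parameter must exceed $10^{-6}$ at every
  *occupied* bin mid-point. Intercepts and per-bin values are box-bounded;
  for linear forms with negative slope the objective adds a smooth penalty
  that pushes the optimizer back into the feasible region. A linear form may
  extrapolate negative outside the occupied bins — only the $n$ discrete
  $r_k$ actually used matter.
* Per-bin values in unoccupied bins are unidentifiable; they are reported as
  `NA` but still counted in the df of the specification, so that df depends
  only on the model form, not on the data.
* Ties in AIC ranking break by smaller df, then by model label.
* LRT p-values use the asymptotic $\chi^2$ on the df difference, with no
  boundary correction: under this parameterization slopes are interior
  parameters, and the 200-replicate calibration test confirms the nominal
  5% level.
* Degenerate inputs error early and specifically: non-sense codons, RSA
  outside $[0,1]$, fewer than 2 bins, alignments that are not two equal
  length in-frame sequences, sites with no usable codons.

## Sites with gaps, ambiguity codes, or no RSA

Any codon containing a non-ACGT character in either sequence is excluded
from the counts (no partial likelihood over ambiguities), as is any site
without an RSA value (unresolved residues, positions without structure).
Exclusions are tallied and reported. ASA values are normalized by the
Miller et al. (1987) extended Gly-X-Gly maxima by default; the table is an
argument, so any alternative published maxima can be substituted. RSA values
above 1 — possible with any maxima table when DSSP reports a distorted
residue — are clamped to 1 rather than rejected.

## Derived rates: two definitions of dN and dS

$dN$ and $dS$ are not fitted parameters; they are computed from the fitted
model. Expected substitution numbers per site come from the rate flow
$t \sum \pi_i Q_{ij}$ over synonymous and nonsynonymous pairs. Site counts
come in two flavors:

* **physical sites** — each of a codon's nine single-nucleotide mutations
  contributes 1/3 of a site, classified by the amino-acid comparison;
* **mutational opportunity** — sites weighted by the probability of a
  synonymous versus nonsynonymous change under the fitted mutation process
  with selection removed ($\omega = 1$, fitted $\kappa$).

Mutations that create stop codons are excluded from both the numerators and
the site counts in both definitions — the substitution process lives on
sense codons, and the simulator never produces stops. As a consequence the
physical total is slightly below 3 sites per codon (by the stop-mutation
fraction), and the mutational-opportunity counts are normalized to that same
total rather than to exactly 3. Any common normalization cancels from
$dN/dS$; this particular one makes the two definitions coincide exactly when
$\kappa = 1$ and frequencies are uniform, which the tests assert. Under the
mutational-opportunity definition $dN/dS$ equals the fitted $\omega(r_k)$
identically — the consistency check tying the fitted rate-ratio curve to the
derived rate profile. Site counts use the stationary frequencies, not
per-bin empirical codon usage, keeping the profile a pure function of the
fitted model.

## Grouped fits

To compare gene classes (large-core vs small-core proteins, high- vs
low-expression genes), `fitGroupedModel()` maximizes one joint likelihood
over several data groups: a single $t(r)$ and $\kappa(r)$ shared by all
groups, and a linear $\omega(r)$ per group whose intercept and slope are
each mapped to *tie classes* — groups sharing a class share the value. This
expresses all three designs of interest: free lines per group; the
common-intercept restriction (is selection on fully buried residues the
same across classes?); and factorial designs where the slope is tied to one
factor only. Restricted fits refit *all* parameters under the constraint,
the standard likelihood-ratio practice. Tying everything reproduces the
pooled single-model fit, which the tests verify.

## What the simulator emulates — and what it does not

`simulateCodonPair()` draws, per site: RSA from a configurable distribution
(uniform; beta; or an "empirical-like" mixture,
$0.6\,\mathrm{Beta}(0.7, 3.5) + 0.4\,\mathrm{Beta}(2.5, 2)$, chosen once to
mimic the buried-skewed, long-tailed RSA histograms of globular proteins);
the bin; an ancestral codon from $\Pi$; and a descendant codon from the
ancestral row of $P_k$. Output is deterministic given the seed.

The generator matches the likelihood's assumptions exactly, which is the
point: it makes parameter recovery, model ranking, LRT calibration and
goodness-of-fit checks possible without external data. For the same reason a
green test establishes *internal* correctness only. Real data violate the
stated world in ways the simulator does not reproduce: RSA is spatially
autocorrelated along the chain and drifts over evolutionary time (here it is
i.i.d. per site and fixed), rate variation exists beyond RSA, codon
frequencies vary among genes and with RSA, and alignments contain indels and
misalignment. Recovering $(\omega_0, \omega_1)$ from simulation says the
estimator works, not that any particular organism's slope has been measured.

## Known limitations

* Pairwise alignments only; no multi-taxon trees or branch-length vectors.
* One rate ratio regardless of which amino acids are exchanged;
  no amino-acid-dependent exchangeabilities, no mutation-selection
  (FMutSel-style) extension.
* No rate variation within an RSA bin.
* Codon frequencies are global F3×4: not per-bin, not per-gene, not
  optimized.
* The standard genetic code is fixed; alternative codes are out of scope,
  which keeps df accounting unambiguous.
* Structure processing starts at ASA tables or DSSP output; computing ASA
  from coordinates and mapping sequences to structures are upstream of this
  package.
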