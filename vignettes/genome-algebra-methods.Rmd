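---
title: "Methods: permutation clouds and maximum likelihood rearrangement distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation clouds and maximum likelihood rearrangement distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomealg)
```

## The model

An unsigned circular genome with $N$ identified regions is recorded as a
permutation $\sigma \in S_N$: $\sigma(i) = j$ means region $i$ occupies
position $j$. The position labels depend on an arbitrary reference frame, so
the $2N$ permutations $\{d\sigma : d \in D_N\}$ — the right coset of the
dihedral group — all describe the same physical molecule. `genomealg`
represents the genome by its *permutation cloud*
$$\mathbf{z}\sigma, \qquad \mathbf{z} = \tfrac{1}{|Z|}\sum_{z\in Z} z,$$
an element of the genome algebra $\mathcal{A} = \mathbf{z}\,\mathbb{R}[S_N]$.
The symmetry subgroup $Z$ is dihedral by default, but any subgroup of $S_N$
is accepted (`"reflection"` for genomes with an origin of replication,
`"rotation"`, `"trivial"`, or explicit generators), and all machinery below
is written for general $Z$.

Evolution is a sequence of independent rearrangement events in continuous
time. A model is a pair $(\mathcal{M}, w)$: a set of rearrangement
permutations acting on the left, with a probability distribution $w$. Two
conditions matter:

* **M1 (model symmetry).** $\mathcal{M}$ is closed under conjugation by $Z$
  with conjugates equally weighted — the model cannot depend on the arbitrary
  reference frame. Users supply base *types* (e.g. "swap two adjacent
  regions" as `(1 2)`); `build_model()` expands each type into its
  conjugation orbit, splits the type weight uniformly over the orbit's
  distinct elements, and renormalizes globally. A type therefore keeps its
  total relative rate whether its orbit has $2N$ elements or, as for
  inversions, only $N$.
* **M2 (reversibility).** $a^{-1} \in \mathcal{M}$ with $w(a^{-1}) = w(a)$;
  equivalent to time-reversibility of the induced Markov chain and required
  for the spectral computations (it makes all representation matrices of the
  model element symmetric). `build_model()` enforces it by default.

The number of events in time $T$ is Poisson with rate 1, so $T$ is measured
in expected numbers of rearrangement events. The likelihood of observing
target genome $\mathbf{z}\sigma$ after time $T$, starting from the reference
cloud $\mathbf{z}$, is
$$L(T \mid \sigma) = \sum_{k \ge 0} \alpha_k(\sigma)\,\frac{e^{-T} T^k}{k!},$$
with $\alpha_k$ the probability that $k$ model-drawn events transform the
reference into the target cloud. The *MLE of evolutionary distance* is the
maximizer $T^*$ of this curve — when one exists.

## The spectral computation

The model element $\mathbf{s} = \sum_a w(a)\,a$ satisfies
$\mathbf{z}^2 = \mathbf{z}$ and $\mathbf{z}\mathbf{s} = \mathbf{s}\mathbf{z}$
(both tested *exactly*: algebra elements carry rational coefficients). For
each partition $p \vdash N$ the package builds the Young-orthogonal
representation $\rho_p$ (dimension $D_p$ by the hook-length formula), the
projection $\rho_p(\mathbf{z})$ — idempotent with spectrum in $\{0,1\}$ —
and an orthonormal basis $Q_p$ of its 1-eigenspace of dimension $k_p$. The
reduced representation
$$\rho_p^{\mathcal{A}}(\tau) = Q_p^{\mathsf T}\, \rho_p(\tau)\, Q_p$$
acts on the $k_p$-dimensional module $W_p = \mathbf{z} V_p$; the counting
identity $\sum_p D_p k_p = N!/|Z|$ (the number of distinct genomes) is
verified for every model the tests build. Eigendecomposing each symmetric
$k_p \times k_p$ matrix $\rho_p^{\mathcal{A}}(\mathbf{z}\mathbf{s})$ into
distinct eigenvalues $\lambda_{p,i}$ with projections $E_{p,i}$ gives
$$\alpha_k(\sigma) = \tfrac{|Z|}{N!} \sum_p D_p \sum_i \lambda_{p,i}^k\,
  c_{p,i}(\sigma), \qquad
  c_{p,i}(\sigma) = \operatorname{tr}\!\big(\rho_p^{\mathcal{A}}
  (\mathbf{z}\sigma^{-1})\,E_{p,i}\big),$$
and the likelihood collapses to the finite closed form
$$L(T \mid \sigma) = \tfrac{|Z|}{N!} \sum_{p,i} D_p\, c_{p,i}(\sigma)\,
  e^{(\lambda_{p,i}-1)T}.$$
At $N = 6$ with dihedral symmetry this is a sum of at most
$\sum_p k_p = 8$ exponential terms, regardless of the model. Working in the
full group algebra instead would spend most of its partial traces on terms
that the projection "knocks out"; `likelihood_full_group()` implements that
route anyway, as a cross-check, and the tests assert both that it agrees to
1e-8 and that the knocked-out traces are below 1e-10.

Two more independent routes guard the spectral one:

* `cloud_markov_matrix()` assembles the $K \times K$ transition matrix of the
  cloud-level Markov chain by direct coset counting
  ($K = N!/|Z|$, entry-wise $\tfrac{1}{|Z|}\,|\{d : a\,d\,\sigma_j \in
  [\sigma_i]\}|$, summed over the model with weights). Matrix powers give
  $\alpha_k$, truncated Poisson sums give $L$; agreement with the spectral
  route is asserted to 1e-10 / 1e-8.
* `enumerate_beta()` enumerates all $|\mathcal{M}|^k$ event sequences at tiny
  $N$ and $k$, pinning the permutation-level path probabilities that
  everything else aggregates.

## Numerical choices

* **Exact rational coefficients** in the group algebra (reduced
  numerator/denominator pairs, overflow-guarded at $2^{53}$). Identities that
  are counting statements — $\mathbf{z}^2 = \mathbf{z}$, M1/M2 closure, the
  regular character case split $\chi^{\mathcal{A}}(\mathbf{z}\sigma) =
  K\cdot[\sigma \in Z]$, the complementary-rearrangement equality at $N=5$ —
  are tested with exact equality, not tolerances.
* **Eigenvalue hygiene.** Projection eigenvalues must lie within 1e-9 of
  $\{0,1\}$ and $k_p$ must equal the rounded projection trace; violations are
  hard errors (they would mean a broken representation, not noisy data).
  Model eigenvalues are grouped at relative tolerance 1e-9; mis-grouping
  would split a projection into two with the same eigenvalue, leaving every
  reported sum unchanged, so the choice is benign. The eigenvector basis
  within each eigenspace is arbitrary; only basis-independent quantities
  (traces, likelihoods) are ever reported or asserted.
* **Tableau order.** Standard Young tableaux are enumerated by a fixed
  recursion (each value placed in the lowest feasible row first), making the
  representation matrices bit-for-bit reproducible. Any other fixed order
  differs by an orthogonal change of basis and leaves all outputs unchanged.
* **MLE search.** $L$ is evaluated on a geometric-then-uniform grid over
  $[0, 5K]$ (a mixing-scale heuristic) and the best bracket refined by
  golden-section search to $|\Delta T| \le 10^{-6}$. Ties go to the smallest
  maximizer and multiple grid-level local maxima raise a `multimodal` flag.
* **No finite MLE.** For a generating model the curve tends to the uniform
  stationary value $1/K$; for many genomes it does so monotonically from
  below, and then no finite maximizer exists — biologically, no discernible
  evidence of relatedness. Detecting this by "argmax lands at $T_{max}$"
  fails numerically: a monotone curve saturates at the asymptote in double
  precision long before $T_{max}$, leaving the argmax anywhere on the flat
  tail. The package therefore flags `no_finite_mle` when the refined maximum
  does not exceed the *analytic* asymptote
  ($\tfrac{|Z|}{N!}\sum_{\lambda_{p,i}=1} D_p c_{p,i}$) by more than a
  relative 1e-6. At $N = 6$ with the adjacent-swap model this flags 29 of
  the 60 genome clouds — a substantial fraction, consistent with earlier
  reports for such models.
* **Degenerate inputs.** Base rearrangements lying in $Z$ act as the identity
  cloud: accepted with a warning (they only inflate the self-loop). Two base
  types with the same double coset ($\mathbf{z}a\mathbf{z}$ equal —
  complementary rearrangements, e.g. 2-region vs 3-region inversions at
  $N=5$) are an error, never a silent merge. Non-generating models warn;
  unreachable targets are reported as unrelated under the model with
  $L \equiv 0$.

## What the fixtures emulate — and what they do not

`fixture_model()` provides two stock models: `adjacent-swaps` (the $N$
swaps of adjacent positions, uniform) and `small-inversions` (2- and
3-region inversions, the shorter twice as likely — weights 2/3 and 1/3 per
type, i.e. $2/3N$ and $1/3N$ per instance). "Inversion of length
$\ell$" is realized as the position transposition orbit (`(1 2)`, `(1 3)`),
the standard unsigned-circular reading for $\ell = 2, 3$; for larger $\ell$
no convention is asserted. Sample genomes are uniform over clouds (uniform
random permutation, then canonicalized), seeded and reproducible.

These fixtures exercise the algebra exhaustively at desk scale
($N \le 8$ clouds enumerable, $N \le 6$ for the full-group route), which is
where every identity can be checked against brute force. A green suite
establishes internal correctness of the framework and the implementation; it
does not establish anything about real genomes: the fixtures have no region
orientation, no origin/terminus, no insertions, deletions or duplications,
and no claim that adjacent swaps or small inversions describe any organism's
rearrangement spectrum. Signed permutations (hyperoctahedral genomes) and
the class algebra's own regular representation are out of scope.

## Known limitations

* Complexity remains factorial in $N$: the reduced algebra shrinks the
  irreducible blocks by a factor $\approx 1/|Z|$ but $K = N!/|Z|$ still
  grows factorially. Resource guards stop the oracle at $N = 8$ and the
  full-group route at $N = 6$.
* The MLE search window $[0, 5K]$ and the saturation rule for "no finite
  MLE" are declared conventions: a maximum beyond the window that also
  exceeds the asymptote by less than the relative tolerance would be
  misflagged. No such case arises in the tested models.
* Weights supplied as doubles are converted to rationals by continued
  fractions (denominator bound $10^6$); supply fraction strings (`"2/3"`)
  for exactness.
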