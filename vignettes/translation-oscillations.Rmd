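---
title: "Modelling translation oscillations under ribosome competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling translation oscillations under ribosome competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfmnp)
```

# The model and its assumptions

`rfmnp` treats translation of each mRNA as a *ribosome flow model* (RFM)
chain — the deterministic mean-field limit of the totally asymmetric
simple exclusion process. The ORF is coarse-grained into $n$ sites of
$q = 10$ codons (roughly one ribosome footprint); the occupancy
$x_i \in [0,1]$ of site $i$ evolves as

$$\dot x_i = \lambda_{i-1} x_{i-1}(1 - x_i) - \lambda_i x_i (1 - x_{i+1}),$$

with the convention that the initiation flow is
$\lambda_0\, u\, (1 - x_1)$ for an external input $u$ and that the exit
flow $R(t) = \lambda_n x_n$ is the translation rate. The soft exclusion
factor $(1 - x_{i+1})$ makes flow stall behind crowded sites, which is
what lets codon order (not only codon content) shape densities and rates.
The chain has a unique, globally asymptotically stable steady state in
the interior of the unit cube, so steady rates and densities are
well-defined regardless of initial conditions.

The whole cell is a network of such chains coupled only through the free
ribosome pool $z$: chain $j$ receives input $u_j = G(z)$ and feeds its
output back,

$$\dot z = \sum_j w_j \lambda_{n_j} x^j_{n_j}
         - \sum_j w_j \lambda_0^j (1 - x_1^j)\, G(z),$$

where $w_j$ is the gene's mRNA copy number: each gene is one mean-field
chain representing all of its copies (exact for identical copies with
identical inputs, and verified as such in the tests). The pool response
$G(z) = \tanh(z/c)$ vanishes at zero, increases strictly, and is linear
near the origin. Total ribosomes
$H = z + \sum_j w_j \sum_i x_i^j$ are conserved identically by
construction, and the test suite asserts a relative drift below $10^{-6}$
over $10^3$ time units of forced integration.

Assumptions worth keeping in mind: no ribosome drop-off, no explicit
mRNA decay, no stochasticity, and no direct gene–gene interactions — all
coupling is resource-mediated through $z$.

# From sequence to rates

An ORF of $K$ codons (stop codon excluded everywhere) is split into
$n + 1$ pieces: the first piece has $q - 1$ codons (folded into
initiation, reflecting late initiation stages), interior pieces have $q$,
and the last piece has between $q/2$ and $3q/2$ codons. The number of
post-first pieces is the half-up rounding of $(K - q + 1)/q$; the
boundary case of a $3q/2$ last piece resolves to one extra site with a
$q/2$ piece. This reproduces the printed worked examples ($K = 146
\Rightarrow n = 14$ with a 7-codon tail; $K = 239 \Rightarrow n = 23$,
with $\lambda_{12}\ldots\lambda_{23}$ spanning codons 120–239).

Rates come from codon decoding times $\tau$: $\lambda_i$ is the
reciprocal of the summed decoding times of its piece, and
$\lambda_0 = 1/(p^{-1} + \sum_{k=1}^{q-1}\tau_k)$ with $p$ the gene's
initiation rate. Two calibrations tie the table and the genome together:

* decoding times are rescaled by one constant so that the **median
  per-gene elongation rate** $K_g / \sum_k \tau_k(g)$ is 6.4 codons/s.
  Whether this median is per-gene or per-codon is a genuinely open
  reading; the per-gene interpretation is the default (the sentence's
  subject is the mRNAs) and the per-codon alternative is available via
  `normalize_decoding_times(..., by = "codon")`;
* initiation rates are $p_g = \kappa\,\text{density}_g/\text{mrna}_g$
  with $\kappa$ set so the median is 0.8/s. No floor or ceiling is
  applied to extreme estimates.

All median matching uses the lower of the two middle order statistics for
even counts, a deterministic tie convention applied uniformly
(`generate_genome`, `normalize_decoding_times`, `estimate_initiation`).

# The synthetic genome

The generator reproduces the *statistical shape* of the yeast
parameterization, not yeast itself:

* **ORF lengths**: log-uniform over 25–4911 codons. Only the range and a
  right-skewed histogram are known; log-uniform reproduces the heavy
  right tail at any genome size.
* **Codons**: uniform over the 61 sense codons. Real codon-usage bias,
  and its correlation with expression, is deliberately out of scope.
* **mRNA levels**: log-normal with $\sigma_{\log} = 1.5$, rescaled to sum
  exactly to the total mRNA pool; expression in the reference organism
  spans about four orders of magnitude, which this width reproduces.
* **Initiation rates**: log-normal ($\sigma_{\log} = 0.5$) rescaled to
  median 0.8/s, independent of expression level.
* **Decoding times**: i.i.d. log-normal with log-sd `spread` (default
  0.5), rescaled to a median decoding rate of 6.4 codons/s.

Because lengths, expression and initiation are drawn independently, the
generator does not reproduce the real organism's correlations between
expression level, codon optimality and initiation efficiency. Passing
tests therefore demonstrate the *mechanisms* (entrainment, conservation,
monotone orderings, linearity) on a realistic economy, not the printed
whole-genome magnitudes — see "Known limitations".

Experiments run at a desk scale of $m$ genes (50 for the main fixtures,
12 for the sweep fixtures) with pools scaled proportionally,
$H_0 = 200000\,m/6310$ and $L_T = 60000\,m/6310$, preserving the
ribosome:mRNA economy while keeping the ODE dimension in the thousands.

# Forcing and entrainment

A sinusoidal mRNA level $\ell(t) = L_h(1 + A\sin(2\pi t/T))$ is realized
as *initiation gating*, not as a time-varying copy number: a baseline
chain of constant weight $\beta_1 = L_h(1 - A)$ plus a modulated chain of
weight $\beta_2 - \beta_1 = 2AL_h$ whose initiation input is multiplied
by $m(t) = (1 + \sin(2\pi t/T))/2$. The identity
$\beta_1 + (\beta_2 - \beta_1)m(t) = \ell(t)$ holds exactly for all $t$,
and — unlike abruptly removing mRNA copies — the scheme cannot strand
bound ribosomes, so conservation survives forcing. Collapsing the
modulated copies into one mean-field chain approximates the heterogeneous
histories individual copies would have; this is the same approximation
already made for constant copies.

`simulate_entrained()` starts from the unforced steady state (modulations
frozen at their mean, 0.5, i.e. the nominal level) and integrates period
by period, comparing each period's sampled states with the previous one
in a max-norm with the pool scaled by its magnitude. Defaults: tolerance
$10^{-6}$, at most 200 periods, 128 samples per period, forcing period
$T = 16$ s (entrainment theory guarantees the orbit period equals $T$,
so no period search is needed; doubling $T$ simply entrains at $2T$, as
a test verifies). The residual sequence is also checked to decrease
monotonically in its tail, guarding against limit cycles longer than the
forcing period. When several endogenous genes oscillate they share one
sinusoid (amplitude, period and phase), matching the experiment designs.

# Amplitude statistics

On the converged period: amplitude is half the peak-to-peak excursion
(equal to the first Fourier coefficient for sinusoidal responses, which a
test confirms to grid accuracy), and the mean is the arithmetic mean on
the period grid. Per gene, $R_a^i$ and $\rho_a^i$ are amplitudes as
percentages of the gene's own period mean; summaries are the gene-wise
mean and the *population* variance (divide by $m$ — the gene set is the
whole population, not a sample). Pool statistics are $\bar z$ (mean free
pool, percent of $H_0$) and $z_a$ (pool amplitude, percent of the mean
free pool). All percentages are carried on the 0–100 scale.

The formal definitions average "over all genes" while the prose measures
the effect on "the rest of the genes"; the package defaults to excluding
the oscillating genes (the `exclude` argument of `summarize_amplitudes()`
restores either reading). Normalized statistics divide by the oscillating
gene's nominal level in percent of total mRNA — the statistic per 1% of
the pool, i.e. per 600 mRNAs at the full-cell scale.

# Decoding-time measure and variant design

$\eta = \sum_i (\tau_i - \psi(i)) w_i / K$, with $\psi(i)$ the minimal
decoding time in codon $i$'s synonymous group, scores how far an ORF is
from its fastest recoding; weights are homogeneous (all 1) or a linear
ramp $w_i = 2i/(K+1)$ with mean exactly 1, encoding the hypothesis that
slow codons near the 3' end build larger jams. The exact published ramp
shape is unknown, so the ramp is pluggable and exact statements are made
only for the homogeneous measure (for which the all-fastest variant
scores 0 and the all-slowest provably maximizes $\eta$ — verified by
exhaustive enumeration on short ORFs).

The five designs recode regions with the fastest, slowest, or median-time
synonym. For the 239-codon reporter the region boundaries are the
published ones (1–119/120–239 halves aligned with the
$\lambda_{11}/\lambda_{12}$ site boundary; 1–79/80–159/160–239 thirds);
other lengths split at $\lceil K/2\rceil$ and thirds. Median codons use
the lower-middle tie convention; ties within a speed class break on
alphabetical codon order. Design is idempotent and preserves the protein.

# Numerical choices

* **Single-chain steady state**: damped Newton on the balance equations
  with a tridiagonal (Thomas) linear solve, globalized by
  pseudo-transient continuation — implicit-Euler steps
  $(I/\Delta t - J)\delta = f$ whose pseudo-timestep grows as the
  residual falls. Plain line-searched Newton stagnates on long chains
  near capacity (the Jacobian is nearly singular along the chain's slow
  mode); the pseudo-transient variant inherits global convergence from
  the chain's cooperative dynamics and ends as quadratic Newton.
  Fallbacks: continuation in $u$ from the initiation-limited regime, then
  ODE relaxation. Tolerance $10^{-10}$ on the max-norm residual;
  initialization at the cube centre, or a caller-provided warm start.
* **Network steady state**: for fixed $z$ each chain's steady state is
  unique, and ribosome conservation
  $z + \sum_j w_j \sum_i e_i^j(G(z)) = H_0$ is strictly increasing in
  $z$, so the network fixed point reduces to one bracketed scalar
  root-find (with per-chain warm starts across iterations). This is
  exact, initial-condition-free, and orders of magnitude cheaper than
  Newton on the full network; uniqueness is still cross-checked in tests
  by ODE relaxation from very different initial ribosome splits.
* **Pool calibration**: $\bar z$ is strictly increasing in the scale $c$
  of $G$, so `calibrate_pool()` brackets on $\log c$ and reports the
  achievable range when a target lies outside it (tolerance 0.01
  percentage points).
* **Integration**: Adams (non-stiff) with `rtol = 1e-8`,
  `atol = 1e-10`. All rate constants are $O(1)$/s, so the network is not
  stiff, and an implicit method would need an $O(N^2)$ numerical Jacobian
  at $N \sim 10^3$–$10^4$ states. State order: chain sites gene by gene,
  pool last.
* **Degenerate inputs**: ORFs shorter than $q - 1 + q/2$ codons are
  rejected by the partition; a forcing amplitude of exactly 0 collapses
  the modulated group to a single constant chain; a gene set that
  oscillates *every* gene yields an empty summary reported as such.

# Known limitations

* The operating point of the calibrated pool sits in the *linear* region
  of $G(z) = \tanh(z/c)$: conservation with a demand slope far exceeding
  $H_0$ forces $G(z) \ll 1$ at any realistic calibration target. In that
  region the endogenous genes' relative input fluctuation equals the pool
  amplitude, so mean translation-rate amplitudes are proportional to
  $z_a$ and fall together with it as $\bar z$ grows. Reproducing a
  translation-rate amplitude that is *insensitive* to $\bar z$ would
  require operating near the saturation knee, reachable only with a
  sub-unit saturation amplitude in $G$ — outside the unit-amplitude
  family used here. The package therefore demonstrates the monotone
  $z_a$–$\bar z$ trend but not the flatness of $\bar R_a$ across the
  sweep.
* Amplitude magnitudes at desk scale are small (strong pool buffering in
  the linear regime, plus low-pass attenuation by chains whose fill time
  exceeds the forcing period); orderings and scalings, not magnitudes,
  are the reproducible content.
* The generator draws lengths, expression, initiation and codon content
  independently; real genomes correlate them.
* No stochastic (TASEP) comparison and no noise analysis; the model is
  deterministic throughout.

# A compact whole-cell run

```{r example, eval = FALSE}
cfg <- experiment_config(n_genes = 12, seed = 7,
                         length_range = c(25L, 1000L))
res <- run_heterologous(cfg, variant = "HIGH_RD")
res[, c("variant", "A", "Lh_pct", "alpha", "zbar", "z_a",
        "Rbar_a", "rhobar_a")]
```

The row reports, for a jam-designed reporter occupying 20% of the mRNA
pool forced at amplitude 1/2 and period 16 s in a cell calibrated to a
30% mean free pool: the achieved mean free pool, its oscillation
amplitude, and the mean translation-rate and density amplitudes induced
on the other genes.
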