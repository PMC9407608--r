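---
title: "Directed brain networks from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed brain networks from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtfnet)
```

# The analysis in one paragraph

`dtfnet` turns multichannel scalp EEG into stage-contrasted directed brain
networks. Scalp potentials are re-referenced, filtered and downsampled, then
converted to current source density (CSD) by a spherical-spline surface
Laplacian, which removes the recording reference and sharpens the spatial
pattern that volume conduction smears. Sliding 4-s windows (1-s step) are
each fitted with a multivariate autoregressive (MVAR) model, whose spectral
transfer matrix yields the directed transfer function (DTF) — a
frequency-domain Granger-causality index — averaged over each rhythm band
(delta, theta, alpha, beta, gamma). Each window's connectivity matrix is
binarised by keeping the strongest fraction *S* of the *N(N−1)* possible
directed edges, with *S* chosen by maximising global cost efficiency
(GCE = E − S) over a sparsity grid. The resulting directed networks are
summarised by the directed clustering coefficient, average shortest path
length, global efficiency, in-/out-degree and causal flow (out − in), and
driving stages are contrasted against rest with one-way ANOVA plus
Benjamini–Hochberg FDR. A synthetic-session generator with a known directed
coupling graph makes every stage verifiable against ground truth.

# Models and estimators

## MVAR and DTF

Each epoch $X(n)$ ($N$ channels) is modelled as
$X(n) = \sum_{r=1}^{p} A_r X(n-r) + W(n)$ with i.i.d. Gaussian innovations.
Coefficients are estimated by least squares on the stacked lag regression.
The solver uses a truncated singular-value decomposition (relative cutoff
$10^{-8}$): narrowband signals make the lag regressors nearly collinear, and
the minimum-norm solution is the standard, deterministic remedy; an epoch
that is genuinely too short for the requested order is rejected with a
message suggesting longer epochs or a smaller order.

The transfer matrix is $H(f) = [I - \sum_r A_r e^{-i 2\pi f r/f_s}]^{-1}$
and the DTF from channel $j$ into channel $i$ is
$\gamma^2_{ij}(f) = |H_{ij}(f)|^2 / \sum_k |H_{ik}(f)|^2$, so the inflow
into every sink sums to one at every frequency — and, because band
aggregation is an arithmetic mean over a 0.5-Hz grid, after band averaging
too. Column (outflow) normalisation is available for sensitivity analysis.

**Broadband fitting, band-restricted evaluation.** By default one MVAR
model is fitted per broadband epoch and only the DTF evaluation is
restricted to each band's frequency grid. The alternative — fitting the
band-filtered epoch itself (`fitOnBand = TRUE`) — is retained but not
recommended: at $N = 60$ and $p \ge 2$ the lag regression of a 4–8 Hz
filtered 4-s epoch is numerically singular (a narrowband signal's lags span
only a few dimensions per channel), and even the minimum-norm fit then
yields DTF values indistinguishable from the $1/N$ background on
ground-truth couplings. The broadband spectral factorisation carries the
band content of interest and recovers the planted structure cleanly; this
is verified by the edge-recovery and directional-effect tests.

## Model order

`selectOrder()` fits every candidate order over a common sample span and
returns the BIC argmin (AIC is reported alongside; a warning flags
disagreement beyond 2). For real 60-channel recordings the pipeline default
is a fixed $p = 5$, a conservative middle ground that avoids 14 extra fits
per window. On the synthetic benchmark sessions the generator's true order
is 2 and BIC recovers it, so all benchmark and acceptance runs fix
$p = 2$.

## Spherical-spline CSD

The potential map at each time sample is interpolated by a spherical
spline built from the kernel
$g(x) = \frac{1}{4\pi}\sum_{n\ge 1} \frac{2n+1}{(n(n+1))^m} P_n(x)$, and
the CSD is the surface Laplacian of that spline, evaluated through the
companion kernel $h(x) = -\frac{1}{4\pi}\sum_{n\ge 1}
\frac{2n+1}{(n(n+1))^{m-1}} P_n(x)$, scaled by the squared head radius.
Defaults are $m = 4$, 50 series terms, ridge $\lambda = 10^{-5}$ and a
10 cm head radius — the long-established CSD-toolchain settings. The series
exponents follow the standard Perrin-style construction. Legendre
polynomials are evaluated by the three-term recurrence; the tests check the
partial sums against an independent Laplace-integral quadrature oracle to
$10^{-12}$.

The interpolation solves the bordered system $Gc + c_0\mathbf{1} = v$,
$\mathbf{1}^\top c = 0$; one factorisation is reused for all time samples
of a recording, making the transform a single precomputed matrix. Direct
consequences, all asserted in tests: spatially constant maps give zero CSD,
adding a constant to every channel changes nothing (reference freedom), and
the transform is linear — so it commutes with temporal filtering, which is
why the pipeline applies CSD before band decomposition.

## Thresholding and network metrics

`binarizeTopFraction()` keeps exactly
$k = \mathrm{round}(S\,N(N-1))$ strongest off-diagonal entries (round half
away from zero; diagonal never eligible; ties broken by ascending row then
column index, which makes edge sets nested across $S$ and the whole
operation deterministic). GCE is computed per window and averaged per stage
to produce a traversal report over $S \in \{0.20, 0.25, \ldots, 0.60\}$;
the pipeline then applies one fixed $S$ (default 0.3) to every window, with
a per-window-optimal mode available, since published workflows describe
both.

Directed clustering uses the union neighbourhood: node $i$'s neighbours are
all nodes connected to it in either direction, and $M_i$ counts directed
edges among them, giving $C_i = M_i / (k_i(k_i-1))$ ($C_i = 0$ for
$k_i < 2$). Shortest paths are directed hop counts; the average path length
is taken over *reachable* ordered pairs with the reachable fraction
reported (a thresholded directed network need not be strongly connected),
while global efficiency $E = \frac{1}{N(N-1)}\sum_{i\ne j} 1/L_{ij}$
handles disconnection natively via $1/\infty = 0$. Causal flow is
out-degree minus in-degree; its sum over nodes is identically zero. All
metrics are validated exactly against brute-force enumerations
(Floyd–Warshall, naive double loops) and igraph on hundreds of random
digraphs.

Electrodes map to nine scalp regions by 10-10 label prefix (pre-frontal,
frontal, fronto-central, central, central-parietal, parietal,
parietal-occipital, occipital, temporal); anterior = {pre-frontal, frontal,
fronto-central} and posterior = {parietal, parietal-occipital, occipital}.
The mapping is a reconstruction from label conventions and can be
overridden with a file.

## Statistics

Stage contrasts are classical one-way ANOVAs of each driving stage against
the baseline, with BH-FDR across the stage contrasts for the global metrics
and across the 60 electrodes for per-electrode causal flow (fatigue stage
vs rest). Normality screening uses the Lilliefors-corrected KS test, since
the plain KS test is anticonservative with estimated parameters.

**Observation unit.** Adjacent 4-s windows stepped by 1 s share 75% of
their samples; treating every window as an independent observation inflates
the ANOVA F by roughly the autocorrelation sum ($\kappa \approx 4$), which
makes the literal epochs-as-observations reading strongly anticonservative.
The default therefore averages window metrics within blocks
(`observation = "block"`): 60-s blocks for full-length 600-s stages —
matching the per-minute averages such studies plot — and window-length
(4-s) blocks for the reduced 60-s stages used in the shipped tests, the
shortest span at which block means are nearly decorrelated. The
epoch-observation mode is retained for comparability, clearly flagged. The
null-calibration acceptance test verifies that with block observations the
family rejection rate on modulation-free sessions stays at the nominal
level.

# The synthetic-data generator

`simulateSession()` realises a stage-structured recording from a
`GroundTruthGraph`: a stable MVAR process (couplings at lag 1, shared AR(2)
self-dynamics $0.5, -0.2$, unit-variance Gaussian innovations) whose named
edge groups are rescaled per stage (e.g. halving `"posterior_to_anterior"`
in T4 emulates the fatigue-related loss of posterior-to-anterior drive).
Stability is enforced at construction — the companion spectral radius must
be below 1 — and each stage draws an independent, reproducible noise stream
sub-seeded from (seed, stage index). Sources sit one under each electrode
and are mixed to the scalp by a row-normalised Gaussian-in-angle kernel, a
deliberately simple smearing surrogate rather than a physical head model.

Design choices that took real tuning-by-mechanism, and their reasons:

* **Mixing spread 0.15 rad.** At 0.3 rad the smear exceeds what the
  spherical-spline CSD can undo on a 60-electrode montage: even switching a
  coupling group *off* left the binarised networks unchanged, so no
  manipulation could propagate to the metrics. 0.15 rad is the heaviest
  smearing at which the CSD stage demonstrably restores sensitivity; it
  still produces strong neighbour correlations at the scalp.
* **Hub pathway.** The default graph couples each of six anterior hub
  electrodes (Fp1, Fpz, Fp2, F1, F3, Fz — the set fatigue experiments
  implicate) to ten posterior sources at strength 0.25, plus twelve
  anterior-to-posterior return edges and twenty random background edges at
  0.4. Concentrating inflow is essential: the sparsity threshold keeps the
  top 30% of 3540 entries, and a single weak inflow per sink moves a node's
  binarised degree by far less than its per-window noise. The hub strength
  is sized so that full-strength band DTF clears the top-30% cutoff while
  the halved version falls near it — the regime in which halving is
  actually visible in degrees.
* **What the generator does not emulate.** Ocular/muscle artifacts,
  realistic BEM/FEM forward physics, nonstationarity within a stage,
  1/f background spectra and per-subject variability. Passing tests
  therefore show the pipeline recovers planted directed structure through
  mixing and CSD under MVAR assumptions — not that real fatigue data will
  behave as cleanly.

# Numerical choices

* Filters: 4th-order Butterworth high-pass and band-passes and a Q = 30
  biquad notch, all forward–backward (zero-phase; magnitude response
  squared). The notch stage uses odd-reflection edge padding (the MATLAB
  `filtfilt` convention) to suppress edge transients; the 0.5-Hz high-pass
  is applied without padding because its impulse response is long enough to
  drag reflected edge content into the retained segment, and the DC term is
  removed exactly by demeaning first. Downsampling is polyphase
  (`signal::resample`), output length $\lceil n p/q \rceil$.
* Repeated conditioning is *approximately* idempotent (≈3% RMS change on
  white noise): any frequency where the squared filter response lies
  strictly between 0 and 1 is re-attenuated on a second pass. Exact
  idempotence is impossible for this (or any practical IIR) filter family;
  the property test asserts a 5% bound and that resampling is skipped at
  equal rates.
* Windows are half-open sample ranges starting at integer multiples of the
  step; a 600-s stage gives exactly 597 windows of 4 s at a 1-s step.
* Truncated-SVD MVAR solve with relative cutoff $10^{-8}$; DTF band grid
  0.5 Hz; transfer-matrix conditioning monitored with a warning above an
  estimated condition number of $10^{12}$.
* Rounding in the edge count is half-away-from-zero, asserted for 500
  random (N, S) pairs.
* Gamma band runs 30–45 Hz so that the band stays clear of the 50-Hz
  notch. All bands are configurable.

# Problem sizes in the shipped tests

The test and acceptance runs use reduced problem sizes chosen to exercise
every code path at full channel count while keeping the suite quick:
60-channel sessions with two or three 60-s stages and the theta band for
the end-to-end checks (15 block observations per stage), 5-node graphs with
60 four-second epochs for edge recovery, and hundreds of ≤12-node random
digraphs for the exact metric oracles. Full-scale runs (seven 600-s stages,
five bands) use identical code paths and only change these sizes.

# Known limitations

* The DTF is a linear Granger measure; nonlinear or instantaneous
  dependencies are outside its model class, and residual volume conduction
  can still induce spurious bidirectional flow that CSD only attenuates.
* Fitting 60-channel MVAR models on 4-s windows estimates 7200 +
  coefficients per window at $p = 2$; estimates are usable for rank-based
  thresholding but individually noisy. Surrogate-based significance of
  single DTF edges is not implemented.
* The ANOVA treats block means within a session as exchangeable
  observations; between-subject inference (mixed models) is out of scope.
* No artifact detection: a hook accepts an externally derived
  channel-space pruning operator, but component inspection happens outside
  the package.
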