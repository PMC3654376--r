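---
title: "Methods: oriented-patch source estimation and spike-locked coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oriented-patch source estimation and spike-locked coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicoh)
```

This vignette documents the models implemented in `epicoh`, the choices made
where the methodology is genuinely open, and the limits of what the
synthetic-data tests demonstrate.

## The source model

The cortical surface is represented as a triangulated mesh partitioned into
edge-connected patches of approximately equal area (`tessellate_patches()`).
Each patch is modelled as a single *oriented equivalent dipole*: laminar
pyramidal-cell populations generate far fields along the local surface
normal, so constraining the dipole to the patch's average orientation
removes two thirds of the unknowns relative to free-orientation "xyz
triple" models and substantially conditions the inverse problem.

**Orientation convention.** The patch orientation is the vector sum of the
triangle normals, normalised to unit length. We use the *un-normalised*
cross-product normals, whose magnitude is twice the triangle area, so the
sum is inherently area-weighted; larger triangles contribute more. Whether
the vector sum should be area-weighted and/or normalised is a convention
rather than a derived fact: we normalise so that every patch carries a unit
dipole moment and all amplitude information lives in the source vector J.
On strongly folded patches the normals can cancel; when the sum's magnitude
falls below 1e-6 of the summed normal magnitudes the patch is flagged
degenerate and an arbitrary axis is kept (with a warning), leaving the drop
decision to the caller.

**Tessellation.** Patches are grown greedily on the triangle adjacency
graph from farthest-point-sampled seeds, always extending the currently
smallest patch. This is deterministic given the seed (default 0),
dependency-free, keeps patch areas balanced around the target (1 cm² is the
classical choice; patch count comes out as total area / target), and
guarantees edge-connectivity by construction. Patch membership never
crosses the hemisphere boundary, and by default the *neighbour* relation
does not either (`across_hemispheres = FALSE`): interhemispheric smoothing
through the medial wall has no physiological basis in a surface model. The
option exists because the choice is a convention.

**The surface Laplacian.** On the patch adjacency graph (patches sharing a
mesh edge; "typically 6" neighbours on a hexagonal-like tessellation) the
smoothing operator is

\[ w_{ij} = \begin{cases} -1 & i = j\\ 1/N_i & j \in \mathrm{nb}(i)\\ 0 &
\text{otherwise,} \end{cases} \]

with \(N_i\) the neighbour count. Rows of non-isolated patches sum to zero,
so spatially constant patterns are unpenalised; W is intentionally *not*
symmetrised when neighbour counts differ. An isolated patch keeps the
\(-1\) diagonal alone — the penalty then shrinks its amplitude — and is
reported.

## The inverse

With scalp potentials \(\Phi = KJ + \varepsilon\), the estimate is the
minimiser of \(\|\Phi - KJ\|^2 + \alpha\|WJ\|^2\): W = I gives the
minimum-norm solution, W = the surface Laplacian gives the
cortical-surface-Laplacian (CSL) solution. The closed form
\((K'K + \alpha W'W + r I)^{-1} K' \Phi\) is used when sensors ≥ patches;
otherwise the algebraically equivalent representer form
\(M^{-1}K'(KM^{-1}K' + I)^{-1}\Phi\) with \(M = \alpha W'W + rI\), which
only factorises a sensors × sensors matrix (both forms agree to 1e-8 in the
tests).

Numerical choices:

* **Ridge stabiliser** \(r\): \(W'W\) annihilates constants, so the normal
  matrix can be singular. We add
  \(r = 10^{-10}\,\mathrm{tr}(K'K + \alpha W'W)/p\) (configurable). At
  \(\alpha = 0\) the ridge is dropped entirely and a full-column-rank check
  is enforced instead, so noiseless overdetermined systems are recovered
  exactly.
* **Reference.** Scalp EEG has no absolute zero; both Φ and the rows of K
  are average-referenced before solving (the standard dense-array
  convention). The estimator is then invariant to common-mode offsets.
* **α selection.** Generalized cross-validation over a log grid
  \(10^{-6}\ldots10^{2}\) scaled by \(\mathrm{tr}(K'K)/\mathrm{tr}(W'W)\).
  GCV needs no noise estimate, selects heavy smoothing on pure noise and
  minimal smoothing on consistent noiseless data, and is cheap here because
  the hat-matrix trace only involves sensor-space quantities. A fixed α is
  accepted wherever `"gcv"` is.
* **Depth weighting** is *not* applied: the minimum-norm variant is the
  plain unweighted one. With oriented superficial patches this is adequate;
  depth-biased applications would want a weighted extension.

## Spike-locked epoching

Segments span [t−1.5 s, t+1.5 s) around each spike peak; the three analysis
intervals are the contiguous 1-s windows pre [t−1.5, t−0.5), spike
[t−0.5, t+0.5), post [t+0.5, t+1.5). Boundaries are computed as
`round(fs * t)` sample indices with half-open windows throughout, and the
spike interval is centred on the nearest sample to the peak (the peak
could equally be centred between samples; the sub-sample difference is far
below the 1 Hz spectral resolution). Spikes closer than the window to a
recording edge are dropped with a warning. Spike peak times are taken as
given — detection and topographic clustering are upstream, expert-reviewed
steps. With non-integer `fs` the epoch is `floor(fs)` samples and the bin
spacing deviates from 1 Hz; this is warned about and reported.
`half_peak_time()` returns the linearly interpolated rising-phase crossing
of 50% peak amplitude immediately preceding the peak — the earlier
timepoint preferred for localisation because discharges propagate by the
peak.

## Coherence estimation

1-s epochs at integer `fs` give exactly 1 Hz resolution with a rectangular
window; we deliberately do not taper by default, because tapering widens
the main lobe and the stated band edges assume exact integer-Hz bins (a
Hann option would be a straightforward extension). Epochs are demeaned but
not detrended. Cross-spectra are averaged *across the spike epochs of the
cluster* — with one 1-s window per interval per spike there is nothing else
to average over — and the coherence is the magnitude of the complex mean
cross-spectrum standardised by the mean autospectra. (Averaging per-spike
coherences instead would be identically 1: the single-segment estimator is
degenerate, which the code warns about.) Bins with vanishing power products
are returned as `NA` and excluded from band means.

Band mapping over the analysed 1–70 Hz range: delta 1–3, theta 4–7, alpha
8–12, beta 13–29, gamma 30–70 Hz. Shared nominal boundaries (4, 8, 13,
30 Hz) go to the upper band; delta starts at 1 Hz because the analysis
range does. The mapping table is exported with every result
(`band_table()`).

Parcel waveforms are *signed* means of member-patch waveforms; antiphase
patches (opposite sulcal walls) can cancel. This is the documented hazard
of averaging oriented sources over large parcels and the reason
finer-grained analyses are preferable when compute allows.

The matrix layout places right-hemisphere parcels (sorted by label) before
left, so intra-right coherences occupy the upper-left quadrant. Top-K edge
extraction (default K = 100) operates on the band matrices, by default
within each band, with deterministic tie-breaking (band order, then parcel
indices); a pooled-across-bands option exists because either reading of
"highest 100" is defensible.

## The synthetic generator

`simulate_recording()` emulates every input the pipeline needs:

* an icosphere "cortex" (radius 9 cm) under a Fibonacci-distributed sensor
  sphere (radius 10 cm) — about 1 cm of standoff, matching the real
  scalp–cortex distance, which materially determines how sharp the
  achievable inverse resolution is;
* an infinite-homogeneous-medium analytic dipole lead field
  (\(V = p\cdot(r-r_0)/4\pi\sigma|r-r_0|^3\), σ = 0.33 S/m) —
  deliberately idealised: no skull, no CSF, no realistic geometry;
* per-patch 1/f Gaussian background (unit SD), a biphasic
  derivative-of-Gaussian spike transient (70 ms, amplitude 10) on a focus
  patch at known times ≥ 3 s apart, and planted coherent pairs: the pair
  members' own band content is replaced by
  \(\sqrt{c}\,s + \sqrt{1-c}\,u_i\) (shared s, private \(u_i\), amplitude
  2× background SD), so the asymptotic band coherence equals the coupling
  \(c\) exactly at the patch level. Finite 1-s windows leak a little
  out-of-band background into the band-edge bins, so even at \(c = 1\) the
  measured edge-bin coherence sits just below 1 — visible in the tests and
  expected from windowing theory.

Default problem sizes (64 sensors, ~200 patches, 10 parcels per hemisphere,
20 spikes at 250 Hz) keep a full end-to-end run in the low seconds, which is
what makes 100-replicate studies routine; clinical-scale geometry
(256 sensors, ~2400 1-cm² patches) is reachable through the same
configuration object.

**What passing tests do and do not show.** The generator is stationary,
artifact-free Gaussian noise on a sphere with a perfectly known lead field.
Recovery of the planted pair under these conditions demonstrates that the
mathematics — tessellation, inverse, epoching, cross-spectral estimation,
ranking — is implemented correctly and that the chain is well-conditioned
at realistic SNR. It does *not* demonstrate clinical validity on real
recordings, where head-model error, muscle and movement artifact,
non-stationarity, volume-conduction leakage through a mis-specified skull,
and antiphase cancellation within anatomical parcels all degrade the
estimate in ways the simulation deliberately omits.

## Known limitations

* Magnitude coherence is leakage-prone: two parcels receiving point-spread
  from the same source appear coherent. Imaginary-part or partial
  coherence variants would mitigate this but are out of scope, as is any
  statistical testing of coherence differences between intervals.
* The EDF writer covers plain continuous EDF (uniform rate, 1-s records,
  events in a TSV sidecar), not EDF+ annotations.
* Tensors travel as delimited text, sized for parcel-level results; the
  full 2400-patch per-frequency tensor is better kept in memory.
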