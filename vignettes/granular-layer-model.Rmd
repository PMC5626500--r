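---
title: "The granet granular-layer model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The granet granular-layer model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`granet` builds and simulates a three-dimensional spiking model of the
cerebellar granular layer: granule cells (GrCs) excited by mossy fibers and
inhibited by Golgi cells (GoCs), GoCs excited by mossy fibers and by GrC
ascending axons (AAs) and parallel fibers (PFs), GoC-GoC inhibitory
synapses, and GoC gap junctions. The full volume is 1500 um (transverse) by
700 um (sagittal) by 430 um (vertical: a 200-um granular layer, a 30-um
Purkinje-cell layer and a 200-um molecular layer). GoCs are placed at the
anatomical density of 9500 cells/mm^3, which yields exactly 1995 GoCs at
full scale; GrCs at 400 per GoC, i.e. 798,000 cells. All cell bodies are
uniform in the granular layer.

The pipeline is: `granular_config()` (all constants, with unit-suffixed
keys) -> `build_network()` (anatomy and connectivity) ->
`stimulus_protocol()` + `mf_spikes()` (mossy-fiber drive) ->
`run_simulation()` (clock-driven network integration) -> the analysis
functions (`oscillation_metrics()`, `discounted_correlation()`,
`shuffle_significance()`, `dynamic_range()`, ...).

# Anatomy generation

## Mossy-fiber rosette fields

Mossy-fiber rosettes are arranged in sagittally elongated strips. The
generator seeds candidate fibers at 5000 fibers/mm^2 over the footprint
plus a 300-um margin (so cells at the volume edge see full rosette
density), then gives each fiber a strip of rosette clusters: the strip
center is displaced along the sagittal axis by a zero-mean Gaussian with SD
1700 um (the primary collateral can arborize far from the entry point, so
most candidate fibers leave no rosette inside the modelled volume), cluster
centers scatter with SD 110 um sagittally, and rosettes scatter with SD 30
um (sagittal) by 9 um (transverse). Cluster and rosette counts are
shifted-Poisson with means 2 and 9. These four free parameters were set
once so that a full-scale build lands on the reference totals of about 2100
instantiated fibers and about 29,500 rosettes (a build at the default seed
gives 2127 and 29,579), with `overlap_histogram()` — the relative number of
volume cubes containing 0, 1, 2, 3, 4+ distinct fibers — as the
diagnostic for the spread.

## Point clouds and touch detection

Connectivity is geometric: structures are point clouds and two cells become
a candidate pair when points approach within a connection radius
(`connect_by_radius()`, a uniform-grid fixed-radius search equivalent to a
k-d tree query and tested against a brute-force oracle). Ascending axons
are vertical 200-um lines with 50-um point spacing; parallel fibers are two
1000-um arms at the AA top with 7.5-um spacing; both get 1-um Gaussian
jitter. GoC apical (cone height 332 um) and basolateral (6 um) dendrites
are lines to the circumference of a 100-um circle at normally distributed
angles (means 30/120 and -20/-240 degrees, SD 10); points every 5 um — the
5-um spacing is our choice, as only the radii and cone dimensions are
anatomically constrained. GoC axons are 512 uniform points in the
(+/-45, +/-160, +/-75)-um box around the soma; GoC-GrC contacts use that
cloud with a 15-um radius, values chosen so the axonal field is densely
covered while the calibrated convergence (below) carries the quantitative
burden. Connection radii: 30 um (rosette to GrC), 100 um (rosette to GoC),
30 um (AA points to basolateral dendrites), 5 um (PF points to apical
dendrites).

## Convergence calibration and interior cells

Each connection type accepts candidate cell pairs independently with a
probability calibrated as `target / mean(candidates)` so that the mean
convergence matches the anatomical targets: 4.5 mossy fibers per GrC, 13.7
per GoC, 8.4 GoC synapses per GrC, 554 AA and 4759 PF inputs per GoC. The
candidate mean is taken over *interior* cells: the printed reference values
describe the full 1500 x 700 um model including its own tissue boundary, so
in reduced volumes a margin equal to the anatomical reach of the connection
is applied along exactly those dimensions that were shrunk below full size
(`edge_interior_margin()`); dimensions at full size keep the full model's
boundary profile and get no margin. The same masks are used when
statistics are reported, which keeps calibration and measurement
consistent.

## Golgi-Golgi coupling

Gap junctions follow a Boltzmann distance-probability
`p(x) = pmax / (1 + exp((x - x0)/k))` with conductance
`g = 1.659 nS x exp(-0.01259 x)`. The Boltzmann parameters are not
restated in the anatomical sources available to us, so we fit them:
holding `pmax = 0.9`, `k = 25 um`, the midpoint `x0 = 53.6 um` makes the
expected junction count per GoC equal 13.7 when integrated over a 200-um
thick layer (the layer-sheet integral, not an infinite medium — vertical
truncation is part of the real geometry and of the reference model alike).

GoC-GoC inhibition is anchored by two measurements: 20% connection
probability at 50 um, and a mean of 2.2 inhibitory inputs per GoC. A single
curve shared with the gap-junction fit cannot satisfy both (with the shared
shape the two constraints demand a shape value above 1 at 50 um), so
inhibition gets its own, steeper Boltzmann (`pmax = 0.504, x0 = 47.9 um,
k = 5 um`) satisfying both anchors under the same layer-sheet integral.

Conduction delays are path length over velocity: 0.3 m/s along the GrC
axon (AA segment plus PF arm to the contact), 2 m/s for mossy-fiber and
GoC axons (their Euclidean contact distances).

## Randomization

Soma diameters vary up to +/-20%, initial potentials uniform in
[-75, -60] mV, and every synaptic weight carries a truncated-Gaussian
factor with CV 0.25. All randomness derives from one master seed; two
builds with the same seed are bit-identical (a tested contract).

# Synapse and neuron models

## The mossy fiber-GrC relay

Release drives a linear five-state cascade approximating glutamate
diffusion (pools P -> T -> I1 -> I2 -> I3, rates `r/tau_D` with
`tau_D = 100 R_d^2 / 4D ~ 6.63 ms`); each presynaptic spike adds a
release fraction `y` to P, where `y` is depressed multiplicatively (factor
0.75 per spike) and recovers with a 50-ms time constant — reference values
for the facilitation/depression mechanism are not printed, so depression
with a configurable recovery constant is our default. The transmitter
concentration T drives AMPA (rise 0.6 ms, decay 1.8 ms) and NMDA (rise 8
ms, decay 52 ms) receptor stages; the NMDA desensitization constant
12e-4 ms^-1 is folded into the open-state decay rate, and the magnesium
block follows `f(V) = 1/(1 + ([Mg]o/K_Mg) exp(-V/delta_V))` with
(1 mM, 1.77 mM, 22.4 mV). The NMDA:AMPA peak-conductance ratio is ~2.8 —
granule-cell excitation is NMDA-dominant at depolarized potentials, which
is what lets driven granule cells keep firing against feedback inhibition
(the winner-keep-winning regime); with a ratio near 1 the circuit cannot
produce strong ON-patch responses at any calibration. Receptor-stage
normalisations are computed numerically at the engine's exact
discretisation so a single release at weight w peaks exactly at
`w x gmax`.

## Other synapses

All other synapses are peak-normalized double exponentials. The GrC IPSC
has a 3-ms rise and two decay components — 5 ms transient plus a 35-ms
spillover component contributing 10% of the peak. GoC AMPA inputs use
sub-millisecond rises and 1.2-1.5-ms decays. GrC tonic inhibition (88 pS,
-73 mV) is switchable. GoCs additionally receive extracortical dendritic
inhibition modelled as ~150 Poisson synapses at 16 Hz with 180-pS peaks and
5-ms decay (total conductance ~2160 pS), which is required to keep the
GoC/GrC rate ratio in the physiological range.

## Surrogate point neurons

The reference multicompartment GrC/GoC models are not part of this
package; both populations are adaptive leaky integrate-and-fire surrogates
(one compartment; the GoC's apical-versus-basal weighting is expressed
through per-synapse-type conductance scales). Granule cells reset to
-63 mV after a spike (a shallow afterhyperpolarization, so sustained drive
supports fast firing). GoCs have a constant pacemaker drive and strong
spike-triggered adaptation (90 pA increments, 120-ms decay), which caps
their firing under strong drive in the tens of hertz as in the reference
model. GoC gap junctions additionally transmit spikelets: a presynaptic
spike couples its voltage-time area (30 mV ms) through the junction —
without this, subthreshold-only coupling transmits nothing but the reset
hyperpolarization and cannot synchronize. GoCs also carry a
depolarization block: a 20-ms low-pass "shadow" of the unreset
synaptic-drive equilibrium potential (adaptation excluded — the block
stands in for sodium-channel inactivation) silences spiking above -8 mV.
The threshold is set high enough that the standard patch paradigms (100-um
patches up to 80-Hz drive) never block — consistent with the reference
model, where blocked conditions occurred only for large patches above
50 Hz and were discarded — while extreme sustained drive still silences
the cell. Because the surrogates do not inherit
the reference models' conductances, all synaptic peak conductances are set
by `calibrate_surrogates()`: a bracketing bisection on three scales
(GrC excitation, GoC excitation, GrC inhibition) until (i) GrC fire ~6x
their baseline without inhibition, (ii) GoC sit at ~8.2 Hz, and (iii) GrC
at ~1 Hz, all under 5-Hz mossy-fiber background. The calibrated scales are
shipped as a JSON manifest (`inst/extdata/calibration.json`, applied by
`apply_calibration()`) together with the achieved rates and residuals.
Calibration runs on a 600 x 150 um harness; because convergences are
re-calibrated per build, per-cell input statistics — and therefore rates —
transfer to other volumes.

# Numerics

The engine is clock-driven at `dt = 0.025 ms` by default; tests use
0.05 ms and the long baseline/property runs 0.1 ms, after a convergence
check (halving dt changes population rates by under 2%, and the 10-s
baseline rates at 0.1 versus 0.05 ms agree to ~2-3%). Synaptic states advance by exact exponential decay
factors between events; the cascade is integrated in modal (eigen)
coordinates — its matrix has distinct real negative eigenvalues — so a
release is five state increments and the per-step update is five
multiplies. The membrane update is implicit (backward) Euler, which is
unconditionally stable under arbitrarily large synaptic conductance; gap
junctions couple explicitly through previous-step potentials. Spikes
travel through per-edge delay queues (ring buffer); delays shorter than
one step are rounded up to one step with a warning. Denormal floats are
flushed to zero in the engine (decaying conductances otherwise underflow
into subnormals and dominate runtime). Event delivery, refractoriness
(1.5 ms GrC, 2 ms GoC) and the NMDA voltage factor (561-entry lookup
table) are tested against closed forms.

# Mossy-fiber input

Each fiber is a leaky integrate-and-fire rate coder (`tau = 1 ms`,
rest -70 mV, threshold -60 mV, refractory 1.1 ms, reset to rest) driven by
`beta*mu(t) + sigma(t)*xi(t)` with noise redrawn every 1 ms and
`mu = g N nu`, `g = 5 uV/ms`, `N = 1000`, `beta = 0.01`. For the noise
amplitude we use `sigma = g N sqrt(nu)`: with the alternative shot-noise
reading `g sqrt(N nu)` the fluctuations are ~0.2 mV against a 10-mV
threshold distance, the fiber never fires, and the defining
fluctuation-driven regime (drift `beta*mu*tau` stays ~0.3 mV below
threshold at working rates) cannot exist; both forms remain selectable via
`sigma_form`. A monotone `nu`-to-rate table is simulated once and inverted
by linear interpolation; realized rates are within ~1% of target over
2-500 Hz and saturate near 530 Hz against the refractory bound.

Stimulation paradigms: constant background (5 Hz); patches of 100- or
200-um radius whose member fibers (membership by rosette position, since
rosettes are the synaptic elements) follow the patch schedule *instead of*
the background; slow rate modulation (five 600-ms epochs alternating 10 Hz
with 50-60 Hz, Gaussian-smoothed, sigma 50 ms); bursts (10 ms at 500 Hz,
five expected spikes per fiber; the unstated inter-burst interval defaults
to 300 ms); weak asynchronous probes (20 Hz, 20 ms). For
temporal-structure equalization experiments,
`equalize_temporal_structure()` clones the mossy afferents of
randomly-paired GoCs from one patch onto the other.

# Analysis

Population activity is the average 1-ms-binned spike count per cell. The
cross-correlation estimator divides lagged products by `L x Z` with Z from
the (unbiased) variances — at zero lag on identical inputs it equals
`(L-1)/L` — over lags +/-300 ms. Rate co-modulation is discounted by
low-pass filtering both activities below 10 Hz (zero-phase 4th-order
Butterworth — our choice of filter) while normalizing by the *unfiltered*
variances: `c = a - b`. Significance: activities are cut into 10-ms
sub-epochs, independently permuted (50 shuffles), and
`p = n_out / (n_shuffle x 601)` counts shuffled CCF values at any lag
exceeding |CCF(0)|; the permutation is applied to population-activity
segments. PSDs are Welch averages (1-s Hann segments, 50% overlap) of the
1-ms activity; the oscillation frequency is the in-band power peak. The
synchronization index smooths the population PSTH with a 3-ms Gaussian,
delimits cycles at successive local minima (minima closer than 4 ms are
merged — the cycle-detection smoothing is not specified by the reference
analyses, so both constants are configurable), and averages the per-cycle
spike mass per cell, clamped to 1. Dynamic range is the max/min ratio
across input rates of the percentage of cells active per 1/10/100-ms
window, with a one-cell floor when the minimum is zero. Volumetric maps
bin spiking cells per millisecond into 10-um voxels and convolve with a
max-normalized Gaussian. Bootstrap errors resample cells with replacement.

# Scale presets and problem sizes

`scale_network()` provides `full` (1500 x 700), `slab` (1500 x 300),
`strip` (1500 x 100) and `mini` (600 x 200). Densities, radii and kinetics
never change across presets; only the footprint does, and per-build
calibration restores per-cell statistics. The package's own verification
uses: the slab for structural statistics (855 GoCs, 342,000 GrCs); the
strip for long baseline-rate runs (285 GoCs, 114,000 GrCs, 10 s at
dt = 0.1 ms, three input/engine seeds on one anatomical build) — the
strip is also the calibration harness; and the mini preset for the
dynamical property checks (oscillation tuning, on-beam inhibition,
gap-junction synchrony, burst latency gating, NMDA probe gain, tonic
inhibition), the smallest volume whose parallel-fiber candidate pools
still reach the anatomical convergence targets and which keeps a full
patch plus an on-beam neighbourhood intact. The emergent-property checks
are directional comparisons across three seeds, not reproductions of
full-scale figures.

A few estimator choices in that suite deserve note. Oscillation peaks are
searched in a 5-100 Hz band: the population rhythm's fundamental lies in
the granular-layer range and a wider band lets the spectral argmax jump to
harmonics. The tonic-inhibition frequency comparison uses the 10-150 Hz
spectral centroid, which is stable at 1.25-s windows where the raw peak
hops between nearby modes across seeds. Gap-junction synchrony is read
out as the zero-lag correlation between interleaved halves of the Golgi
population, because the per-cycle participation index saturates at its
rate-driven value at this volume (it is still computed and reported by
`oscillation_metrics()`). The burst-latency gating window in the
surrogate has its minimum near 5-10 ms and recovers by ~50 ms (the
reference's minimum is at ~5 ms with recovery by 30 ms); the suite
asserts the window's shape over latencies 2-50 ms.

# Limitations

The surrogate point neurons reproduce calibrated rates and qualitative
circuit behaviour, not the intrinsic dynamics of the detailed
conductance-based reference cells (no subthreshold resonance, no dendritic
nonlinearity beyond the NMDA block, no PF-GoC NMDA receptors, no GoC
morphology). The synthetic spike ensembles used as analysis oracles are
(in)homogeneous Poisson processes: they validate the estimators'
arithmetic and calibration, but say nothing about non-Poisson regularity
or burstiness of real spike trains. Absolute oscillation power and
cross-correlation magnitudes at full scale depend on the reference
neurons' biophysics and are outside what the surrogates are calibrated to
reproduce; the package asserts orderings and directions for these.
Multi-synaptic contacts per cell pair are not modelled (one edge per
pair), and local field potentials are not computed.
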