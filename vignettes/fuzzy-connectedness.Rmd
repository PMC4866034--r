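---
title: "Seeded fuzzy connectedness and exact block-parallel propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seeded fuzzy connectedness and exact block-parallel propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcseg)
```

## The model

Fuzzy connectedness (FC) segments an object by asking, for every voxel, how
strongly it is connected to a user-placed seed. The primitive is a *fuzzy
spel affinity* between 6-face-adjacent voxels,

$$\mu_k(c,d) \;=\; \mu_\alpha(c,d)\,
  \sqrt{\,g_1\!\Big(\tfrac{f(c)+f(d)}{2}\Big)\;
        g_2\!\Big(\tfrac{|f(c)-f(d)|}{2}\Big)}\,,$$

where $f$ is the intensity image, $g_1$ is a Gaussian in the pair mean
(object brightness model, mean $m_1$, variance $v_1$) and $g_2$ a zero-mean
Gaussian in half the absolute intensity difference (homogeneity model,
variance $v_2$). $\mu_\alpha$ is the hard 6-adjacency indicator: affinity is
1 on the diagonal, 0 off the face neighbourhood. The connectedness of voxel
$c$ to the seed set is then the *max-min path strength*

$$\mathrm{FC}(c) \;=\; \max_{\text{paths } P:\,\text{seed}\rightsquigarrow c}\;
  \min_{(u,v)\in P} \mu_k(u,v),$$

the transitive max-min closure of the affinity: a path is as strong as its
weakest link, and a voxel as connected as its best path. Thresholding the
resulting *fuzzy scene* at $\theta$ yields the segmentation mask.

Assumptions worth keeping in view: the object (here, a contrast-enhanced
vessel in CT) is approximately Gaussian in intensity and locally homogeneous;
intensities are non-negative integers (the package refuses floating-point
input rather than quantizing silently); and adjacency is isotropic — voxel
spacing is carried through the I/O layer but does not enter the affinity.

### Choices the formula leaves open

* **Normalization.** Both Gaussians are *peak*-normalized
  ($g(m) = 1$), not area-normalized. This is the only choice under which
  $\mu_k \le 1$, as a fuzzy relation requires, so it is forced rather than
  free.
* **The scale of $g_2$.** Only its zero mean is inherent to the model; the
  package defaults to $v_2 = v_1$ (configurable through
  `estimate_affinity(..., sigma2_mode = )`), on the view that intensity noise
  drives both the spread of the object distribution and of adjacent-voxel
  differences.
* **Parameter estimation.** `estimate_affinity()` pools intensities from
  boxes of half-width `radius` (default 2 voxels, clipped at the volume
  boundary) around the seeds and uses the sample mean and the unbiased
  ($n-1$) sample variance. Degenerate regions are handled by a variance
  floor of $10^{-6}$ intensity² units.
* **Strict positivity.** Gaussian tails underflow to zero for extreme
  arguments at 12-bit range; table entries are floored at the smallest
  positive normal double, and $\sqrt{g_1 g_2}$ is evaluated as
  $\sqrt{g_1}\sqrt{g_2}$ so the product cannot underflow either. Every
  adjacent affinity is therefore strictly positive and the closure reaches
  every voxel (with astronomically small values across the background, which
  is the correct limit behaviour).

## The exact lookup table

Because intensities are integers, $\tfrac{f(c)+f(d)}{2}$ ranges over the
half-integers $s/2$, $s \in [0, 2\,\texttt{intensity\_max}]$, and
$\tfrac{|f(c)-f(d)|}{2}$ over $u/2$, $u \in [0, \texttt{intensity\_max}]$.
Two 1-D tables — `sum_table[s] = g1(s/2)` and `diff_table[u] = g2(u/2)` —
therefore replace per-edge affinity evaluation with two gathers and two
square roots, in $O(\texttt{intensity\_max})$ memory rather than a per-edge
affinity volume. This is *exact*, not an approximation: the table build and
the direct evaluation perform identical floating-point operations, and the
test suite asserts bit-equality over all $256^2$ integer pairs at an 8-bit
range. Both solvers evaluate affinities through the same expression, which
is what makes "error points = 0" a meaningful bit-exact criterion downstream.

## Reference solver and its oracle

`kfoe_reference()` computes the closure as a single-source widest-path
problem: best-first extraction from a priority queue ordered by descending
connectivity, with lazy re-insertion. Ties are broken FIFO by insertion
order; since the max-min fixpoint is unique, tie-breaking is observationally
irrelevant and FIFO merely makes traces reproducible. Seeds are fixed at
exactly 1.

Correctness is anchored two ways:

* `brute_force_connectedness()` enumerates *every simple path* from the seed
  on volumes of at most 32 voxels and takes the max of per-path minima — a
  definitionally faithful oracle with no shared machinery beyond the affinity
  table. The suite checks bit-identity on hundreds of random tiny volumes.
* `fixpoint_violations()` certifies any scene post hoc: at the closure,
  $\mathrm{FC}(d) \ge \min(\mathrm{FC}(c), \mu_k(c,d))$ for every adjacent
  pair, and seeds are exactly 1. This is checked exhaustively after solver
  runs.

## Emulating block-parallel propagation

Hardware implementations tile the volume into thread blocks and propagate
iteratively with flag arrays: active voxels relax their neighbours, improved
neighbours become active, and the run stops when no flag remains. Blocks
execute in no guaranteed order and communicate only through (atomic-max)
global memory, which is precisely where the known failure lives: an update
that crosses a block boundary can arrive *after* its target's flag was
already consumed in the same sweep, and the improved value then never
re-propagates.

The package reproduces this deterministically rather than with real threads.
`run_block_iterative()` executes blocks sequentially in a schedule-controlled
order; one pass visits every block once. Three policies bracket the
behaviour:

* **synchronous** — value reads come from a pass-start snapshot, and
  re-activation marks are double-buffered into the next pass. Quiescence
  provably implies the fixpoint.
* **sequential_asynchronous** — blocks read values *and* flags live, so a
  block scheduled later in a pass sees updates from earlier blocks (as blocks
  within one kernel launch do). No mark is ever lost; quiescence again
  implies the fixpoint.
* **adversarial** — live reads plus the flag race: when a voxel that was
  already processed in the current pass is re-raised *from another block*,
  its value is still max-updated but the re-activation is dropped, modelling
  a flag-clear landing after a concurrent flag-set. Intra-block raises are
  never dropped (blocks can synchronize internally). This is the policy that
  reproduces the real failure, and on random 32³ phantoms it produces
  thousands of stale voxels when correction is disabled.

A design note on why the race must be modelled explicitly: with strictly
double-buffered marks and a single seed, the active front on a 6-adjacency
grid alternates between the two parity classes of the lattice (every raise
of a voxel happens one pass after a raise of a neighbour), so a voxel and
its neighbour are *never* processed in the same pass and no interleaving of
a mark-preserving emulator can err. The failure is a property of racy flag
handling, not of block ordering alone, and the adversarial policy injects
exactly that race — nothing else — so that the correction machinery has a
real disease to cure.

`enumerate_interleavings()` plus `apply_events()` expose the same mechanism
at the scale of individual update events: all admissible orders of a small
event set can be replayed with consume-once flags, and the orders in which a
voxel propagates before being refreshed are exactly those that under-fill
its downstream neighbours. `make_edge_race_fixture()` packages a 24×3×1
three-block volume whose corridor lengths are tuned (one pass apart at the
block edge) so the race fires deterministically under the fixture's explicit
A→B→C schedule: 15 downstream voxels keep a weak bottleneck value of
$e^{-1/8} \approx 0.8825$ where the true connectedness is 1.

### Correction iterations

After the main loop reaches quiescence, a correction round re-activates
every voxel on a block face whose outward direction is among the first
`correction_directions` entries of the fixed order
$(-x, +x, -y, +y, -z, +z)$, then re-runs passes to quiescence; rounds repeat
until one changes nothing (or `max_correction_rounds`, default 8, is hit).
Two rounds repair a two-block crossing and three a three-block crossing;
iterating to a change-free round upgrades "usually enough" to a guarantee:

* every *lost* re-activation is by construction a cross-block raise, so its
  victim lies on a block face;
* a change-free full-face round has just re-processed every face voxel with
  its final value and raised nothing, so no adjacent pair violates the
  fixpoint inequality at a face, and interior voxels (whose raises are never
  lost) already satisfy it;
* a monotonically-reached fixpoint whose values are all realized by actual
  paths is the unique max-min closure.

Hence with `correction_directions = 6` the emulator's output is bit-identical
to the sequential reference for *every* partition, policy and schedule seed —
the property the test suite asserts over 300 phantom runs. With fewer
directions only a subset of faces is repaired, which is what
`direction_sweep()` measures: error counts non-increasing in the direction
count, reaching 0 at 6. The mapping from direction indices to faces is a
declared package convention; only the monotone trend, not per-index counts,
is meaningful.

## The phantom generator

`generate_phantom()` emulates the intensity structure the affinity model
assumes, at desk scale: a tubular foreground (polyline/helix centerline,
radius in voxels, default 2.5) with Gaussian intensities
$N(\mu_{fg} = 1250, \sigma_{fg} = 30)$ against background
$N(\mu_{bg} = 1100, \sigma_{bg} = 20)$ on a 12-bit range — the contrast and
noise scale of a portal-phase hepatic CT, in HU-shifted counts — rounded
(half-to-even, R's `round()`) then clamped to $[0, 4095]$. The ground-truth
mask is geometric (pre-noise), and the default volume is 32³ with 8³ blocks
so that desk-scale runs still contain dozens of inter-block faces to stress.
The suggested seed is the voxel nearest the centerline midpoint. Identical
specs and RNG seeds are bit-reproducible.

What the phantom does *not* emulate — and hence what passing tests do not
show about clinical data: branching vascular trees, partial-volume blur at
the vessel wall, beam hardening and other CT physics, anisotropic voxels,
and touching structures of similar intensity. The exactness claims
(LUT = direct, corrected block run = reference) are data-independent
algebraic properties and do transfer; segmentation *quality* on real series
depends on the affinity model actually fitting the anatomy and is not
certified by this suite.

## Numerical and degenerate-input choices

* Connectivity values are min/max selections over the finite set of table
  affinities, so reference and emulator can agree *bit-exactly*; comparisons
  (`error_points()`) therefore default to tolerance 0, and a nonzero
  tolerance exists only for cross-implementation comparisons.
* Variance floor $10^{-6}$; Gaussian floor at the smallest positive normal
  double; $\sqrt{g_1}\sqrt{g_2}$ rather than $\sqrt{g_1 g_2}$ (no product
  underflow).
* 1×1×1 volumes, blocks larger than the volume, seed boxes clipped at the
  boundary, and constant seed regions are all legal degenerate inputs with
  tested behaviour.
* Propagation passes are guarded against non-termination by a generous cap
  (20 n + 1000 passes); monotone ascent over a finite value set guarantees
  the cap is never reached in correct operation.
* The per-pass block shuffle of the asynchronous policies uses a
  self-contained xorshift generator so schedules are bit-reproducible across
  platforms and independent of R's RNG state.

## Problem sizes in the shipped tests

The suite runs oracle comparisons on ~200 random volumes of ≤ 18 voxels
(within the 32-voxel brute-force guard), block-vs-reference exactness on
twenty 32³ phantoms × five schedule seeds × three policies, and the full
65 536-pair LUT identity at 8-bit range — sizes chosen so the whole suite
completes in well under a minute on one core while still exercising many
blocks, faces and interleavings per run.

## Known limitations

* Single-object FC only: no relative/iterative-relative FC, no multi-object
  competition (multi-seed input is treated as a union of one object).
* The affinity is intensity-based and isotropic; spacing is metadata.
* The emulator models block asynchrony and the flag race; it does not model
  warp-level effects, memory fences, or torn reads (values are updated
  atomically by assumption), and makes no wall-clock claims.
* DICOM series input is out of scope; convert to NIfTI/NRRD first.

## A worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(rng_seed = 7))
lut <- build_lut(estimate_affinity(ph$volume, ph$seeds, radius = 2),
                 ph$volume$intensity_max)
ref <- kfoe_reference(ph$volume, ph$seeds, lut)

sched <- block_schedule("adversarial", rng_seed = 1)
broken <- run_block_iterative(ph$volume, ph$seeds, lut,
                              block_partition(ph$volume), sched,
                              correction_directions = 0)
fixed <- run_block_iterative(ph$volume, ph$seeds, lut,
                             block_partition(ph$volume), sched,
                             correction_directions = 6)
error_points(ref, broken)$error_points   # > 0: the asynchrony disease
error_points(ref, fixed)$error_points    # 0: corrected, bit-exact
mask <- threshold_segment(fixed, 0.5)
```
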