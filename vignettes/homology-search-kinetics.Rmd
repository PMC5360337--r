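---
title: "Kinetics of homology recognition between rigid dsDNA rods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of homology recognition between rigid dsDNA rods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodsearch)
```

## The model

Two segments of double-stranded DNA are represented as rigid rods, each
carrying `n_sites` binding sites spaced `spacing_a` apart — one
interaction locus per helical turn, 3.4 nm, so the default 17-site rod is
57.8 nm long, about one persistence length.  A homology test begins when
the centers of two rods collide at a planar angle $\theta_0$.  Sites $i$
on rod A and $j$ on rod B attract if and only if their sequence symbols
match, with a rapidly decaying radial kernel normalized to 1 at contact:

$$U(\theta) \;=\; -\epsilon \sum_{(i,j)\,:\,\text{match}} K\!\big(r_{ij}(\theta)\big),
\qquad K(r) = e^{-(r - r_0)/\lambda}
\;\text{ or }\; \Big(\tfrac{\lambda}{r - r_0 + \lambda}\Big)^{3},$$

where $r_{ij}$ combines the in-plane distance between the two sites with
a constant closest-approach offset $r_0$ in quadrature.  Because
$\lambda \ll a$, at any appreciable angle only the few sites nearest the
collision point interact: a collision probes a short central stretch of
sequence, and rotating towards the parallel state $\theta = 0$
progressively engages the rest of the rod.

The bound pair evolves as a continuous-time Markov chain over a discrete
angle grid.  Thermal fluctuations rotate the pair towards or away from
alignment; from every bound state the pair can also unbind, irreversibly,
with the Arrhenius escape rate $k_{\mathrm{off}}(\theta) =
k_{\mathrm{off},0}\, e^{U(\theta)}$.  The bare rate
$k_{\mathrm{off},0} = 1$ defines the unit of time: a fully mismatched,
zero-energy contact lives for one time unit on average.  The model has no
sliding coordinate (a slide is a composition of unbinding and a fresh
collision), no torsional-deformation energy, and no explicit
electrostatics; the kernel above is the entire interaction.

On top of the single-collision chain sits a kinetic-proofreading layer:
a pairing that remains bound for a delay $T_D$ is irreversibly
stabilized.  Writing $f_N$ for the expected number of genome segments
whose central match-run with the searcher has length exactly $N$, and
$P_N(T_D)$, $P_T(T_D)$ for the angle-averaged survival probabilities of
class-$N$ off-targets and of the true target, the specificity, expected
off-target dwell per search round, and total search time are

$$\sigma(T_D) = \frac{f_T P_T}{f_T P_T + \sum_{N=1}^{n} f_N P_N},\qquad
\tau_{\mathrm{off}} = \int_0^{\theta_{\max}}\! p(\theta_0)
\sum_{N=1}^{n} f_N \tau_N(\theta_0)\, d\theta_0,\qquad
\langle T_{\mathrm{search}}\rangle =
\frac{\tau_{\mathrm{off}} + \tau_{\mathrm{diff}}}{P_T},$$

with collision angles sin-weighted ($p(\theta_0)\propto\sin\theta_0$,
collisions uniform over a half sphere, truncated at $\theta_{\max}$ when
crowding biases collisions towards small angles).  For $k$ correlated
parallel collision points, $P_T'(k) = 1 - (1 - P_T)^k$ replaces $P_T$.

## Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `n_sites` | 17 | — | sites per rod (one per helical turn) |
| `spacing_a` | 3.4 | nm | inter-site distance |
| `epsilon` | 1.5 | $k_BT$ | attraction per matched pair at contact |
| `decay_length_lambda` | 0.34 (= a/10) | nm | kernel decay length |
| `contact_r0` | 2.0 | nm | closest approach of facing sites |
| `kernel` | exponential | — | radial form (`power_law_3` optional) |
| `alphabet_size` | 4 | — | accidental match probability $q = 1/4$ |
| `theta_max` | $\pi/2$ | rad | largest collision angle |
| `n_angle_bins` | 90 | — | angle grid resolution |
| `k_rot` | 14.632 | $k_{\mathrm{off},0}$ | rotational attempt rate (see below) |
| `k_off0` | 1 | — | time unit; fixed |

Two of these deserve comment.  The decay length is set to a tenth of the
site spacing so that the interaction is genuinely short-ranged: at the
default geometry the nearest-neighbour cross-term at contact is
$e^{-5.7} \approx 3\times10^{-3}$ of a facing-pair contact, which is what
confines the initial homology test to a few sites around the collision
point.  The contact offset `contact_r0` stands in for the out-of-plane
separation of the rod centers: rather than track that separation as a
second coordinate, it is folded into a constant added in quadrature, so
bound states are indexed by the angle alone and unbinding is a single
irreversible transition.  Only differences $r - r_0$ enter the kernel, so
this constant mostly fixes how fast cross-terms die off.

The power-law kernel $[r - r_0]^{-3}$ diverges at contact; it is softened
to $(\lambda/(r - r_0 + \lambda))^3$, which is normalized to 1 at contact
like the exponential, so a matched facing pair contributes $-\epsilon$
under either kernel and results are comparable across kernels.

## Discretization of the rotational dynamics

The angle grid is uniform on $[0, \theta_{\max}]$ with the parallel state
at exactly $\theta = 0$.  Hops between adjacent states use Metropolis
rates with respect to the stationary weight $\pi_i \propto
e^{-U(\theta_i)} h_i$, where $h_i$ is the width of the grid cell a state
represents — full width in the interior, half width for the two end
states.  This half-cell convention makes the chain a finite-volume
approximation of reflected rotational diffusion in the potential
$U(\theta)$: without it the end states carry twice their share of
Boltzmann mass and mean unbinding times shift by ~10% when the grid is
refined; with it, doubling `n_angle_bins` moves first-passage
probabilities and mean unbinding times by only ~2–3%.

The hop attempt rate is `k_rot` on the reference grid (90 bins on
$[0, \pi/2]$) and scales as $1/\delta\theta^2$ on any other grid, so the
rotational diffusion coefficient $D = k_{\mathrm{rot}}\,
\delta\theta_{\mathrm{ref}}^2$ is a grid-independent physical quantity.
Sweeps over `theta_max` therefore change the geometry of the collision,
not the speed of rotation.

**Calibration of `k_rot`.**  The model separates three timescales: fully
mismatched contacts reject in ~1 time unit; a matched pair needs a
characteristic time $\tau_{\mathrm{rotation}}$ to rotate into alignment;
and near-matches trapped at alignment unbind $>10^6\times$ more slowly
than they rotate.  We pin the middle scale by calibrating `k_rot` once so
that the mean time for a perfectly matched pair to rotate from a
sin-distributed collision angle into the parallel state is exactly 100
time units (`rotation_time()`, and `scripts/calibrate_krot.R` for the
one-time solve).  This rotation time is computed for the rotational
dynamics alone, with unbinding switched off.  The alternative — the mean
arrival time conditioned on beating unbinding — is dominated by the rare
collisions that start almost parallel (survivorship bias), and
calibrating on it would force the attempt rate far below the unbinding
rate, erasing the distinction between the rotating and the rotationally
constrained model that the whole analysis is about.  The conditional
quantity remains available via `rotation_time(conditional = TRUE)`.

## The sequence ensembles

`random_sequence()` draws i.i.d. uniform symbols from an alphabet of
`alphabet_size` letters, so two random sites match with probability
$q$.  Off-target classes are defined by the maximal run of matched facing
sites containing the central site (the collision point): N = 0 means the
central site mismatches.  `offtarget_with_N_matches()` constructs class
members directly — run placed as symmetrically as possible about the
center (even runs extend one site to the right), bounding mismatches
forced so classes are disjoint, all remaining sites matching with
probability $q$ — and `fN_random()` gives the closed-form expected class
counts for a genome of `G` segments, which sum to `G` exactly.
`fN_genome()` computes the same spectrum empirically by sliding a
17-symbol window one base at a time over a FASTA genome; each
nucleotide-level window is a proxy for one potential collision partner
(how a real genome maps onto one-site-per-helical-turn sequences is not
uniquely defined; the window proxy is this package's convention, and
record boundaries break windows).

What the generator emulates is a well-mixed ensemble: every search round
exposes the searcher to the class statistics of the whole genome.  It
does not emulate local genomic neighbourhoods (a crowded nucleus may
confine a searcher to a biased local ensemble), nucleosome occupancy,
or strand secondary structure.  Tests passing on these ensembles
demonstrate the kinetic mechanism — they do not certify quantitative
search times for any particular organism.  The headline "genome-scale"
computations in the test suite use the closed-form random ensemble with
$q = 1/4$ and $G = 4{,}641{,}652$ segments (an E. coli-sized genome);
the empirical path is exercised on synthetic FASTA fixtures generated at
test time, since no genome file ships with the package.

## Numerical choices

*Exact solvers first.*  Reach probabilities and mean unbinding times are
linear solves on the generator; survival curves use the spectral
decomposition of the bound-state block.  Because the rotation rates are
reversible with respect to $\pi$, the block is symmetrizable by
$D^{1/2} Q D^{-1/2}$ with $D = \mathrm{diag}(\pi)$, and one symmetric
eigendecomposition per sequence gives the survival from every initial
angle at every time — this is what makes 200–2000-sequence ensembles
cheap.  Deep wells decay at rates as small as $e^{-\epsilon n}$, far
below the $\varepsilon_{\mathrm{mach}}\|S\|$ resolution of a dense
eigensolver, so each eigenvalue is refined as a Rayleigh quotient in
Dirichlet form (a ratio of sums of nonnegative terms, free of
cancellation) and survival logs are evaluated stably at arbitrarily
large delays.  Mean unbinding times of rotating chains come from the same
spectrum ($\tau = \sum_k -c_k/\lambda_k$).

*Delay selection.*  $\sigma(T_D)$ is evaluated in log space.  Its
long-delay limit $\sigma_{\max}$ is taken at a horizon of $10^3\times$
the slowest class decay time, with a convergence check (relative change
$< 10^{-4}$ over the last decade); `choose_delay()` then bisects for the
smallest $T_D$ with $\sigma \ge f\,\sigma_{\max}$ to 1% relative
tolerance, erroring rather than answering if the bracket is inconsistent
with monotone $\sigma$.  When full-length accidental matches exist
($q = 1/2$ makes $f_{17} \approx 35$ on a bacterial genome) those
segments are indistinguishable from the true target and
$\sigma_{\max} = f_T/(f_T + f_{17})$; the package reproduces this limit.

*Sums over classes.*  The printed specificity and dwell formulas start
at $N = 1$; whether the enormous $N = 0$ class (dwell $\approx 1$) should
enter $\tau_{\mathrm{off}}$ is ambiguous, so the literal form is the
default and `include_N0 = TRUE` adds it.

*Stochastic oracle.*  The Gillespie simulator (Rcpp, driven by R's RNG,
so `set.seed()` reproduces trajectories bit for bit) is the independent
check on every deterministic quantity and the engine for
trajectory-level output.  Ensembles derive per-replicate seeds from a
master seed by a fixed counter scheme, so replicate $i$ is reproducible
regardless of how many replicates run.  Deep-well mean unbinding times
are deliberately out of scope for simulation (the linear solver owns
them); simulation cross-checks are restricted to chains with mean
unbinding times below $10^6$.

*Degenerate inputs.*  Off-grid initial angles are an error, never
silently snapped; all-mismatch pairings give a flat zero landscape and
unit unbinding everywhere; ensembles require an odd `n_sites` (a central
site must exist), while the geometry itself supports even counts with
the collision point midway between the central sites.

## Problem sizes

The headline study condition is 2000 sequences per off-target class.
The test suite reproduces every qualitative result at 200 sequences per
class (and 15–50 for pure plumbing checks), where class-mean curves are
already stable to a few percent; the simulation cross-checks use $10^5$
trajectories per chain.  These are the package's chosen verification
sizes; `n_replicates` raises any of them.

## Known limitations

- Rigid rods: no bending, no torsional registration penalty, no sliding.
- One binding site per helical turn, identical for all sequence symbols;
  real stacking/sequence effects on the attraction are not modeled.
- `tau_diff` is a scalar input, not a spatial diffusion model, and the
  parallel-collision count `k` is an input, not a polymer calculation.
- The absolute time axis rests on the `k_rot` calibration convention
  described above; ratios between model variants are the robust outputs.
- Off-target capture ends a search wrongly; this is accounted in
  $\sigma$, while $T_{\mathrm{search}}$ conditions on eventual correct
  capture.

## A short session

```{r example, eval = FALSE}
p <- model_params()
ens <- fN_random(p, genome_length = 4641652)     # E. coli-sized, q = 1/4

kin <- search_kinetics(p, n_replicates = 200, master_seed = 1)
sm  <- search_pipeline(p, ens, kinetics = kin)   # rotating searcher
sm

sweep_search("epsilon", c(0.3, 0.5, 0.75, 1, 1.5), p, ens,
             n_replicates = 200, master_seed = 1)
```
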