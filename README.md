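# syllabr

Sub-second behavioral syllable analysis for open-field locomotion, built
for phenotyping dopamine-depletion (Parkinsonian) mouse models and testing
treatments against them.

Rodent locomotion decomposes into brief stereotyped motifs — *behavioral
syllables* (runs, pauses, freezes, turns) lasting a few hundred
milliseconds. Parkinsonian dopamine loss does not slow all movement
uniformly: it preferentially degrades fast syllables, shifts expression
from fast to slow syllables, and makes syllable sequences more repetitive.
`syllabr` implements the full analysis chain needed to quantify these
effects, together with a seeded synthetic cohort generator so every stage
is testable end to end without any video data.

## What the package computes

**Segmentation** (pose → syllables): egocentric alignment of keypoints
(translate the centroid to the origin, rotate the posterior→anterior body
axis to +x), PCA to 5 components, and a reduced *sticky AR(1)-HMM* fit by
blocked Gibbs sampling:

    x_t | z_t = s  ~  N(A_s x_{t-1} + b_s, Σ_s)
    z_t | z_{t-1}  ~  rows with Dirichlet(α/S · 1 + κ e_i + counts) posterior

The stickiness mass κ inflates self-transitions and thereby sets syllable
duration; `kappa_scan()` selects the κ whose median decoded duration is
closest to a 400 ms target (~12 frames at 30 fps). Decoding is Viterbi,
so downstream statistics are exactly reproducible.

**Kinematics and expression** per animal × syllable: velocity (mean
frame-to-frame displacement of the frames assigned to a syllable, × fps),
usage (fraction of frames), duration, the 0.5 %-of-time inclusion filter,
session-average speed, and velocity ranking.

**Temporal organization**: instance-level transition matrices *A* (zero
diagonal), steady state π (π = πA, damped power iteration restricted to
the recurrent class), entropy rate

    H = − Σ_ij π_i A_ij ln A_ij    (plus the unweighted row-entropy sum)

and transition frequency (syllable change-points per second).

**Group statistics**: per-syllable Kruskal–Wallis with Dunn's post hoc
(exact permutation p for small untied samples), Benjamini–Hochberg across
syllables at q = 0.05, Mann–Whitney U for scalar measures, mean ± SEM
summaries, and the Δvelocity / Δusage versus control-velocity regressions
that test whether dopamine loss hits faster syllables harder.

**Synthetic cohorts**: `simulate_cohort()` generates control, lesion, and
optional lesion+treatment groups — a Markov syllable chain with geometric
dwell, truncated-Gaussian step emission, persistent-heading bounded walk
in a 40 × 40 cm arena — with known speeds, usage, and transition
structure, so parameter recovery is checkable.

## Worked example

```r
library(syllabr)

cfg <- sim_config(seed = 1)          # 20 syllables, 3-17 cm/s, 8 vs 8,
co  <- simulate_cohort(cfg)          # 20-min sessions at 30 fps
st  <- syllable_stats(co$sessions)
uf  <- filter_by_usage(st, min_usage = 0.005)

delta_regression(st, "velocity", syllables = uf$retained)
#> delta_regression (velocity): slope = 0.3997, intercept = -1.1996,
#>   R^2 = 1.000, p = 1.5e-44, n = 20
```

The slope recovers the generator's proportional velocity-loss parameter
(β = 0.4): the lesion group loses ~0.4 cm/s of syllable velocity per cm/s
of control velocity, i.e. fast syllables are hit hardest. Transition
structure shows the complementary sequencing deficit:

```r
models <- lapply(co$sessions, transition_model, syllables = 0:19)
tf <- sapply(models, function(m) m$transition_frequency)
gr <- sapply(co$sessions, function(s) s$group[1])
round(tapply(tf, gr, mean), 2)
#> control  lesion
#>    2.01    1.56
```

Lesioned animals switch syllables ~22 % less often — they dwell longer in
each motif. The numbered scripts under `analysis/` run the same workflow
as a five-stage narrative (simulate → segmentation demo → metrics →
transitions → statistics) and write tables under `results/analysis/`.

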