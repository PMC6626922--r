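---
title: "Modelling cytotoxic memory, clonal competition and interferon attrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cytotoxic memory, clonal competition and interferon attrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(manaim)
```

## The model

`manaim` is a stochastic, agent-based simulation of the CD8+ cytotoxic
T-cell (Tc) arm of the adaptive immune response in a small volume of
lymphoid tissue.  Its purpose is to study *clonal competition*: how a
pre-existing, cross-reactive memory repertoire interacts with the naive
repertoire when the host is challenged with a virus similar -- but not
identical -- to one seen before.  Two emergent phenomena are the focus:

* **memory anti-naive (MaN) dominance** -- fast, abundant, low-affinity
  cross-reactive memory wins the competition for antigen and silences a
  potentially higher-affinity naive response, while clearing the virus
  poorly; and
* its mitigation by **type-I interferon driven attrition**, which
  preferentially culls aged, low-affinity cytotoxic cells early in an
  infection and thereby frees space for naive, high-affinity clones.

### Bit-string specificity

Specificity follows the classic binary-string (cellular-automaton) immune
models.  A receptor is an `N = 16` bit integer; a viral peptide is an
`N/2 = 8` bit integer.  The *match* `m` between two strings is the number
of complementary bit positions (the Hamming distance of the strings).
The half of the TCR facing the MHC molecule is held at a constant full
match, so only the 8 peptide-facing bits discriminate viruses and the
total match ranges over `8..16`.  Binding requires `m >= m_c = 13`; the
affinity potential is

$$ f(m) = \exp\!\Big(\log A_L\,\frac{m-N}{m_c-N}\Big)
        = A_L^{(N-m)/(N-m_c)}, \qquad m_c \le m \le N, $$

and 0 below the cut-off; `f(N) = 1` and `f(m_c) = A_L`.  With the
defaults there are exactly four binding classes, `m` in 13..16.  `A_L`
is a free slope parameter; the package ships `A_L = 0.05`, a steep ladder
under which one lost match bit costs a factor of about `0.37` in
affinity, which keeps low-affinity cross-reactive binding clearly inferior
to a full match while still allowing it to compete by abundance.

The receptor diversity is `2^16 = 65,536`.  For a given peptide the
number of receptors in class `m = 8 + c` is `choose(8, c)`, so perfect
binders are rare (1 low-half pattern in 256) while cut-off binders are
plentiful (56 in 256) -- the combinatorial backbone of every result below.

### The virus panel and antigenic distance

Nine strains `V0..V8` carry the prefix-of-ones peptide ladder
(`00000000`, `00000001`, ..., `11111111`), giving the exact distance
relation `d(V_i, V_j) = |i - j|`.  All strains share one fitness triple
(replication factor per 8 h step, per virion-cell infectivity, lethal
load), so antigenicity is the only variable in the protocol.  A clone
with `c` complementary peptide bits against `V0` matches `V_d` with
`c' = c - d + 2x`, where `x` counts its mismatches that fall inside the
`d` mutated bits.  Two consequences matter:

* a perfect anti-`V0` clone (`m = 16`) binds `V_d` with `16 - d`, so pure
  top-class memory cross-reacts exactly down to `d = 3`;
* class-15 memory whose single mismatch falls in the mutated region binds
  `V_4` at the cut-off, extending effective cross-reactivity to `d = 4`,
  while *no* class-15 or class-16 clone can bind at `d = 5`.  Distances 7
  and 8 admit no cross-reactive binder at all.

The memory pool's class composition therefore decides where, on the `d`
axis, cross-reactive dominance collapses.

### World, agents and phases

The volume is a toroidal 3D lattice (default `8x8x8` sites standing for
10 microliters of lymphoid tissue) carrying two fields -- free virions
per strain and an IFN-beta concentration -- and three agent populations:
T cells, epithelial target cells, and macrophages.  One step is 8 h.
Each step applies, in fixed order: infection, intracellular replication
and burst (with the lethal-load check), MHC-I presentation, virion
transport, IFN-beta secretion and field transport, T-cell movement,
stimulation, proliferation, cytotoxic killing, attrition culling, and
homeostasis.  All stochastic choices use the run's seed, so a run is a
pure function of `(config, seed)`.

The *antigen-competition bottleneck* is the stimulation rule: per step,
each presenting cell engages at most one co-located T cell, drawn with
probability proportional to `f(m)`, multiplied by `memory_speed_factor`
for memory cells.  Everything the package says about MaN flows through
this bottleneck.

Memory speed of deployment is implemented by three asymmetries: resting
memory kills on contact without re-expanding first (an effector-memory
phenotype); an engaged memory cell starts duplicating immediately while
an engaged naive cell arms only after `act_delay_naive` steps; and memory
carries the competition weight above.  Conversely, memory expansion is
*bounded*: a memory cell retains only `mem_division_budget` divisions
under the Hayflick cap (replicative senescence), so a recalled memory
lineage can expand at most `2^mem_division_budget`-fold whereas a naive
lineage has the full cap available.  A homologous challenge is therefore
eliminated while pathogens are still few, and the lack of further
stimulation keeps the effector count low -- the compression signature.

Memory differentiation happens at contraction: an effector whose
stimulating strain is no longer presented anywhere differentiates to
resting memory with probability
`mem_diff_prob * f(m)^mem_diff_exponent`.  The exponent concentrates the
memory pool in the top match classes, mirroring affinity-dependent
selection into the memory compartment; it is the single most influential
calibration parameter for where the compression cliff sits (see above).

Cell age is lineage age: daughters inherit their parent's age rather
than being born at zero.  Age only enters the attrition death law, and
this choice is what lets attrition discriminate against expanding
low-affinity clones -- with birth-age-zero daughters every expansion is
uniformly young and the age arm of the death law never sees it.

### Attrition

Macrophages at danger sites (free virions at or above
`danger_threshold`) secrete IFN-beta, which diffuses to the six
neighbours and decays.  Each T cell then dies with probability

$$ \Pr[\mathrm{die}] \;=\; \frac{a^{n_1}}{a^{n_1}+k_1}\cdot
   \frac{\alpha\, i^{n_2}}{\alpha\, i^{n_2}+k_2}\cdot (1-f), $$

with age `a` in days (steps/3), local concentration `i` in pg/ml,
`k_1 = 10^6`, `k_2 = 10^9`, `n_1 = 3 > n_2 = 2` (age is the limiting
factor), and `f` the cell's best affinity to any currently presented
peptide (0 if it binds none -- unmatched cells are maximally exposed).
`alpha` in 0..5 scales the interferon arm; `alpha = 0` is the control
and skips the step entirely, so a control run is step-for-step identical
to one without the mechanism.  The constants are treated as pure numbers
on their stated unit scales.  Aged, unmatched memory is culled orders of
magnitude faster than young naive cells, which is the entire mitigation
mechanism: attrition thins the dominant old pool during the early
challenge and lets fresh high-affinity clones take the antigen.

## The prime/challenge protocol and metrics

A protocol run primes a naive world with `V0` at `t_I = 0` and
challenges with `V_d` at `t_II = 1000` steps, both at the saturating dose
of `10^3` virions per microliter over 10 microliters; the horizon is
1300 steps.  The full experiment grid crosses `alpha = 0..5` with
`d = 0..8` (54 configurations), with a deterministic injective seed per
`(d, alpha, replicate)`.

Per run and challenge virus the package computes the class counts
`q_m(t)`, per-class affinity `A_m(t) = f(m) q_m(t)`, total affinity
`TA(t) = sum_m A_m(t)`, the time-to-clear
`t_c = min{t >= t_II : V(t) = 0} - t_II` (censored if never zero), the
efficacy `E = max_{t >= t_II} TA(t) / t_c`, and the peak count
`M~ = max_{t >= t_II} sum_m q_m(t)`.  Compression is
`C(d) = <M~>_{d=8} - <M~>_d` within one attrition stratum.  Conventions
chosen where the definitions leave room (each documented at the
function): censored runs score `E = 0`; `E` is averaged per run rather
than formed from averaged numerator and denominator (both views are a
one-liner from the grid table); the `d = 8` reference of `C` is taken at
the same `alpha` as the compared cell; and the "critical distance" of a
curve is the location of its largest one-step decrease.

## Calibration and the shipped defaults

The protocol constants (`N`, `m_c`, `k_1`, `k_2`, `n_1`, `n_2`,
dose, volume, `t_II`, the virus panel) are fixed.  Everything else --
per-step rates the underlying biology does not pin down -- is a named
configuration parameter.  The shipped defaults were calibrated, in this
order, against three gates:

1. *Primary clearance*: a saturating `V0` prime must peak and clear well
   before the challenge in essentially all replicates.  This sets the
   balance of infectivity (0.01), replication factor (3), burst size
   (64), free-virion decay (0.4/step), epithelial regeneration (0.01)
   and the killing scale against the expansion machinery.
2. *Memory formation and speed*: a homologous (`d = 0`) challenge must be
   cleared faster than a heterologous one, by a standing memory pool of a
   few hundred to ~2000 cells.
3. *Competition structure*: cross-reactive dominance should hold through
   mid distances and collapse where the combinatorics stop supplying
   binders, which is governed by the memory-pool composition
   (`mem_diff_exponent`), the competition weight
   (`memory_speed_factor`) and the affinity slope (`A_L`).

Desk-scale problem sizes are used throughout: an `8^3` lattice with 1024
T cells, 2048 epithelial cells and 128 macrophages, and 20 replicates
per grid cell (the full protocol's 100 replicates are one flag away,
`paper_scale = TRUE`).  At this scale one protocol run takes on the
order of a second.

## What the generator does and does not emulate

The synthetic world captures: finite-repertoire sampling noise (naive
precursor counts per class are small and hypergeometric-ish), spatial
encounter stochasticity, the antigen bottleneck, replicative senescence,
and danger-triggered local interferon.  It does not model: helper T
cells and licensing, the humoral branch (no antibodies -- free virions
are cleared only by decay and infection), affinity maturation of T cells
(the repertoire is fixed; "maturation" here is purely selective),
explicit thymic selection, anergy, or migration between organs.
Passing tests therefore demonstrate the internal consistency of this
competition model, not quantitative agreement with any in-vivo
measurement; all cross-run comparisons are relative, within one
calibration.

## Numerical and degenerate-input conventions

Virion counts are integers; transport uses exact multinomial thinning
(per-direction binomials), so virion mass balances to the unit and
extinction (`V = 0`) is exact, making `t_c` well defined without a
threshold.  The IFN field is continuous with a deterministic stencil.
Ties inside a phase (strain order at co-infected sites, engagement
draws, movement) are resolved by seeded draws.  A `1x1x1` lattice is its
own neighbour six times; dead hosts refuse to advance with a warning;
min-max normalisation of a constant series is an error rather than a
silent `NaN`; and a censored `t_c` is `NA`, never a sentinel number.

## A worked example

```{r example, eval = FALSE}
run <- run_protocol(protocol_config(d = 2), seed = 1)
summary(run)
plot(run, what = "counts")

g0 <- run_grid(alpha_values = 0, replicates = 20)
E <- efficacy(g0, alpha = 0)
C <- compression(g0, alpha = 0)
eye_analysis(minmax_normalize(E$E_mean), minmax_normalize(C$C), E$d)
```

## Known limitations

* The competition bottleneck resolves at site granularity; very small
  lattices exaggerate MaN because every presenter sees every cell.
* With no humoral clearance, `t_c` has a floor set by free-virion decay
  of the injected dose; efficacy differences between nearby distances
  are therefore compressed relative to a model with antibodies.
* The critical-distance estimators act on means over a modest number of
  replicates; their argmax is an integer statistic and can flip between
  adjacent distances when the underlying drops are close.
* Cell counts are a few thousand, orders of magnitude below a real lymph
  node; all comparisons should be read as relative, within one
  calibration.
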