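# manaim

Agent-based, bit-string simulation of the CD8+ cytotoxic T-cell (Tc)
response to viral infection in a small lymph-node volume, built to study
**clonal competition between memory and naive repertoires** and the two
phenomena that emerge from it:

* the **memory anti-naive (MaN) effect** — when a second infection is
  similar but not identical to the first, fast-deploying, cross-reactive
  memory clones win the competition for antigen and silence a potentially
  higher-affinity naive response, while themselves clearing the virus
  poorly ("original antigenic sin" on the cytotoxic side);
* its mitigation by **type-I interferon (IFN-β) attrition** — early in an
  infection, macrophage-derived IFN-β preferentially kills aged,
  low-affinity cytotoxic cells, thinning the dominant memory pool and
  letting fresh high-affinity clones through.

## The model in brief

Receptors are `N = 16`-bit strings, viral peptides `N/2 = 8`-bit strings;
a "match" `m` is the number of complementary bits (the MHC-facing half is
held at a constant full match).  Binding requires `m ≥ m_c = 13` and has
affinity

```
f(m) = A_L^((N − m)/(N − m_c)),   m_c ≤ m ≤ N      (0 below the cut-off)
```

so `f(N) = 1` and `f(m_c) = A_L`.  Nine viruses `V0…V8` with peptides
`00000000`, `00000001`, `00000011`, …, `11111111` realise antigenic
distances `d(V_i, V_j) = |i − j|`.  The protocol primes a naive lattice
world with `V0`, challenges at step 1000 with `V_d` (saturating dose
`10^3` virions/µl in 10 µl), and tracks per-match-class Tc counts
`q_m(t)`, viral load, total affinity `TA(t) = Σ_m f(m) q_m(t)`,
time-to-clear `t_c`, **efficacy** `E(d) = max_{t≥t_II} TA(t) / t_c`, and
**compression** `C(d) = ⟨M̃⟩_{d=8} − ⟨M̃⟩_d` where `M̃` is the
post-challenge peak Tc count.  Attrition culls each Tc per step with

```
Pr[die] = a^3/(a^3 + k1) · α i^2/(α i^2 + k2) · (1 − f),
          k1 = 10^6 (days), k2 = 10^9 (pg/ml), α = 0…5
```

The full experiment grid crosses `α = 0…5` with `d = 0…8`
(54 configurations, replicated with deterministic per-cell seeds).

## Worked example

```r
library(manaim)

run <- run_protocol(protocol_config(d = 2), seed = 1)
summary(run)
#> Prime/challenge run: d=2, alpha=0, seed=1
#>   challenge V2 at t_II=1000; cleared in 45 steps
#>   peak TA=460.384  efficacy E=10.2307  peak Tc count=3998
#>   per-class affinity peaks: m=13 86.95, m=14 117.13, m=15 195.99, m=16 68.00
```

The cross-reacting challenge two bits away from the primer is cleared in
45 steps (15 days); the peak response of ~4,000 cytotoxic cells is well
below what the same dose elicits at full antigenic distance (the
compression signature), and the class `m = 15` affinity peak dominates:
perfect `m = 16` binders are combinatorially rare, so the response is
carried by abundant near-perfect clones.  Continuing with the grid
analyses:

```r
g0 <- run_grid(alpha_values = 0, replicates = 20)
E <- efficacy(g0, alpha = 0)      # data frame: d, E_mean, E_sd, n
C <- compression(g0, alpha = 0)   # data frame: d, M_mean, C
eye_analysis(minmax_normalize(E$E_mean), minmax_normalize(C$C), E$d)
```

A shell entry point ships in `exec/`:

```sh
manaim run  --d 4 --alpha 3 --seed 7 --out run.csv
manaim grid --replicates 20 --out results/
manaim fig1 --variant c --seed 7          # three-virus co-injection run
```

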