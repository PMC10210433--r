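---
title: "Modelling plasmid-mediated cooperation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling plasmid-mediated cooperation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidcoop)
```

## The question

Conjugative plasmids let genes jump between bacterial cells. Because a
cooperative gene that jumps into a neighbour turns that neighbour into a
cooperator, horizontal gene transfer has been proposed as a road to high
relatedness at plasmid loci — and hence to public-goods cooperation that a
chromosomal gene could never sustain. `plasmidcoop` implements a
patch-structured population-genetic model in which that intuition can be
made quantitative, and in which its limits show up clearly: transfer only
raises relatedness while there are plasmid-free cells left to infect, so a
plasmid cannot be both common and highly related. The package provides the
deterministic recursion, an exact relatedness calculator, equilibrium and
invasion analyses, and a stochastic individual-based simulator used to
validate both.

## Lifecycle and state space

A haploid cell is described by its chromosomal allele (cooperative or not)
and its plasmid state (none, cooperator plasmid, defector plasmid), giving
six genotypes. Plasmids sharing an origin of replication are incompatible: a
bearer can never acquire a second plasmid, so "at most one plasmid" is a
structural constraint, not an approximation.

Each discrete generation:

1. **Founding.** The (infinite) population is divided into patches, each
   founded by `N` cells drawn independently from the global genotype pool.
2. **Clonal growth.** Patches grow to a large size; each founder lineage
   holds exactly a `1/N` share (growth contributes neither drift nor
   selection).
3. **Transfer.** Every cell pairs with a uniformly chosen patch member. If a
   plasmid-free cell is paired with a bearer it acquires the partner's
   plasmid with probability `beta`. Bearer–bearer and free–free pairs are
   unchanged, and newly infected cells do not retransmit within the
   generation. In the infinite-patch limit this is mass action: the free
   frequency on each chromosomal background shrinks by the factor
   `1 - beta * P` (with `P` the bearer frequency) and conversions are
   allocated across plasmid types in proportion to their patch frequency.
4. **Public goods and survival.** Cells carrying a cooperation gene (on
   chromosome, plasmid, or both) produce a public good at cost `C_G`, paid
   once even under redundant carriage — production, not gene count, is
   costly. The summed benefit is shared by the whole patch, including the
   producer, so fitness is `w = 1 + B * g - C_G [cooperator] - C_C [bearer]`
   with `g` the post-transfer cooperator fraction of the patch. Survival is
   proportional to `w`; next-generation frequencies are fitness-weighted
   expectations normalised by the population mean fitness.
5. **Segregation loss.** Bearers lose their plasmid with probability `s`.
6. **Mutation.** Cooperator plasmids become defectors with probability `mu`
   (default 0; defector pressure is normally represented by seeding
   defectors explicitly, which keeps the all-or-nothing cooperativeness
   result exact).
7. **Dispersal.** Complete global mixing; competition is global, so there is
   no local-competition discount on the shared benefit.

The event order above is fixed; `generation_step()` implements one full
cycle, and since the expectation over patches only involves genotypes at
positive frequency, the multinomial enumeration
(`enumerate_patch_compositions()`) is restricted to the active genotypes —
mathematically exact, because absent genotypes can only be created by loss,
transfer, or mutation from present ones, which the step handles globally.

Because the benefit is shared with the producer itself, a chromosomal
cooperation allele spreads exactly when `(1/N) * B > C_G`: the familiar
whole-group Hamilton rule with chromosomal relatedness `1/N`. This anchor
is tested (`chromosomal cooperation fixes when B/N exceeds C_G`).

## Plasmid relatedness

`plasmid_relatedness()` computes whole-group relatedness at the plasmid
locus at the moment the public good is produced, i.e. after transfer. Two
observations pin the definition down.

First, what matters for the evolution of plasmid-borne cooperation is
competition between cooperator and defector plasmids, which are
incompatible and therefore never co-resident: a rare variant plasmid *is*
a lineage. Second, transfer is type-blind — in a patch with free-cell
frequency `f0`, every plasmid lineage present is amplified by the same
factor `T = 1 + beta * f0` during the transfer round.

We therefore define plasmid relatedness as the copy-weighted expected patch
share of a focal plasmid lineage at the time of social action. A focal
plasmid founder holds a `1/N` lineage share amplified to `T/N`, and the
focal copy is sampled with weight `T`, so with the `N - 1` co-founders drawn
multinomially from the population,

```
R_plas = E[T^2] / (N * E[T]),      T = 1 + beta * f0 .
```

The package evaluates the expectation by exact enumeration over the
co-founder compositions. The definition earns its keep on every limit the
model imposes:

* `beta = 0` gives `T = 1` and `R_plas = 1/N`: an untransferred plasmid is
  inherited exactly like a chromosomal locus.
* At total plasmid fixation there are no free cells, `T = 1`, and
  `R_plas = 1/N` from *any* direction of approach — including
  `p_C -> 1` with no defectors present.
* `1/N <= R_plas <= 1` always, with the rare-plasmid ceiling
  `(1 + beta (N-1)/N) / N`.
* `R_plas` is strictly decreasing in total plasmid frequency (fewer free
  cells), increasing in `beta`, and depends on the cooperator/defector
  split only through the total — which is why adding defectors weakly
  lowers it at fixed `p_C`.
* Linearising the recursion around a single-plasmid-type equilibrium shows
  that a rare incompatible variant differing only in whether it carries the
  cooperation gene grows exactly when its side of
  `R_plas * B` vs `C_G` is the favourable one. The derivation is three
  lines: focal-plasmid patches (one focal founder, `N - 1` multinomial
  co-founders) have the same distribution of `T` for both types, cooperator
  output adds `B * T/N` per copy through its own patch share of the benefit
  and subtracts `C_G`, and weighting by copy number `T` gives the threshold
  `B * E[T^2] / (N E[T]) = C_G`.

A natural-looking alternative — the F\_ST-style variance ratio
`Var(q) / (E[q](1 - E[q]))` over post-transfer patch allele frequencies —
does **not** satisfy the second and fifth properties: near `p_C = 1` it
tends to `1/N - beta (N-1)/N^2` rather than `1/N`, and its Hamilton
threshold misclassifies equilibria that sit close to the boundary. The
variance form conflates the lineage structure that selection acts on
(incompatible plasmids compete as lineages) with allelic variance across
patches; the lineage form is the one the dynamics obey, which is why the
package uses it and why the simulator estimates the same quantity by direct
lineage tracking (`estimate_relatedness()`: the copy-weighted mean
own-lineage patch share after a transfer round).

The realized transfer rate `beta * ((N-1)/N) * (1 - p_total)` is the mean
lineage amplification minus one, `E[T] - 1`: transfer opportunity falls
linearly with plasmid frequency and vanishes at fixation. This identity is
tested.

## Equilibria, invasion, and the sweep protocol

`iterate_to_equilibrium()` runs the recursion until the L-infinity
frequency change stays below `tol` for 50 consecutive generations.
Defaults, chosen once for the package's analyses:

| parameter | default | rationale |
|---|---|---|
| `tol` | `1e-10` | far below any frequency of interest; the 50-generation persistence requirement protects against slow transients pausing near a ghost equilibrium |
| `max_gen` | `2e5` | enough for the slowest clean cells of the standard plane; cells still moving are flagged `not-converged`, never an error |
| seeding | `p_C = p_D = 1e-3` | small enough to start in the rare-invader regime, large enough to stay well above the clamping threshold |
| clamp | `1e-15` | frequencies below it are set to 0 and the state renormalised; a deterministic frequency twenty orders below seeding is numerical residue, and clamping lets losing types reach exactly 0 |

`sweep_equilibria()` applies the standard protocol over a `beta` x `s`
grid (default 21 x 21 on `[0,1]^2`) with the chromosome fixed
noncooperative, classifies each equilibrium (cooperativeness
`p_C*/(p_C* + p_D*)`, cooperator frequency = cooperativeness x total
frequency), evaluates `R_plas` at the equilibrium, and challenges each
converged cell by re-invasion of whichever plasmid type is absent
(`invasion_test()`, 200 generations from `eps = 1e-6`) — maintenance, not
just invasion.

Cells with `|R_plas* x B - C_G| < 1e-3` are flagged `near-boundary` rather
than forced into the 0/1 classification: on the threshold line cooperator
and defector plasmids are selectively equivalent, the recursion converges
onto a line of mixed equilibria, and any binary label would be an artefact
of the tolerance. On the standard plane (`N = 20`, `C_C = 0.2`,
`C_G = 0.1`, `B = 1.435`) 9 of 441 cells are flagged; every clean cell with
persisting plasmids is within `1e-6` of cooperativeness 0 or 1, on the side
the Hamilton check predicts.

`hamilton_check()` uses the strict inequality `R_plas* x B > C_G`; exact
equality is classified as "not favoured" and flagged near-boundary.

`frequency_dependence_profile()` reports the one-generation per-capita
growth factor of total plasmid frequency along a frequency grid. Its
default is a pure *defector* profile: for a cost-only plasmid the
transfer/loss/carriage forces are isolated and the profile is strictly
non-increasing — selection on plasmids is negatively frequency-dependent
because rarity is what supplies free hosts. For pure cooperator plasmids
the shared-benefit feedback adds a slight initial rise at very low
frequency before the same decline takes over; the package exposes
`coop_share` so both can be inspected.

## The individual-based simulator

`run_ibs()` is a finite-population implementation of the identical
lifecycle and serves as the package's Monte-Carlo oracle; it is first-class,
tested code, not a fixture. Finite-size choices:

* patches hold `patch_size` cells at pairing time (a multiple of `N`, even,
  default the smallest such value at least 64), so founder lineages have
  exact `1/N` shares;
* pairing is a uniform random perfect matching, which converges to mass
  action as `patch_size` grows; the residual discrepancy is `O(1/patch_size)`;
* survival and dispersal are one fitness-proportional multinomial draw of
  the next founder pool from the whole population;
* loss and mutation are applied per founder, equivalent in distribution to
  applying them before dispersal;
* everything is reproducible from a single integer seed.

The validation tests compare (i) recursion trajectories against
replicate-averaged simulation trajectories and (ii) enumerated relatedness
against the lineage-tracking estimator, both within three Monte-Carlo
standard errors. Problem sizes were fixed in advance at desk scale: the
trajectory check uses 8 replicates of 600 patches of 400 cells over 25
generations on the cooperative example cell (`beta = 0.95`, `s = 0.3`),
compared on the log scale where the multiplicative growth noise is closest
to Gaussian; the relatedness check uses 8 replicates of 250 patches of
1024 cells over a `(p, beta, N)` grid. The patch sizes are deliberately
large so the `O(1/patch_size)` matching bias sits well inside the
Monte-Carlo band.

What the simulator does *not* emulate: real plasmid biology with variable
copy number, transitive conjugation chains within a generation, spatial
structure beyond the patch, chromosomal mutation, or environmental
fluctuation. Agreement between recursion and simulation therefore validates
the mathematics of this lifecycle, not the fidelity of the lifecycle to any
particular organism.

## Headline behaviour

On the standard plane the package reproduces, by computation:

* plasmids that invade with `s = 0` sweep to total fixation, where
  `R_plas = 1/N` — the relatedness floor of the plane (0.05 at `N = 20`);
* equilibrium cooperativeness is bang-bang at the Hamilton threshold;
* the cooperator frequency (cooperativeness x frequency) peaks at
  intermediate `s` and high `beta` and stays far below fixation
  (maximum about 0.50 at `beta = 1`, `s = 0.3`): high relatedness needs
  fast loss, high frequency needs slow loss, and no cell gets both.

## Known limitations

* The deterministic model is infinite-population; finite-population effects
  live only in the simulator.
* No chromosomal suppression of plasmid traits, no plasmid–chromosome arms
  race, and no suppressor loci: the model's cooperation levels are an upper
  bound in that respect.
* Equilibrium analyses assume a constant environment; nonequilibrium
  questions can be explored only as fixed-length runs of
  `run_recursion()`.
* The near-boundary flag is a numerical honesty device, not a biological
  prediction; on the threshold line the model genuinely has no preference
  between plasmid types.
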