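---
title: "Switchback DNA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switchback DNA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchbackdna)
```

## The pairing model

Switchback DNA is a two-strand structure in which both strands run
parallel overall while pairing locally as antiparallel B-DNA, switching
helices after every half-turn. The modular unit is the **half-turn
domain**: six base pairs of B-DNA. For a strand partitioned 5'→3' into
domains $d_1 d_2 \dots d_k$, the package distinguishes

* the **duplex complement** $\mathrm{rc}(d_k)\cdots\mathrm{rc}(d_1)$
  (ordinary reverse complement), and
* the **switchback complement** $\mathrm{rc}(d_1)\cdots\mathrm{rc}(d_k)$
  (each domain reverse-complemented in place).

The two operators are involutions and are conjugate: the switchback
complement equals the duplex complement with domain order reversed. A
strand whose domains are all reverse-complement palindromes is its own
switchback complement and forms a homodimer; its duplex complement is
then again domain-palindromic, which is why such designs always come in
self-pairing pairs.

**Pairing register.** Domain $i$ of one strand pairs domain $i$ of the
other (5' ends co-located). This is the register implied by
fluorophore/quencher proximity in parallel-oriented constructs. The
index-reversed register is exposed as an option
(`switchback_complement(..., register = "reversed")`), where the operator
degenerates to the duplex complement; it is not the default. For 3- and
4-domain layouts the index-matched register is assumed to generalize
unchanged — the package applies it uniformly and documents the
assumption here rather than warning at every call. Layouts beyond 4
domains are accepted with an aggregation caveat message, since larger
switchback stacks tend to aggregate.

**Input discipline.** Sequences are 5'→3', canonicalized to uppercase;
IUPAC ambiguity codes are rejected rather than expanded, because the
complement operators are only defined on fully specified sequences. A
core that is not an exact multiple of the domain length is an error, not
a truncation — partial domains never pair in this model. Terminal caps
(typically single thymines, used to prevent blunt-end aggregation) are
declared in the layout, never pair, and are re-attached to computed
complements by default (`keep_caps = FALSE` yields bare cores).

**Mismatch variants.** The canonical stability probe mutates mid-domain
positions: in-domain position $\lceil L/2\rceil$ (position 3 of 6), away
from the strand-switch points. The fixed transversion map A↔C, G↔T makes
the series deterministic and guarantees each mutation breaks its
Watson–Crick pair. Variants: `1mm` (one mutation, domain 1), `2mm-adj`
(two adjacent, domain 1), `2mm-sep` (one each in domains 1 and 2).

## Repeat screening

A repeat tract is **switchback-compatible** when its switchback and
duplex complements are identical, so that a single partner strand serves
either geometry. For a pure tract this is equivalent to the tract's
*smallest period* dividing the domain length. We state the rule in terms
of the smallest period rather than the literal unit length: a tract
written with the non-primitive unit `ACAC` has period 2, which divides 6,
so it is compatible even though 4 does not divide 6. The test suite
verifies the equivalence exhaustively for all units of length 1–6 over
all rotation phases against direct complement comparison.

The genome scanner detects maximal tandem tracts by the self-offset
criterion (runs of `seq[i] == seq[i+u]` of length at least
`(min_copies−1)·u`). Resolution policy, applied deterministically:
report the smallest period per locus (a `CAGCAG` tract is a CAG tract);
overlapping candidates of different unit lengths keep the longer tract,
ties broken toward the smaller unit. Copies may be fractional at tract
edges; compatibility of a locus is evaluated on its repeat unit expanded
to one layout core (the largest in-frame window of a pure tract), with
any partial trailing domain ignored. Exact tandem tracts are
strand-symmetric — the reverse complement of a tract is a tandem tract of
the complementary unit over the same interval — so the forward scan
already finds every locus; `strand = "both"` maps reverse-scan
coordinates back and deduplicates. BED output is 0-based half-open; the
TSV sidecar is 1-based inclusive and says so in its header.

## Thermodynamic model

Duplex predictions use the standard unified nearest-neighbor set
(shipped as `inst/extdata/nn_unified.tsv`, provenance `unified-1998`,
1 M NaCl reference): $\Delta H$ and $\Delta S$ are sums over the $L-1$
dinucleotide stacks plus terminal initiation terms, with the symmetry
correction and $C_T/1$ (vs $C_T/4$) factor for self-complementary
sequences, and the per-phosphate entropic salt correction
$0.368\,(L-1)\ln[\mathrm{Na}^+_\mathrm{eq}]$. Divalent ions enter through
the empirical equivalence
$[\mathrm{Na}^+_\mathrm{eq}] = [\mathrm{mono}] + 120\sqrt{[\mathrm{Mg}^{2+}]\,(\mathrm{mM})}$ (mM).

The **switchback correction** removes, per inter-domain junction
($k-1$ of them), the enthalpy and entropy of the one base stack that the
strand switch eliminates, and adds a per-junction free-energy penalty
$\Delta G_J$:

$$\Delta G_\mathrm{sb} = \Delta G_\mathrm{dup}
  - \sum_{j\in\mathrm{junctions}} \Delta G^\mathrm{stack}_j
  + (k-1)\,\Delta G_J.$$

Because eliminated stacks are stabilizing and $\Delta G_J \ge 0$ in
practice, the switchback is never predicted more stable than its duplex —
matching the measured ordering. $\Delta G_J$ is calibrated from an
observed free-energy pair:
`calibrate_junction_penalty(-12.23, -10.26, seq)` returns the penalty
that makes the model's gap equal the observed total junction cost of
1.97 kcal/mol, exactly, by construction. The shipped default penalty
uses that calibration with the *mean* stack free energy standing in for
the eliminated stack, because the characterized construct's sequence is
not published; recalibrating for a known sequence is one call.

**Bookkeeping.** The penalty is applied entropically
($\Delta H$ unchanged; $\Delta S \mathrel{-}= \Delta G_J\cdot 1000/T$),
consistent with the observation that the switchback's enthalpy deficit
is accounted for by lost stacking while its entropic penalty is smaller
than the duplex's. How the junction cost truly splits between $\Delta H$
and $\Delta S$ is not known; `bookkeeping = "enthalpic"` switches the
convention. Note the measured duplex pair (−12.23 kcal/mol, Kd 1.3 nM)
is internally inconsistent by ~0.1 kcal/mol under $\Delta G = RT\ln K_d$
at 25 °C; the package treats $\Delta G$ as canonical for calibration.

**Magnesium.** Switchback assembly requires ≳10 mM Mg²⁺. Only the
threshold is known, so predictions at lower Mg²⁺ are *flagged
unreliable* (`reliable = FALSE`) rather than corrected.

**Mismatch energetics** use a coarse per-domain rule rather than full NN
mismatch tables, because the available evidence is domain-level: one
internal mismatch costs a fixed increment (default 1.5 kcal/mol, of the
order of single internal-mismatch destabilization); a domain with two or
more internal mismatches counts as melted and loses its stacks entirely.
This reproduces the observed stability order
control > 1mm > 2mm-sep > 2mm-adj whenever a domain is worth more than
two increments, which holds for all 6-bp domains under the unified table.

**Conventions.** Temperatures are °C at the interface, K internally;
$R = 1.987\times10^{-3}$ kcal mol⁻¹ K⁻¹; $K_d = \exp(\Delta G/RT)$ in M.
Default condition: 25 °C, 8 µM total strand, 50 mM monovalent,
12.5 mM Mg²⁺ (a typical annealing buffer).

**Melt curves** are fit to the four-parameter Boltzmann sigmoid
$A(T) = A_1 + (A_2-A_1)/(1+e^{(T_m-T)/w})$ by Levenberg–Marquardt least
squares (starting values: data extremes, half-height temperature, width
2 °C). $T_m$ is the inflection, where the curve equals the baseline
midpoint. Default fit window 15–65 °C (switchback transitions); duplex
curves are typically fit over 15–90 °C. Flat curves, windows with fewer
than 8 points, or solver failure return `converged = FALSE` with
diagnostics instead of an error.

## Competition and displacement equilibria

Two models predict species populations in strand mixtures.

The **absolute-preference** model is the limit observed in competition
experiments: duplexes form first (at the minimum of available partners;
a strand facing several duplex partners splits proportionally to their
availability — a documented choice that does not arise in the
characterized pools), then heterodimeric switchbacks, then switchback
homodimers; leftovers stay free. The hetero-switchback tier is our
extension of the stated rule (duplexes, then self-pairing): without it a
pool containing only a strand and its switchback complement — a complex
that demonstrably assembles — would be left unpaired. Under this model
the duplex yield at ratio $r:(10-r)$ is $2\min(r,10-r)/10$ of total
strands, the titration maximum sits at 1:1, and displacement by the
duplex complement is complete at 1.25 equivalents.

The **mass-action** model solves the coupled dimerization equilibria
$[S_iS_j]=K_{ij}[S_i][S_j]$ by damped Newton iteration on free-monomer
concentrations: deterministic initialization at `free = total/2`, full
Newton steps halved (factor 0.5) whenever an iterate would go negative
or fail to reduce the residual, 200-iteration cap, convergence at
relative mass-conservation residual below $10^{-12}$ (tighter than the
$10^{-10}$ asserted on outputs). Association constants default to the
NN model's $\exp(-\Delta G/RT)$, with the **statistical factor 2** on
hetero species relative to homodimers so that equal per-contact
energetics reproduce 1:2:1 random-pairing statistics — a convention the
experimental record is silent on, chosen to make the combinatorial limit
exact.

Both models are thermodynamic (path-independent): a displacement
endpoint equals the co-annealed partition at the same totals, which is
what makes toehold-less displacement by structural preference
well-defined without kinetics. Species enumeration uses a canonical
(sorted) strand order, so permuting the order of strand addition gives
bit-identical output. Kinetic simulation is out of scope by design: the
displacement observations justify thermodynamic control at assay
timescales.

## Construct design

`design_switchback_set()` emits X (core), Y (switchback complement) and
Z (duplex complement) with terminal-T caps, re-validates the intended
pairings, reports core GC content, warns when the core is itself
homodimeric, and notes when Y and Z coincide (repeat cores).

`build_dx_reporter()` models the double-crossover (DX) scaffold reporter
at the sequence level: two helices, each covered by one continuous
strand and two crossover strands exchanging helices at two crossover
points; both interacting regions extend 5'→3' off the scaffold behind a
TT linker, region 1 carrying a 3' quencher (Iowa Black) and region 2 a
3' fluorophore (fluorescein). The scaffold strand sequences are
**synthetic stand-ins** (the characterized scaffold's sequences are not
published); only the crossover topology and the complementarity map are
reproduced, and the segments were chosen free of ≥6 nt complementarity
to the CAG/CTG repeat regions. The predicted interaction class is
computed per domain in the index-matched register, counting a domain
only on perfect complementarity — partial-domain scoring is out of scope
because the characterized constructs are exact: (CTG)₄ → `full`,
(CTG)₂T₆ → `one-domain`, T₁₂ → `none`.

`crosstalk_check()` reports, for every strand pair including self-pairs,
the longest contiguous complementary run in the duplex sense (longest
common substring against the reverse complement) and the switchback
sense (against the unreversed complement, i.e. parallel index-aligned
contact), flagging non-intended pairs at ≥6 nt — one full domain, the
shortest stretch that could nucleate a stable half-turn.

## Synthetic data

`generate_fixtures(seed)` produces every input the package is exercised
with; identical seeds give bit-identical bundles, and each artifact is
validated by its consuming module before being returned. It emulates:

* **homodimer cores** — random reverse-complement-palindromic 6-mers,
  one per domain. Full-palindrome cores (whose duplex complement is the
  core itself) are redrawn, since the homodimer design requires a
  distinct duplex-complement strand;
* **heterodimer cores** at an exact GC target (default 2/3, i.e. 8 of
  12 nt, matching the 67% GC interacting-region design);
* a **synthetic genome** (default 10 kb uniform-random) with planted
  (CAG)₂₀ and (CCTG)₁₅ tracts — one compatible, one incompatible;
* **melt curves** (default Tm 55 °C, width 2 °C, Gaussian noise
  σ = 0.01 on a normalized 15–90 °C sweep at 0.5 °C steps, matching
  typical instrument sampling and noise);
* the **toy NN table** (every stack exactly −1 kcal/mol, nothing else),
  which turns free energies into stack counting for didactic checks;
* an example homodimer **strand pool** at 10 µM total.

What the generator does *not* emulate: base-composition bias, sequencing
errors, interrupted or nested repeats, chromatin or supercoiling
context, and instrument baseline drift. Passing tests therefore
demonstrate algorithmic correctness on clean, fully specified inputs —
not robustness to the messiness of real genomes or real melt data.

## Problem sizes and numerical choices

The shipped test suite runs the property checks at these sizes, chosen
to keep a full run in minutes on one CPU while still being exhaustive
where exhaustiveness is the point: involution/conjugation laws on 10⁴
random 12-mers; the homodimer theorem on all 64² two-domain palindromic
cores; the divisibility theorem on all 5,460 units of length 1–6 over
all phases; classifier-vs-oracle equivalence on all 4⁶ doubled 3-mer
pairs; scanner-vs-brute-force equivalence on 10 kb genomes; equilibrium
limit checks on five seeded random pools.

Degenerate inputs are handled explicitly rather than by accident: odd
domain lengths make self-complementarity impossible (reported with the
reason), empty motif tables screen to empty outputs, flat melt curves
flag non-convergence, zero association constants leave all strands free,
and an all-zero pool partitions trivially.

## Known limitations

* The NN junction model treats every junction identically; any
  sequence dependence of the junction cost beyond the eliminated stack
  is absorbed into the single calibrated penalty.
* Mismatch thermodynamics are domain-coarse by design; they order
  variants correctly but are not quantitative per-mismatch predictions.
* The Mg²⁺ requirement is a validity flag, not a correction — no
  divalent thermodynamic model is attempted beyond the monovalent
  equivalence used for duplex Tm.
* Competition models ignore kinetics, gel-staining efficiency and
  higher-order aggregates; species are monomers and dimers only.
* The DX scaffold is a sequence-level topology; no 3D geometry, strand
  tension or crossover strain is modelled.
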