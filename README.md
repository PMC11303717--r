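# switchbackdna

Design and analysis toolkit for **switchback DNA** — a globally left-handed,
parallel-stranded two-strand structure assembled from laterally stacked
right-handed B-DNA half-turns. The two strands run parallel overall and
switch helices after every half-turn **domain** (six base pairs), so a
strand's partner in the switchback sense is *not* its reverse complement:
it is the concatenation, in original domain order, of the reverse
complement of each domain individually.

The package is aimed at DNA nanotechnologists designing switchback-based
motifs and reporters, and at anyone screening short tandem repeats (STRs)
for the alternate-structure hypothesis: repeat tracts whose unit period
divides the half-turn length have *identical* switchback and duplex
complements, so a single partner strand can form either structure.

## What it computes

For a strand `S` partitioned into domains `d1 d2 … dk` (5'→3'):

* **duplex complement** `rc(S) = rc(dk)…rc(d1)` — the partner in a
  conventional antiparallel duplex;
* **switchback complement** `sbc(S) = rc(d1)…rc(dk)` — the partner in the
  parallel switchback structure (domain *i* pairs domain *i*, 5' ends
  co-located);
* **pair classification** (`duplex` / `switchback` / `both` / `none`) with
  per-domain match counts and mismatch positions, plus generation of the
  canonical mid-domain mismatch series (control, 1mm, 2mm-adj, 2mm-sep);
* **nearest-neighbor thermodynamics**: standard unified stack table for
  the duplex, and a switchback model that removes the one eliminated base
  stack per inter-domain junction and adds a per-junction penalty ΔG_J,
  calibrated from measured free energies via
  `ΔΔG = ΔG_switchback − ΔG_duplex` (1.97 kcal/mol for the characterized
  two-domain construct, from the ITC pair −12.23 / −10.26 kcal/mol);
* **ΔG ↔ Kd conversion** (`ΔG = RT ln Kd`), Tm from the two-state formula,
  and four-parameter Boltzmann melt-curve fitting;
* **competition and toehold-less displacement**: equilibrium species
  partitions for strand pools under an absolute structural-preference
  limit and a mass-action model (damped Newton solver), with titration /
  displacement series;
* **STR screening**: motif tables and genome-scale FASTA scans (BED6 +
  TSV output) annotated with switchback compatibility;
* **construct design**: X/Y/Z switchback strand sets, a DX-scaffold
  fluorophore/quencher reporter with parallel interacting regions, a
  crosstalk checker, and synthesis order-sheet export.

## Worked example

```r
library(switchbackdna)

# the two complements differ in general ...
switchback_complement("AAAAAACCCCCC")   # "TTTTTTGGGGGG"
duplex_complement("AAAAAACCCCCC")       # "GGGGGGTTTTTT"

# ... but coincide for CAG repeats (period 3 divides the 6-bp half-turn),
# so one CTG strand serves both geometries:
classify_pair("CAGCAGCAGCAG", "CTGCTGCTGCTG")
#> <pairing_report> relationship: both
#>   switchback per-domain matches: 6 6 (of 6)
#>   duplex matches: 12 of 12

# free energy from the measured switchback Kd (30.7 nM, 25 C)
free_energy_kd_convert(30.7e-9, "kd_to_dG")   # -10.24835 kcal/mol

# calibrate the junction penalty from the measured dG pair and predict
cal <- calibrate_junction_penalty(-12.23, -10.26, "CAGCAGCAGCAG")
cal$junction_cost                             # 1.97 kcal/mol
nn_duplex_thermo("CAGCAGCAGCAG")
#> <thermo_result> duplex: dH -94.40 kcal/mol, dS -256.62 cal/(mol K),
#>   dG(25.0 C) -17.89 kcal/mol, Tm 60.8 C, Kd 7.69e-14 M (0 junctions)
switchback_thermo("CAGCAGCAGCAG", penalty = cal$penalty)
#> <thermo_result> switchback: dH -84.60 kcal/mol, dS -230.36 cal/(mol K),
#>   dG(25.0 C) -15.92 kcal/mol, Tm 56.8 C, Kd 2.14e-12 M (1 junction)
```

The calibrated free-energy gap between the two predictions is exactly the
observed 1.97 kcal/mol junction cost; the switchback's enthalpy deficit is
the eliminated junction stack, and the remaining cost is booked
entropically.

A repeat motif that fails the divisibility rule is incompatible:

```r
r <- is_switchback_compatible("CCTG")
r$switchback_compatible   # FALSE
r$reason
#> "domain length 6 is not a multiple of the tract's smallest period 4 (unit CCTG)"
```

## Command line

A thin CLI over the same functions ships at `inst/cli/sbk.R`:

```sh
Rscript inst/cli/sbk.R complement --sense switchback --input AAAAAACCCCCC
Rscript inst/cli/sbk.R screen --motifs inst/extdata/repeat_motifs.tsv
Rscript inst/cli/sbk.R scan --fasta genome.fa --min-copies 5 --unit-lengths 1-6
Rscript inst/cli/sbk.R thermo --input CAGCAGCAGCAG --structure switchback
Rscript inst/cli/sbk.R fixtures --seed 7 --out-dir fixtures
```

## Scope notes

The package models sequence-level pairing and two-state thermodynamics.
It does not generate 3D coordinates, simulate kinetics or gel staining,
or predict fluorescence intensities; helical handedness is descriptive
metadata. See the methods vignette (`vignettes/switchback-methods.Rmd`)
for the model, its assumptions, parameter defaults, and limitations.
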