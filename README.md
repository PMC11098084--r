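# chrompair

Brownian-dynamics simulation of homologous chromosome pairing by
**nonspecific button barcodes**.

## The problem

In *Drosophila* and many other systems, homologous chromosomes find and pair
with each other in somatic nuclei without double-strand breaks or any
sequence-level homology search. A long-standing puzzle is how pairing can be
*selective* if the adhesive contacts themselves are not: an adhesion site
("button") that binds any other button equally well carries no information
about chromosome identity, and uniformly spaced nonspecific buttons pair
correct and incorrect partners alike.

`chrompair` implements and explores the button-barcode answer: encode identity
in the **spacing pattern** of the buttons. Aligning two chains with identical
spacing patterns costs no elastic energy; aligning chains whose patterns
differ forces the chromatin polymer to stretch or bend. For a worm-like chain
of persistence length Lp, pairing buttons whose genomic spacings differ by Δ
costs on the order of ½ k_eff Δ² (several kBT per button pair), so correct
pairing is thermodynamically favoured even though every individual contact is
molecularly identical — the same way an industrial barcode encodes digits
purely in the widths of its bars.

The package is aimed at quantitative biologists studying somatic (and
recombination-independent meiotic) homolog pairing, nuclear architecture and
chromosome mechanics.

## The model

* Chromosome arm = bead–spring worm-like chain: stretch energy
  ½k_s(d−d₀)² per bond, bending energy ½k_bend|xᵢ − midpoint(xᵢ₋₁,xᵢ₊₁)|² per
  interior bead (persistence length ≈ k_bend/4 in bond lengths).
* Spherical nucleus (harmonic wall), Rabl organisation: each centromere
  (bead 0) is tethered to a spherical cap of chord radius `rabl_patch_radius`
  around the +z pole; cap radius 2R removes the constraint.
* Overdamped Langevin (Euler–Maruyama) dynamics:
  x ← x + (dt/γ)F + √(2 kBT dt/γ) η.
* Reversible nonspecific adhesion: per iteration every bond breaks with
  probability `p_unpair`; free buttons within `capture_radius` then bond
  greedily nearest-first, one bond per button, cis contacts included, with no
  specificity of any kind.
* Fidelity = fraction of buttons bonded to the correct homolog
  (`chromosome` mode), or to the same-index node on it (`locus` mode);
  unpaired and cis-bonded buttons count as incorrect. Chance floor for
  `n` homolog pairs is 1/(2n).

All quantities are in simulation units: length unit = rest bond length
(≈0.2 µm chromatin), kBT = 1, friction = 1. See the methods vignette
(`vignettes/button-barcode-model.Rmd`) for parameter rationale, numerical
stability analysis and design decisions.

## Worked example: an industrial barcode on a chromosome

Encode the digits 0 and 1 in code 2 of 5 (five gaps per digit, exactly two
wide; wide gap = 6 nodes, narrow = 2), give one code to each homolog pair,
and simulate:

```r
library(chrompair)

encode_2of5(0)
#> [1] 2 2 6 6 2

code0 <- gaps_to_barcode(encode_2of5(0), arm_length = 28)
code1 <- gaps_to_barcode(encode_2of5(1), arm_length = 28)
code0
#> <barcode> 6 buttons on 28 nodes: 0,2,4,10,16,18
code1
#> <barcode> 6 buttons on 28 nodes: 0,6,8,10,12,18

cfg  <- sim_config(seed = 42)        # 300,000 iterations, strong Rabl, p_unpair 0.8
traj <- run_simulation(cfg, barcodes = list(code0, code1))

final_fidelity(traj, "chromosome")
#> [1] 0.9489796
time_to_fraction_paired(traj, 0.9)
#> [1] 47000
chance_baseline(2)
#> [1] 0.25
```

With four chains in the nucleus, random association would pair only 25% of
buttons correctly; the two barcodes reach ~95% correct pairing in this run,
crossing 90% after 47,000 iterations (≈10 min of nuclear time at the
documented conversion of one 300k-step run ≈ 1 h). Ensemble means over many
seeds settle near 0.89 (`run_ensemble()` reports per-run values, so SEMs are
recomputable).

The mechanical origin of the selectivity is directly computable: relaxing two
five-button tracts with 3- vs 4-node spacing into enforced (incorrect)
alignment costs

```r
de <- discrimination_energy(cfg, barcode(3 * (0:4), 28), barcode(4 * (0:4), 28))
as.numeric(de)
#> [1] 8.633482
```

— several kBT of chain deformation, and exactly 0 for identical codes.

Figure-style experiments (reversibility scan, Rabl ablation, random-code
beeswarms, multi-chromosome scaling, shifts and translocations) are one call
each:

```r
sc <- run_scenario("fig3c", n_runs = 30, base_seed = 1, out_dir = "out/fig3c")
sc$summary   # mean/SEM/median fidelity per p_unpair grid point
```

A thin command-line front end is installed as `exec/chrompair`
(`simulate`, `scenario`, `analyze`, `barcode encode25`).

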