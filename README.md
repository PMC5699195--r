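# pgpflux

Mass-action kinetic modelling of P-glycoprotein (P-gp) mediated paclitaxel
efflux and its inhibition by tyrosine kinase inhibitors (TKIs).

## The problem

P-gp is an ATP-driven membrane pump that exports chemotherapy drugs from
tumor cells; overexpression (~300,000 copies/cell in resistant lines versus
~300 in sensitive ones) makes paclitaxel therapy fail. TKIs such as
nilotinib, imatinib and dasatinib can restore paclitaxel accumulation in two
ways: by competing with paclitaxel for the transmembrane substrate-binding
domain (SBD), and by competing with ATP for the cytoplasmic
nucleotide-binding domain (NBD). Which mechanism dominates — and whether a
given TKI is mostly an inhibitor or mostly just another substrate to be
pumped out — depends on its two binding affinities and its membrane
partition coefficient. This package is for modellers who want those
mechanisms separated, quantified and stress-tested.

## The model

A stiff mass-action ODE system of 16 variables: two drugs × three
compartments (extracellular, membrane, cytosol), cytosolic ATP, and nine
pump states — the lattice (SBD ∈ {∅, paclitaxel, TKI}) × (NBD ∈ {∅, ATP,
TKI}) governed by four dissociation constants

    Kd_P = exp(ΔG_P/RT),  Kd_N,  Kd_A = 11.6 µM,  Kd_I (fitted)

with membrane-phase affinities `ΔG_mem = ΔG_aq + RT·ln(PC)`. Drugs enter
passively (aqueous→membrane `k_p`, back `k_p/PC`, so membrane/aqueous
equilibrates at the partition coefficient PC); only SBD-loaded, ATP-bound
states transport, ejecting the SBD occupant and consuming the ATP. A
twelve-state noncompetitive variant (independent SBD sub-sites) backs the
fitting of NBD constants from efflux-inhibition dose-response data by
grid-search RMSE minimisation. A synthetic calcein-assay generator with
known ground truth closes the loop for testing.

No ODE-solver package is assumed: the package ships an L-stable Rosenbrock
(ode23s-type) stepper with analytic Jacobians and a Newton steady-state
polisher (see the methods vignette, `vignettes/pgp-efflux-kinetics.Rmd`).

## Worked example

```r
library(pgpflux)

verify_derivations()
#>                                  quantity      value expected tolerance   ok
#> 1      Kd(ATP@NBD) from -7.0 kcal/mol [uM]  11.616942    11.60     0.050 TRUE
#> 2   membrane affinity nilotinib [kcal/mol]  -4.844563    -4.85     0.010 TRUE
#> 3    membrane affinity imatinib [kcal/mol]  -4.087127    -4.09     0.010 TRUE
#> 4   membrane affinity dasatinib [kcal/mol]  -3.381547    -3.38     0.010 TRUE
#> 5  membrane affinity paclitaxel [kcal/mol]  -5.878695    -5.88     0.010 TRUE
#> 6                 P-gp 300,000 copies [uM] 101.128704   100.00     2.000 TRUE
#> 7                     P-gp 300 copies [uM]   0.101129     0.10     0.002 TRUE

# Resistant cells (P-gp 10 uM) exclude 3 uM paclitaxel almost completely
# (cytosolic level 9.0e-9 M = 0.3% of the 3e-6 M no-pump level); nilotinib
# restores it with increasing dose:
s <- scenario(tki = "nilotinib",
              sweep = list(axis = "tki_ext", values = log_grid(1e-7, 1e-4, 7)))
signif(run_scenario(s)$readout, 4)
#> [1] 9.135e-09 9.443e-09 1.058e-08 1.752e-08 2.916e-06 2.991e-06 2.999e-06
```

Half-restoration doses at the 10 µM pump level reproduce the published
potency order nilotinib (6.9 µM) < imatinib (22 µM) < dasatinib (83 µM).
Mechanism-isolated ATP sweeps locate the crossover where SBD competition
overtakes NBD inhibition: ~54 mM ATP for nilotinib versus ~0.5 mM for
imatinib and dasatinib.

```r
# estimate a nucleotide-site Kd from (synthetic) inhibition data
ds  <- generate_calcein_dataset(generator_spec(2e-9, tki = "nilotinib", seed = 1))
fit <- grid_search_kd(ds)
fit$best_Kd
#> [1] 2.030918e-09
```

## Command line

```sh
Rscript inst/cli/pgpflux demo --out demo_out --seed 1   # from the source tree
pgpflux derive|simulate|fit --config config.json        # installed script
pgpflux verify-paper                                    # printed-value self-test
```

Configs are JSON (unknown keys rejected); outputs are tidy CSV plus a
manifest with the config hash and seed.

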