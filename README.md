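# sipshift

Analysis of DNA stable isotope probing (DNA-SIP) experiments in R: who in
a mixed microbial community assimilates a ¹³C-labeled substrate, when they
start, and how much of the substrate carbon ends up fully mineralized.

DNA-SIP feeds a community the substrate with and without a heavy-isotope
label. Assimilators synthesize heavier DNA, which bands at higher buoyant
density in a CsCl equilibrium gradient. `sipshift` implements the complete
inference chain around that idea, for the classical community readouts:

* **Gradient densitometry** — refractometer readings convert to buoyant
  density via the affine CsCl calibration *d = αn − β* (α = 10.927,
  β = 13.593 at 20 °C); fractions pair across treatments by nearest
  density, and the *heavy* fraction is the one closest to 1.732 g cm⁻³.
* **T-RFLP profiles** — terminal restriction fragment peak tables are
  cleaned (area ≥ 50 units, lengths 20–600 bases), normalized to relative
  abundance per fraction, and aligned across runs by ±1-base binning.
  `predict_trf_length()` digests sequences in silico (Ba27f forward
  primer, *Hha*I, IUPAC-aware) to map fragments back to phylotypes.
* **Labeled-phylotype detection** — for each candidate phylotype (top-10
  T-RFs, or OTUs > 1% in the labeled heavy fraction), the enrichment
  score is the mean relative abundance over the heavy density window
  (d ≥ 1.725 g cm⁻³) in the labeled treatment minus the same mean in the
  density-matched unlabeled fractions; scores ≥ 0.1 flag a phylotype as
  labeled, and per-day reports yield each phylotype's first labeled day.
* **Amplicon OTUs** — mean-quality/length/homopolymer read QC, greedy
  abundance-sorted clustering at 97% identity with deterministic
  tie-breaks, representative = most abundant member.
* **Carbon balance** — Henry's-law headspace conversion, per-vial
  two-phase inventory, 6 C per benzene, and exact partitioning of
  degraded carbon into CH₄ + CO₂ (mineralization), a ≤10% biomass bound,
  and residual intermediates.
* **Synthetic data** — a ground-truthed generator (community with planted
  primer/restriction sites, GC-driven densities, Gaussian banding over 22
  fractions, lognormal peak noise with a detection floor, multinomial
  reads, schedule-calibrated benzene decay) so the whole chain is
  testable without any external data.

## Worked example

Simulate a 12-taxon community in which two taxa (T-RFs 340 and 460)
assimilate the label starting between days 23 and 38, then run the
detection chain:

```r
library(sipshift)

cfg <- sim_config(seed = 42)
com <- sim_community(cfg)

clean <- function(g) bin_trf_lengths(
  lapply(g$profiles, function(p) normalize_profile(filter_peaks(p))), 1)

reports <- lapply(c(23, 38, 64), function(d)
  detect_labeled_trfs(clean(simulate_gradient(com, cfg, d, "labeled")),
                      clean(simulate_gradient(com, cfg, d, "unlabeled"))))
names(reports) <- c(23, 38, 64)

reports[["64"]]
#> SIP shift report: 5 phylotype(s), 2 labeled (threshold 0.1)
#>   phylotype_id enrichment_score is_labeled
#> 1          340      0.294042305       TRUE
#> 2          460      0.429950266       TRUE
#> 3          500     -0.111801298      FALSE
#> 4          420     -0.008957054      FALSE
#> 5          380     -0.004446956      FALSE
```

Exactly the two planted assimilators are flagged: their relative
abundance over the heavy window is ~0.3–0.4 higher in the labeled
treatment, while every unlabeled taxon sits near zero (or negative —
taxon 500 is *displaced* from the heavy fractions by the newly labeled
DNA). Their first labeled day recovers the configured onset window:

```r
first_labeled_day(reports)
#>   phylotype_id first_labeled_day
#> 1          500                NA
#> 2          460                38
#> 3          420                NA
#> 4          380                NA
#> 5          340                38
```

And the gas module closes the carbon balance for the simulated benzene
degradation (schedule: ~0/33/66/100% degraded at days 0/23/38/64):

```r
balance_from_series(simulate_gas(cfg))
#> Carbon balance (umol-C per vial)
#>   degraded:           157.8
#>   CH4-C:               44.2
#>   CO2-C:               69.4
#>   residual:            44.2 (intermediates + biomass)
#>   biomass (max):       15.8
#>   mineralized:          72% (72.0000%)
```

72% of the degraded benzene carbon is recovered as CH₄ + CO₂; the rest is
the biomass allowance plus intermediates still in solution.

An end-to-end run with reports, a first-labeled-day table, a balance and
a reproducibility manifest on disk:

```r
res <- run_sip_analysis(list(seed = 42, out_dir = "sip_run"))
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/sipshift.R` (subcommands `simulate`, `density`, `digest`,
`trflp-clean`, `detect`, `balance`, `run`).

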