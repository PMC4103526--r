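---
title: "Methods: detecting substrate assimilators by DNA-SIP with sipshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting substrate assimilators by DNA-SIP with sipshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipshift)
```

## The problem

DNA stable isotope probing (DNA-SIP) identifies which members of a mixed
microbial community assimilate a particular substrate. A culture is fed the
substrate with a heavy carbon label (^13^C) in one treatment and without it
in a parallel control. Organisms that build biomass from the substrate
synthesize heavier DNA, which bands at a higher buoyant density in a CsCl
equilibrium gradient. Comparing community fingerprints across density
fractions between the two treatments — at several timepoints — reveals who
assimilated the label and when. `sipshift` implements this inference chain
for the classical readouts of the 454-pyrosequencing era: T-RFLP
fingerprints of every fraction, amplicon sequencing of the heavy fractions,
and a headspace gas balance tying the community response to substrate
mineralization. The motivating application is anaerobic benzene degradation
in a methanogenic enrichment culture, where the substrate carbon ends up in
CH~4~, CO~2~, biomass and transient intermediates.

## Gradient densitometry

Fraction densities are not measured directly; a refractometer reading `n`
is converted by the affine calibration

\[ d = \alpha n - \beta, \qquad \alpha = 10.927,\ \beta = 13.593
\ (20\,^\circ\mathrm{C}), \]

the standard constants for CsCl. `density_from_refractive_index()` applies
it; readings outside 1.30–1.50 draw a warning because they are almost
always transcription errors. Fractions are numbered bottom-up (densest
first, the order they leave the tube), but every comparison downstream is
keyed on density, never on fraction number, because two gradients never
fractionate identically.

Two selection rules matter:

* **Heavy fraction** — the fraction closest to a target density, 1.732
  g cm^-3^ by default (the conventional band of ^13^C-labeled bacterial
  DNA). Ties break toward the denser fraction: heavier DNA is the signal
  of interest. An equidistance tolerance of 10^-9^ g cm^-3^ absorbs
  floating-point noise.
* **Cross-treatment pairing** — each labeled-treatment fraction is paired
  with the unlabeled-treatment fraction of the same or closest density
  (`match_fractions()`), with the same dense-side tie-break. The pairing is
  deterministic and order-independent.

## T-RFLP processing

A T-RFLP fingerprint is the set of terminal restriction fragment (T-RF)
lengths released by a restriction enzyme from fluorescently end-labeled
PCR amplicons; fragment length acts as a phylotype identifier.

**Peak cleaning** follows the usual instrument-side conventions, read
literally: peaks with an area *smaller than* 50 arbitrary units are
discarded (an area of exactly 50 survives), and only lengths 20–600 bases
(both ends inclusive) are kept. Both boundaries are arguments to
`filter_peaks()` so either convention can be flipped. Areas are then
normalized to relative abundances within each fraction
(`normalize_profile()`); a fraction whose valid peaks sum to zero area
normalizes to an empty profile with a warning rather than NaNs.

**Cross-run alignment.** Capillary sizing jitters lengths by about a base,
so before profiles are compared, observed lengths are binned by
single-linkage chaining with a ±1-base default tolerance
(`bin_trf_lengths()`); each bin's canonical length is its rounded centroid
and co-binned peaks within one profile sum their areas. Tolerance 0
degrades to exact matching.

**In-silico digestion.** `predict_trf_length()` predicts a sequence's T-RF:
find the forward primer (IUPAC degeneracies in the primer match concrete
template bases, zero mismatches by default), find the first enzyme
recognition site fully downstream of the primer, and report the distance
from the primer's 5' end through the cut, primer included. Only the
forward strand counts, because only the forward primer carries the
fluorophore in the assay this mirrors (Ba27f-FAM with *Hha*I, which cuts
GCG^C). A site straddling the primer's 3' boundary is not honored: it
would imply a fragment shorter than primer-plus-offset, which the sizing
convention cannot produce. Sequences with no primer match or no downstream
site return `NA`.

## Detecting labeled phylotypes

The qualitative observation "this fragment shifted toward the heavy
fractions of the labeled treatment" is formalized as an additive
difference of windowed means. For phylotype *i* with relative abundance
\(a_i(d)\) in the labeled and \(b_i(d)\) in the density-matched unlabeled
fractions,

\[ s_i = \operatorname{mean}_{d \ge d_w} a_i(d) -
         \operatorname{mean}_{d \ge d_w} b_i(d), \]

with the heavy window starting at \(d_w = 1.725\) g cm^-3^. A phylotype is
called labeled when \(s_i \ge 0.1\). Candidates are screened first — the
10 most abundant T-RFs in the labeled treatment's heavy fraction (ties at
the cut keep the shorter fragment), or OTUs above 1% relative abundance
there — because minor peaks carry mostly noise. The report always retains
the underlying abundance curves so users can re-threshold without
recomputing.

Both the window and the threshold are configuration knobs, and the 0.1
default is this package's operational choice, not a community standard.
Two caveats follow directly from the score being a difference of
*relative* abundances:

* It is antisymmetric under swapping treatments, so a depleted phylotype
  scores negative rather than flagging.
* Relative abundances are compositional. When many taxa assimilate label
  simultaneously, they share the heavy window and each one's windowed mean
  shrinks roughly like \(1/N\); with 12 co-labeled taxa the individual
  scores settle near 0.05 and none reach the default threshold, even
  though every score is strictly positive. The score separates *which*
  community members are labeled; it deliberately does not estimate atom
  fraction (that is quantitative SIP, out of scope here).

Time-resolved runs repeat the comparison per sampling day, using the final
day's candidate list on earlier days (the final day has the clearest
signal, and re-screening earlier days with their own top-10 would let
noise choose the candidates). `first_labeled_day()` then reports the
earliest day each phylotype was called.

For amplicon data, the same difference is computed from OTU tables of the
matched heavy fractions. OTU identity across the two independently
clustered tables is established by matching representative sequences at
the clustering identity (97%), never by OTU numbering, which is arbitrary.

## Amplicon processing

Reads are QC-filtered with the era-standard rules: mean Phred quality
≥ 25 (the quality cutoff is read as a mean because per-read means were
the default semantics of the original pipelines; sliding-window trimming
is not implemented), length 100–390 bases inclusive, and no homopolymer
of 6 or more bases. `cluster_otus()` performs abundance-sorted greedy
clustering at 97% identity: dereplicate, sort unique sequences by
abundance (ties lexicographic, for determinism), and either assign each
sequence to the best-matching existing representative at ≥ 97% identity
or seed a new OTU. Identity is matches divided by the columns of an
end-gap-free global alignment (match/mismatch/gap = +1/−1/−2), with
unaligned overhangs counted as columns so that a short spurious overlap
between unrelated sequences cannot masquerade as high identity. The OTU's
representative is its most abundant member sequence. Flowgram denoising
and chimera removal are deliberately absent: both are external published
algorithms, and the synthetic reads this package generates are
chimera-free by construction.

`assign_taxonomy_nearest()` is a nearest-reference labeler for
ground-truthed references (identity there is computed over the query, so
a short read scores 1.0 against its full-length source); it stands in for
database classifiers only in the sense that it gives synthetic OTUs their
known labels back.

## Carbon mass balance

Headspace measurements convert to aqueous concentrations through a
dimensionless Henry coefficient, `c_aq = c_gas / H_cc`. The coefficient is
a mandatory configuration value with default 0.227 (benzene, 25 °C,
literature value) — users with their own calibration should override it.
Vial geometry defaults to 20 mL liquid in a 72 mL vial (52 mL headspace).
The per-vial inventory closes both phases:
`c_aq · V_liq + c_aq · H_cc · V_gas`, and benzene converts to carbon at
6 C per molecule. The balance partitions degraded carbon as

\[ C_{degraded} = C_{CH_4} + C_{CO_2} + C_{residual}, \]

exactly, with mineralization reported as
\(100\,(C_{CH_4}+C_{CO_2})/C_{degraded}\) — full precision in machine
output, nearest percent in the printed report. A biomass allowance of at
most 10% of degraded carbon is reported as a bound, not subtracted: the
residual is intermediates *plus* biomass, and the split between them is
not observable from gas data alone.

With the measured per-vial amounts of the motivating experiment (157.7
μmol-C degraded, 44.1 μmol-C CH~4~, 68.8 μmol-C CO~2~) the balance yields
71.6%, i.e. 72% mineralization at headline precision — the number the
acceptance script recomputes.

## The synthetic-data generator

Real SIP raw data (traces, flowgrams, gradients) are rarely archived, so
every stage is tested against a generator whose ground truth is exact.

* **Community**: 12 taxa, equal abundances, GC contents evenly spaced
  0.36–0.58. Each taxon's 16S-like sequence is random at its GC
  composition with the forward-primer site planted at the 5' end and one
  recognition site planted so its T-RF length (60–500 bases, unique per
  taxon) is known exactly; accidental upstream sites and ≥6-base
  homopolymers are rewritten away (fix-up substitutions use only A/T,
  which cannot create a GCGC site), so no taxon loses its fragment — or
  its entire read population — to an artifact of random sequence.
* **Density model**: unlabeled buoyant density follows the standard GC
  relation \( \rho = 1.660 + 0.098\,\mathrm{GC} \); full ^13^C labeling
  adds 0.036 g cm^-3^, linearly in atom fraction. Both constants are
  configurable; they are literature conventions, not fitted values.
* **Gradient**: 22 fractions spanning 1.66–1.78 g cm^-3^; each taxon's
  DNA is a Gaussian band (σ = 0.008 g cm^-3^) integrated over each
  fraction's density interval. The width reflects diffusion and
  fragment-length spread; it is wide enough that heavy fractions of both
  treatments contain measurable DNA at every timepoint, as observed
  gradients do. Peak areas are band masses times a lognormal
  multiplicative noise (CV 0.2) with a detection floor of 50 area units —
  chosen to exercise the analysis-side area filter. The noise stream for
  a given (seed, day, taxon) is shared between treatments, so labeled and
  unlabeled gradients differ *only* through taxa with a nonzero label
  schedule.
* **Label schedule**: atom fraction 0/0/0.6/0.99 at days 0/23/38/64 —
  assimilation begins between days 23 and 38 and is essentially complete
  by day 64, so the expected first-detection day is 38.
* **Reads**: per heavy fraction, 500 reads of 150 bases drawn
  multinomially over taxon masses from a fixed window of each template,
  with 0.5% per-base substitution errors and plausible Phred qualities.
* **Gas**: benzene follows, by default, a monotone interpolation of the
  sampling schedule (0/33/66/100% cumulative degradation at days
  0/23/38/64 — the condition under which the gradient samples were
  drawn). A lagged first-order mode is available; least-squares
  calibration against the same schedule is the best a single rate
  constant can do, and it demonstrably cannot pass through all three
  interior anchors (it leaves ~7% benzene at day 64), which is why it is
  not the default. Degraded carbon partitions into CH~4~ (0.28), CO~2~
  (0.44), biomass (0.10) and intermediates (remainder), conserving carbon
  exactly at every timepoint; the default gas fractions give 72%
  mineralization at completion, matching the measured ratio.

Everything is a deterministic function of one integer seed; sub-streams
are derived per (day, taxon, treatment) so that partial re-simulation is
reproducible.

What the generator does **not** emulate: PCR amplification bias, chimera
formation, flowgram noise, gradient asymmetries, inter-replicate
variability (the motivating design pooled replicates before
fractionation). Passing tests therefore demonstrate that the inference
chain is correct under its stated statistical assumptions, not that those
assumptions hold for any particular instrument.

## Problem sizes and numerical choices

The test suite and the acceptance script run the T-RF recovery on 20
seeds (12 taxa × 22 fractions × 4 days × 2 treatments each) and the
amplicon recovery on a handful of seeds at 500 reads per heavy fraction —
sizes chosen so a full verification pass completes in a few minutes on a
laptop while keeping the multinomial sampling error well below the
detection threshold. Degenerate inputs are handled explicitly rather than
by accident: empty profiles normalize to empty with a warning, zero-count
OTU columns and zero initial benzene raise errors, and all nearest-value
selections carry documented deterministic tie-breaks.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
com <- sim_community(cfg)

clean <- function(g) bin_trf_lengths(
  lapply(g$profiles, function(p) normalize_profile(filter_peaks(p))), 1)

reports <- lapply(c(23, 38, 64), function(d)
  detect_labeled_trfs(clean(simulate_gradient(com, cfg, d, "labeled")),
                      clean(simulate_gradient(com, cfg, d, "unlabeled"))))
names(reports) <- c(23, 38, 64)

first_labeled_day(reports)      # the two planted assimilators, day 38
balance_from_series(simulate_gas(cfg))  # 72% mineralization
```

Or, end to end with reports and a manifest on disk:

```{r pipeline, eval = FALSE}
res <- run_sip_analysis(list(seed = 42, out_dir = "sip_run"))
res$first_labeled
```

## Known limitations

* The enrichment score is comparative, not quantitative: it ranks and
  flags phylotypes but does not estimate isotope incorporation.
* Greedy OTU clustering is order-dependent by design (abundance-sorted,
  deterministic); it reproduces the behavior of the classical tools, not
  of exact-linkage clustering.
* No statistical testing across biological replicates is provided; the
  motivating design pooled replicates before fractionation, so the
  package reports effect sizes, not p-values.
* The biomass term of the carbon balance is an upper bound taken from
  anaerobic growth-yield expectations, not a measurement.
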