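# mosquant

Quantification of in vivo methionine oxidation stoichiometries (MOS) from
¹⁶O/¹⁸O-labeled peptide pairs in MS1 spectra.

## The problem

Methionine sulfoxide is both an oxidative-damage mark and a reversible
regulatory modification, but its *site-level stoichiometry* — what fraction
of a given methionine is oxidized in the living tissue — is hard to
measure: the in vivo modification is chemically identical to oxidation
introduced during sample handling. The blocking strategy solves this by
force-oxidizing every remaining unmodified methionine at lysis with
¹⁸O-labeled peroxide. After blocking, each methionine is fully oxidized and
carries either a ¹⁶O sulfoxide (oxidized in vivo) or an ¹⁸O sulfoxide
(blocked in vitro). The stoichiometry of interest is then simply the light
fraction

    MOS = L / (L + H)

where `L` and `H` are the MS1 signals of the ¹⁶O (light) and ¹⁸O (heavy)
species of a peptide.

Two computational obstacles make this nontrivial:

1. **Envelope overlap.** The label offset is only 2.004246 Da, so the M+2,
   M+3, … isotopologues of the light species fall onto the heavy species'
   peak positions (unresolved at typical Orbitrap MS1 resolution). mosquant
   models the observed channels as a 2×2 mixture of the true species
   signals, with weights given by the theoretical isotope envelope, and
   inverts that model to recover the true L/H ratio.
2. **Accuracy at low stoichiometry.** In vivo stoichiometries are mostly a
   few percent. Accuracy is established by *titration*: each sample is
   mixed with a fully light carrier proteome at a known fraction `t`
   (0.10 and 0.25 in the reference design), so the measured value follows

       MOS_ij = t_i + (1 − t_i) · MOS_invivo,j

   and per-peptide nonlinear regression extrapolates to `t = 0`, returning
   the in vivo stoichiometry with a standard error.

Downstream, *oxidation-prone* methionines (sites whose interage MOS
exceeds the global median) are identified with an empirical-Bayes adaptive
shrinkage model using a half-uniform, positive-effects mixture prior
(significance at q ≤ 0.01), and age-group differences are tested per
peptide with Welch t statistics on the titration estimates under
Holm–Bonferroni family-wise error control.

The package is aimed at proteomics researchers applying ¹⁶O/¹⁸O
methionine-blocking workflows: it consumes centroided mzML/mzXML MS1 data
plus a search-engine evidence export, and ships a fully ground-truthed
synthetic-data generator so every stage can be validated without any raw
data download.

## The pipeline

For each peptide × charge × run target from the evidence table:

1. theoretical isotope envelope of the (sulfoxide) peptide by convolving
   per-element natural isotope distributions; light/heavy m/z positions;
2. per-isotopologue trace extraction (default 10 ppm, ±1 min);
3. Gaussian / Gaussian-mixture elution fit (BIC-selected, the component
   nearest the predicted retention time delineates the peak);
4. cosine linking of consecutive isotopologues (threshold 0.6);
5. light/heavy ratio as the OLS slope of summed light-channel on summed
   heavy-channel intensities across scans (quality gate R² ≥ 0.8);
6. envelope-overlap correction and conversion to MOS.

Per-run MOS values are filtered (≥ 7 valid of 12 per age group; cysteine
peptides removed), titration responses are fit per age group and pooled
("interage"; quality gate NRMSE ≤ 0.2), and the shrinkage and contrast
analyses run on the passing estimates.

## Worked example

Simulate a complete 24-run titration experiment (2 age groups × 3
biological × 2 technical replicates × t ∈ {0.10, 0.25}) for 10 peptides and
run the full pipeline:

```r
library(mosquant)
sim <- simulate_experiment(n_peptides = 10, seed = 42, noise_sdlog = 0.01)
res <- run_pipeline(sim$runs, sim$evidence, sim$design, mos_config(seed = 42))
res
#> <mos_results>
#>   pair quants: 240 (234 valid)
#>   peptides retained: 10 (dropped: 0 Cys, 0 below min_valid)
#>   interage global median MOS: 0.0451
#>   oxidation-prone: 5; age-significant: 0

est <- merge(res$estimates$interage, sim$truth$peptides[, c("peptide", "mos_true")])
head(est[order(-est$mos_invivo),
         c("peptide", "mos_invivo", "sem", "nrmse", "mos_true")], 4)
#>                  peptide mos_invivo      sem   nrmse mos_true
#>  VEIFVETAAMGAVFILIVPNPLR     0.3404 0.000374 0.00326   0.3404
#>             GGMPHDNHEPNK     0.0549 0.000153 0.00276   0.0550
#> VGNMPADGWYILPNVFPDAYSNNK     0.0520 0.000260 0.00470   0.0517
#>     VPAEISDGDIFQYTDIPMTK     0.0519 0.000166 0.00303   0.0522
```

240 pair quantifications were attempted (10 peptides × 24 runs); 6 fell to
the R² quality gate. Each retained peptide's in vivo stoichiometry is
recovered to ~3 decimal places at the simulated noise level, with the
titration-fit SEM reported per peptide. `write_results(res, "out/")` writes
the PairQuant, estimate, oxidation-prone and age-contrast tables as TSV
plus a JSON summary with the counts at every filter gate.

A thin command-line front end (`inst/scripts/mosquant-cli.R`) exposes
`simulate` and `run` subcommands over the same functions for shell use.

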