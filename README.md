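# albuquench

Spectroscopic analysis of small-molecule binding to serum albumin and
similar fluorescent proteins.

When a drug binds a protein carrying an intrinsic fluorophore (for human
serum albumin, the single tryptophan Trp214), it quenches the protein's
fluorescence. The concentration-, temperature- and wavelength-dependence
of that quenching carries essentially the whole binding story, and this
package implements the standard analysis chain over it:

* **Quenching fits** — Stern–Volmer (`F0/F = 1 + Ksv[Q]`, with
  `kq = Ksv/τ0`) and the double-logarithmic binding law
  (`log10((F0−F)/F) = log10(Kb) + n·log10[Q]`), with inner-filter
  correction `F·exp((A_ex+A_em)/2)` and emission-maximum shift metrics.
* **Thermodynamics** — Van 't Hoff regression
  (`ln Kb = −ΔH°/(RT) + ΔS°/R`), per-temperature `TΔS°` and
  `ΔG° = ΔH° − TΔS°`, and sign-based classification of the dominant
  binding force (van der Waals/H-bond, hydrophobic, electrostatic).
* **FRET** — spectral overlap integral
  `J = ∫F(λ)ε(λ)λ⁴dλ / ∫F(λ)dλ` (λ in cm), Förster radius
  `R0⁶ = 8.79×10⁻²⁵ κ² n⁻⁴ Φ J`, transfer efficiency
  `E = R0⁶/(R0⁶+r⁶) = 1 − F/F0`, donor–acceptor distance, and the
  `0.5R0 < r < 1.5R0` validity window.
* **Structure** — CD mean-residue ellipticity and α-helix content
  (`%α = (−[θ]₂₂₂ − 2340)/30300 × 100`), UV-Vis molar absorptivity and
  hyperchromicity, synchronous-fluorescence traces (Δλ = 15/60 nm), and
  excitation–emission-matrix peak extraction.
* **Synthetic data** — a seeded generator of titrations, band pairs,
  EEMs and CD spectra with analytically known ground truth, so every
  stage is testable without instrument data.

Inputs are plain delimited text (tab/comma/semicolon auto-detected,
`#` comments): two-column spectra, wide titration tables, and EEM
matrices. See the methods vignette (`vignettes/binding-analysis.Rmd`)
for the models, assumptions and numerical choices.

## Worked example

Simulate a four-temperature titration study and run the full pipeline:

```r
library(albuquench)
gs <- generator_spec(n_sites = 1, band_centre_end_nm = 339)   # stationary band
titr <- lapply(gs$temperatures_K, function(tk) make_titration(gs, tk))
pair <- make_fret_pair(gs)
run_pipeline(titr, donor = pair$donor, acceptor = pair$acceptor,
             fret_efficiency = 0.45,
             eem_input = make_eem(gs),
             cd_input = list(theta = make_cd(gs),
                             conc_mg_ml = gs$cd_conc_mg_ml,
                             path_cm = gs$cd_path_cm))
```

```
== Binding-analysis report ==

Quenching / binding fits (per temperature):
 temperature_K   Ksv_M1     kq_M1s1 sv_intercept sv_r_squared    Kb_M1 n_sites
           298 18439.28 1.84393e+12            1            1 18439.28       1
           303 15256.37 1.52564e+12            1            1 15256.37       1
           310 11822.27 1.18223e+12            1            1 11822.27       1
           315  9922.19 9.92219e+11            1            1  9922.19       1

Thermodynamics:
<thermo_result> dH = -6.8 kcal/mol, dS = -3.3 cal/mol/K (r2 = 1, n = 4)
 temperature_K TdS_kcal_mol dG_kcal_mol
           298      -0.9834     -5.8166
           303      -0.9999     -5.8001
           310      -1.0230     -5.7770
           315      -1.0395     -5.7605
<force_classification> vdw_hbond (dH = -6.8 kcal/mol, dS = -3.3 cal/mol/K, near-zero band 0.5)

FRET:
<fret_result> J = 7.88e-15 M-1 cm3, R0 = 2.363 nm, E = 0.450, r = 2.443 nm
  window 0.5*R0 < r < 1.5*R0: ok

EEM peaks:
<eem_peaks> 2 peak(s), min separation 10 nm
 ex_nm em_nm intensity
   280   335  3736.171
   230   330  1097.582

CD:
<cd_result> MRE(222 nm) = -2.113e+04 deg cm2 dmol-1, helix = 62.00%
```

Reading the report: the binding constant falls from 1.84×10⁴ M⁻¹ at
298 K to 0.99×10⁴ M⁻¹ at 315 K — the signature of static quenching —
and the Van 't Hoff fit over those constants returns exactly the
enthalpy (−6.80 kcal/mol) and entropy (−3.30 cal/mol/K) that generated
them; both negative, so the complex is held by van der Waals contacts
and hydrogen bonds, with ΔG° ≈ −5.8 kcal/mol (spontaneous). The FRET
block converts the simulated band overlap into a Förster radius and a
donor–acceptor distance inside the reliable window, and the structure
blocks recover the programmed EEM peaks and the 62% helix content.

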