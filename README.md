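# curvassay

Quantitative image analysis for curvature-sensing protein experiments.

Non-erythroid spectrin (αII/βII) scaffolds the plasma membrane and is
excluded from highly curved membrane regions, preferring flat membrane
(|κ| below about 0.2 µm⁻¹); this preference can be probed in cells
(boundary curvature vs. fluorescence localization), by microfluidic
deformability cytometry (stiffness readout), and in vitro with spherical
supported lipid bilayers (SSLBs) of defined curvature. `curvassay`
implements the full analysis chain for such experiments as a tested R
package, for cell biologists and biophysicists who need reproducible,
scriptable versions of what is usually done with ad-hoc ImageJ/MATLAB
steps:

* **geometry** — closed-contour resampling and signed curvature
  κ = (x′y″ − y′x″)/(x′² + y′²)^{3/2} along cell outlines (periodic
  Savitzky–Golay derivatives), with the smoothed magnitude track
  |κ̄| used for classification;
* **boundary** — cell segmentation (Otsu), sub-pixel boundary extraction
  (marching squares at the 0.5 iso-level), and per-channel boundary
  intensity profiles;
* **enrichment** — explicit dominance-margin classification of actin- vs
  spectrin-enriched boundary regions and comparison of their |κ|
  distributions (medians, fraction below a cutoff, Wilcoxon rank-sum +
  rank-biserial effect);
* **deformability** — deformation index DI = H/W per cell at maximum
  deformation in a cross-flow junction, aggregated into DI-vs-flow-rate
  curves;
* **densitometry** — gel band / strip spot integration with background
  subtraction and the dilution-corrected bound fraction
  ratio = B/(B + d·U);
* **assaydesign** — SSLB calculators: sphere curvature κ = 2/d and
  equal-surface-area bead masses;
* **synthetic** — seeded phantom generators (two-channel cells,
  deformation videos, gels, strips) with analytic ground truth, used by
  the validation suite.

## Worked example

```r
library(curvassay)

# SSLB design: equal-area masses from 2 mg of 1000 nm beads, and bead curvature
sslb_design_table()
#>   diameter_nm mass_ug kappa_per_um
#> 1        1000    2000      2.00000
#> 2         100     200     20.00000
#> 3          50     100     40.00000
#> 4          30      60     66.66667

# a synthetic two-channel cell whose spectrin channel avoids |kappa| > 0.2 1/um
ph  <- make_phantom_cell(phantom_cell_spec(kappa0_per_um = 0.2, snr = 5, seed = 1))
res <- run_curvature(list(images = ph$images, pixel_size_um = 0.2))
res$by_class
#> <curvature_by_class> cutoff 0.2 1/um
#>               class   n median_kappa        q25       q75 frac_below_cutoff
#> 1    actin_enriched 322   0.36577096 0.27468987 0.5202571        0.04968944
#> 2 spectrin_enriched 630   0.07919028 0.03560584 0.1242134        0.94603175
```

The spectrin-enriched boundary sits on flat membrane (median |κ| ≈ 0.08
µm⁻¹, 95 % below the 0.2 µm⁻¹ cutoff) while actin-enriched regions are
the curved protrusions (median ≈ 0.37 µm⁻¹) — the phantom's programmed
preference, recovered through segmentation, curvature estimation,
intensity sampling and classification. The rank-sum comparison
(`res$comparison`) gives p = 1.4e-134 with rank-biserial effect 0.98.

```r
# deformability: 50 synthetic cells per flow rate, programmed DI = 1 + 0.04 Q
spec <- deformation_cohort_spec(n_cells_per_Q = 50, seed = 1)
recs <- do.call(rbind, lapply(c(5, 15, 25), function(Q) {
  track_max_deformation(make_deformation_video(spec, Q)$frames, Q = Q)
}))
aggregate_di_curve(recs)
#>    Q  mean_DI     sd_DI  n sd_undefined
#> 1  5 1.241579 0.1080734 50        FALSE
#> 2 15 1.617024 0.1065238 50        FALSE
#> 3 25 2.003584 0.1119194 49        FALSE
```

The recovered means track the programmed curve (1.2, 1.6, 2.0).

## Command line

`exec/curvassay` provides subcommands `curvature`, `deform`, `densito`
(YAML configs), `design` (prints the SSLB design table as CSV) and
`simulate` (writes synthetic data + ground truth). Exit codes: 0 ok,
1 data error, 2 config error. Every pipeline run writes a
`provenance.json` (package version, seed, config and its MD5 hash).

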