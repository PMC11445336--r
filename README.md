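# fpetconn

Subject-level metabolic connectomics from constant-infusion dynamic
[18F]FDG-PET (fPET) and BOLD fMRI.

## The problem

Static FDG-PET gives one summed uptake image per subject, so "metabolic
connectivity" has traditionally been an across-subject statistic: the
correlation of regional uptake over the members of a group (metabolic
covariance, sPET). Constant tracer infusion changes that: a 90-minute
acquisition reconstructed into one-minute frames yields a glucose-uptake
*time series* per subject, and interregional correlation of those series —
like BOLD functional connectivity — becomes a per-subject quantity. That
opens the door to individual-level network markers of neurodegeneration,
e.g. exaggerated sensorimotor coupling in Parkinson's disease and its
relation to motor severity.

`fpetconn` implements the full analysis chain for a multimodal cohort
(patients and controls, each with a dynamic PET and a BOLD series) and a
synthetic-data generator with known ground truth, so every stage is testable
without any imaging download:

1. **Preprocessing** — retain the last 30 of 90 one-minute PET frames,
   global-mean intensity normalization, voxel-wise summation to a static
   image, atlas-based ROI series extraction, per-voxel detrending for
   decomposition inputs.
2. **Networks** — group spatial ICA (temporal concatenation, PCA whitening,
   symmetric FastICA, 10 components), component z-thresholding (z = 1.5;
   z = 1 for the sensorimotor component), parcellation of the network mask.
3. **Connectivity** — three constructions: group-level sPET covariance
   across subjects; subject-level fPET correlation over 30 frames;
   subject-level fMRI correlation over 490 frames. Fisher z, one-sample t
   group statistics, signed adjacency at p < 0.05.
4. **Connectomes** — multimodal common-edge (tertiary) matrices per modality
   pair, Sörensen–Dice similarity
   DC = 2|M1 ∩ M2| / (|M1| + |M2|),
   nodal degree and per-unit aggregation, BrainNet Viewer export.
5. **Statistics** — Shapiro-Wilk-gated Student/Welch t vs Mann-Whitney U,
   Bonferroni-Holm family correction for unit-degree comparisons,
   Spearman correlation of subject-level motor degree with severity,
   conditional-MLE odds ratio with Fisher's exact test, Welch t from
   printed summary statistics.

## Worked example

```r
library(fpetconn)

# a full synthetic cohort at the study conditions: 12 patients, 13 controls,
# 30 regions, 90 PET frames, 490 BOLD frames, planted motor hyperconnectivity
res <- run_pipeline(pipeline_config(seed = 1))
print(res)
#> pipeline_result: seed 1
#>   spet_fmri_PD     Dice = 0.841
#>   fpet_fmri_PD     Dice = 0.854
#>   spet_fpet_PD     Dice = 0.961
#>   spet_fmri_HC     Dice = 0.800
#>   fpet_fmri_HC     Dice = 0.776
#>   spet_fpet_HC     Dice = 0.814
#>   severity rho = 0.84 (p = 0.000626 )

res$network_rois                       # ICA-identified motor network
#> [1] 1 2 3 4 5 6
res$degree_stats$fpet_fmri$unit_pd["cortical_motor"]
#> cortical_motor
#>             33
res$degree_stats$fpet_fmri$unit_hc["cortical_motor"]
#> cortical_motor
#>              6
```

The Dice values quantify cross-modal edge overlap per group; the
`degree_stats` tables compare per-region nodal degree between groups within
each functional unit (Holm-corrected); `severity rho` is the Spearman
correlation between each patient's motor-network degree (subject-level fPET
connectivity) and the planted severity score. The cortical-motor degree
excess in patients and the positive severity correlation are the planted
disease effects recovered end to end.

Individual stages are exported (`simulate_cohort`, `extract_roi_series`,
`group_spatial_ica`, `subject_connectivity`, `common_edges`, `dice`,
`nodal_degree`, `shapiro_gate_compare`, ...) — see the help pages and the
methods vignette (`vignettes/fpetconn-methods.Rmd`). A thin command-line
wrapper lives at `inst/cli/fpetconn.R`.

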