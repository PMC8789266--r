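# dentomark

Automated tooth landmarking and occlusal scoring on dental arch meshes.

## The problem

Measuring how the upper and lower dental arches relate — crossbite, arch
constriction, overjet — is a core outcome measure in cleft lip and palate
care and in orthodontics generally. The modified Huddart–Bodenham (MHB)
index quantifies it tooth by tooth on an ordinal scale from the transverse
position of each maxillary tooth relative to the mandibular arch, and,
unlike examiner-calibrated categorical indices, is fully automatable. What
automation needs first is landmarking: finding and naming every cusp tip on
a scanned arch. Doing that by hand is slow and error-prone; `dentomark`
does it automatically from a triangle mesh.

## What the package does

Given a single-arch surface mesh (STL, millimetres) and its jaw/dentition
type, the pipeline

1. **orients** the arch: principal component analysis of the vertex cloud
   gives transverse > anteroposterior > occlusal axes by variance order;
   signs are fixed by a crown-taper test and the arch-form direction, and
   the occlusal axis is refined as the least-squares normal of the plane
   through the detected tooth tips;
2. **detects peak points**: local height maxima within a 6 mm band below
   the highest point — cusp tips, incisal edges, and some junk that later
   stages remove;
3. **partitions teeth**: from each peak, region growing over faces that
   stops at concave creases (per-edge signed dihedral, plus an integrated
   minimum-principal-curvature field that is robust on finely tessellated
   meshes), with a maximum-travel spill rule that discards non-tooth
   regions; a quadratic **jawline** `ap = a·t² + b·t + c` is fitted to the
   peaks and overlapping or same-position blobs are merged;
4. **assigns tooth types**: each blob's dimensional features (surface area,
   mesiodistal and buccolingual widths, crown height, peak count) are
   z-scored against a labelled training set, and a dynamic programme
   aligns the blob sequence to the arch template
   (`MMMPPCIIIICPPMMM` / `mmciiiicmm`), allowing missing teeth, non-tooth
   blobs, and mesial/distal half-molar pairs (`UR6.0`/`UR6.1`);
5. **extracts landmarks**: highest peak for incisors and canines, the
   buccal cusp for premolars and molars;
6. **scores MHB** on a registered maxillary/mandibular pair: a natural
   cubic spline through the mandibular cusp landmarks, a least-squares
   reference plane, and per-tooth signed transverse displacements mapped
   to ordinal scores (positive buccal; negative towards crossbite).

A deterministic synthetic arch generator (`generate_arch()`,
`generate_occluded_pair()`) builds implicit-surface arches with complete
ground truth — per-tooth face masks, cusp apices, intended displacements —
so every stage is testable without clinical scans, and
`generate_training_set()` derives the packaged training data from it.
Validation helpers (`tally_outcomes()`, `deviation_stats()`) reproduce the
standard evaluation summaries: per-tooth outcome categories
(OK / PartitionError / WrongAssignment with a WrongKind sub-row) and
landmark deviation statistics with geometric-mean confidence intervals.

## Worked example

```r
library(dentomark)

spec <- arch_spec(jaw = "mandibular", dentition = "permanent", seed = 1)
gen  <- generate_arch(spec)
gen$mesh
#> <dental_mesh: 133960 vertices, 267740 faces, extent 93.6 x 71.3 x 12.9 mm>

res <- run_recognition(gen$mesh, jaw = "mandibular", dentition = "permanent")
res
#> <arch_recognition: mandibular permanent arch; 42 peaks, 16 blobs, 16 labelled teeth>
#> <tooth_assignment: 16 blobs -> 16 labelled, 0 discarded, 0 slots skipped; total cost 5.71>
#>   LL8 LL7 LL6 LL5 LL4 LL3 LL2 LL1 LR1 LR2 LR3 LR4 LR5 LR6 LR7 LR8

head(res$landmarks, 4)
#> # A tibble: 4 x 6
#>   tooth_type vertex     x     y     z jaw_parameter
#>   <chr>       <int> <dbl> <dbl> <dbl>         <dbl>
#> 1 LL8         76111 -44.5 -44.3  9.19         -73.3
#> 2 LL7         98154 -39.0 -31.2  9.49         -60.0
#> 3 LL6         40855 -36.2 -24.1  9.67         -53.5
#> 4 LL5         98482 -30.0 -14.2 10.1          -41.0
```

All 16 teeth of the generated arch were partitioned and labelled (total
mismatch cost 5.71 squared-z units across 16 teeth, i.e. well inside
training spread), and each landmark sits on a cusp apex — compare with
`gen$truth$cusps`. `tidy()`, `glance()` and `autoplot()` methods give
tabular and graphical views of every result object, and `run_mhb()` scores
an occluded pair end to end:

```r
pair <- generate_occluded_pair(
  arch_spec(jaw = "maxillary", dentition = "permanent",
            tooth_offsets = c(UR6 = -2.5, UR5 = -2.5, UR4 = -2.5), seed = 2),
  arch_spec(jaw = "mandibular", dentition = "permanent", seed = 3)
)
out <- run_mhb(pair$maxillary$mesh, pair$mandibular$mesh)
out$scorecard   # per-tooth displacement + ordinal score, arch total
```

A thin command-line wrapper with `recognize`, `score-mhb`, `synth` and
`train` subcommands ships in `inst/scripts/dentomark`.

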