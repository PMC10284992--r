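# meshdeform

Continuous recovery of deforming tissue surfaces from stereo scene flow,
robust to occlusion by surgical instruments.

## The problem

During minimally invasive surgery, forceps press and release the tissue
surface. Recovering the resulting deformation — as a mesh whose vertices are
tracked over time — supports strain analysis, stiffness estimation and force
feedback, without fiducial markers or patient-specific biomechanical priors.
A stereo endoscope provides per-frame 3D scene flow (disparity + optical
flow), but the raw flow is noisy, has vacancies, and is contaminated wherever
the instrument occludes the tissue: there the observed motion belongs to the
tool, not the surface. Updating vertices directly with raw flow therefore
fails catastrophically under occlusion.

`meshdeform` implements a three-stage pipeline:

1. **Scene flow composition** — each mesh vertex is projected into the left
   image; disparity at frames *t* and *t+1* plus the optical flow between
   them yield the per-vertex 3D displacement `F_s` (or per-vertex flow is
   ingested directly).
2. **Strain-based filtering** — a vertex-wise least-squares (VWLS) fit of the
   local displacement field estimates the displacement gradient **G**; the
   infinitesimal strain tensor `ε = (G + Gᵀ)/2` gives the maximal absolute
   principal strain `ε_max`, and vertices whose strain outlier score exceeds
   `ε_t = 1` are rejected, as are vertices under the tracked instrument mask.
3. **Mesh optimization** — per frame, the stacked linear system

   ```
   [ Ĩ  ]        [ C*   ]
   [ αE ]  C  =  [ αΔ_E ]
   ```

   is solved in the constrained least-squares sense. The *dynamic term*
   `ĨC = C*` anchors validly tracked vertices to their flow-updated
   positions `C* = ĨC_p + F_s`; the *smoothness term* `EC = Δ_E` pulls every
   edge difference vector toward that of the initial mesh, where `E` is the
   sparse differential edge matrix (one `+1/−1` row per edge) and
   `Δ_E = E C_0` stays fixed over the whole sequence. Occluded vertices obey
   the instrument depth constraint `Z_o ≥ P_z`: recovered tissue must stay
   at or below (deeper than) the nearest reconstructed instrument point.

Evaluation metrics (three-point plane-projection surface distance with
per-axis decomposition, 95th-percentile Hausdorff distance, Cauchy edge
strain `(L − L0)/L0`), rigid ICP registration, mesh/flow file I/O (PLY, OBJ,
Middlebury `.flo`, PFM, PNG) and a fully seeded synthetic phantom simulator
are included, so the entire pipeline is testable offline.

## Worked example

Simulate the default phantom scenario (60×60 grid at 100 mm depth, Gaussian
indentation to 5 mm over 10 frames, 0.1 mm flow noise, 10% gross outliers, a
rod occluder over the indentation), recover the surface, and evaluate:

```r
library(meshdeform)

sq  <- generate_sequence(synthetic_scenario(), seed = 42)
rec <- run_sequence(sq$mesh0, sq$frames)
glance(rec)
#> # A tibble: 1 × 5
#>   n_frames n_skipped mean_valid mean_residual_dynamic mean_residual_smooth
#>      <int>     <int>      <dbl>                 <dbl>                <dbl>
#> 1       10         0      2639.                  8.40                 3.94

# final-frame accuracy against ground truth
mean_vertex_error(rec$meshes[[11]], sq$truth[[11]])
#> [1] 0.296884

# the raw-flow update the filter and optimization protect against
raw <- run_sequence(sq$mesh0, sq$frames,
                    config = recover_config(raw_update = TRUE))
mean_vertex_error(raw$meshes[[11]], sq$truth[[11]])
#> [1] 6.724507

glance(surface_distance(rec$meshes[[11]], sq$truth[[11]]$vertices))
#> # A tibble: 4 × 4
#>   axis      max   mean    sd
#>   <chr>   <dbl>  <dbl> <dbl>
#> 1 x       0.730 0.0367 0.103
#> 2 y       0.697 0.0381 0.106
#> 3 z       2.90  0.269  0.435
#> 4 overall 2.92  0.278  0.457
```

On each frame about 2,600 of the 3,600 vertices survive filtering and anchor
the solve; the rest (noise outliers — caught at 100% with 1.3% false
positives — instrument-contaminated and vacant vertices) are positioned by
the smoothness term. The full method tracks the surface to ~0.3 mm while the
raw update drifts by ~6.7 mm; the z (depth) component dominates the residual
error, as expected for stereo geometry. The same pipeline is scriptable from
the shell via `inst/cli/meshdeform.R` (`simulate` / `recover` / `evaluate` /
`filter` subcommands).

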