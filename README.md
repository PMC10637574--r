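# tistim

Modeling, optimization and visualization of **interferential stimulation**
(IFS), also called transcranial **temporal interference** stimulation
(TI/tTIS), in R.

Conventional transcranial electric stimulation cannot focally reach
deep-brain targets. IFS injects two transcranial currents at nearby
frequencies; their superposed electric fields beat, and the slowly
oscillating **amplitude-modulation envelope** — not the fast carrier — is
what neurons are thought to follow. `tistim` gives researchers and students
a self-contained toolbox to compute, optimize and *see* this process: the
rotating total field, its Lissajous trace, the envelope, and the
modulation-depth maps that decide where stimulation lands. Because
MRI-derived head meshes are rarely redistributable, the package ships its
own forward model: a concentric-sphere volume conductor solved by a
finite-difference Laplace solver, which exhibits the same physics at desk
scale.

## The model

With montage current vectors `s1`, `s2` (mA, zero net current each) driven
at angular frequencies `w1`, `w2`, and the lead field `A(r)` (V/m per mA,
one row per electrode against a fixed reference), the total field is

    E(r,t) = sin(w1 t + phi1) A(r) s1 + sin(w2 t + phi2) A(r) s2

Along a unit direction `d(r)` (radial-in toward the head centre, or
posterior-anterior), the envelope is the absolute analytic signal

    |E~(r,t)| = | d(r)' E(r,t) + j H[ d(r)' E(r,t) ] |,   H = Hilbert transform

and the **modulation depth** is its peak-to-trough depth, which reduces to a
closed form — twice the weaker of the two projected component amplitudes:

    MD(r) = max_t |E~| - min_t |E~| = 2 min( |d'A s1|, |d'A s2| )

The time-resolved view uses the instantaneous depth
`MD(r,t) = |E~(r,t)| - min_t |E~(r,t)|`. **Focality** of a map is the cube
root of the brain volume exceeding half the target's MD (cm; smaller is
more focal). Montages are found either by exhaustive search over two
electrode pairs or by constrained optimization of two whole-array current
patterns maximizing target MD while minimizing off-target MD energy.

## Worked example

Build an 8 mm four-layer phantom (brain/CSF/skull/scalp), place 17
electrodes, solve the lead field, and optimize a two-pair montage for a deep
target:

```r
library(tistim)
head   <- default_head_model(grid_spacing = 8)
layout <- place_electrodes(head, n_rings = 2, n_per_ring = 8)
lf     <- build_leadfield(head, layout)
lf
#> <ti_leadfield> 16 electrodes vs E0, 4945 brain nodes at 8 mm (V/m per mA)

target <- target_spec(c(-16, 10, 2), direction = "radial_in")
pairs  <- search_pairs(lf, target, total_current_mA = 2)
pairs
#> <ti_optim> (pairs) MD at target 0.4906 V/m, focality 5.066 cm
#> <ti_montage> 10 Hz, phase 0: E12 (1), E8 (-1)
#> <ti_montage> 12 Hz, phase 3.14: E16 (1), E4 (-1)
```

The optimum puts 1 mA through the pair E12–E8 at 10 Hz and 1 mA through
E16–E4 at 12 Hz: the target's radial MD is 0.49 V/m and the half-max
volume has a 5.07 cm cube-root. Simulate the protocol and compare the
target with an off-target probe:

```r
proto  <- stim_protocol(pairs$montage_a, pairs$montage_b, duration = 1)
report <- md_report(lf, proto, target = pairs$target_node,
                    off_target = 2395)  # brain-node index of an off-target probe
print(report, digits = 3)
#>     location node          direction     p1      p2 peak_field     md
#> 1     target 2492          radial_in  0.247 -0.2453      0.488 0.4906
#> 2 off_target 2395          radial_in -0.302  0.2175      0.514 0.4350
#> 3     target 2492 posterior_anterior -0.111  0.1544      0.262 0.2212
#> 4 off_target 2395 posterior_anterior -0.230  0.0333      0.262 0.0666
```

`p1`, `p2` are the two per-montage projected field amplitudes at each
probe; `md = 2*min(|p1|,|p2|)` — note how the MD along the optimized
(radial) direction exceeds the MD along the unoptimized PA direction, even
where the raw peak field is similar. Hotspot decomposition shows that
modulation is not confined to the midpoint between the pairs:

```r
md <- md_map(lf, pairs$montage_a, pairs$montage_b, "radial_in")
hotspots(md)
#>   region peak_node   peak_md volume_cm3   x   y  z
#> 1      1      2531 0.5094187    120.832 -40  24  0
#> 2      2      3309 0.2567280      0.512 -48  64 16
#> 3      3      3025 0.2567280      0.512  48 -64 16
```

Array optimization (`optimize_arrays`), Lissajous traces (`lissajous`),
slice maps (`render_slice`), and full animations (`animate`) follow the
same pattern; `run_pipeline()` chains everything from one YAML config, and
`inst/cli/tistim` exposes it as a command line tool
(`tistim run --config cfg.yaml`).

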