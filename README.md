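# pedrecon

Forensic reconstruction of vehicle–pedestrian collisions as an inverse
problem. Given the physical contact marks an accident leaves behind — a
spiderweb fracture on the windscreen, an imprint on the bonnet leading
edge, a scuff on the bumper, and the head's impact point on the road —
the package identifies the unknown pre-impact conditions by searching for
the simulated collision that best reproduces those marks.

The decision vector is `x = (V, D, α, β, γ)`: vehicle impact speed (m/s),
pedestrian lateral offset from the vehicle's longitudinal axis (m),
pedestrian yaw relative to the vehicle heading, and the head's pitch and
yaw angles (rad). The reconstruction problem is

```
min  F(x) = Σ_{k ∈ G} d_k(x),    d_k(x) = ‖ p_k(x; t_k) − m_k ‖₂
s.t. a_j ≤ x_j ≤ b_j,            0 ≤ d_k(x) ≤ 2 m
```

where, for each marker pair `k` in the chosen group `G ⊆ {I, II, III, IV}`,
`m_k` is the recorded mark, `p_k` is the matching pedestrian-body marker,
and `t_k` is the first contact of that pair's body segment with its
surface (pair I shoulder–windscreen, II thigh–bonnet leading edge, III
calf–bumper, IV head–ground). Distances beyond 2 m are treated as not
corresponding to reality.

The package provides:

* a simplified forward model: an 11-segment articulated ellipsoid
  pedestrian (penalty joints, semi-implicit Euler, compiled core) struck
  by a zoned vehicle front with EuroNCAP-style piecewise-linear
  force–deflection contact and regularized Coulomb friction;
* three from-scratch multiobjective optimizers at the study budget of
  20 × 20 = 400 evaluations per run: `nsga2()`, `ncga()`, `mopso()`, with
  full evaluation histories and the noninferior / inferior / locally
  optimal solution taxonomy (`classify_history()`);
* the design of experiments over the 11 marker-subset groups
  (`enumerate_groups()`, `run_campaign()`, one-way ANOVA, Tukey outlier
  rule);
* injury criteria: `hic()` (Head Injury Criterion, 36/15 ms windows) and
  `femur_assessment()` (3–10 kN fracture band);
* pre-impact utilities: `speed_from_video()`, `speed_bounds()`,
  `friction_defaults()`;
* a synthetic ground-truth generator (`generate_case()`) and closed-loop
  recovery experiments (`recovery_experiment()`), so the whole pipeline is
  testable without any external case data.

## Worked example

```r
library(pedrecon)

# vehicle speed from surveillance video: 17.96 m between frames 1 and 17
# at 16 frames/s
v <- speed_from_video(17.96, 1, 17, 16)
speed_bounds(v, half_width = 2)
#> lower upper
#>    16    20

# a synthetic case with a known truth, and its reconstruction
case <- generate_case(seed = 101)
case
#> <ground_truth_case> truth: V=17.49, D=0.1575, alpha=0.5839,
#>   beta=0.06308, gamma=-0.1001; noise_sd = 0 m

h <- reconstruct(case, group = c("I", "II", "III", "IV"),
                 algorithm = "nsga2", seed = 1)
classify_history(h)$global_best[c("V", "D", "alpha", "beta", "gamma", "F_sum")]
#>            V         D     alpha      beta      gamma      F_sum
#> 264 17.44677 0.1626518 0.6623844 0.1441431 -0.0370724 0.05702489
```

The recovered design lies within 0.05 m/s of the true impact speed and
the four marker distances sum to under 6 cm. Injury post-processing of a
simulated impact:

```r
sc <- scenario(case$template$pedestrian, case$template$vehicle,
               case$template$environment, case$true_design, dt = 5e-4)
injury_report(simulate_impact(sc))$femur$band
#> [1] "within"
```

A thin command-line front end over the same functions is installed at
`inst/cli/pedrecon.R` (subcommands `simulate`, `optimize`, `campaign`,
`make-case`, `recover`, `speed`, `hic`).

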