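# graspadapt

Trial-by-trial sensorimotor adaptation and perturbation detection in
visuo-haptic grasping.

When people repeatedly grasp an object whose *felt* size differs from its
*seen* size, their grip adapts: the maximum grip aperture (MGA) drifts
towards the felt size over trials. `graspadapt` provides a complete, tested
pipeline for experiments that probe this adaptation and ask whether it makes
the size mismatch *harder to notice*:

- **Perturbation schedules** — abrupt blocks (a constant mismatch bracketed
  by unperturbed baseline and washout trials) and sinusoidal blocks (the
  mismatch follows a sine over trials), with felt sizes quantized to the
  apparatus step size.
- **Synthetic experiments** — MGAs generated from the adaptation model plus
  motor noise, full 3-D marker trajectories realising those MGAs, and
  two-alternative forced-choice (2AFC) size judgments from a parameterised
  observer whose internal reference can be shifted by the adaptation state.
- **Kinematics** — cubic-spline interpolation of missing motion-capture
  frames, Savitzky–Golay smoothing (200 ms window), velocity-based movement
  segmentation, MGA extraction, and the four standard per-trial exclusion
  rules.
- **Adaptation model** — the linear state-space error-correction model
  fitted block-wise by RMSE minimisation.
- **Psychophysics** — per-trial percent correct, participant-wise detection
  trends, half-cycle folding for sinusoidal blocks, and cumulative-normal
  psychometric fits yielding PSE and JND.
- **Inference** — repeated-measures ANOVA, paired t with Cohen's d, JZS
  Bayes factors (t-tests and correlations), Deming regression, percentile
  bootstrap CIs.

## The model

Unperturbed grasping follows a linear response function,
`MGA = int + slope · v`, for seen size `v`. Adaptation is a latent state
`x_t` (a shift of the visuomotor mapping) added to the seen size:

```
MGA_mod_t = int + slope · (v_t + x_t)
x_{t+1}   = A · x_t − b · E_t
E_t       = MGA_t − (int + slope · h_t)
```

`A ∈ [0, 1]` is the retention of the state across trials and `b ∈ [0, 1]`
the fraction of the error corrected on the next trial. The error signal
`E_t` compares the executed grip with the grip that would have been
comfortable for the *felt* size `h_t`, so a grasp that was too large for the
object in the hand pushes the state down (see the methods vignette for the
sign convention). `A`, `b` and the intercept are estimated per block by
minimising the RMSE between observed and modelled MGAs, with the slope fixed
at the cohort-level estimate. Detection is summarised by a cumulative-normal
psychometric function of the mismatch `h − v`, whose spread gives the
just-noticeable difference (JND).

## Worked example

```r
library(graspadapt)
library(dplyr)

# one abrupt block: +12 mm mismatch on trials 5-20, seen size 44 mm
sp   <- schedule_spec("abrupt", magnitude = 12)
sch  <- make_abrupt_schedule(sp, rep(44, 24))

# simulate a participant (A = 0.95, b = 0.2, 2 mm motor noise) and refit
p    <- sim_participant()
mgas <- simulate_mgas(p, sch, seed = 7)
fit  <- fit_block(mgas$mga_mm, sch, slope_fixed = 0.93)
fit
#> <adaptation_fit>  A = 0.9517, b = 0.312, intercept = 23.42 mm (slope fixed at 0.93)
#>   RMSE = 2.0943 mm over 24 trials
```

The fit recovers the generating retention almost exactly; with a single
noisy 24-trial block the error-correction rate is less precise (averaging
over replicate blocks removes the scatter — the test suite does this over
200 blocks). `autoplot(fit)` overlays the model on the simulated MGAs.

A full synthetic cohort, end to end:

```r
cfg <- run_config("main", n_participants = 8, seed = 1,
                  bootstrap_reps = 1000)
out <- run_pipeline(cfg)

out$psychometric |> group_by(schedule_kind) |> summarise(mean_jnd = mean(jnd))
#>   schedule_kind mean_jnd
#> 1 abrupt           10.7
#> 2 sinusoidal        5.17

out$stats$t_jnd
#>       t    df         p cohens_d mean_diff  bf10
#> 1  9.50     7 0.0000300     3.36      5.52  748.
```

With the simulated observer coupled to the adaptation state, mismatches in
abrupt blocks become harder to detect as the grip adapts: the JND for abrupt
schedules exceeds the sinusoidal JND, here by 5.5 mm on average (paired
t-test above). Schedule-resolved model parameters with bootstrap CIs are in
`out$fit_summary`, detection trends in `out$trends`.

Bayes factors are computed by numerical integration; for example, for a
paired t of 2.76 over 23 participants with the conventional medium prior:

```r
bf10_ttest(2.76, 23, prior_scale = 0.707)
#> [1] 4.389875
```

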