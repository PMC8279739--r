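# credmap

Simulation and model-based analysis of a dual-outcome bandit task that
dissociates two routes of credit assignment. Four choice options
("persons") each yield one animal and one vegetable outcome; every outcome
is shared by exactly two persons, so reward feedback can be credited either
to the chosen person as a whole (model-free credit assignment, MFCA) or to
the individual outcomes through the task's bipartite cognitive map
(model-based credit assignment, MBCA), which generalizes value to the other
person sharing the outcome. On a third of trials one outcome is concealed
and must be inferred — prospectively (second outcome hidden) or
retrospectively (first outcome hidden). The package is for researchers in
computational cognitive modelling who want to simulate this task, fit its
learning models, and run its model-agnostic analyses on real or synthetic
session data.

## The model

Latent values reset at every block start: person-level MF values
`Q_MF(p)`, outcome-level MB values `Q_MB(o)`, and perseveration values
`PERS(p)`. With signed rewards (`+1` coin, `-1` nothing), after choosing
person `c` whose outcomes at temporal positions 1, 2 were `o1, o2` with
rewards `r1, r2` in format `f` (S, PI, or RI):

    Q_MF(c)   <- (1 - f_MF) Q_MF(c)   + c_MF (r1 + r2)      (others decay)
    Q_MB(o_i) <- (1 - f_MB) Q_MB(o_i) + c_MB[f, i] r_i      (others decay)
    PERS(p)   <- (1 - f_P)  PERS(p)   + pr 1[p = c]

Choice is a softmax over `Q_net(p) = Q_MF(p) + Q_MB(animal_p) +
Q_MB(vegetable_p) + PERS(p)` for the two offered persons (no inverse
temperature; the gains carry the scale). The six MBCA gains `c_MB[format,
position]` are the quantities of interest. A nested family constrains them
(pure MB/MF, no presentation, no position, no format, additive,
flipped-functional-position), and a cross-credit extension lets each reward
on retrospective-inference trials also reinforce the other outcome.

The workflow around the model: multi-start maximum-likelihood fitting with
analytic gradients, parametric-bootstrap likelihood-ratio model comparison
(BGLRT) at the participant and group level, parameter/model recovery
studies, trial-transition mixed-effects signature analyses (choice
repetition isolates MFCA, choice generalization isolates MBCA), and
reward-earnings simulations standardized against guessing and oracle
baselines.

## Worked example

```r
library(credmap)

# one synthetic participant: map, plan, simulated choices
map   <- build_task_map(seed = 11)
plan  <- generate_session_plan(map, session_config(), seed = 12)
truth <- param_vector(c_mf = 0.3, f_mf = 0.2,
                      c_mb = c(0.3, 0.3, 0.25, 0.25, 0.2, 0.1),
                      f_mb = 0.15, pr = 0.2, f_p = 0.5)
session <- simulate_session(truth, plan, seed = 13)

fit <- fit_participant(session, model_spec("full"), n_starts = 50, seed = 14)
fit
#> <cm_fit> full: loglik -207.823 (50 starts)
#>     c_mf     f_mf  c_mb_S1  c_mb_S2 c_mb_PI1 c_mb_PI2 c_mb_RI1 c_mb_RI2
#>   0.3177   0.4286   0.1141   0.1356   0.4422   0.4494   0.3703   0.1145
#>     f_mb       pr      f_p
#>   0.1158   0.5109   0.9096

# is MFCA needed? BGLRT of the full model against the pure-MB sub-model
bg <- bglrt_participant(session, model_spec("pure_MB"), model_spec("full"),
                        n_boot = 99, n_starts = 20, seed = 15)
bg
#> <cm_bglrt> full vs pure_MB: 2*dLL = 6.398, p = 0.0505 (99 bootstraps)

# MBCA signature on a simulated cohort: common-reward effect on
# choice generalization
cohort   <- generate_synthetic_cohort(20, seed = 6)
sessions <- lapply(cohort, `[[`, "session")
sig <- fit_mixed_logistic(generalization_transitions(sessions),
                          "GENERALIZE", re = "intercept")
sig$contrasts[sig$contrasts$contrast == "common_main",
              c("contrast", "estimate", "se", "p")]
#>      contrast  estimate        se            p
#> 1 common_main 0.5535452 0.0676051 3.652139e-16
```

The MFCA gain is recovered well (0.32 vs 0.3) and the MBCA gains track the
generating ones up to single-session estimation noise (the packaged
recovery study quantifies it). The likelihood-ratio statistic of 6.4 is exceeded by 5 of the 99
bootstrap statistics (p ≈ 0.05): one 360-trial session gives only
borderline evidence against pure-MB for a moderate MF gain, which is
exactly why the group-level test (`bglrt_group()`) aggregates statistics
across participants. The cohort-level generalization analysis recovers a
clearly positive common-reward effect — the model-based credit-assignment
signature — of about 0.55 log-odds.

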