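# booldelay

Time-delayed Boolean networks for intracellular signalling, with a fully
parameterized model of the NF-κB inflammation pathway.

## The problem

Signal-transduction cascades are well charted qualitatively (who
activates whom) but rarely come with the kinetic constants an ODE model
needs. Delayed Boolean networks occupy the middle ground: every species
is ON or OFF, and each regulatory edge *j → i* carries just two integer
dynamic parameters, estimable from sparse time-course data:

- **delayed activation θᵢⱼ** — the minutes node *j* must be
  *continuously* on before its effect on *i* switches on;
- **sustained / delayed response rᵢⱼ** — for *r ≥ 1*, every minute the
  input condition holds banks *r − 1* minutes of sustained output after
  the input lapses; for *r ≤ −1*, activation needs a further |*r*|
  minutes of accumulated input and resets when the input drops.

A node's transfer function combines its edges' gate bits with AND / OR /
NOT (OR for alternative activators, AND for synergy, NOT for
inhibition), and the whole network updates synchronously at 1-minute
resolution:

```
x_i(t) = f_i( g_i1(t), …, g_iN(t) ),   g_ij from x_j up to t − 1
```

The package provides, for networks in this formalism:

- a rule language and parser (`parse_rule()`, e.g.
  `"4*TNF(t-1) AND NOT A20(t-10)"`), JSON serialization, validation;
- a compiled synchronous simulator with stimulus protocols and
  in-silico knockouts (`simulate_network()`), plus a literal pure-R
  reference interpreter used as its oracle (`simulate_reference()`);
- structural analysis: linear-chain reduction (`simplify_network()`),
  kernel-pathway identification (`find_kernel()`), feedback-loop
  enumeration (`feedback_regulators()`);
- maximum-entropy (Kapur) binarization of densitometry-style time
  courses (`binarize_profile()`);
- a genetic-algorithm parameter fitter with roulette selection,
  single-point crossover, per-gene mutation and elitism (`run_ga()`),
  including the two-stage kernel-first protocol (`two_stage_fit()`);
- synthetic-data generators so everything is testable end to end
  (`random_network()`, `generate_continuous_traces()`,
  `synthetic_training_set()`).

## Worked example

```r
library(booldelay)

net <- builtin_nfkb_network()
net
#> Time-delayed Boolean network: 11 nodes, 10 rules
#>   pure inputs: LPS
#>   stimulus:    TNF, IL1, LPS
#>   observable:  IKK, IkBa, NFkB
#>   IRAK1(t) = 5*IL1(t-1) OR 3*LPS(t-87)
#>   ...
#>   TNFR1(t) = 4*TNF(t-1) AND NOT A20(t-10)

# 45-minute TNF treatment, wild type: one acute IKK episode
acute <- simulate_network(net, stimulus_protocol(stim_event("TNF", 0, 45), 720))
activation_intervals(acute, "IKK")
#>   start end
#> 1     3 125

# chronic TNF: a secondary IKK episode (the pro-inflammatory relapse)
chronic <- simulate_network(net, stimulus_protocol(stim_event("TNF", 0, 720), 720))
activation_intervals(chronic, "IKK")
#>   start end
#> 1     3 125
#> 2   481 603

# knocking out the negative regulator A20 prolongs the TNF response
a20ko <- simulate_network(net, stimulus_protocol(stim_event("TNF", 0, 45), 720),
                          knockouts = "A20")
activation_intervals(a20ko, "IKK")
#>   start end
#> 1     3 298
#> 2   300 415
#> 3   460 575
#> 4   620 720

# every stimulus must funnel through the IKK–IκBα–NF-κB kernel,
# and NF-κB feeds back through TNF, A20 and IL-1
find_kernel(net, c("TNF", "IL1", "LPS"), "NFkB")
#> [1] "IKK"  "IkBa" "NFkB"
feedback_regulators(net, "NFkB")
#> [1] "A20" "IL1" "TNF"
```

The first interval start (minute 3) is the stimulus-to-IKK transport
delay along TNF → TNFR1 → NIK → IKK (three θ = 1 edges); the long tail
comes from the unbounded sustain accumulator of the TNF → TNFR1 edge
(r = 4). The vignette discusses this reading of the update pseudocode,
the bounded alternative (`accumulator = "bounded"`), and how the two
compare against the model's published behaviour.

A thin command-line wrapper ships in `inst/cli/booldelay`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","booldelay",package="booldelay"))')" \
    simulate --network builtin:nfkb --horizon 720 --stimulus TNF:0-45 --out run/
```

Subcommands: `simulate`, `analyze`, `binarize`, `generate`, `fit`,
`repro` (the last re-runs the bundled stimulation/knockout experiments).
Every run writes a `manifest.json` with its configuration.

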