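# popspike

Tools for quantifying how precisely the spike timing of a cortical neuronal
population encodes the time of a sensory event — a passive whisker deflection
under anesthesia or a whisker-pole touch during active whisking — and how an
optogenetic manipulation of layer V changes that precision.

Neurons recorded one at a time (juxtasomal, whole-cell, or linear-probe
channels) are pooled into **pseudo-simultaneous population trials**. In each
trial, pooled spike counts are taken in non-overlapping bins (10 ms over
[-40, 100) ms, or 4 ms over [-20, 40) ms for the awake peri-touch variant),
and a **population response event (PRE)** is declared in every bin where

```
pooled count / n_units > Th        (Th in spikes per neuron, strict)
```

with canonical thresholds Th = 0.1, 0.04 (juxtasomal datasets) and 0.05
spikes/channel (probes). The precision statistic is the **absolute error of
stimulus-time estimation**: within each condition,

```
error_i = | t_PRE,i − mode(PRE times) |
```

Smaller errors mean supra-threshold population activity concentrates at one
reproducible latency. Conditions are compared with normality-gated two-sample
tests (t / Mann-Whitney / Wilcoxon), Kruskal-Wallis + Dunn for more than two
groups, and — for awake data with unequal touch counts — a 100-repetition
subsample procedure (53 touches per cell, without replacement) aggregated by
an exact binomial test with Benjamini-Hochberg / Benjamini-Yekutieli FDR
cross-checks.

Because the underlying recordings are not publicly deposited, the package
ships a first-class synthetic-data module: inhomogeneous-Poisson or
latent-Gaussian-copula spike counts that match peri-stimulus rate profiles
exactly while sweeping pairwise noise correlations, renewal touch streams
(27 ms touches, 70 ms inter-touch intervals), and bimodal resting/activated
membrane-potential sweeps. Membrane-potential and synaptic-current metrics
(state classification by the 5 / 13 mV baseline rules, evoked peaks and
areas, >4.5 mV hyperpolarization response probability, charge transfer,
rheobase / input resistance / adaptation ratio) round out the analysis
surface.

## Worked example

Simulate a 13-neuron population (150 trials per condition), with layer V
activation truncating the evoked response 30 ms after onset, then detect PREs
and compare error distributions:

```r
library(popspike)

ctl <- rateProfile(condition = "control")
act <- rateProfile(condition = "opto_activation", truncationS = 0.030)
simC <- simulatePopulation(ctl, nNeurons = 13, nTrials = 150, seed = 1)
simA <- simulatePopulation(act, nNeurons = 13, nTrials = 150, seed = 2)

periC <- alignToEvents(simC$spikes, simC$events, window = c(-0.040, 0.100))
periA <- alignToEvents(simA$spikes, simA$events, window = c(-0.040, 0.100))
popC <- buildPseudoPopulation(periC, binWidth = 0.010, seed = 3)
popA <- buildPseudoPopulation(periA, binWidth = 0.010, seed = 4)

pre <- absoluteError(detectPREs(list(popC, popA), th = 0.1))
pre
#> PREResult: Th = 0.1 spikes/unit, 959 PREs; modes (ms): control = 15, opto_activation = 15

er <- preErrors(pre)
round(1000 * tapply(er$abs_error_s, er$condition, mean), 1)
#>         control opto_activation
#>            21.0             8.3

tt <- compareConditions(er$abs_error_s[er$condition == "opto_activation"],
                        er$abs_error_s[er$condition == "control"],
                        alternative = "less")
sprintf("%s: p = %.3g (one-sided)", tt$method, tt$p.value)
#> [1] "Mann-Whitney: p = 1.08e-17 (one-sided)"
```

Both conditions lock their typical population response at 15 ms after the
stimulus, but truncating late firing shrinks the mean absolute error from
21 ms to 8 ms: the population encodes the deflection time more precisely.
The same analysis runs end to end from a single config via
`runPipeline(pipelineConfig("anesthetized_activation", seed = 42))`, and the
awake variant (`"awake_touch"`) performs the 53-touch / 100-repetition
binomial procedure instead.

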