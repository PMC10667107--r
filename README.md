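# hdsynapse

Quantitative analytics for studies of complement-mediated synapse loss in
Huntington's disease (HD) models and patient cohorts. The package is aimed
at imaging and physiology labs that count synapses as co-localized
pre/postsynaptic puncta, measure glial engulfment of neuronal material,
score microglial activation, compare spontaneous EPSC (sEPSC)
distributions between genotypes or treatments, and stratify patient
cohorts by genetic disease burden.

## What it computes

- **Synapse counting.** Puncta are detected per channel in 3D
  (smooth → global threshold → connected components → dimension criteria,
  with peak-based splitting of touching puncta) and a synapse is called
  when a presynaptic and a postsynaptic center lie strictly closer than
  0.3 μm, matched one-to-one with maximum cardinality. Complement
  co-localization is the fraction of called synapses with a complement
  punctum within the same threshold, and chance co-localization is
  calibrated by rotating the complement channel 90° in-plane
  (`rotate_channel_90()`).
- **Engulfment.** `percent engulfment = 100 × engulfed cargo volume /
  cell volume`, normalized by the field's `input density = cargo volume /
  field volume`.
- **Phagocytic state.** Per microglial cell, a 0–3 morphology score plus
  a 0–2 CD68 (lysosomal) score gives the 0–5 state; plus Sholl profiles
  of branch points and terminals by distance from the soma.
- **sEPSC comparison.** Equal-cell-weight bootstrap (100 events per cell
  per iteration; 1,000 iterations for CDF variance bands) and a two-group
  comparison of pooled 75th percentiles over 5,000 iterations, with
  p-value floor 1/5,000 = 0.0002.
- **Cohort stratification.** CAP = 100 × Age × (CAG − 30)/627; burden of
  pathology = (CAG − 35.5) × Age, splitting premanifest carriers at 250;
  age adjustment `Y − b(age − mean age)` with `b` fitted on controls;
  Kruskal–Wallis + Dunn pairwise comparisons and Spearman CAP–analyte
  correlations.
- **Synthetic data.** `gen_synapse_field()`, `gen_engulfment_scene()`,
  `gen_microglia_morphology()`, `gen_event_trains()` and `gen_cohort()`
  generate every input with known ground truth, so the full pipeline is
  testable without external data.

## Worked example

```r
library(hdsynapse)

# simulate a field with 50% of true synapse pairs tagged by complement
spec <- field_spec(complement_tag_fraction = 0.5, seed = 42)
sim  <- gen_synapse_field(spec)

pars <- detection_params()
pre  <- detect_puncta(sim$field, "pre",  pars)
post <- detect_puncta(sim$field, "post", pars)
syn  <- pair_synapses(pre, post)              # synapse calls, < 0.3 um
comp <- detect_puncta(sim$field, "complement", pars)
cf   <- coloc_fraction(syn, comp)             # % synapses tagged
null <- coloc_fraction(syn,
          detect_puncta(rotate_channel_90(sim$field, "complement"),
                        "complement", pars))  # chance level
```

This prints (seed 42): `synapses: 194 (true pairs 197)`, complement
co-localization `44.3%` against a rotation null of `1.5%`, i.e. an
estimated tagged fraction of `0.43` versus the generated truth `0.45` —
the rotation null removes what chance proximity would otherwise
attribute to tagging.

```r
coh <- gen_cohort(cohort_spec(seed = 7))
cap_score(50, 42)                      # 95.69
burden_score(50, 42)                   # 325  -> late premanifest
table(stratify(coh))                   # 20 / 13 / 18 / 32, 0 unclassified
group_compare(coh, "C3")$kw_p          # 3.4e-12 (CAP-driven group effect)
cap_correlation(coh, "C3", subset = "premanifest")$rho   # 0.89

tr <- gen_event_trains(train_spec(n_cells = 6,
                                  group_effect = list(freq = 0.6, amp = 1),
                                  seed = 5))
g  <- vapply(tr, function(t) t$group, "")
percentile_test(tr[g == "A"], tr[g == "B"], "isi",
                n_iterations = 5000, seed = 1)$p_value   # 0.0002 (the floor)
```

A 40% frequency reduction drives the 75th-percentile ISI comparison to
the test's resolution floor, 0.0002 — one iteration out of 5,000.

See `vignettes/hdsynapse-methods.Rmd` for the models, parameter
defaults, and the reasoning behind every configurable band and
threshold.

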