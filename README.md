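# psifold

Quantitative prediction of how single-nucleotide variants near a 5' splice
site change alternative-splicing outcome — percent spliced in (PSI) — by
combining chemical-probing-guided RNA structural ensembles with
splicing-regulatory-element (SRE) motif strength changes in a
category-gated beta regression.

psifold is for computational RNA biologists studying variants around
alternatively spliced exons (the motivating system is a tau-like exon whose
inclusion ratio is disturbed by disease mutations at its exon–intron
junction): it turns probing data plus a mutation list into per-variant
structural and motif features and calibrated PSI predictions.

## The model

Exon inclusion requires the spliceosome to engage a donor 9-mer (last 3
exonic + first 6 intronic nucleotides) and to hold a stage-specific
footprint of pre-mRNA single-stranded.  For a structure *s* and a footprint
region, the unfolding free energy

ΔG‡ = ΔG(region forced single-stranded) − ΔG(s) ≥ 0

is the cost of disrupting that region without refolding.  psifold samples
N structures from the reactivity-restrained Boltzmann distribution of the
junction region (a self-contained nearest-neighbor engine with
partition-function, base-pair-probability, MFE, and stochastic-sampling
routines, verified against exhaustive enumeration), computes ΔG‡ for every
member, and summarizes the ensemble by Mean(X), SD(X), Skew(X),
Kurtosis(X), plus Y for the MFE structure.  Sequence features are the
donor-strength change ΔSS and threshold-gated sliding-window Δstrengths
aggregated into enhancer (E), silencer (S), and RBP (Ex, In) terms.

PSI ∈ (0,1) is fitted by maximum-likelihood beta regression
(logit link, precision φ).  Seven formulas are supported, including the
category-gated interactive model

PSI ~ [Mean(X)+SD(X)+Skew(X)+Kurtosis(X)]·[isSynonymous+isIntronic] +
[E+S+SS]·[isNonSynonymous]

A synthetic-data module generates every input the pipeline consumes
(junction sequences with planted hairpins, context-dependent reactivities,
ShapeMapper-style rate tables, mutation panels with Beta-distributed PSI,
coordinate fixtures), so the whole pipeline is testable end to end without
any external download.

## Worked example

Simulate a study-sized junction (234 nt, junction after position 93, a
10-pair hairpin straddling it), build a 47-mutation panel whose features
are computed by the real pipeline (200-structure ensembles per mutant,
B^act^ footprint), and fit the interactive model:

```r
library(psifold)

wt <- gen_junction_sequence(length = 234, junction_offset = 93,
                            hairpin_arm = 10, seed = 7)
config <- default_synthetic_config(wt, n_samples = 200, seed = 1)
config$stage <- "Bact"

spec <- synthetic_panel_spec(n_mutations = 47, precision_phi = 50, seed = 2)
panel <- simulate_mutation_panel(spec, wt, config = config)

fit <- fit_beta_regression(panel, "interactive")
print(fit)
#> beta regression (interactive), logit link, n = 47
#>                 estimate     se
#> (Intercept)       0.4392 0.0443
#> mean_dg:gate     -0.1170 0.0191
#> sd_dg:gate       -0.2362 0.1492
#> skew_dg:gate     -0.1250 0.0910
#> kurt_dg:gate      0.0525 0.0280
#> enhancer:nonsyn   0.2394 0.0406
#> silencer:nonsyn  -0.1019 0.0821
#> dss:nonsyn        0.5591 0.2279
#> phi = 77.184  loglik = 71.287

pred <- predict_psi(fit, panel)
cor(panel$psi, pred)^2
#> [1] 0.7615248

boots <- bootstrap_r2(panel, "interactive", seed = 3)
median(boots$overall)
#> [1] 0.7733703
```

Reading the output: `mean_dg:gate = -0.117` says that for synonymous and
intronic mutations each extra kcal/mol of ensemble-mean unfolding cost
(relative to wild type) lowers the log-odds of inclusion by 0.117 — more
sequestered junctions are spliced in less — while `dss:nonsyn = 0.56` says
donor-site strengthening by non-synonymous mutations promotes inclusion.
The in-sample R² of 0.76 and the bootstrap median of 0.77 summarize fit
quality on this synthetic panel (the generating coefficients sit inside
the reported standard errors).

Individual variants follow mutation-id grammar relative to the junction
(`"+19C>G"` is intronic position 19; `"-6G>A"` exonic position 6 from the
junction; compensatory doubles join two substitutions with `;`):

```r
res <- run_variant_prediction(config, c("+2A>C"), fit = fit)
sat <- saturation_mutagenesis(config,
         c(wt$junction_offset - 49L, wt$junction_offset + 50L), fit)
nrow(sat$predictions)   # 300 mutants for a 100-nt window
```

A thin CLI over the same functions ships in `inst/cli/psifold`
(subcommands `simulate`, `fold`, `footprint`).

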