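# paleomito

Authentication, decontamination and dating of ancient mitochondrial
genomes, for researchers working with heavily contaminated ancient-DNA
capture libraries.

DNA extracted from Pleistocene skeletal material is a mixture of short,
damaged endogenous molecules and present-day human contamination — often
mostly the latter. `paleomito` implements the computational chain that
turns such a mixture into a trustworthy mitochondrial genome and a date:

* **Damage profiling.** Post-mortem cytosine deamination is read as C→T
  substitutions concentrated at fragment ends. The package tabulates the
  C→T frequency by distance from each read end, and the *conditional*
  frequency over fragments already damaged at the opposite end: in a
  mixture, conditioning selects authentic molecules, so
  conditional ≫ unconditional is the signature of contamination.
* **Decontamination.** Fragments carrying a C→T in their three first or
  three last read positions are retained (`filter_deaminated()`); all
  terminal T bases are then masked to `N` so damage cannot enter the
  genome sequence.
* **Consensus.** A pileup-based threshold caller: a position is called
  when coverage ≥ 5 and majority support ≥ 80% (both inclusive);
  well-covered positions failing the support rule are flagged as
  heteroplasmy candidates and left uncalled.
* **Contamination estimate.** At diagnostic positions — where the
  consensus differs from every member of a present-day panel — each
  covering fragment is one Bernoulli observation; the fraction carrying a
  panel state estimates contamination, with a Wilson 95% CI, before and
  after deamination filtering.
* **Molecular clock.** `k` substitutions private to the consensus, over
  `L` comparable sites at rate μ (substitutions/site/year), date the
  lineage to `t̂ = k/(μL)`, with exact (Garwood) Poisson bounds
  `[qgamma(α/2, k), qgamma(1−α/2, k+1)]/(μL)`.
* **Radiocarbon.** QC arithmetic for dated material (atomic C:N from
  formula or mass percentages, percent yield, `F14C = exp(−age/8033)`)
  and single-date calibration against a tabulated curve, reporting
  highest-posterior-density calendar ranges.
* **Synthetic data.** A generator plants an endogenous haplotype with
  private substitutions, a present-day panel, and a labelled fragment
  mixture with terminal-decaying damage — so every estimator above is
  testable against known truth.

## Worked example

Simulate a 16,569-bp circular genome with 10 planted private
substitutions, a 311-member present-day panel, and one library of 30,000
fragments at 30% contamination and ~100× raw coverage, then run the full
chain:

```r
library(paleomito)
rep <- run_pipeline(pipeline_config(
  input = list(type = "sim", L = 16569L,
               libraries = list(list(name = "libB", n_fragments = 30000L,
                                     contamination = 0.3))),
  seed = 42))
print(rep)
```

```
== paleomito pipeline report (seed 42) ==

Per-library statistics:
 library n_unique_fragments coverage contamination_pct ct5_pct cond_ct5_pct
    libB              29659     97.9              28.7      28           41
 ct3_pct cond_ct3_pct n_deaminated coverage_deam contamination_deam_pct
    29.1         40.3         7985          26.5                    1.6

consensus_sequence: 16569 / 16569 positions called (min_cov 5, min_support 80%)
  mean coverage 25.3; 0 heteroplasmy candidate(s)
contamination: 28.7% (all fragments) -> 1.6% (deaminated only)
divergence time: 22,604 years (10 substitutions over 16569 sites at mu = 2.67e-08)
  95% Poisson interval: 10,840 - 41,570 years
truth: 100.000% of 16569 compared positions correct; 10/10 private substitutions recovered
```

Reading the report: the raw library is ~29% contaminant (the estimator
recovers the planted 30%); the terminal C→T rate of 28% rises to 41%
conditional on damage at the other end, betraying the mixture; restricting
to the 7,985 deaminated fragments collapses the contamination estimate to
1.6%, and the masked, damage-restricted consensus reproduces the planted
haplotype at every called position, recovering all 10 private
substitutions — which the Poisson clock converts to ≈ 22,600 years.

Calibration works against any `.14c`-format curve file; with a noiseless
identity curve the posterior is the measurement Gaussian, a built-in
correctness check:

```r
cc <- calibration_curve(seq(5000, 15000, 5), seq(5000, 15000, 5), rep(0, 2001))
calibrate_c14(10000, 100, cc, p = 0.954)
#> calibrated date for 10,000 +/- 100 BP (95.4% HPD):
#>   10,200 - 9,800 cal BP (95.4%)
```

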