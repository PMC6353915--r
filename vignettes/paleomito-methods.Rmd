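---
title: "Methods: authenticating, assembling and dating an ancient mitochondrial genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: authenticating, assembling and dating an ancient mitochondrial genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomito)
```

## The problem

DNA recovered from Pleistocene skeletal material is a mixture: short
endogenous molecules degraded over tens of millennia, and present-day human
DNA introduced during excavation, handling and laboratory work. For
mitochondrial capture data the contaminant fraction can exceed the
endogenous one, so a consensus called naively from all reads can be partly,
or mostly, the genome of whoever touched the bone. `paleomito` implements
the standard defence: use the chemical signature of ancient DNA — cytosine
deamination, read as C→T substitutions concentrated at fragment ends — to
quantify the mixture, select the authentic molecules, and only then call
the genome, estimate contamination, and place the individual in time.

The package covers the full chain: a synthetic-data generator with planted
truth, fragment ingestion (SAM/BAM/TSV), length filtering and PCR-duplicate
fusing, damage profiling, deamination-restricted consensus calling with
heteroplasmy flagging, contamination estimation at lineage-diagnostic
positions, a Poisson molecular clock, and radiocarbon QC/calibration
arithmetic.

## Coordinate and orientation conventions

All positions are 0-based on a circular reference; intervals are half-open
`[start, end)` with `start < L` and `end` allowed to exceed `L` for
fragments spanning the origin (arithmetic is done against the doubled
reference). Fragment sequences are stored reference-forward; damage
bookkeeping is done in read orientation: the 5' end of a minus-strand
fragment is its right-hand reference coordinate, and a read-orientation
C→T event appears reference-forward as G→A. These two conventions are the
ones most easily got wrong in this field, so they are asserted at module
boundaries and covered by hand-built strand tests.

## The synthetic-data generator

The generator is first-class code, not a fixture: every estimator in the
package is validated against its planted truth.

* **Reference and haplotypes.** A uniform-random circular genome
  (default L = 16,569 bases, the length of the human mitochondrial
  reference). A present-day panel (default 311 members, each with 20
  random substitutions from the root) and an endogenous haplotype with
  exactly `k_private` substitutions (default 10) planted at positions
  untouched by any panel member — so the planted substitutions are, by
  construction, exactly the diagnostic positions an exhaustive comparison
  recovers.
* **Fragments.** Each molecule is endogenous with probability
  `1 − contamination_fraction`, else drawn uniformly from the panel.
  Starts are uniform on the circle; strand is uniform; lengths follow a
  geometric distribution shifted to a 35-bp floor with mean 55, truncated
  at 150 bp — typical for ancient inserts, with the floor matching the
  35-bp retention filter.
* **Damage.** In read orientation, each C flips to T with probability
  `delta_term * exp(-d / lambda_decay) + delta_bg`, `d` being the distance
  to the nearer end; both ends are elevated, the behaviour of
  single-stranded libraries. Defaults `delta_term = 0.4`,
  `lambda_decay = 3`, `delta_bg = 0.01` mimic the terminal frequencies
  (~35–42% at position 1) seen in heavily deaminated Pleistocene
  libraries. Contaminants receive only `delta_bg`: present-day DNA is
  modelled as undamaged.
* **Noise and duplicates.** A uniform per-base miscall rate (default
  0.001) is drawn independently per emitted copy; a fraction of molecules
  (default `duplicate_rate = 0.1`) is emitted twice with identical
  coordinates, emulating PCR duplicates that share the molecule's damage
  but not its sequencing errors.

What the generator does **not** emulate: indels, per-position coverage
biases from capture probes, G→A damage of double-stranded library
chemistry, reference bias during mapping, and amplification bias. Passing
tests therefore demonstrate the estimators' correctness under the stated
mixture model, not robustness to every artefact of real libraries.

## Preprocessing

Fragments shorter than 35 bp are discarded (boundary inclusive — "at
least 35"). Fragments sharing `(library, start, end, strand)` are fused to
one molecule: per-column majority base, ties becoming `N`. Majority fusing
is a package choice — coordinate-duplicate reconciliation is not uniquely
defined in the field — and the tie rule is deliberately conservative.
Duplicate keys include library and strand: identical coordinates across
libraries are coincidence, not PCR duplication. Coverage is reported as
total retained bases divided by L.

## Damage profiling and authentication

`mismatch_profile()` tabulates, at each distance from the 5' and 3' read
ends (default 15 positions), the number of read-orientation reference-C
sites and the fraction reading T. `conditional_profile()` recomputes the
profile over fragments already carrying a C→T within `cond_window`
positions of the opposite end. In a two-component mixture in which only
endogenous molecules carry terminal damage, conditioning selects
endogenous molecules, so the conditional terminal frequency approaches the
endogenous damage rate while the unconditional one is diluted by the
contaminant fraction — the classic authenticity signature. The
conditioning window defaults to 1 (the terminal base, the strictest
reading of damage "at one end") and is a parameter because no single
convention exists.

`is_deaminated()` flags fragments with a C→T in the first three or last
three read positions; `filter_deaminated()` keeps only those. With the
default damage model roughly a third of endogenous molecules carry such a
mismatch, against ~1–2% of contaminants, so the retained set is strongly
enriched — the package's decontamination step.

`mask_terminal_t()` then replaces ALL T bases (not only those over a
reference C) in the three terminal read positions with `N`, so that
deamination-derived T's cannot enter the consensus or be mistaken for
diagnostic states. Masking every terminal T is the literal, conservative
choice; its cost — genuine terminal T alleles are lost and must be
recovered from fragments covering the position internally — is accepted
and documented.

## Consensus calling

`build_pileup()` counts A/C/G/T per position (N contributes nothing;
origin-spanning fragments wrap). `call_consensus()` calls the majority
base where coverage ≥ 5 and support ≥ 80%, both boundaries inclusive
("at least"); the support comparison uses a 1e-9 slack so that an exact
8/10 column is called rather than lost to floating-point representation.
Well-covered positions failing only the support rule are reported as
heteroplasmy candidates with their counts — reported, never called: an
88C/29T column at coverage 117 stays `N`. No automatic homopolymer logic
exists; a manually curated region can be applied explicitly via
`patch_consensus()`, which records the override in the position status.

## Contamination estimation

Diagnostic positions are those where the called consensus differs from
every panel member (consensus-N or panel-N positions excluded). Each
(fragment, covered diagnostic position) pair is one observation — a
fragment contributes once per diagnostic site it covers; observations are
pooled across sites because a ~55-bp fragment cannot span two sites that
lie kilobases apart. Observations matching a panel state count as
contamination; those matching the endogenous state as endogenous; `N` and
third alleles are excluded and reported separately as putative
errors/damage. The proportion carries a Wilson 95% interval (chosen over
Wald for its small-count behaviour).

Two procedural points matter:

* **Masking precedes estimation.** Deamination flags are computed on
  unmasked fragments, but both the all-fragment and deaminated-only
  estimates are taken on terminal-T-masked fragments. Without masking,
  terminal C→T damage at sites where the derived state is C and the
  ancestral state is T systematically inflates the estimate.
* **Pooled observations are treated as independent**, which holds when
  diagnostic sites are farther apart than a fragment length — true at
  full mitochondrial geometry. On short toy genomes with randomly planted
  sites this can fail (one fragment covering two sites yields correlated
  observations), which is why the calibration-style simulation tests run
  at L = 16,569.

`contamination_before_after()` contrasts the all-fragment estimate with
the deaminated-only one; a sharp drop is the expected signature of
present-day contamination, and its absence (when contaminants are as
damaged as the endogenous component) is itself informative.

## The molecular clock

`count_private_substitutions()` counts called positions differing from a
root haplotype, optionally restricted to positions also differing from
every panel member; `N` positions are uncomparable and reduce the
effective site count `L_eff`, which (rather than the fixed genome length)
enters the clock to avoid bias from masked regions. Under a Poisson model
with rate μ substitutions/site/year, `t̂ = k / (μ · L_eff)`; with k = 10,
μ = 2.67e-8 and L = 16,569 this gives ≈ 22,600 years. The interval
transforms the exact (Garwood) Poisson bounds on the expected count,
`[qgamma(α/2, k), qgamma(1−α/2, k+1)]`; for k = 0 the lower bound is 0
and the upper bound reduces to `−ln(α/2)/(μL)`. These pure-count bounds
(≈ 10,800–41,600 years for k = 10) are deliberately wider than
tree-based posteriors that add information from related lineages; when a
rate interval is supplied the envelope over it is reported as well, and
the package claims neither interval matches any particular published
bracket.

## Radiocarbon arithmetic and calibration

The QC helpers are exact arithmetic: atomic C:N from a molecular formula
(hydroxyproline C5H9NO3 → 5.0) or from mass percentages (weights 12.011,
14.007); percent yield to one decimal; fraction modern
`F14C = exp(−age/8033)` with the Libby mean life, the constant that
defines conventional ages.

`calibrate_c14()` maps an age ± σ through a tabulated curve: on a 1-year
calendar grid the posterior mass is
`∝ exp(−(age − μ(θ))² / (2(σ² + τ(θ)²)))` with the curve linearly
interpolated, under a flat calendar prior, normalized on the grid. The
highest-posterior-density selection takes grid years in decreasing density
order (ties toward older ages) until the target mass is reached — provably
the minimal selection — and contiguous runs are reported with bounds
rounded outward to 10 years, the convention of standard calibration
software. The default probability is 0.954 (the 2σ convention of that
software; 0.95 is a parameter away). A warning is raised when
non-negligible mass is truncated at the curve edge. With a noiseless
identity curve the posterior is exactly the measurement Gaussian, so the
HPD must reproduce Gaussian quantiles to grid resolution — the package's
built-in correctness check, independent of any curve file. The published
IntCal curve files are not shipped; `read_calibration_curve()` parses
their `.14c` dialect (comment lines, comma or whitespace separation, first
three numeric columns) so a downloaded file can be used directly.

## Pipeline and reproducibility

`run_pipeline()` executes: simulate/ingest → length filter → duplicate
fuse → per-library damage profiles → deamination filter → mask → pileup →
consensus (→ optional patch) → diagnostic positions → contamination
before/after → clock (→ optional calibration), and returns a single
report whose per-library block mirrors the standard per-library accounting
(unique fragments, coverage, terminal and conditional C→T, contamination
on all vs deaminated-only fragments). Every random stage is driven by one
integer seed; a fixed configuration reproduces the report byte for byte.
With `out_dir` set, stage artifacts (fragment TSVs, consensus FASTA,
report JSON) are persisted so any stage can be re-run from its inputs.

## Problem sizes used in the test suite

Chosen as the smallest sizes at which each property is statistically
sharp: hand-built fragments for exact counting oracles; mixtures of
5,000–10,000 fragments on 2,500–3,000-bp genomes for enrichment and
profile properties; the end-to-end recovery and Wilson-coverage batteries
at full 16,569-bp geometry (30,000 and 16,000 fragments; 5 and 100
replicates respectively), where consensus recovery is required at ≥ 99.9%
of called positions with all planted substitutions found, and the
interval-coverage checks at ≥ 93/100.

## Known limitations

Gapless fragment model (indel-containing alignments are dropped, with a
count); no quality-aware calling; no likelihood-based contamination or
damage-parameter estimation; no G→A handling for double-stranded
libraries; the consensus patch hook records manual curation but cannot
reproduce it; calibration supports single dates only (no phases or
reservoir corrections).
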