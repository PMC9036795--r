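---
title: "Methods: genome comparison statistics and 13C metabolic flux analysis"
author: "komaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome comparison statistics and 13C metabolic flux analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(komaflux)
```

komaflux bundles two analysis arms that meet in the biology of
*Komagataella* (syn. *Pichia pastoris*) yeasts: quantifying how divergent
the genomes of the different species are, and demonstrating — via ¹³C
isotope labeling — that these yeasts assimilate D-xylose through the
oxidoreductase pathway (xylose → xylitol → xylulose → xylulose-5-phosphate,
feeding the non-oxidative pentose phosphate pathway). This vignette explains
the models and procedures, the tunable parameters, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## Genome comparison statistics

Whole-genome aligners (minimap2, nucmer) report *matches*: locally aligned
regions between a query assembly and a reference. komaflux consumes their
tabular outputs (PAF via `read_paf()`, `show-coords -qldcoHT` via
`read_coords()`) and normalises everything to one convention: 0-based,
half-open intervals with `start < end` and an explicit strand. All
downstream interval arithmetic assumes this convention.

Matches are filtered before any statistic is computed: the analysis filter
keeps matches with mapping quality > 0 spanning at least 1 kbp
(`filter_matches()`, defaults `min_len = 1000`, `min_mapq = 1`), while
synteny-plot exports use a 10 kbp display filter (`link_table()`). Every
filter logs read/kept/dropped counts to the run log (`kf_run_log()`) so the
per-chromosome match counts in the summary tables can be audited.

Per reference chromosome, three statistics are reported:

* **Weighted identity** (`weighted_identity()`): each match's identity is
  weighted by its match length, `100 * sum(id_i * len_i) / sum(len_i)`.
  "Match length" is the *reference* span — the tables are organised by
  reference chromosome, and query spans can differ through indels.
* **Coverage** (`coverage_fraction()`): the covered fraction of the
  chromosome. Overlapping match intervals are merged (an `IRanges` union)
  before summing, because coverage is a property of the covered *set*; this
  makes the statistic invariant to splitting a match in two.
* **Match count** per chromosome.

Contigs are assigned to chromosomes (`assign_contigs()`) by the largest
summed matched length; orientation is the strand carrying the majority of
matched bases; ordering along the chromosome uses the length-weighted median
match position. A contig whose winning chromosome holds less than 50% of
its matched bases is flagged ambiguous but still assigned; the threshold is
an argument. Assembly metrics (`assembly_metrics()`) implement the
conventional N50: the length of the contig at which the cumulative
descending-sorted length first reaches half the assembly size, with the
rank of that contig reported as the "N50 number".

## Sketch distances and the least-squares tree

Genome-scale distances use bottom-s MinHash sketches of canonical k-mers
(`sketch()`, defaults `k = 21`, `s = 1000` — the defaults of the standard
sketching tool, chosen because no other values are documented for this kind
of analysis). The Jaccard index `j` of two genomes is estimated on the
merged bottom-s sketch of the union, and converted to a distance by

$$d = -\frac{1}{k}\,\ln\frac{2j}{1+j}.$$

Disjoint sketches (`j = 0`) get the capped distance 1 — the logarithm is
undefined there, and a bounded distance keeps tree fitting finite. Hashing
is a 64-bit mix of the 2-bit-packed canonical k-mer (compiled code);
k-mers overlapping non-ACGT characters are skipped and counted.

Trees are fitted to distance matrices by weighted least squares with the
Fitch–Margoliash criterion (weighting power 2):

$$\min_{b \ge 0} \sum_{i<j} \left(\frac{d_{ij} - p_{ij}(b)}{d_{ij}}\right)^2,$$

where `p_ij` is the tree path length. For a fixed topology this is a
nonnegative least-squares problem on the path incidence matrix
(`evaluate_tree()`, solved with `pracma::lsqnonneg`). Negative branch
lengths are forbidden by construction — classic implementations allow them
by default; we prefer the constrained variant because negative lengths have
no evolutionary interpretation, and document the difference here. Zero
off-diagonal distances would put infinite weight on a pair; they are
replaced by a configurable epsilon (default 1e-6) with a warning.

Topology search (`build_tree()`) is stepwise addition under `n_jumbles`
seeded random taxon orders (default 10, jumble seed 23893) — each taxon is
placed on the criterion-minimising branch — followed by
nearest-neighbour-interchange passes until no swap improves the criterion;
the best tree over all jumbles is returned. NNI is used rather than the
wider subtree-pruning moves of classic software; for the problem sizes this
package targets (around a dozen taxa) an exhaustive enumeration oracle in
the test suite confirms the search attains the global optimum at n = 5 and
recovers generating topologies on additive matrices up to n = 8.

## The stoichiometric model and its fixture

`read_model()` parses a CSV dialect in which every reaction carries a
carbon atom transition map, e.g.
`X5P (abcde) + R5P (fghij) -> GAP (cde) + S7P (abfghij)`. Letters are
unique per side and must balance across sides (carbon conservation is a
parse-time error). Metabolite roles are inferred from topology: never
produced → external substrate, never consumed → sink, otherwise balanced
and subject to the steady-state constraint `S v = 0`.

The packaged network (`komagataella_model()`,
`inst/extdata/ccm_xylose_model_synthetic.csv`) is a **synthetic
reconstruction** of a yeast central-carbon model: the oxidoreductase xylose
block (xylose and xylitol transport, xylose reductase, xylitol
dehydrogenase, xylulokinase — 5 reactions, tagged `xylose_extension` with
aliases R25/R48–R50/R59), the non-oxidative PPP (two transketolase steps
and transaldolase with standard atom maps), the oxidative PPP
(G6P → 6-phosphogluconate → Ru5P + CO₂, releasing C1), glycolysis run
gluconeogenically up to glucose, the pyruvate node (PDH, pyruvate
carboxylase), a lumped TCA cycle, a CO₂ balance with sink, and
per-precursor biomass drains. Lumping choices: PGI/FBA/GAPDH each lump
adjacent fast steps; CS lumps citrate synthase through isocitrate
dehydrogenase (the released CO₂ derives from the oxaloacetate C1, per the
standard mapping); succinate scrambling is omitted from the lumped TCA
return — a documented simplification that affects only OAA/AKG positional
detail, not the pathway-level conclusions the fixture supports. The
fixture is a documented reconstruction rather than a redistribution of any
curated model file; conventional reaction ids are kept as aliases so the
extension block is recognisable.

Reversible reactions are parameterised as net + exchange fluxes; exchange
coordinates map through `x/(1-x)` from [0, 1) to [0, ∞) during fitting so
the optimizer works on a bounded box.

## EMU simulation and the isotopomer oracle

Steady-state mass isotopologue distributions (MDVs) are simulated with the
elementary-metabolite-unit decomposition (`emu_decompose()`,
`simulate_mdv()`): the minimal set of carbon-position subsets reachable
backward from the requested metabolites is traced through the atom maps,
layered by size, and solved size-by-size as small dense linear systems;
condensation reactions contribute convolution source terms. The
decomposition is compiled once into index arrays (the assembly plan), so a
single simulation is index arithmetic plus a handful of dense solves — this
is the hot loop of flux fitting. Isotopic steady state is assumed
throughout (stationary MFA; a 10-day labeling cultivation amply justifies
it), and pools are assumed well mixed, so joint substrate labeling
factorises over pools.

Natural ¹³C abundance (0.0107) is included at unlabeled tracer positions by
default, so simulated backbone MDVs are directly comparable to
natural-abundance-corrected measurements; `natural = 0` disables it.

A pool that receives no production flux under a given flux vector — the
oxidative-PPP product 6-phosphogluconate when that branch carries zero flux
— has no steady-state labeling signal. The default behaviour
(`on_unreachable = "natural"`) reports such pools at the natural-abundance
background, emulating a stale metabolite pool whose material predates the
tracer; `on_unreachable = "error"` raises instead. The default is what
makes the zero-flux scenario physically meaningful: the measured
counterpart of an inactive pathway is an unlabeled pool, not a missing
peak.

`isotopomer_oracle()` is an independent verification route: it iterates the
full positional-isotopomer balances (2ⁿ states per metabolite) to a fixed
point, with no EMU reduction, and is feasible only for small networks.
One numerical subtlety: the unit-mass solution of the unnormalised
fixed-point map is only neutrally stable, and condensation cycles amplify
rounding-level mass loss multiplicatively, so each pool is projected back
to the probability simplex every sweep. The EMU route and the oracle agree
to ~1e-12 on the packaged network and to better than 1e-8 across randomized
flux draws in the tests.

## Isotope correction of GC-TOFMS data

Ethoxime-TMS derivatization adds C, H, N, O and Si atoms to each analyte;
their natural isotopes smear the measured mass-shift distribution of a
fragment ion. `correction_matrix()` builds, per fragment, the matrix whose
column j is the spectrum of a fragment with exactly j heavy backbone
carbons: a j-shifted delta convolved with the natural distributions of all
derivatization atoms (H, N, O, Si, S and the non-backbone carbons —
backbone carbons are deliberately *not* corrected, so an unlabeled
metabolite reports its natural backbone binomial). The isotope table is the
IUPAC representative composition; ¹³C is 0.0107, which is also the 1.1%
(at one decimal) unlabeled-biomass baseline reported by
`natural_13c_fraction()`.

`correct_cid()` solves `M x = A_raw` by nonnegative least squares rather
than matrix inversion — inversion can return negative isotopologue areas on
noisy data — and reports the NNLS residual for quality control. Relative
abundances follow `RA_i [%] = 100 A_i / sum(A_i)`. The truncation length
defaults to `n + 4` mass shifts; heavily silylated fragments (up to 7 Si in
the synthetic fragment table) leave up to ~1% of spectral mass beyond that
truncation, which the NNLS absorbs into the residual; `K` is configurable
where more of the tail matters.

The packaged fragment compositions (`synthetic_fragments()`) are
**synthetic reconstructions** with plausible ethoxime/TMS chemistry, not
instrument-derived formulas.

Quality control uses extracts grown on a 50:50 mix of unlabeled and fully
labeled carbon source: every metabolite's backbone then follows the
binomial with p = 1/2 — Pascal's-triangle row n — and `qc_pascal()` reports
the maximum absolute deviation from that expectation (default pass
threshold 5 percentage points, configurable).

## Flux fitting and confidence intervals

`fit_fluxes()` minimises the SD-weighted sum of squared residuals between
simulated and measured (corrected) CIDs over the scenario's free net fluxes
and exchange coordinates, subject to `S v = 0`, irreversibility (enforced
by quadratic penalty inside the objective, exact clipping at the optimum),
and the fixed constraints. The balance solve is affine in the free fluxes
and is precomputed as a base solution plus one direction per free flux.
Optimization is bounded L-BFGS-B with seeded multi-start (default 10
restarts).

The packaged scenario (`flux_scenario()`) normalises xylose uptake to 1,
fixes xylitol and glucose secretion and the nine biomass precursor drains,
and leaves the oxidative-PPP entry (`G6PDH`) as the free net flux — with
the drains fixed, every other net flux is implied by the balance (notably,
anaplerotic pyruvate carboxylase must exactly supply the OAA and AKG
drains). The drain and secretion values are chosen once to represent slow
growth on xylose with most carbon respired (≈61% of assimilated carbon
leaves as CO₂ in the base scenario) and a small xylitol overflow; they are
the generator's study conditions, not tuning knobs. The `"oxppp_zero"`
scenario sets the oxidative-PPP flux to exactly zero — the situation the
labeling experiment diagnosed — and the `"base"` scenario to 0.15.

Why this is identifiable: with a 1-¹³C pentose tracer, the label enters at
X5P C1 and reaches hexoses via transketolase; the oxidative PPP consumes
labeled G6P but releases the labeled C1 as CO₂, returning *unlabeled*
pentose to the pool. Oxidative-PPP flux therefore dilutes pentose-phosphate
labeling continuously (a smooth, identifiable signal), while
6-phosphogluconate itself acts as a near-binary indicator (labeled like G6P
whenever the branch runs, natural background when it does not).

`monte_carlo_ci()` resamples each corrected CID entry with Gaussian noise
at its SD, clips at zero, rescales to sum 100 (a documented deviation from
naive Gaussian resampling — CIDs must remain distributions), refits from
the point estimate, and reports percentile intervals (default 95%). SD
propagation matters here: `correct_measurements()` pushes the raw-area SDs
through the first-order least-squares map of the deconvolution, because the
NNLS amplifies measurement noise and using raw-scale SDs directly would
understate CID uncertainty (and demonstrably under-covers). A floor of 0.1
percentage points keeps weights finite.

A known limitation of percentile intervals centred on a point estimate:
under measurement noise the flux estimator carries a small bias (weakly
identified exchange coordinates interacting with the free net flux), so
empirical coverage of the nominal 95% intervals sits at the lower edge of
nominal — around 90% in the package's own calibration studies rather than
exactly 95%. This is a property of the percentile Monte-Carlo method
itself, not of its implementation, and is shared by the standard workflow
the method follows.

## Biomass enrichment accounting

`expected_total_13c()` implements two-pool mixing: growing
`fold`-fold builds fraction `f = (fold-1)/fold` of final carbon from the
tracer at its mean per-carbon enrichment (for 1-¹³C xylose at purity 0.99
that is (0.99 + 4×0.0107)/5 ≈ 0.207), the rest stays at the initial
enrichment. At the measured 1.85-fold increase this predicts ≈10.1% total
¹³C. The model deliberately ignores respiratory fractionation and carbon
turnover, and the package surfaces rather than hides that a simple mixing
expectation can disagree with a measured bulk enrichment — CO₂ loss alone
pulls the realised value below this bound, since respired carbon is
disproportionately tracer-derived.

## Synthetic data: what it emulates, and what it does not

The generators (`gen_genome_pair()`, `gen_tree_distances()`,
`gen_mfa_dataset()`, `gen_qc_sample()`) produce inputs with the statistical
structure each stage assumes, each paired with its ground truth, and are
byte-reproducible per seed. Defaults represent the study conditions: 4
chromosomes, point mutations at a programmed SNP rate (so weighted identity
has expectation `100(1-rate)` — e.g. 90% at rate 0.10, the regime of the
intermediate-divergence species pairs), contig-level inversions and order
shuffles; an 11-taxon distance preset with two sister species pairs, a
distant three-species clade and an outgroup, with within-species distances
of ~0.002 and an outgroup distance of ~0.3 on the sketch-distance scale;
and labeling data generated by simulating MDVs from known fluxes, pushing
them through each fragment's correction matrix, scaling to ~10⁶-area peaks
and adding Gaussian noise at 0.5% of each fragment's largest peak.

Limits worth keeping in mind: genome pairs have uniform base composition,
no repeats, and rearrangements at contig granularity, so contig assignment
is easier than on real assemblies with repeat-induced ambiguous matches;
match tables are constructed directly rather than produced by an aligner,
so aligner-specific artefacts (split matches, overlapping segments) appear
only where tests construct them; labeling noise is independent Gaussian per
isotopologue, whereas real GC-TOFMS errors correlate across a peak group;
and the fragment chemistry is plausible but synthetic. Passing tests
therefore demonstrate correctness of the computational machinery under its
stated assumptions, not robustness to every artefact of real instruments
and real genomes.

## Problem sizes and determinism

The test-suite and acceptance-script problem sizes are chosen to exercise
each claim at full strength while keeping a complete run lightweight:
1 Mbp synthetic genomes for identity statistics; 100 seeded additive-matrix
trials (4–8 taxa) plus an exhaustive 15-topology oracle at n = 5 for the
tree search; 20 randomized flux draws for the EMU-vs-oracle comparison;
noise-free end-to-end fits for parameter recovery; and a 50-replication
coverage study of the Monte-Carlo intervals at 20 inner resamples each
(the package default of 1000 resamples is for production fits; percentile
intervals from 20 warm-started refits are sufficient to measure coverage).
Every stochastic step takes an explicit seed, and seeded runs are
bit-reproducible.
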