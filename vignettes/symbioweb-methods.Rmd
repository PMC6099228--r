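---
title: "Methods: endosymbiont-structured parasitoid networks in symbioweb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endosymbiont-structured parasitoid networks in symbioweb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system and the questions

Cereal aphids (*Sitobion avenae*) commonly carry heritable facultative
bacterial endosymbionts — *Hamiltonella defensa* (Hd), *Regiella
insecticola* (Ri) and the X-type symbiont (PAXS) — that can kill the eggs
and larvae of hymenopteran parasitoids developing inside the aphid.
`symbioweb` implements an analysis chain for individual-level field surveys
in which every collected aphid and mummy is screened molecularly for
endosymbionts, primary parasitoids and hyperparasitoids. The chain answers
three kinds of question:

1. **Rates.** Does endosymbiont infection differ between living
   unparasitized aphids, living parasitized aphids and mummies? A deficit of
   infection in mummies, with no deficit in living parasitized aphids, is
   the signature of protection acting on parasitoid *survival* rather than
   on oviposition choice.
2. **Community composition.** Do primary and hyperparasitoid assemblages
   differ between uninfected, Hd-infected and Ri-infected hosts, beyond
   what sampling date, plant fertilization and landscape complexity explain?
3. **Network structure.** Does the specialization of the
   primary-hyperparasitoid food web increase when endosymbiont infection is
   common?

## Operational definitions and filters

A sample is *primary parasitized* if it is a mummy (mummification proves
parasitism) or a living aphid with a molecular primary-parasitoid
detection. *Hyperparasitism* is the detection of a hyperparasitoid in a
primary-parasitized sample; hyperparasitoid DNA in a living unparasitized
aphid is excluded by definition (and counted in a diagnostic attribute).
Infection classes are uninfected, Hd-only, Ri-only and superinfected
(both); PAXS is carried in the schema but ignored for classing because it
is never detected in this system. Superinfected samples are excluded from
community analyses by default because they are too rare (&lt; 1%) to
estimate effects.

Community tables apply two strict inclusion filters before analysis:
species observed **more than 5** times in total, and plots with **more
than 3** molecularly analysed individuals. The community unit defaults to
plot x sampling date x infection class. The unit is a genuinely open
choice — the field protocol does not dictate it — and `build_abundance_table()`
exposes `unit_by` so coarser units (plot x date, plot) can be used; the
default splits by infection class because the downstream ordination asks a
question *about* infection classes and needs them as separate rows.

## The synthetic field study

`generate_study()` simulates the full hierarchical design: 13 fields (7 in
complex, 6 in simple landscapes), 8 plots of 6 x 6 m per field with
alternating fertilization, two sampling dates (wheat milk and dough
ripening), and collection-tube (colony) clustering. Defaults are the study
conditions: 20-50 living aphids per plot and date in ~4 tubes, 5-15 mummies
per plot and date, living-aphid infection probabilities Hd 0.401, Ri 0.395,
superinfection 0.0089.

**Random effects and calibration.** Infection probabilities vary between
fields, plots and colonies through logit-normal random effects
(`sigma_field` 0.3, `sigma_plot` 0.2, `sigma_colony` 0.4 by default —
moderate clustering of heritable symbionts within colonies, chosen once as
field-realistic; the field protocol reports no variance components). A
logit-normal effect shifts the *marginal* rate away from `plogis` of the
mean, so the logit mean is calibrated numerically (Gauss quadrature +
root finding) to make the marginal living-aphid infection rate equal
`pi = pi_hd + pi_ri + pi_super = 0.8049` exactly.

**The protection mechanism.** Mummies are generated from the attacked-aphid
stream with the survival odds of the immature parasitoid multiplied by
`s_protect` in infected hosts. Under a homogeneous infection probability
`pi` this gives an infected fraction among mummies of

$$\frac{\pi s}{\pi s + 1 - \pi},$$

which equals 0.387 at the default `s_protect = 0.153` — the survival ratio
that reproduces the observed ~38% mummy infection from ~80% living-aphid
infection. Under colony heterogeneity the naive per-colony odds tilt would
inflate the marginal mummy rate (Jensen's inequality; +2.6 percentage
points at the default variances), so the tilt is applied on the calibrated
marginal scale: the mummy stream's logit mean is calibrated so that the
closed form holds exactly in expectation, while colony random effects still
cluster mummy infection. `fert_protect_boost` multiplies the survival ratio
in fertilized plots; it defaults to 1 (off) so that the aggregate mummy
expectation stays at the closed-form anchor. Setting `s_protect = 0.188`
with `fert_protect_boost = 0.595` reproduces the observed fertilized /
unfertilized mummy split (31.6% / 43.7%) for users who want that contrast
switched on.

**Parasitism and the hyperparasitoid association.** Living aphids carry a
Bernoulli primary-parasitoid detection with class-specific probability
(defaults near 11-13%, slightly higher for Hd than Ri hosts); primary taxa
follow class-specific composition vectors derived from the observed
per-class mean abundances of the ten primary taxa. Hyperparasitism on
parasitized samples has class- and date-specific probabilities (uninfected
hosts ~16-22%, infected hosts ~8-15%, with the infected deficit growing at
the second date). The hyperparasitoid taxon is drawn from a
primary-taxon association matrix; for infected hosts the association row is
sharpened (`hyper_concentration_fe = 3`, each row raised to that power and
renormalized). This knob is the planted mechanism behind the
specialization-infection relationship: when infection is common,
hyperparasitoids concentrate on their preferred primary host, and resampled
webs with a high infected share are more specialized. Setting all
association rows equal and the concentration to 1
(`config_no_association()`) removes the link entirely, which is the null
configuration used in the engine's tests.

The generator emulates design structure, clustering and effect mechanisms —
not aphid population dynamics, spatial layout, aphid genotype, endosymbiont
strain/phage variation, or detection error other than a fixed probability
(0.85) of identifying the primary taxon inside a mummy. Passing tests on
synthetic data therefore validate the *statistical machinery* under known
truth; they cannot validate the biology of any particular field dataset.

## Rate estimation: hierarchical bootstrap

The nested design (fields / plots / tubes) makes individuals from one
colony non-independent. Instead of refitting the original binomial
mixed-effects models (routine off-the-shelf machinery), `estimate_rates()`
quantifies uncertainty with a hierarchical bootstrap that mirrors the
nesting directly: resample 13 of 13 fields with replacement, then plots
within each drawn field, then colonies within each drawn plot, keeping
individuals within a colony together. This is a deliberate, documented
methodological substitution: it reproduces the inferential structure of the
random-effects specification transparently and makes the interval
construction visible. Point estimates are pooled proportions and do not
depend on the bootstrap; intervals are percentile intervals at 75% and 95%,
mirroring the box/whisker convention used for reporting. Contrasts reuse
the *shared* bootstrap replicates (paired at the field draw), with
two-sided p-values `2 min(P(d<=0), P(d>=0))` under the +1 convention and
Benjamini-Hochberg FDR correction across the contrast family.

## Community analysis

`bray_curtis()` computes Bray-Curtis dissimilarities (via `vegan::vegdist`).
`simper_bc()` decomposes the mean between-group dissimilarity into
per-species contributions — for a unit pair (j, l) the species component is
`|y_kj - y_kl| / sum_s (y_sj + y_sl)`, averaged over all between-group
pairs — so contributions sum to the mean between-group dissimilarity
*exactly*, an invariant the tests assert to 1e-12. Significance per species
is a one-sided ("greater") label-permutation test with the +1 correction:
it asks whether the species discriminates the groups more than chance
relabelling would.

`dbrda_bc()` implements partial distance-based redundancy analysis from
first principles: Gower double centering of `-D^2/2`, eigendecomposition,
site coordinates on positive axes scaled by the square root of the
eigenvalue. Negative eigenvalues (Bray-Curtis is non-Euclidean) are
*dropped*, not square-root corrected, matching the default constrained
ordination behaviour of the ecology toolchain the approach comes from;
their total magnitude is reported so distortion can be judged. Conditioning
variables are removed by residualizing the coordinates on `[1, Z]`;
constrained inertia is the squared-fitted-value sum from regressing the
residualized coordinates on `[1, X]`. All proportions are quoted relative
to total positive inertia *before* conditioning, and the conditioned /
constrained / residual decomposition is exact. Because nested partial
models can be quoted against either denominator, the object retains the
raw inertias so either convention can be reported. The permutation test
permutes rows of the residualized coordinates (reduced-model scheme) and
recomputes the pseudo-F. On Euclidean distance matrices the whole
construction collapses to ordinary linear redundancy analysis, which is the
oracle the tests compare against at 1e-6.

## The H2 entropy family

Network-level specialization of a bipartite count web `a` with total `m`
uses the joint Shannon entropy `H2 = -sum p_ij ln p_ij`, `p_ij = a_ij/m`
(natural logarithms throughout), standardized by the extreme entropies
achievable with the observed marginal totals:

$$H_2' = \frac{H_{2max} - H_2}{H_{2max} - H_{2min}} \in [0, 1],$$

1 for a perfectly specialized one-to-one web, 0 for the
independence-like allocation. The default `integer` mode evaluates the
bounds over *integer* matrices with the observed marginals, the convention
for count webs; `continuous` mode uses the independence entropy
`H(r/m) + H(c/m)` for the maximum and real-valued greedy concentration for
the minimum.

Integer-mode bounds are entropies of actual realizable matrices, so both
are inner bounds of the exact extrema by construction:

* **H2max** is exact: maximizing entropy is minimizing the convex function
  `sum a ln a` over the transportation polytope, whose continuous optimum
  is the expected-count table `r_i c_j / m`; the integer optimum is found
  by successive shortest-path augmentation with convex unit costs (one
  interaction at a time along the cheapest row-to-column path, allowing
  reallocation through residual arcs).
* **H2min** (maximal concentration) is convex *maximization*, so a
  portfolio of three greedy variants is used and the most concentrated
  result kept: the classical pairing of the largest remaining row marginal
  with the largest remaining column marginal (ties to the lowest index), a
  variant that first forms perfect blocks from exactly matching marginals,
  and a one-step lookahead on the largest row. Against exhaustive
  enumeration of *all* integer matrices for every pair of marginal
  partitions with m <= 12 (up to four parts), the portfolio's worst
  observed gap is numerically zero; the classical greedy alone can be off
  by ~0.2 nats on skewed marginals, which is why the portfolio exists.

Degenerate webs whose marginals force a single allocation (one row, one
column, or `H2max - H2min < 1e-12`) return `H2' = 0` by convention — the
resampling engine can legitimately draw such webs and needs a total
function. The exhaustive enumerator itself (`exact_bounds_oracle()`,
budgeted at m <= 12) is implemented independently in R and serves only as
a test oracle for the C++ production path.

## Resampled food webs

Hyperparasitism is rare, so per-field webs differ greatly in size, and raw
network metrics are size-biased. The resampling device fixes the size:
each of `n_webs` (study value 200,000) webs consists of `web_size` (100)
interactions drawn uniformly with replacement from the pooled interaction
list; H2' is computed per web in integer mode, and every binary covariate
(infection, fertilization, landscape complexity, date) is summarized as
the *proportion* of drawn interactions carrying it. A sample with several
primary and hyperparasitoid detections contributes all pairs (a
`multiplicity = "single"` switch keeps one pair per sample); samples whose
hyperparasitoid lacks an identified primary taxon cannot form a link and
are counted, not silently dropped. Webs stream from one seeded RNG
sequence, so memory is flat in `n_webs` and the first k webs are unchanged
when `n_webs` grows.

Ordinary least squares then relates per-web H2' to the proportional
covariates. The candidate space is all subsets of the four main effects
plus the infection x date and infection x fertilization interactions
(marginality respected; the full factorial interaction space is excluded
as uninterpretable at this design size), selected by minimum AIC. Because
resampled webs are statistically dependent (they share source
interactions), p-values from this regression would be meaningless; only
effect sizes and directions are reported, alongside the full-model R², the
single-predictor R² per covariate and the Pearson correlation between H2'
and the infection proportion — both attribution conventions are reported
because "variance explained" for correlated proportions is not unique.

## Numerical choices and problem sizes

* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; the pipeline derives per-stage seeds from one master
  seed and logs them in its manifest, so reruns are bit-identical.
* Permutation p-values use the +1 convention everywhere and can never be 0.
* Degeneracy threshold for H2': 1e-12 on the entropy span; dbRDA eigenvalue
  threshold: 1e-9 relative to the largest magnitude.
* The test-suite problem sizes are chosen to exercise each property at
  desk scale: exhaustive entropy enumeration to m = 12, 10,000-20,000
  resampled webs, bootstrap B = 200-1000, permutation tests at 200-999.
  The pipeline defaults (`run_config()`) use 10,000 webs; the full
  200,000-web study configuration is a parameter change, not a code path
  change.

## Known limitations

* The hierarchical bootstrap with 13 fields is asymptotically justified in
  the number of fields, which is small; percentile intervals can undercover
  slightly at the field level (the coverage test asserts >= 85% observed at
  the nominal 95% level).
* H2min is heuristic (inner bound); it is numerically exact on the
  exhaustive m <= 12 suite but carries no optimality proof for arbitrary
  marginals.
* SIMPER contributions are decompositions of dissimilarity, not effect
  sizes; a species can contribute strongly through within-group variance
  alone, which is exactly why the permutation test accompanies the ranking.
* The generator's effect mechanisms are parametric stand-ins: they
  reproduce the direction and rough magnitude of the field patterns, not
  any particular dataset.
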