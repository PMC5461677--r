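---
title: "Methods: molecular food-web inference for psyllid-parasitoid communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular food-web inference for psyllid-parasitoid communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psyllidwebs)
```

## The problem

Parasitoid wasps of *Eucalyptus*-feeding psyllids (genera *Cardiaspina* and
*Spondyliaspis*) are morphologically cryptic: a handful of recognisable
morphospecies can hide many genetically distinct species, and their trophic
roles — primary parasitoid of the psyllid, hyperparasitoid of another
parasitoid, or heteronomous hyperparasitoid with different hosts for the two
sexes — cannot be observed directly because development happens inside a
psyllid "mummy". `psyllidwebs` implements a complete analysis chain for this
setting:

1. **seqdiv** — p-distance divergence matrices between host populations from
   aligned sequences (mitochondrial cytb and similar short loci);
2. **delimit** — putative species delimitation by divergence-threshold
   clustering, morphotype sex-matching, and thelytoky flagging;
3. **primers** — design of morphospecies-specific primer pairs for multiplex
   PCR, with in-silico validation;
4. **trophic** — the forensic core: classify trophic roles from which species'
   DNA co-occurs in post-emergence mummies;
5. **cophylo** — cophylogenetic congruence tests (ParaFit, Hommola) and
   exhaustive event-based reconciliation for small trees;
6. **synth** — a synthetic-data generator that reproduces the statistical
   structure every other module assumes, so the pipeline is fully testable
   without any external data.

## Divergence and species delimitation

`p_distance()` is the uncorrected proportion of differing sites, in percent,
with *pairwise deletion*: any column where either sequence holds `-` or `N`
is excluded. The source tables do not state their deletion rule; pairwise
deletion is the common default of the distance software in this field and is
flagged here as a choice, not a fact about the original analysis.
`divergence_matrix()` aggregates all cross-population sequence pairs with
either `max` (matching the published "maximum divergence" tables) or `mean`.
The diagonal holds the within-population statistic — published tables carry
non-zero within-population values (0.3%, 0.9%, ...), so the package does not
force a zero diagonal; singleton populations report 0.

`single_linkage_partition()` delimits putative species as connected
components of the graph that links two populations whenever their divergence
is at or below the threshold. Single linkage (chaining) rather than complete
or average linkage mirrors the verbal logic of the study system: populations
a few tenths of a percent apart are conspecific, and chains of such links
form one species. The default threshold of **5%** for cytb sits in the
empirical gap of the system — conspecific populations diverge by at most
about 4.7%, heterospecific ones by at least 8.4% — and is a configuration
knob, not a constant. Missing comparisons (`NA`) contribute no edge.

A bPTP-style model-based delimitation is deliberately out of scope: the
threshold method reproduces the species *counts and memberships* of the
study system but cannot produce posterior delimitation probabilities.
Locus discordance (e.g. a nuclear locus merging species that the
mitochondrial locus separates) is not resolved by the package; per-locus
partitions are reported side by side and the user decides.

`infer_thelytoky()` flags all-female morphospecies as thelytoky candidates
only when at least `min_females = 5` females were collected; with fewer, the
absence of males is uninformative and the call is `undetermined`. The value 5
is our floor; the positive control in the bundled data has hundreds of
females and no males.

## Primer design and in-silico PCR

A *diagnostic site* is an alignment column where every target sequence
carries one unambiguous base that no non-target sequence carries.
`design_species_primer()` scans deterministically (leftmost forward start,
then shortest amplicon, then shortest primers) for a pair in which **each
primer has at least two diagnostic sites among its five 3'-terminal
positions**, the amplicon is 145–400 bp, and the two primers' melting
temperatures differ by at most 2 °C. Primer sequences come from the majority
consensus of the target alignment. Tm uses the Wallace rule
(`2(A+T) + 4(G+C)`): the primers are short, and Tm is used comparatively for
panel assembly, not thermodynamically.

`assemble_multiplex()` packs pairs into the fewest PCR stages such that
amplicon lengths within a stage differ by at least 30 bp (distinguishable on
a gel; the 30 bp default generalises the study's observed need to split its
panel into two stages) and the Tm spread stays within 4 °C. First-fit
decreasing is provably minimal on the panel sizes involved (tests compare
against exhaustive set-partition search up to six pairs).

`in_silico_pcr()` scans every template offset: a primer binds where its
3'-terminal pentamer matches exactly and at most 2 mismatches occur
elsewhere. The exact-pentamer rule operationalises the diagnostic-site
constraint — a non-target template disagrees at ≥ 2 of those 5 positions by
construction, so designed panels are sound against their own design
alignment (a property the tests assert, and which the acceptance suite
checks on 50 random template mixtures).

## Forensic trophic classification

A post-emergence mummy is **informative** if both psyllid DNA and the
emerged wasp's DNA were detected; only informative mummies say anything
about additional occupants. `detection_success()` reports the informative
percentage per (host, species, sex) stratum, rounded half-up (the published
table prints 63% for 5/8).

`classify_trophic_roles()` works per sex first:

* **primary** — at least a `consistency` fraction of informative mummies
  contain no non-emerged parasitoid DNA;
* **hyperparasitoid of X** — at least that fraction contain exactly one
  non-emerged species X, and the emerged species never appears without
  another parasitoid;
* anything else, or fewer than `min_n = 2` informative mummies, is
  **undetermined** — a first-class outcome, never an exception.

`consistency` defaults to **1.0** because in the motivating data the primary
host's DNA was present in hyperparasitised mummies on every occasion; it can
be lowered to 0.9 for noisier panels but not below 0.5. After the per-sex
pass, a morphospecies whose females classify primary and whose males
classify hyperparasitoid of some primary X is re-labelled **heteronomous
hyperparasitoid**, with prey recorded per sex — this two-pass order is what
makes heteronomy expressible at all. `min_n = 2` matches the smallest
stratum the original screen accepted and is acknowledged as arbitrary.

`validate_assignments()` cross-checks that every hyperparasitoid's prey
classifies primary in the same host system; prey strata that are absent or
undetermined are not violations (absence of evidence is not a
contradiction), only determinate conflicts are reported. The method cannot
detect self- or conspecific superparasitism: a conspecific second occupant
leaves no distinguishable signal.

## Cophylogenetic tests

`patristic_distances()` (branch-length path sums), `parafit_test()` and
`hommola_test()` operate on rooted trees with branch lengths plus a binary
parasite-by-host association matrix. Parasites attacking several hosts
contribute one link per host (pseudo-tip expansion) to the link-based test.

**ParaFit.** Host and parasite distance matrices are embedded by principal
coordinates (eigen-decomposition of the Gower-centred `-D²/2`; axes with
non-negative eigenvalues kept; if the discarded negative mass exceeds 5% of
the positive mass a warning is recorded in the result). The global statistic
is the sum of squared entries of `t(B_p) A B_h`. The null permutes each
parasite's host assignments — each row of `A` — independently, the published
test's null. P-values use the add-one estimator
`(1 + #{null ≥ obs}) / (1 + n_perm)` and so are never zero.

A subtlety worth stating plainly: with one-to-one observed links this null
resamples a *different* link distribution (rows independently) than the
observed one (a bijection), so ParaFit's null p-values are not uniform over
(0, 1] — their bulk is compressed — although the rejection tail is
calibrated: over 1000 null simulations the type-I error at α = 0.05 is
0.049 for ParaFit and 0.048 for Hommola (both inside the acceptance band
[0.03, 0.07]). Hommola's null — independent permutation of host labels and
parasite labels — is exchangeable with the observed bijection, and its
p-values test as exactly uniform. The test suite asserts exactly these two
properties, not more.

`n_perm` defaults to 10,000 as in the original analysis; the test suite runs
at 99–999 permutations for speed. Identical seed and inputs give identical
p-values.

**Event-based reconciliation.** `enumerate_reconciliations()` exhaustively
maps parasite internal nodes onto host tree nodes, subject to one
persistence rule: at each parasite divergence mapped to host node *h*, at
least one daughter lineage must remain inside the subtree of *h*; a daughter
mapped outside records a **host switch** and lands exactly at its target.
Within the subtree, a divergence that separates the daughters into the two
child subtrees of *h* is a **codivergence**; otherwise it is a
**duplication**. Every internal host node passed through without an event
costs one **lineage sorting/loss**. Mappings are scored and the solutions
maximising codivergence are returned, ties broken by fewer switches, then
duplications, then losses — the tie-break order is this package's
convention, since the reference implementation's internal ordering is not
published. Mirror trees with 1:1 links always yield exactly `n − 1`
codivergences and nothing else. The search is exponential and refuses trees
above `max_tips = 8`; polytomies are refused by default or arbitrarily
resolved on request (`polytomy = "resolve"`), because guessing the intent of
an unresolved node would silently change event counts.

## The synthetic world

The generator states a world and sticks to it:

* `simulate_host_tree()` — Yule pure-birth trees: with *k* lineages the wait
  is Exp(*k*λ), from *k* = 2 up to *n*, with the final interval reaching the
  present, so trees are ultrametric and mean root-to-tip depth is
  `Σ 1/(kλ)` for `k = 2..n` (a closed form the tests check).
* `simulate_parasite_evolution()` — the parasite rides host branches; at
  each host divergence it codiverges, dies (probability `p_loss`; lineage
  sorting — with `p_loss = 1` the system is flagged empty), or host-switches
  (probability `p_switch`) with one daughter jumping to a uniformly chosen
  contemporary host branch. Switching is uniform, not distance-weighted — no
  process model exists to justify weighting. At the root there is no
  external branch, so a drawn switch is realised as codivergence.
  Duplications are not simulated independently; `true_events$duplication`
  is always 0 (documented limitation).
* `evolve_sequences()` — Jukes–Cantor along branches using the exact
  transition kernel `P(change) = 3/4 (1 − e^{−4t/3})`, root drawn uniformly;
  the mean tip-pair p-distance matches `75(1 − e^{−4t/3})` % in expectation.
  JC69 is the simplest model that produces the divergence structure the
  delimitation module needs; richer models are out of scope.
* `simulate_divergent_populations()` — a cryptic-species complex with deep
  species splits (~0.15 substitutions/site, ≈ 14% expected p-distance) and
  shallow population splits (~0.01, ≈ 1%), reproducing the ≤ 2.6% within
  versus ≥ 8.4% between pattern of the real system.
* `simulate_mummy_table()` — per-stratum mummies whose psyllid and
  emerged-species detections are Bernoulli with per-species probabilities,
  while prey DNA within informative mummies is present with probability 1:
  detectability is noisy, the trophic signal itself is not. The
  role-recovery experiment uses 60 mummies per stratum with detection
  probabilities (psyllid 0.9, P1 0.2, others 0.9): the low-detection primary
  in the real screen was sampled at 12–182 mummies per stratum precisely
  because two informative mummies are needed for a call, and at 10 mummies a
  ~0.18 informative rate leaves that stratum undetermined in almost half of
  replicates — a sampling-depth fact, not an inference failure.

What a green test establishes: that the pipeline recovers *known* structure
from data generated under its own assumptions (independent detections, no
alignment error, no contamination, uniform switching, clock-like trees).
Real data violate most of these at some level; the bundled study tables are
therefore carried as a second, fully empirical test surface.

## Numerical and degenerate-input policy

* Divergence percentages live in [0, 100]; matrices must be symmetric with
  labels; `NA` means "not sampled" and never an implicit zero.
* Zero comparable sites between two sequences is an error, not NaN.
* Hommola with zero variance in either distance vector returns a flagged
  degenerate result instead of erroring.
* All permutation streams and generators are seeded; identical seed plus
  inputs reproduce outputs bit-for-bit.
* Ties in primer-design scanning are broken deterministically
  (leftmost/shortest first); consensus ties alphabetically.
* The pipeline records package version, a configuration hash (output
  directory excluded — where results land does not alter them) and the seed
  in every summary.

## Known limitations

* The delimitation surrogate cannot produce support values; counts and
  memberships only.
* The reconciliation enumerator is exact but exponential; eight tips is the
  practical ceiling, matching the size of the motivating system.
* Wallace-rule Tm is a ranking device; no dimer/hairpin screening, no
  degenerate bases.
* The mummy simulator draws detections independently per mummy; real PCR
  failures are correlated within extractions.
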