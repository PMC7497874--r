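---
title: "Egocentric and duocentric network methods in duonet"
author: "duonet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egocentric and duocentric network methods in duonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duonet)
```

## The measurement problem

Egocentric network surveys elicit a respondent's ("ego's") personal network
with a *name generator* — here, "name up to five people who are very
important to you" — followed, for each named person ("alter"), by questions
on their role, the supports they provide, and, for every unordered pair of
alters, whether and how often the two interact. The resulting alter-only
graph supports compositional measures (who is in the network) and
structural measures (how the network hangs together).

A *duocentric* network extends this to a matched respondent pair — a young
adult and a parent who completes a parallel survey about the people who
help them support that young adult. After resolving which named alters are
the same person, the two egocentric networks merge into one joint network
that captures the young adult's social ecosystem more completely than
either report alone, including the brokerage a parent provides to people
and resources outside the young adult's own roster.

`duonet` implements the full pipeline: survey I/O in a documented wide
format, the egocentric measure suite, exact-name alter matching, the
maximum-value merge with a discrepancy log, the duocentric measure suite
with its 75%-rule characteristics and social-capital "ADD" accounting, a
seeded synthetic cohort generator, and sociogram export with an MDS layout.

## Data model and conventions

An `ego_survey` holds the ordered roster (rank 1 = most important, at most
`roster_cap` alters, default 5), each alter's free-text role and its class
in {family, community, professional}, six binary support flags
(friendship, emotional, advice, financial, logistical, job), and one tie
report per unordered alter pair. Tie frequency is ordinal 0–3
(never / rarely / monthly / weekly or more); the survey instrument behind
this design asks "How often?" without fixing response options, so the
four-point scale is a documented package convention, configurable via
`freq_cap`. Every structural measure binarizes at frequency ≥ 1.

Two conventions matter throughout:

* **The ego is not a node.** The name generator ties the ego to every named
  alter by construction, so ego ties carry no information. Density,
  disconnection, and composition are always alter–alter quantities.
* **Density is undefined below two alters.** With `n < 2` there are no
  possible pairs; `network_density()` returns `NA` rather than 0. A
  two-alter network with no tie *is* defined and scores 0.

## Egocentric measures

For an alter network with `n` alters and `t` binarized alter–alter ties:

* network size `n` (ego excluded);
* density `t / (n(n-1)/2)`;
* role composition: percent of alters per role class (sums to 100);
* support prevalence: per support type, 100 × (providers) / `n`;
* family friendship: percent of *family* alters providing friendship — the
  denominator is the family alters only. Networks without family alters
  return `NA`; cohort means coerce that `NA` to 0 so that a subgroup
  naming no family reports a 0% mean rather than a missing value;
* disconnected members: alters with zero alter ties.

`cohort_summary()` averages the per-ego values (unweighted) and adds the
median network size. Density is averaged over the egos for which it is
defined; one-alter networks drop out of that mean rather than entering as
zeros, since their density is not a zero but a non-quantity.

Values are kept at full precision; printing rounds densities to two
decimals and percentages to whole numbers, matching field reporting
practice.

## Alter matching and the duocentric merge

Matching is exact on a normalized name key (case-folded,
punctuation-stripped, whitespace-collapsed): "J. Smith" and "j smith"
match, "Sue" and "Susan" never do. No fuzzy or phonetic matching is
attempted — false merges are more damaging in small rosters than missed
matches, and the study workflow this emulates resolved names manually.
Role class is consulted only when one survey holds several alters under
the same key; candidates that role agreement cannot pair uniquely raise an
ambiguity error, or with `on_ambiguity = "flag"` are left unmatched and
marked for a manual-review export.

`merge_duocentric()` unifies the rosters and resolves every doubly-reported
alter pair by the **maximum-value rule**: the merged ordinal frequency is
the larger of the two reports, and any disagreement is logged as a
discrepancy with both values and the resolved maximum. The rule is
symmetric (swapping who reported the higher value changes nothing) and
idempotent (merging a merged network's two projections reproduces it);
both properties are exercised in the test suite. Pairs only one respondent
could observe stand as reported; pairs neither could observe (a young
adult-only alter against a parent-only alter) are structurally unknowable
and are returned in an `unobserved` table rather than silently treated as
absent ties.

The parent respondent becomes a node only when the young adult named the
parent as an alter. A present parent node additionally gains
generator-implied ties to every alter on the parent's own roster — the
parent knows those people by construction. Implied ties are flagged,
excluded from all density and disconnection computations, and used only
where the merged frame needs them (the optional merged-frame centrality
below). The young adult's own generator-implied ties have no
representation because the young adult is never a node.

## Duocentric measures

Per-respondent size, density, and disconnected counts come straight from
the egocentric suite. The pair-level measures:

* **Overlap / unique members** count alters named by both respondents
  versus one. The parent node is counted in neither bucket: the parent
  belongs to both networks by construction as the ego of one of them, so
  a five-alter young-adult roster containing the parent contributes one
  overlap alter and three unique alters, not four.
* **Parent centrality** = (alters tied to the parent) / (alters − parent),
  computed on the young adult's own network: `NA` when the young adult did
  not name the parent. An optional `frame = "merged"` mode computes the
  same ratio on the merged node set with implied ties included; it has no
  per-respondent reporting counterpart and is labeled accordingly.
* **Five characteristics**, coded yes/no: parent-only alters present,
  youth-only alters present, parent network a subset of the young adult's,
  every overlap alter tied to ≥ 75% of the other merged alters, and parent
  tied to ≥ 75% of the other alters. The threshold is inclusive ("75% or
  more") and configurable. A pair whose parent was never named codes
  parent-high-centrality "no"; a pair with no overlap alters codes the
  overlap-high-tie characteristic "no"; an empty parent roster is a
  vacuous subset.
* **Social-capital configuration**: role and support percentages for each
  respondent's network, plus **ADD counts** — for each role class and
  support type, the number of *parent-unique* alters carrying it. ADD
  counts alters, not support instances, and runs only over parent-only
  alters, so a subset parent network adds nothing by definition.

## The synthetic cohort generator

No survey data are distributed; the generator emulates the study design so
every stage is testable from code. Its defaults are fixed study
conditions, not tuning dials:

* 17 egos; roster sizes 4 with probability 0.12, 5 with probability 0.88
  (mean 4.88, median 5 — a cohort pressed against the five-person cap);
* role mix 61 : 36 : 4 family : community : professional, normalized to a
  simplex (the reported rounded percentages sum to 101);
* support probabilities conditioned on role class, chosen once so that the
  implied overall prevalences land near the reported cohort profile
  (friendship and emotional support common, job support rare, family
  friendship well below overall friendship);
* role-block tie probabilities (family–family 0.95, family–community 0.5,
  family–professional 0.4, community–community 0.3, others 0.2),
  reproducing the family-closure motif — near-complete ties among family
  members — with sparser community connectivity;
* matched pairs for 3 of 17 egos; parent rosters of 2–4 alters; a
  parent-roster slot copies a young-adult alter (exact name string) with
  probability 0.5; the young adult names the parent with probability 2/3;
  a shared pair's duplicated tie report is flipped with probability 0.1.

Matched alters share exact name strings to exercise exact matching; an
optional `name_noise_prob` perturbs copied names with case/punctuation
noise that `normalize_name()` must undo. Generation is fully seeded:
the same `cohort_spec` yields byte-identical emitted files.

What the generator does *not* emulate: recall error in name generation
(the same person misspelled beyond punctuation), role misclassification
between respondents, systematic reporter bias (parents over- or
under-reporting ties), attribute-dependent tie formation beyond role
blocks, and any dependence between support flags. Passing
parameter-recovery tests therefore shows the pipeline is a consistent
estimator of the generator's own parameters — not that real survey data
meet these assumptions.

## Numerical and design choices

* Tie-breaks in matching are deterministic: keys are processed in roster
  order, parent-roster candidates in rank order.
* The merge generalizes the maximum-value rule from binary to ordinal
  frequencies (max of the two ordinals); binarization happens after
  merging.
* Layout: geodesic distance is undefined across components, so each
  connected component is scaled independently by classical MDS
  (`stats::cmdscale`) and satellite components — isolates included — ring
  the largest component at a radius that keeps bounding boxes disjoint. A
  single global embedding with a finite pseudo-distance was rejected
  because equal-sized components produce degenerate eigenvalues and
  collapsed coordinates. Layouts are deterministic; for graphs with exact
  symmetries the embedding is unique only up to rotation/reflection, so
  tests compare distance matrices, not raw coordinates.
* Degenerate inputs: empty rosters are valid surveys (all measures `NA` or
  0 as documented); an empty parent roster merges to the young adult's
  network with a vacuous subset code.
* Unmapped free-text roles classify to *community* (the residual informal
  category) with a warning, configurable to error.

Problem sizes in the shipped tests — 1,000 random instances for the
brute-force oracle suites and cohorts of 200–250 egos for parameter
recovery — were chosen to keep Monte-Carlo error well inside the ±3
standard-error acceptance bands while remaining quick on a single CPU.

## Limitations

The duocentric method itself is strictly two-respondent; merging three or
more reporters needs a different conflict model than pairwise maximum. The
maximum-value rule treats over-reporting as impossible, which is an
assumption, not a finding. Exact-name matching will under-merge real data
containing nicknames or spelling variants; the manual-review flag is the
intended escape hatch. Reported cohort statistics from any small
feasibility sample (17 egos, 3 pairs) characterize feasibility, not the
population; this package deliberately provides no inferential statistics
across subgroups.
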