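---
title: "Synteny-anchored reconstruction of visual opsin duplication history: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-anchored reconstruction of visual opsin duplication history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(opsinteny)
```

# The problem

The five vertebrate visual opsin subtypes (LWS, SWS1, SWS2, RH2 and the
rod opsin RH1) arose through some combination of tandem gene duplications
and the early vertebrate whole-genome duplications. Sequence phylogenies
alone cannot settle the order of those events: substitution rates vary
strongly among the paralogs and across lineages, and jawless and jawed
vertebrates do not share the same duplication history — both inherit the
first round (1R), after which the jawed lineage underwent a second round
(2R) while the cyclostome lineage underwent an independent genome
triplication, leaving it effectively hexaploid relative to the
pre-1R ancestor.

Gene *arrangements* carry the complementary signal. If two subtypes sit
side by side on the same strand within a short window in lineages that
separated half a billion years ago, the simplest explanation is a tandem
duplication that predates 1R. And if phylogenies of the *neighbouring*
gene families — concatenated per chromosome rather than per species —
resolve which extant chromosomes descend from which 1R duplicate, one can
ask which ancestral gene order explains the extant arrangements with the
fewest duplications, losses and translocations.

This package implements that whole chain of reasoning as testable code,
exercised end to end on a synthetic-genome generator with a known event
history, so that every stage can be scored against its generating truth.

# The synthetic world

`simulate_history()` evolves a genome along a species tree. Branches are
named by the node they lead to; whole-genome events sit at the start of
their branch: a `WGD` doubles every chromosome and a `TRIPLICATION`
triples it, preserving gene order and strand on each copy (copy suffixes
`_A`, `_B`, `_C` encode the path, so truth is string-parseable). Tandem
duplications insert the copy immediately downstream of its source on the
same strand; losses delete one gene; translocations move one gene to
another chromosome with a new strand. Events are either *scripted*
(a deterministic list, used for the default study conditions) or drawn
per branch as Poisson counts (`rate x branch length`, with loss and
translocation rates per gene). Rates implying an expected genome above a
cap are rejected up front. Gene ids are stable along lineages; every copy
records its parent, so each extant gene traces to exactly one root gene.

Proteins evolve by a 20-state substitution process with equal
exchangeabilities and equal frequencies, and no indels in this version:
at expected distance $d$ per site, a site keeps its residue with
probability $1/20 + (19/20)\,e^{-20d/19}$ and otherwise moves uniformly
to one of the 19 alternatives, so the expected proportion of differing
sites is $p(d) = (19/20)(1 - e^{-20d/19})$ and `poisson_distance()`
($d = -\tfrac{19}{20}\log(1 - \tfrac{20}{19}p)$) is its exact inverse.
Keeping the model this simple makes the closed forms exactly testable;
indel support is a flagged extension, and the consequence — family
"alignments" are ungapped and equal-length — is stated wherever it is
used. Per-branch and per-family rate multipliers implement the rate
heterogeneity that confounds sequence-only phylogenies.

The default configuration (`paper_scenario_config()`) encodes the study
conditions: an outgroup species (no WGD; amphioxus-like), two jawless
species (1R, then the triplication on their stem), and two jawed species
(1R then 2R; one flagged teleost with a 1.3x branch rate). The ancestral
opsin-bearing chromosome carries the pre-1R tandem cluster
`SWS1, SWS2, RH, LWS` — the RH gene resolves into RH1 on one 1R copy and
RH2 on the other, which is the "RH1/RH2 split at 1R" model — flanked by
ten anchor families (two of them, GNAI-like and parapinopsin-like, play
the curated-family role; one, NLGN, is configured to fail the selection
rule so the selector has something to reject). A second chromosome holds
background families and the non-visual OPN3. Scripted losses carve out
the extant arrangements: each lamprey keeps an RH1–LWS tandem on one
1R-copy chromosome and an SWS2–RH2 tandem on the other, with SWS1
translocated to a chromosome outside the paralogon; the jawed species
keep the LWS–SWS2 tandem on one chromosome and RH1, RH2, SWS1 alone on
three others.

Numeric choices and why:

* branch lengths put roughly 0.44 expected substitutions per site
  between the root of the vertebrate clade and each tip at rate 1; the
  post-1R shared stem is short (0.08) — short enough that single anchor
  families cannot reliably resolve the 1R chromosome clades (over a
  ~150-aa gene the split is supported by ~10 expected substitutions
  against a pairwise-distance standard error of similar size), long
  enough that the ~1,500-column concatenation resolves them with
  bootstrap support near 1. This is the designed regime for the
  concatenation-advantage experiment, chosen by this power reasoning.
* per-family rate multipliers span 0.5–1.3. The upper end is bounded by
  orthology recoverability: at the configured divergences a family
  evolving much faster drops below the 0.3 identity floor of the
  orthogroup step within a genome, so its family would not be selectable
  — which would contradict the intended study condition that seven
  neighbour families pass the selection rule. (An early draft used 1.6
  and hit exactly that artefact.)
* intergene gap 5,000 bp, gene span `3 x protein length`: cluster genes
  are unambiguously proximal (gaps well under the 100-kbp window) and
  re-laid-out uniformly after losses; physical distances between
  non-adjacent survivors are not modelled beyond the uniform gap.
* opsin-class families descend from one ur-opsin at 0.5 substitutions
  per site, so subtypes are homologous but well separated; anchor
  families are independent random proteins.

What passing tests on this generator do **not** show about real data:
no indels or alignment error, no assembly artefacts or scaffold breaks
(the generator has no analog of a gene split across scaffolds), no gene
conversion, uniform intergenic distances, and subtype truth by
construction. The generator is an instrument for validating the
*inference machinery*, not a model of lamprey genome evolution.

# Subtype classification

`classify_subtype()` profile-aligns a query into the reference column
space (global affine-gap alignment against per-column residue
frequencies, Gotoh recursion in C++, ties broken match > delete >
insert), then resamples columns with replacement; each of the `n_boot`
replicates votes for the subtype with the smallest mean Poisson-corrected
distance between the query and that subtype's rows. Support is the modal
vote fraction; the call is accepted at support ≥ 0.95, mirroring the
≥95% ultrafast-bootstrap convention (the companion approximate
likelihood-ratio channel of that convention has no analog in a
distance-based placement and is dropped). Two guards precede voting: a
query aligning with under half the reference columns is returned
"unalignable", and a query whose best identity to any reference row is
below 0.25 is reported as non-opsin — the role the homology search plays
before classification in practice.

Reference panels are leave-one-species-out: a gene is classified against
the labelled genes of the *other* species. This is not a convenience but
a necessity of the synthetic design: the two 1R copies of RH are created
identical, so RH1 and RH2 exist as distinguishable sequence clades only
within a shared history. A reference panel simulated independently of
the analysis run would be exactly equidistant from both subtypes. Real
curated alignments share history with real queries in just this way.
Under the default conditions the nearest reference for a lamprey gene is
its sister-lamprey ortholog at about 0.3 substitutions per site, which
is the divergence regime in which the classifier is validated
(accepted-call accuracy ≥ 99%).

# Tandem-pair detection

`scan_pairs()` emits one event per unordered pair of genes with
different accepted visual subtypes sharing species, chromosome and
strand. The gap is the inter-gene gap (nearest ends; 0 for overlaps),
not start-to-start — separation phrasing such as "~6 kbp apart" refers
to the space between genes and is robust to gene length; a
start-to-start mode exists behind a flag for sensitivity checks.
Proximal means strictly `gap < window` (default 100,000 bp; exact
equality at the boundary is distal by this convention, which the
boundary tests pin down). Same-subtype pairs are excluded; genes without
an accepted subtype are skipped with a warning. `summarize_pairs()`
counts events per subtype pair and distance class and computes each
taxon group's percentage share within a class; because published pair
counts do not always state whether the unit is the gene pair or the
species exhibiting it, a species-collapsed counting mode is provided
alongside the default per-pair counts.

# Orthogroups and anchor-family selection

`build_orthogroups()` connects cross-species reciprocal best hits (by
global alignment score, BLOSUM62, gap open 10 / extend 1) and, within
each species, every pair with positive score and identity at or above
the floor (default 0.3). The within-species edges are what keep
whole-genome duplicates in one family — a reciprocal best hit links only
one in-paralog pair, and without recruitment every 1R/triplication copy
set fragments into per-copy orthogroups. Identity is counted as
identical residues over the *longer* sequence length: counting only
aligned pairs lets a gap-happy global alignment of two unrelated
proteins chain isolated identities and exceed the floor. Components are
deterministic (lexicographic tie-breaks) and symmetric in species order.
This is deliberately simpler than a full orthology pipeline
(no MCL, no tree reconciliation): the selection step only needs family
membership and chromosome occupancy.

`select_anchor_families()` applies the two-part rule: a family passes if
its members in the focal species occupy at least two distinct
opsin-bearing chromosomes, and its members across the jawless-group
species occupy at least three distinct chromosomes. Chromosome counting
is pooled across the jawless species by default — the rule's second
clause does not say whether the count is per species or pooled, so a
stricter per-species mode sits behind a flag. Any sequence region id
counts as a chromosome; short-scaffold exclusion is left to
configuration. The curated extra families (GNAI-like, parapinopsin-like)
are added by family symbol rather than selected, reflecting their
independent-evidence role.

# Chromosome-keyed supermatrix and the paralogon tree

`build_supermatrix()` concatenates family alignments with one row per
(species, chromosome): a family's segment is filled from that
chromosome's member and all-gap where the family is absent; when a
chromosome carries more than one member the one closest to the family
consensus is kept and the exclusion recorded. Distances are
pairwise-deletion Poisson distances (gap-rich rows are expected by
construction, so complete deletion would discard most columns);
`nj_tree()` is canonical neighbor joining on the lexicographically
ordered taxon set with negative branches clamped at zero, and
`bootstrap_tree()` counts, over column resamples, how often each
bipartition of the full-data tree recurs; rows sharing under 10% of
columns with some partner are dropped greedily, worst offender first.
Reliability is support ≥ 0.95 on this single bootstrap channel.
`root_tree()` roots on a monophyletic outgroup (refusing otherwise, with
the offending bipartition named), and `paralogon_clades()` labels the
two basal ingroup clades "1" and "2" — these are the 1R-derived
chromosome sets that the downstream parsimony step conditions on; a
chromosome carrying opsins but no anchor row (the translocated-SWS1
case) falls outside the tree and is labelled "other".

The replication experiment behind the design (analysis/07, and the
acceptance suite at 50 replicates) measures how often the concatenation
recovers both 1R clades with reliable support versus how often a single
family does; one family is sampled per replicate for the single-family
rate, which estimates the same quantity at a third of the cost.

# Event parsimony over ancestral arrangements

The engine conditions on the WGD structure — 1R shared, then per lineage
a triplication (jawless) or a second WGD (jawed) — and these events cost
nothing, because they are established by evidence independent of the
opsins. A candidate history consists of pre-1R tandem duplications
(searched only on the pre-1R stem; both classical hypotheses place them
there), losses on any edge of the chromosome-copy tree (one early loss
explains absence from every descendant copy), and single-gene
translocations on terminal edges (sufficient for the lamprey SWS1 case;
earlier translocations would need copy-tracking of the target chromosome
and are out of scope). Default weights are 1 per event; they are
configuration, not estimates.

Two modelling decisions matter most:

* **Subtype classes must be monophyletic in the implied gene
  genealogy.** Subtypes are, operationally, clades in sequence
  phylogenies; a scenario in which one ancestral gene independently
  "becomes" SWS2 on both 1R copies would make SWS2 polyphyletic and is
  inadmissible. The genealogy is: an unresolved polytomy over the
  hypothesis's root genes, an unresolved polytomy over each root's
  pre-1R tandem copies (same-stem duplications have no constrained
  branching order), then the 1R split, the speciation, and the group
  WGD/triplication. A class spanning several children of a node is
  admissible only if each such child is pure — i.e. monophyly holds in
  some resolution of the polytomies. Without this constraint the
  two-gene hypothesis can always shadow the cheapest labelled
  hypothesis and the comparison degenerates.
* **Scenarios are reported up to copy exchange.** Copies produced by one
  WGD or triplication are biologically unlabelled, so assignments of
  observed chromosomes to copies, and translocation sources on leaves
  with identical content, are enumerated once per equivalence class.
  Co-optimal scenarios that remain — for instance the alternative
  sources of the translocated lamprey SWS1, whose original chromosome
  the data genuinely do not determine — are all returned, and the count
  is reported rather than hidden behind a tie-break.

The search is exact within its declared envelope (pre-1R order capped at
five genes by default): it enumerates duplication-extended orders, the
two assignments of 1R copies to observed clade labels, subsequence
embeddings of each observed chromosome into the (possibly reversed,
strand-flipped) ancestral order, and translocation sources; loss events
are then placed optimally on the copy tree (an absence shared by all
leaves under an edge costs one event; stem losses shared by both 1R
clades merge into a single pre-1R loss), with branch-and-bound pruning
against the incumbent. Chromosome orientation is arbitrary, so an
observed order also matches its reversal with flipped strands;
inversions as events are not modelled. `compare_hypotheses()` ranks
hypotheses by minimum cost with deterministic name-order tie-breaking
and reports infeasibility (an observed subtype no label can produce) as
infinite cost rather than an error.

On the default synthetic world this reproduces the expected result: the
jawed-only arrangement is far cheaper under a two-gene ancestral cluster
than under a five-gene one (the "substantially more losses" argument,
with the gap verified against brute-force enumeration in the tests), and
once the lamprey arrangements and paralogon clades are included, the
four-gene model whose RH1/RH2 split happens at 1R — with lamprey SWS1
translocated — is the strict minimum-cost explanation.

# Pipeline, determinism and problem sizes

`run_pipeline()` chains simulate → classify → scan → families →
paralogon → scenarios → report, with every stage reading and writing
plain-text files (TSV/FASTA/GFF3/Newick/YAML) in the run directory, a
failing stage named in the error, and a manifest of md5 checksums; a
rerun with the same seed reproduces every stage file byte for byte. All
randomness flows from the single seed. The numbered scripts under
`analysis/` run the same stages as self-contained drivers writing under
`results/`.

Default problem sizes keep every experiment desk-scale: 5 species,
~300 genes, 18 families, 100-column-bootstrap trees on ~21 chromosome
rows, 20-seed pattern-recovery and 50-replicate concatenation
experiments, and parsimony instances with at most 5 pre-1R genes. The
acceptance-style checks in `tests/testthat/test-acceptance.R` and the
recomputation script `scripts/acceptance.R` state their replicate counts
explicitly.

# Known limitations

* No indels, alignment uncertainty, or assembly error; the generator's
  "alignments" are exact.
* Translocations in the parsimony engine are terminal-edge only, and
  inversions, fissions and fusions are not modelled (an opposite-strand
  tandem neighbour is treated as a data artefact upstream, not an
  event).
* Distance-based classification and NJ bootstrap stand in for
  likelihood-based tree inference; they are validated against the
  generator's matching substitution model, and their behaviour under
  model misspecification is untested.
* The event-parsimony optimum is exact only within the declared search
  envelope; larger ancestral clusters would need the cap raised and cost
  revisited.
* Event weights are equal by assumption; no attempt is made to estimate
  relative rates of loss versus translocation.
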