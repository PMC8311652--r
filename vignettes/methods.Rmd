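---
title: "Methods: mining drug interactions with epigenetic enzymes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining drug interactions with epigenetic enzymes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidrugminer)
```

This vignette documents the models, procedures and design choices behind
the package: what each stage computes, which parameters matter, what the
synthetic-data generators emulate (and what they deliberately do not), and
where the design was genuinely open.

## 1. The enzyme registry

Classical epigenetic regulation acts at two substrates: the DNA itself,
where methyl groups are added to or removed from cytosines, and histones,
whose tails carry reversible marks (methyl, acetyl, phosphoryl, ubiquitin,
ADP-ribosyl groups, citrulline, biotin). The registry models one enzyme
per record with its gene symbol, gene name, NCBI gene id, optional UniProt
accession and an action label from a **closed vocabulary of 14 reactions**
(`enzyme_actions`). Substrate classification is mechanical: DNA-prefixed
actions act on DNA, everything else on histones.

The registry XML dialect is deliberately minimal — a `<registry>` root
with one `<enzyme>` element per record and child elements for symbol,
name, ids and the action (`<subclass>`) — because the archive layouts of
public enzyme databases vary and only these fields feed the analysis.
Parsing is strict about the vocabulary (records with unknown or missing
actions are skipped and reported) and deterministic about duplicates:
first occurrence wins, duplicates are logged. Identifier verification,
which online would be a nomenclature-service lookup, runs against a
packaged reference symbol table so the package works offline.

The packaged fixture (`load_packaged_registry()`) is the curated table of
68 human epigenetic enzymes with known approved/investigational drug
interactions: 8 DNA-substrate and 60 histone-substrate enzymes, among them
10 histone deacetylases/sirtuins, 4 DNA methyltransferases and 30
histone-phosphorylating kinases.

## 2. The query language

Queries follow PubMed conventions: case-insensitive whole-token matching
on title+abstract text, trailing-`*` prefix wildcards, and the field tags
`[PT]` (publication type) and `[PL]` (country of the first-author
affiliation) bound to the immediately preceding term. Operator precedence
is `NOT > AND > OR`, left-associative, with `A NOT B` meaning the matches
of A minus the matches of B. Tokenization splits on non-alphanumerics and
lowercases — a reproducible approximation of a search engine's term
matching that makes no attempt at stemming or thesaurus (MeSH) expansion,
which is why hit counts on real corpora will differ from a live search.
An empty query string is an explicit match-all node, used to count a
corpus' total output. Double quotes are stripped before parsing, and the
packaged default search string (`epigenetics_drug_query()`) is the
balanced-parenthesis repair of the circulating form, whose historical
spelling variants ("acethylase") are kept verbatim.

The manual inclusion screening a human reviewer applies after a database
search is represented by an optional per-record `included` flag which
`filter_corpus(honor_included = TRUE)` subtracts from the matches; the
package does not attempt to model the screening itself.

## 3. Citation expectation and accrual fitting

Citation accrual is modelled as a saturating exponential: a paper
published Δt years before the query has accumulated
C(Δt) = N(1 − e^(−Δt/β)) of its eventual N citations. β (years) is the
time by which 63 % of the eventual total is reached and encodes the
citation culture of a discipline; the package ships the presets
β_bio = 5.4 and β_pharma = 7.1. Inverting the model,
`expected_total_citations()` extrapolates a cohort's eventual mean from
its observed mean. Three numerical conventions matter:

* the model is applied to the **exact** cohort mean; only tabular display
  truncates toward zero (a mean of 274.5 prints as 274 while 274.5 enters
  the model, yielding 279 after rounding for the worked 1999 cohort);
* Δt is `query_year − publication_year` in integer years;
* cohorts in or after the query year are omitted from trend tables
  (Δt must be positive).

`fit_beta()` recovers (N, β) from an accrual series by nonlinear least
squares (`stats::nls`, with a Levenberg–Marquardt fallback via
minpack.lm when the Gauss–Newton step fails), started at
N₀ = 1.2·max(C) and β₀ = max(t)/3. Recovery is exact (≤ 10⁻⁶) on
noiseless series and within 10 % relative error on per-year means of 200
Poisson-noised simulated papers, which the test suite verifies.

Country normalization divides per-country hit counts either by the mean
population over an analysis window (per capita) or by the country's total
non-review output (per output); countries without a usable denominator
are excluded with a warning rather than silently assigned a rate.

## 4. The interaction matrix

The drug XML dialect is a documented minimal subset of the DrugBank v5
layout: per drug its id, name, development groups (multi-membership
preserved — a drug can be both approved and investigational), category
labels and targets as polypeptides with UniProt id and organism.
`select_drugs()` keeps drugs with at least one allowed group (default:
approved, investigational — the groups with plausible therapeutic
relevance) and restricts targets to the configured organism label
(default `"Humans"`, matched case-insensitively); drugs left without
targets are retained and simply contribute no interactions, keeping the
filter idempotent.

A matrix cell (d, e) is 1 when drug d lists a target mapping to enzyme
e's gene symbol. UniProt→gene mapping comes from a supplied table
(offline stand-in for an id service); unmapped targets fall back to an
embedded gene symbol when present, otherwise they are dropped and
counted. Drugs and enzymes without interactions are excluded from the
axes, which are sorted lexicographically so serialization is
deterministic — the ordering of a published heatmap is a display choice
the matrix does not encode. The class invariant `total = Σ cells = Σ row
marginals = Σ column marginals` is property-tested against the synthetic
generator's planted truth.

`two_by_two_chi_square()` is the plain Pearson form (no continuity
correction) with df = 1, with a flag for the Yates correction. The
bundled pipeline applies it to the one 2×2 table derivable from its own
data — development group (approved vs investigational-only) crossed with
epigenetic interaction — since published underrepresentation statistics
depend on database snapshot counts whose exact table is not recoverable.

## 5. Over/under-representation analysis

Terms of the ontology form a rooted DAG over `is_a`/`part_of` edges
(`regulates` edges are parsed but never used for propagation, standard
true-path practice). Under the true-path rule each term's propagated gene
set is its direct genes joined with the propagated sets of its children;
the implementation processes terms in topological order and is tested
against a brute-force reachability oracle.

For a study set of n genes in a universe of N, a term annotating K
universe genes with a of them in the set is tested on the 2×2 table
(a, n−a; K−a, N−n−K+a) with a **two-sided Fisher exact test**: the
two-sided p sums hypergeometric outcomes no more probable than the
observed table (with the conventional 1 + 10⁻⁷ near-tie tolerance). The
two-sided choice is deliberate: the analysis reports both over- and
underrepresentation, and direction is assigned afterwards by the sign of
observed − expected, with expected = n·K/N. Bonferroni multiplies p by
the number m of terms actually tested — after the namespace, curated-only
and minimum-annotation filters (default: ≥ 2 universe genes per term) —
and caps at 1; a term is significant when p_adj < t_p (default
t_p = 0.001, strict inequality, the usual Bonferroni convention).

**Details and headlines.** A *detail* is a significant term with no
significant descendant — the end of a significant branch. For every path
from a detail up to a root, the significant node with the highest
*remarkableness* is that branch's *headline*; ties break by smaller
corrected p, then by greater depth (distance from the root). The
authoritative remarkableness measure lives in prior literature, so the
package implements a documented default behind a pluggable interface
(`score_fn`): R = (1 − p_adj) · IC with information content
IC = −log₂(K/N). This directly operationalizes the two stated headline
criteria — statistical certainty and information value — while letting a
user substitute another scorer; coverage- or conciseness-based refinement
of headline choice is not modelled. Headline selection is tested against
an exhaustive per-path maximization oracle. The colored DAG export (DOT)
codes structural, over-, underrepresented, detail and headline nodes
with deterministic node ordering.

## 6. Synthetic data: what it emulates, what it does not

All generators are pure functions of their arguments and seed
(byte-identical re-runs, caller's RNG untouched) and return truth records
that downstream tests treat as ground truth.

* **Registry**: actions allocated from a mix by largest remainder, so the
  default mix at n = 68 reproduces the packaged composition (8 DNA / 60
  histone).
* **Drug database**: development groups drawn per-group with
  multi-membership (probabilities roughly mirroring the observed mix of a
  public drug database, where experimental entries dominate and dual
  approved/investigational membership is common); targets mix registry
  genes (a drug is an epigenetic interactor with probability
  `overlap_fraction`) with decoys from a disjoint `DECOY` namespace so
  planted overlap is unambiguous; 15 % of targets get a non-human
  organism to exercise the organism filter. The truth record stores the
  exact post-filter interaction matrix.
* **Ontology**: a random rooted DAG (each term attaches to 1–2 existing
  terms, 80 % `is_a`), background annotation rate 0.08 per gene–term
  pair, and planted enrichment: study genes annotate a planted (leaf)
  term with the probability whose odds are `odds_ratio` times the
  background odds. The planted-recovery study uses odds ratio 8, a set
  of 50 genes in a universe of 1000 and 100 replicate seeds, requiring
  ≥ 95 detections and ≤ 5 % corrected false positives on
  neutral (non-planted, non-ancestor) terms.
* **Corpus**: per-year planted matching records (text constructed to
  satisfy the default search string), background records that miss the
  query or are reviews (default review fraction 0.2, roughly the share
  of reviews in biomedical literature), and cumulative citations
  following the accrual curve with β = 5.4 by default, either rounded
  deterministically or Poisson-distributed around the curve — the
  simplest count-noise model.

These generators reproduce the *structure* the pipeline consumes, not the
statistical texture of real literature or drug databases: no MeSH
vocabulary, no citation heavy tails beyond what the accrual model plus
Poisson noise produces, no realistic category marginals, no correlation
between a drug's group and its target count. Passing tests therefore
demonstrate correctness of the computations and recoverability of planted
structure — not that real-world hit counts (which depend on dated
database snapshots) would be reproduced.

## 7. Problem sizes and runtime choices

The test suite and analysis scripts run at sizes chosen to exercise every
code path while keeping a full run in well under a minute of CPU for the
deterministic parts: registries of 20–68 enzymes, drug databases of
10–150 drugs, ontologies of 12–60 terms, corpora of tens to hundreds of
records. The two simulation studies use the sizes stated above (100 ORA
replicates at universe 1000; 200 noisy papers for β recovery) because
those are the conditions under which the stated tolerances are
meaningful.

## 8. Known limitations

* The query engine approximates, and does not replicate, a production
  search engine (no stemming, phrase search, or thesaurus expansion).
* The chi-square on published snapshot counts is not reproducible because
  the underlying 2×2 table is not recoverable from printed shares; the
  package computes the statistic only on tables it can derive.
* The default remarkableness scorer is a documented stand-in for the
  measure defined in prior literature; headline sets under other scorers
  can differ, which is why the scorer is pluggable.
* First-author country is the only geographic attribution supported;
  collaborative contributions are not split across countries.
* Live database access (enzyme archives, drug databases, literature
  services) is out of scope by design; all inputs are local files.
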