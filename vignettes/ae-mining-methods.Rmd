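---
title: "Methods: mining adverse-event mentions of GLP-1 receptor agonists from social-media posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining adverse-event mentions of GLP-1 receptor agonists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

GLP-1 receptor agonists (semaglutide, tirzepatide and their brands
Ozempic, Wegovy, Mounjaro and Zepbound) have seen explosive uptake for
weight management. Public social-media posts are a complementary
pharmacovigilance signal: people describe adverse events (AEs) —
nausea, pancreatitis, hair loss, mood changes — that may be rare,
delayed, or under-ascertained in trials. `aeminer` implements a complete
mention-level analysis of such a corpus: inclusion filtering,
lexicon-based extraction, per-drug frequency tables, monthly trend
series, and a weighted AE co-occurrence network clustered by modularity
optimisation.

Because the original platform export tool has been discontinued and raw
post text cannot be redistributed, the package ships a synthetic corpus
generator whose defaults encode the published study conditions; every
downstream operation is exercised and tested against corpora with known
ground truth.

## Corpus model and inclusion criteria

A post is a record `(message, date, page name, page-admin country,
engagement counts)`. The inclusion pipeline has a fixed order:

1. **Date window** — day resolution, both endpoints inclusive; default
   2022-01-01 to 2024-05-31 (29 calendar months).
2. **Page-admin country** — exact equality with one ISO-3166 code
   (default `US`); posts with no country (e.g. group posts) are
   excluded.
3. **Duplicate removal** — one post per *byte-identical* message. No
   normalisation is applied: case or whitespace variants count as
   distinct messages. This is the most conservative reading of
   "same message" dedup; the retained copy is the earliest-dated one,
   ties broken by input order, which makes the operation deterministic
   and idempotent.

The filter report (counts after each stage) is checked internally:
counts are non-increasing and `n_after_country - n_after_dedup` always
equals the number of duplicates removed.

## Lexicon matching

Two editable CSV lexicons ship with the package: drug surface forms for
seven exclusive categories (six specific products plus the class-level
category), and 51 AE terms in 7 clinical categories, each with a
canonical phrase plus a small set of synonym surface forms (e.g.
*hypertension* ← "high blood pressure"; the general gastrointestinal
term ← "gi issues", "stomach issues"). Synonyms are configuration, not
code; MD5 checksums of the loaded lexicons are logged in every run
manifest.

Matching is case-insensitive at word boundaries: a hit may not be
flanked by a letter or digit, so "ozempicious" does not match
*ozempic*, while hyphens inside a form ("GLP-1") match literally.
Extraction has set semantics — an AE counts once per post no matter how
often it is mentioned.

Drug-category assignment partitions the corpus: if any specific drug
matches, class-level terms are ignored; among several specific drugs
the earliest match wins, with a fixed precedence order (ozempic,
wegovy, mounjaro, zepbound, semaglutide, tirzepatide) breaking
equal-position ties; the class category applies only when class terms
match alone. A published partition of this kind must have used *some*
exclusive rule; since none is stated anywhere we chose an explicit,
deterministic one and documented it. Category counts summing exactly to
the annotated corpus size is asserted on every run.

**Known limitation:** negation is not handled ("no nausea" counts as a
mention), consistent with mention-level framing; hashtags and URLs
inside the message are matched like any other text.

## Tables and trends

The headline statistic is the percentage cell
`100 * n_posts_mentioning_AE / n_posts_about_drug`, rounded **half-up**
to 2 decimals (1 decimal for narrative shares). Half-up rounding, not
R's default round-half-even, reproduces every arithmetically consistent
published percentage we checked (355 of 357 cells; the remaining two
are internal inconsistencies of the source table, as their printed
counts and totals imply different percentages than printed).

Rows of the frequency table are grouped by AE category and ordered by
descending corpus-wide mention totals, reproducing the published layout
convention; the ordering column is configurable.

The monthly series aggregates by calendar month over a contiguous
range, emitting zero months explicitly. "Frequency of adverse events"
is ambiguous between counting *mentions* (sum of per-post AE-set sizes,
which can exceed the post count) and *posts with at least one AE*; both
modes are implemented, with `mention_sum` the default. Four key
regulatory/media events ship as a data file and are attached to the
series for plotting.

## Co-occurrence network

Nodes are AEs (size = distinct mentioning posts); the weight of edge
`(i, j)` is the number of posts mentioning both; AEs that never
co-occur are excluded. The network is corpus-wide across all drug
categories (a per-drug restriction and a minimum-edge-weight filter are
available). Edge width tiers follow the published thresholds, resolved
half-open where the published bands overlap at 100: thick `[100, Inf)`,
moderate `[50, 100)`, thin `[0, 50)`.

Weighted Newman–Girvan modularity
`Q = sum_c [ S_in,c/(2m) - (S_tot,c/(2m))^2 ]` and the Louvain
optimiser are implemented in the package (the igraph implementations
serve only as independent cross-checks in the test suite). Louvain runs
the standard two phases — greedy local moves maximising the modularity
gain, then aggregation of communities into super-nodes with internal
weight as self-loops — until a level improves `Q` by less than `1e-7`
(at most 100 levels). Node visit order is shuffled per sweep under the
run seed.

Greedy local moves are order-sensitive: on ~2–3% of small dense random
graphs a single run stalls in a local optimum that no sequence of
single-node moves escapes (reference implementations stall at the same
partitions). The optimiser therefore performs 10 internally shuffled
restarts (all derived from the one seed, so results stay
bit-reproducible) and keeps the best-modularity partition; on graphs
small enough to enumerate this reliably attains the exhaustive optimum,
though it remains a heuristic in general. An exhaustive-partition
oracle (restricted-growth-string enumeration, ties to the
lexicographically smallest labelling) is exported for graphs of at most
10 nodes and anchors the tests.

Layout is a seeded Fruchterman–Reingold spring embedding with optimal
distance `k = 7.8` and 100 iterations (the published layout
parameters): repulsion `k^2/d` between all pairs, attraction `d^2/k`
along edges scaled by `w / max(w)` (the attraction weighting is our
choice, flagged here), displacement capped by a temperature cooling
linearly from 0.1. Initial positions are uniform in the unit square
under the seed; a single node sits at the origin.

## The synthetic corpus generator

The generator emulates the study conditions with known ground truth:

* **Category shares** — the exact published partition fractions
  (semaglutide 28.9%, ozempic 31.6%, wegovy 14.4%, tirzepatide 7.1%,
  mounjaro 6.8%, zepbound 3.0%, class 8.2%). We use the exact count
  fractions rather than the printed rounded percentages, which do not
  quite sum to 1.
* **Per-drug AE rates** — the published percentage cells divided by
  100, i.e. each AE is included independently per post at its
  per-category rate.
* **Planted co-mention clusters** — the three published co-occurrence
  communities (27 AEs: a somatic/metabolic group, a
  neurological/inflammatory group, and a gastrointestinal group). For
  each cluster with at least one member drawn in the base draw, the
  remaining members' inclusion *odds* are multiplied by `rho`
  (default 8), which keeps probabilities below 1 and leaves
  between-cluster pairs exactly independent. A member that failed its
  base draw receives a second chance calibrated so its conditional
  inclusion probability given an active cluster is exactly the
  odds-boosted rate. With `rho = 1` all indicators are independent.
  Boosting therefore inflates the *marginal* rates of clustered AEs
  above their configured base rates; rate-fidelity checks accordingly
  use `rho = 1`.
* **Duplicates** — with probability `duplicate_rate` (default 7.65%,
  the share implied by the published collected-vs-deduplicated corpus
  sizes) a post clones an earlier message, drawing its date at or
  after the source's so earliest-copy dedup retains the original.
  Non-duplicate messages embed a unique serial token, making
  byte-identical messages and ledger duplicate flags coincide exactly.
* **Off-filter noise** — with probability `offfilter_rate` (default 0)
  a post violates exactly one inclusion criterion (country or date),
  so each filter is independently testable.

Messages are neutral English carrier sentences embedding one drug
surface form and the canonical AE phrases. The generator makes **no**
attempt at realistic discourse: no negation, no misspellings beyond the
lexicon's listed variants, no engagement dynamics, no temporal bursts
around the key events (dates are uniform), and no language variation.
Tests passing on synthetic corpora therefore establish the correctness
of the extraction and analysis machinery, not the real-world recall of
the lexicon on informal text.

## Numerical and design choices

* Half-up rounding with a `1e-9` epsilon absorbing binary
  representation error; percentages over an empty category are `NA`,
  never NaN.
* Modularity is undefined (classed error) on edgeless graphs;
  partitions must cover every node.
* Louvain tolerance `1e-7`, 100-level cap, 10 restarts, seed default 0;
  `Q` of the returned partition is recomputed from the partition (and
  asserted consistent to `1e-12` in tests), and the per-level `Q` trace
  is non-decreasing.
* Determinism: generation, community detection and layout are
  bit-reproducible under fixed seeds; two runs of the pipeline with the
  same config produce byte-identical tables, partitions and layouts.

## Problem sizes used in the tests

The acceptance-style checks run at the study's published scale: a
59,293-post corpus for the partition invariant, 50,000 posts for
per-cell rate recovery (each of the 357 (drug, AE) cells within its
exact binomial 99% acceptance band, ≥95% required), 20,000 posts for
planted-cluster recovery (adjusted Rand index ≥ 0.9 against the planted
labels at `rho = 8`, base rate 0.05), and 50 random weighted graphs of
4–8 nodes for the Louvain-vs-exhaustive-optimum check. Unit and
property tests use corpora of 100–5,000 posts.

## Limitations

Mention counting is not incidence: posts may describe second-hand
experience, concerns, or news. The lexicon is closed-vocabulary; the
exact surface forms behind the general gastrointestinal term are a
best-effort stand-in. Dedup compares message text only (not
message + page). Edge tiering and layout parameters reproduce the
published presentation conventions, not a statistical model of
co-occurrence strength; no significance testing (lift, Fisher) is
attached to edges, matching the descriptive framing of the analysis.
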