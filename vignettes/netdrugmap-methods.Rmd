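---
title: "Methods: mapping disease genes and drug targets onto network gene sets"
author: "netdrugmap"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analytical problem

Pathway enrichment for rare and intractable diseases faces a resolution
problem. Classical pathway maps are large mosaics: dozens of parallel
branches drawn on one diagram. When a disease's genes and the targets of
its drugs both fall somewhere on a 300-gene map, that coincidence says
little about whether the drug acts anywhere near the disease mechanism.
Network elements — short, one-dimensional segments of signaling or
metabolic pathways, each nested inside one or more pathway maps — restore
the resolution: a disease gene and a drug target on the *same* small
segment plausibly participate in the same molecular event.

`netdrugmap` formalizes this as pure set arithmetic over two gene-set
universes (pathway maps and networks) crossed with per-disease gene sets
and phase-structured drug lists, and then asks the downstream question
that motivates the whole exercise: do drugs whose targets share a network
with disease genes become *relatively more frequent* as drugs progress
from development through clinical trials to approval? That enrichment is
the classical "genetic support predicts approval" signal, here measured
at network resolution.

## Model and procedure

All gene identifiers are opaque strings compared by literal equality; the
package performs no identifier normalization, because all inputs are
assumed to share one namespace.

**Stage 1 — coverage.** For each element \(i\) of a universe and each
disease \(j\) with gene set \(Dg_j\) and pooled drug-target set
\(T_j = \bigcup_k T_{kj}\) (union before intersection, so a target shared
by two drugs of one disease counts once):

\[ SPG_i = \sum_j |P_i \cap Dg_j|, \qquad SPT_i = \sum_j |P_i \cap T_j|,
\qquad S_i = \sum_j \mathbf{1}\{|P_i \cap Dg_j| > 0 \wedge
|P_i \cap T_j| > 0\}. \]

The four coverage counts are the numbers of elements with \(SPG_i > 0\),
\(SPT_i > 0\), both, and \(S_i > 0\); they always satisfy the chain
`same_disease_pair <= both <= min(genes, targets) <= element_count`. The
denominators are universe sizes, never filtered sizes: an element whose
genes appear in no disease or drug list still counts toward the total.

**Stage 2 — group rankings.** Within a disease group, networks are scored
by summed gene overlap (\(SNG_i\)) and by summed drug counts
(\(SND_i = \sum_j \beta_{ij}\), with \(\beta_{ij}\) the number of disease
\(j\)'s drugs having at least one target in network \(i\)). The sum runs
over drug–disease pairs: a drug developed for two diseases of the group
counts once per disease, which is the literal reading of the summation;
`snd_scores(dedup = TRUE)` provides the distinct-drug variant as a
sensitivity analysis. Rankings exclude zero-score networks and break ties
lexicographically by element ID — a repository convention chosen for
determinism, not a scientific claim. All tied entries at rank *k* are
returned unless `strict = TRUE`.

**Stage 3 — disease-related networks and rates.** For one disease,
\(NC_j\) collects the networks intersecting both \(Dg_j\) and \(T_j\);
\(DNGT_{j}\_s\) is the union of the drugs targeting them, and \(DNA_j\)
the drugs targeting any network at all. Every drug is classified by a
priority order: targets a disease gene directly; else targets another
gene of a network containing a disease gene; else targets a network
without disease genes; else targets nothing in any network. The priority
order resolves drugs with targets in several categories in favor of the
strongest genetic link; the underlying definitions imply but do not force
this choice, and it is fixed here as a design decision.

The default disease-gene mode is `"integrated"` (Mendelian genes union
GWAS risk genes); `"omim"` restricts to the Mendelian lists so both
variants of the analysis are switchable per run.

## Two denominators, and why the ANOVA uses the second

The percentage tables support two denominators:

- `"dna"` (default): percentages of the three in-network categories among
  drugs targeting at least one network, \(|DNA_j|\). Out-of-network drugs
  are reported separately and change no percentage. This is the natural
  denominator for the *fold change* of a category across the pipeline.
- `"all_drugs"`: percentages of all four categories among the whole phase
  drug set \(|Dd_j|\).

For the three-way ANOVA the choice is not free. With the `"dna"`
denominator the three in-network percentages sum to exactly 100 within
every (disease, phase) cell, so the DISEASE and PHASE main effects are
*structurally zero* — no data could ever make them significant. A
factorial analysis in which PHASE can carry a real effect must therefore
use whole-drug-set percentages of the three in-network categories (which
do not sum to a constant). `run_all()` and the acceptance script follow
that design; `rate_table()` keeps `"dna"` as its default for rate and
fold-change reporting.

## Statistical layer

The universe comparison decomposes the overlapping coverage counts into
mutually exclusive cells before testing: per universe, genes-only,
targets-only, both, neither (a 2 × 4 table), or the coarser 2 × 2
both-vs-rest layout. The four-category layout is preferred when defined,
but at full annotation scale the pathway universe saturates (every map
holds genes and targets), the "neither" column empties, and the
chi-square is undefined there; the 2 × 2 layout is the comparison that
remains meaningful. Pearson's statistic is used without continuity
correction by default; Yates correction is available by flag.

The rate table is a balanced single-observation-per-cell three-factor
design, so the three-way interaction serves as the error term — the
standard convention when a factorial has no replication, and consistent
with reporting only two-way interactions. Percentages are analyzed
untransformed. Degenerate decompositions are flagged, not hidden: a zero
effect sum of squares reports F = 0, an exactly additive table (zero
residual) reports F = Inf for non-null effects. Tukey HSD contrasts are
computed from cell means and the ANOVA error mean square via the
studentized range distribution (`q = |m_a - m_b| / sqrt(MS_e / n)`), with
the conventional significance stars (\*, \*\*, \*\*\*, \*\*\*\* at 0.05,
0.01, 0.001, 0.0001).

## The synthetic generator

`generate_universe()` draws a complete study universe with known ground
truth so that every stage can be validated without licensed annotation
snapshots. Its structural defaults follow the full annotation scale the
pipeline was designed around: 1260 networks of 2–10 genes, 353 pathway
maps built as unions of sampled networks plus extra genes (guaranteeing
every network is nested in at least one map), 15 disease groups, 22
diseases per group (330 diseases — equal group sizes approximate the 338
of the real registry), and 12273 drugs. The knobs without a stated
real-world counterpart were fixed once at values realistic for
clinical-trial registries of rare diseases: 6 Mendelian gene draws and 30
GWAS risk-gene draws per disease, 1–3 targets per drug, 10–60 drugs per
disease, 60% of a disease's drugs reaching clinical trials and a 20%
baseline approval rate.

Two parameters carry the scientific structure:

- `group_enrichment` (gamma, default 0.8): each group owns a designated
  pool of networks; a disease's Mendelian genes are drawn from the pool's
  genes with probability gamma and uniformly otherwise. Risk genes are
  drawn half from the pool and half uniformly, so the integrated and
  Mendelian-only gene modes differ measurably.
- `approval_odds_multiplier` (rho, default 4): approval is a coin whose
  *odds* are multiplied by rho when the drug targets a network containing
  its disease's genes. Acting on odds rather than probability keeps rho
  well-defined at high baseline rates. Writing \(q\) for the support rate
  among in-network drug pairs, \(p_0\) for the baseline approval
  probability and \(p_1\) for the boosted one, the expected fold change
  is \(p_1 / (q p_1 + (1-q) p_0)\): exactly 1 at rho = 1, saturating at
  \(1/(q + (1-q)p_0)\) as rho grows.

Diseases carry a single group label during synthesis by default
(`multi_group_prob = 0`) so the ground truth stays unambiguous; the
analysis side nevertheless counts a multi-label disease in every group it
carries.

What the generator does *not* emulate: network topology (edges,
direction, feedback — only set membership matters to the analysis),
overlapping group pools, size-biased drug-disease assignment, and any
correlation between a disease's gene-list length and its drug count.
Passing tests therefore demonstrate the correctness of the set
arithmetic, the statistics, and the recoverability of planted structure —
not that real annotation data satisfy the generator's independence
assumptions.

## Numerical choices and degenerate inputs

- Counts are exact integer arithmetic throughout; no floating-point
  scores enter the coverage counts.
- A fold change with a zero all-stage percentage is returned as `NaN`
  (flagged), never an exception; a rate-table cell whose disease has no
  in-network drugs is an error naming the cell.
- Contingency tables with a zero row or column marginal, or a zero
  expected cell, are rejected with advice to merge categories.
- Drugs with empty target sets are legal everywhere and fall in the
  no-network category; in the drug/target pair file they are declared
  with the reserved gene ID `-`.
- Diseases may lack a group label (loader warns) and approved drugs need
  not be a subset of clinical-trial drugs (approvals can predate the
  registries a database covers); both phase sets must be subsets of the
  all-drugs set, enforced at load.

## Validation-study sizes

The test suite validates every score and count family against naive
enumeration oracles on 200 random universes of 30 networks, 10 pathway
maps, 12 diseases and 80 drugs (exact integer agreement); checks the
chi-square against the closed 2 × 2 formula on 500 random tables and the
ANOVA sum-of-squares conservation to 1e-9; recovers the approval-odds
fold for rho in {1, 2, 4} within three Monte-Carlo standard errors over
200 replicates per rho (12 diseases, 20–40 drugs each); and recovers each
group's planted top network in at least 90% of 100 replicates at
gamma = 0.8. These sizes were chosen as the smallest universes that keep
all cells of the design populated with high probability.

## Known limitations

- Group-level analyses count multi-label diseases once per group, so
  group totals are not additive across groups.
- The chi-square comparison of universes treats elements as independent
  units; nested networks sharing genes violate that independence, so its
  p-value is descriptive rather than strictly inferential — a caveat
  inherited by any element-count comparison of overlapping annotation
  universes.
- The single-observation factorial cannot estimate the three-way
  interaction; if one exists in real data it inflates the error term and
  the reported F statistics are conservative.
- `expected_fold()` conditions on the realized support rate of a
  generated universe; it is an expectation over approval draws, not over
  universe draws.
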