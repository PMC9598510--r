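---
title: "Predicting cross-species cancer interactomes from domain-domain interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cross-species cancer interactomes from domain-domain interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossddi)
```

## The model

Direct experimental evidence for protein–protein interactions between a
non-model organism (here, typically an edible macroalga) and human proteins
is essentially nonexistent. What both sides share is domain vocabulary:
proteins are annotated with Pfam families, and a substantial catalogue of
**domain–domain interactions** (DDIs) — unordered Pfam pairs known or
predicted to interact physically, with confidence tiers — has been distilled
from solved structures and curated interaction databases (DOMINE-style).

`crossddi` uses the DDI catalogue as a bridge. Writing $D(p)$ for the domain
set of a foreign protein $p$ and $D(g)$ for the domain set of a human cancer
gene $g$, the **putative interactome** is the bipartite graph

$$
(p, g) \in I \iff \exists\, a \in D(p),\; b \in D(g):\; \{a, b\} \in \mathrm{DDI}.
$$

Every qualifying $(a, b)$ is retained as a *supporting pair*, recorded
directionally (foreign accession, human accession); a self-interacting
domain family yields the pair $(a, a)$. Two counts are first-class outputs
and must not be conflated:

* `n_interactions` — distinct $(p, g)$ pairs;
* `n_domain_links` — supporting pairs summed over interactions.

Published interaction totals for analyses of this kind rarely state which
convention they use, so the package always reports both, with
`n_interactions <= n_domain_links` guaranteed.

**Assumptions.** The model is deliberately permissive: one shared DDI edge
suffices, domain order/architecture is ignored, and no attempt is made to
verify structural compatibility, co-localisation, or that the foreign
protein ever reaches a human cell. The output is a hypothesis set for
prioritisation, not a predicted physical network. The confidence filter on
the DDI table (default: high-confidence rows only) is the single
edge-quality control.

## The cancer gene catalogue and the dual-role ratio

Tumour suppressor genes (TSGs) and oncogenes (OCGs) arrive as two symbol
lists. Their union forms the catalogue; symbols on both lists are labelled
`DUAL` (context-dependent genes). The catalogue size is exactly
$|T| + |O| - |T \cap O|$; matching is exact and case-sensitive, and alias
resolution is explicitly out of scope — upstream curation should emit
official symbols.

Each domain inherits cancer roles from the genes that carry it. With
$t$ = number of associated TSG-side genes and $o$ = OCG-side genes, the
**dual-role ratio** is

$$ r = \frac{t}{t + o} \in [0, 1], $$

undefined (rendered `"Not available"`, never 0) when $t = o = 0$. A domain
is `TSG_SPECIFIC` iff $t > 0, o = 0$ (ratio 1), `OCG_SPECIFIC` iff the
reverse (ratio 0), `DUAL_ROLE` iff both positive, `UNKNOWN` iff neither —
the four categories partition any domain universe.

A genuinely open design point is how a `DUAL` gene contributes. The package
defaults to counting it on **both** sides (`dual_counts_both = TRUE`):
under this rule the three non-empty categories close the arithmetic of the
standard TSG/OCG domain partitions, and dual-role domains get ratios
strictly inside $(0, 1)$. The alternative (dual genes count toward neither
tally) is exposed as an argument since some curation styles prefer it.

## Hubs, the secretome, and enrichment

* **TSG hubs** are foreign proteins with at least `min_tsg_partners`
  (default 100) *distinct* TSG partners. The threshold is inclusive
  ("100 or more"). Whether dual-role partners count is configurable
  (`include_dual`, default `FALSE`), since conventions differ; the default
  restricts to TSG-specific genes.
* **Secretome calls** implement signal-peptide-minus-transmembrane
  subtraction: secreted ⇔ signal peptide predicted AND effective
  transmembrane helix count zero. The default is the strict rule (any
  predicted helix disqualifies). Because signal peptides are frequently
  mis-predicted as a first transmembrane helix, `nterm_exempt_len` can
  discount helices lying entirely within the first *k* residues; it is off
  (0) by default, and enlarging it can only grow the secreted set.
* **Enrichment** of the top-ranked cancer partners is an exact upper-tail
  hypergeometric test per term: with background size $N$, term size $K$,
  query size $n$ and overlap $k$,
  $P(X \ge k) = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$,
  summed in log space via `lchoose` so deep tails (adjusted p-values around
  $10^{-70}$ are typical at genome scale) do not underflow.
  Benjamini–Hochberg step-up correction is applied across tested terms and
  significance is called at `adj_p <= 0.01`. The background is always an
  explicit input: there is no defensible built-in universe, and the choice
  (all protein-coding genes vs an expressed subset) materially changes the
  p-values.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `accepted_confidence` | `read_ddi_table()` | `"HC"` | high-confidence DDI edges only; the single edge-quality knob |
| `evalue_max` | `read_domain_annotations()` | `1e-5` (domtblout only) | conventional per-domain independent E-value cutoff; the TSV dialect is assumed pre-thresholded (e.g. Pfam gathering thresholds) |
| `dual_counts_both` | `classify_domain_roles()` | `TRUE` | closes the category partition arithmetic; see above |
| `min_tsg_partners` | `filter_tsg_hubs()` | `100` | inclusive hub threshold |
| `include_dual` | `filter_tsg_hubs()` | `FALSE` | dual-role partners excluded from the hub count by default |
| `nterm_exempt_len` | `call_secreted()` | `0` residues | strict transmembrane subtraction by default |
| `alpha` | `enrich()` | `0.01` | adjusted-p significance cutoff |

Pfam version suffixes (`PF00069.25` → `PF00069`) are stripped on every
input path, because DDI catalogues use unversioned accessions and the join
must be on bare identifiers. All residue coordinates are 1-based inclusive
(the HMMER/TMHMM convention).

## Numerical and degenerate-input choices

* Domain rankings order by interaction count descending with ties broken by
  accession ascending, so output is byte-reproducible.
* An empty DDI table yields an empty interactome with a warning, not an
  error; proteins or genes without domain annotations simply never interact
  (no imputation).
* Proteins absent from the SignalP-like table get `sp_call = FALSE`; absent
  from the TMHMM-like table, a helix count of 0 (outer join with stated
  defaults). Proteins with no secretion evidence at all are non-secreted,
  not errors.
* `dual_role_ratio(0, 0)` is `NA` — "no evidence" is kept distinct from
  "purely oncogenic".
* Ratios are stored at full precision; the TSV writer rounds to 6 decimals
  for display.
* Hypergeometric inputs are validated ($k \le \min(K, n)$, $n, K \le N$);
  `bh_adjust` rejects p-values outside $(0, 1]$. Note the step-up transform
  is not idempotent on general inputs (re-adjusting an adjusted vector
  with distinct values changes it); only constant vectors are fixed points,
  and the tests assert exactly that.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` emits a complete dataset: per-species FASTA and
annotation tables, TSG/OCG lists with a controlled dual overlap, a
gene-to-domain map, a confidence-tiered DDI table, and SignalP-5- /
TMHMM-2-style secretion tables, together with ground truth recomputed from
the emitted tables by an independent reference procedure (a hash-map
adjacency walk sharing no code with `build_interactome()`).

Defaults — chosen once as a realistic desk-scale testbed and not revisited:
5 species × 200 proteins over a 150-accession vocabulary; 150 TSGs and 100
OCGs sharing 20 dual-role symbols (roughly the 3:2 TSG:OCG proportion seen
in curated catalogues, scaled down); DDI density 0.02 with an HC/MC/LC mix
of 0.5/0.3/0.2; 15% signal-peptide and 25% transmembrane rates; 90% of
proteins and 95% of genes annotated. Ten hub proteins are planted by
constructive wiring — a reserved hub domain is connected by high-confidence
edges to domains covering 100 distinct TSG-only genes — so hub status is
guaranteed by construction and unsatisfiable configurations (e.g. a hub
target exceeding the TSG-only gene count) abort before any file is written.
Five of the ten planted hubs are additionally secreted (signal peptide,
zero helices); the other five carry a helix and must be subtracted. One
integer seed drives documented per-stage sub-seeds: one seed, one byte
stream.

What the generator does **not** emulate: realistic amino-acid composition
(sequences are uniform over the 20 letters and only lengths matter
downstream), real domain architectures or co-occurrence patterns,
evolutionary relatedness between the species, gene-family structure, or
biased DDI degree distributions. Passing the planted-recovery suite
therefore demonstrates that the pipeline's set logic, joins, thresholds and
parsers are correct — it says nothing about predictive validity on real
proteomes, which depends entirely on the quality of the upstream Pfam,
DDI and secretion-prediction inputs.

Test problem sizes were likewise fixed once: the brute-force equivalence
suite uses 200 random instances of up to 50 proteins × 30 genes × 20
domains (where a literal triple loop is feasible as the oracle), and the
end-to-end recovery test runs the default generator configuration.

## Known limitations

* Gene symbols are matched exactly; synonym drift between TSG/OCG lists and
  the gene-to-domain mapping silently reduces coverage (reported in the
  `attach_domains()` coverage summary — watch it).
* The DDI bridge cannot distinguish paralogues: every human gene sharing a
  domain inherits the same foreign partners, which inflates partner counts
  for large families (kinases especially). The dual-role ratio is likewise
  a gene-count statistic, unweighted by evidence strength.
* Secretion calls inherit every false positive/negative of the upstream
  predictors; the package only combines their outputs.
* `hypergeom_upper_tail()` treats gene sets as unstructured; no term-term
  redundancy reduction is attempted, so related terms rise and fall
  together.
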