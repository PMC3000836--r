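---
title: "Context-aware pathway maps and modular enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware pathway maps and modular enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcml)
```

# The problem this package addresses

Public pathway databases describe signalling generically: a reaction is
recorded once, with no statement about the organism or cell type in which it
was demonstrated. For immunology this is a real loss — dendritic cells (DCs)
and macrophages respond differently to the same stimulus, and human and
mouse DC models diverge in well-documented ways. `bcml` implements a pathway
representation in which every element can carry *findings*: evidence
annotations naming the organism, tissue, cell type, biological environment
and experiment type behind it. On top of that representation it provides the
machinery to filter a map to a biological context, to export analysis-ready
derivatives, and to run a module-level enrichment analysis whose output — a
matrix of signed Pathway Enrichment Factors (PEFs) — is clustered with
multiscale bootstrap support.

# The document model and XML dialect

A pathway is a container of SBGN Process Description glyphs (entity pool
nodes, processes, logic operators), arcs (consumption, production and the
modulation family), compartments and *modules*. The grammar of the Process
Description language is enforced by `validate()` as a catalogue of rules
with stable identifiers (`PD-ARC-01` … `PD-MOD-02`, documented on the
`validate` help page); violations are returned as data, never thrown, so a
broken document can be inspected.

The XML dialect is this package's own (the format reference is effectively
this section plus the bundled schema, `inst/extdata/bcml.xsd`): a single
`<pathway>` root with `<organism>`, `<compartment>`, `<glyph>` (complex
components nested), `<arc>`, `<module>` and `<chain>` children, ids as XML
IDs. Three representational choices deserve a note:

* **Canonical order.** The in-memory model and the serializer both keep
  glyphs, arcs and modules sorted by id, and module members sorted. Two
  structurally equal documents are therefore `identical()` in R and
  byte-identical on disk, which makes round-trip testing exact and
  diffs meaningful under version control. Unknown root-level elements are
  preserved verbatim in an extension slot for forward compatibility.
* **Families as complexes.** A protein family (MHC class II, PI3K, the
  dynamins) is a complex-class glyph with `family = TRUE` and one component
  per member gene. This is forced by the curation arithmetic: family
  members count individually in gene lists, so the expansion must be
  mechanical. `entity_kind()` is *derived*, never stored: a glyph is a gene
  iff it carries an EntrezGene xref, a chemical iff it is a simple
  chemical; that keeps chemical exclusion (e.g. PI(4,5)P2) computable.
* **Curation tags.** Glyphs may carry free-form tags; the bundled fixtures
  tag newly curated entries `"new"`, which is what
  `gene_list(scope = "new_only")` selects. The dialect stores no layout
  coordinates — rendering is delegated to GraphML consumers.

Modules come in three types — *sensing* (receptor/ligand recognition),
*transduction* (relay to a transcription factor) and *outcome*
(transcription-factor-driven targets and phenotypes) — and chained modules
share their boundary glyph: the exit of one is the entry of the next. A
chaining break is a warning, not an error, because module structure is a
curation convention layered on the PD grammar, not part of it.

# Context filtering and the affected state

Filtering assigns each element one of three states. An element *matches*
criteria when at least one of its findings carries, for every constrained
vocabulary, exactly the required term; matching elements are `included`,
elements with findings but no match are `excluded`. Elements without any
findings follow the `unknown_policy`: the default is permissive (included),
because curation coverage is incomplete and absence of evidence is not
evidence of absence; strict mode excludes them and thereby exposes the
gaps. Arcs without findings of their own inherit from their endpoints by
default (an arc whose endpoint is excluded is excluded); the alternative —
applying the unknown policy to arcs directly — is available via
`arc_findings = "own"`, since the two conventions are both defensible and
data rarely distinguishes them.

`propagate_affected()` then marks the structural consequences with four
monotone rules, iterated to a fixpoint: a complex with a compromised
component may not form; a process loses feasibility when an
existence-critical input (consumption, catalysis, necessary stimulation) is
compromised; an arc with a compromised endpoint is compromised; an entity
whose producers are all compromised cannot be made. Plain stimulation and
inhibition inputs deliberately do **not** propagate — a missing modulator
changes kinetics, not feasibility — but the critical arc set is an argument
for users who disagree. `excluded` dominates `affected`: exclusion is an
evidential statement, affectedness a structural inference, and the map
keeps them distinct.

Because the rules only ever promote `included` to `affected` (a two-point
lattice with `excluded` frozen), the fixpoint exists, is unique, and is
reached in at most one sweep per element; the test suite checks agreement
with an exhaustive one-rule-at-a-time oracle under randomized visiting
orders on hundreds of random small pathways.

# Exports

Gene lists (`.grp`), per-module gene sets (GMT), GraphML with display
colours (excluded grey, affected blue, up-regulated red, down-regulated
green), and SPIA-style signed relation tables. The relation conversion
stops at the first process: every gene feeding a process is related to
every gene it produces, with sign flipped by inhibition arcs and
not-operators, plus symmetric `binding` rows for complex co-members.
Transitive propagation is intentionally left to the downstream impact
analysis — the conversion translates format, not semantics. When a filter
status is supplied, excluded elements contribute no relations.

For expression overlays on multi-gene glyphs (complexes, families) the
glyph takes the member value of maximum magnitude; an exact-magnitude tie
between members of opposite sign yields `unchanged`. Max-magnitude
preserves the strongest signal and is deterministic; averaging would dilute
a single strongly regulated subunit.

# The modular enrichment analysis

The expression side follows a paired-ratio design: per-replicate
treated/control ratios (replicate *i* over replicate *i*; unpaired extras
over the control mean), log2-transformed, then averaged over replicates to
damp inter-donor variability. Differential expression is a fold-change
rule: `|mean log2 ratio| >= log2(fold_threshold)`, boundary inclusive,
default 2-fold. The default is configurable and recorded in the result's
metadata; a fold-change rule (rather than a variance-moderated test) is the
natural choice when the upstream summary is already a mean of ratios.

Each module is scored per condition by the one-sided Fisher exact
(hypergeometric) test against the background of genes measured on the
array — standard enrichment practice, and configurable. Writing `N` for the
background size, `K` for the DEG count, `n` for measured module genes and
`k` for module DEGs, the p-value is the upper tail `P(X >= k)`. The test is
one-sided because the PEF construction attaches a direction to each score.

The signed PEF is

* `sign * min(-log10 p, cap)` for modules with at least
  `small_module_threshold` (default 5) measured genes, and
* `sign * cap * n_de / n_module` below that threshold,

with `sign` the sign of the summed log2 ratios of the module's DEGs (+1
when there are none or they cancel), and `cap = 16` by default. The exact
transform behind published PEF matrices is not recoverable from the
literature; `-log10 p` is the conventional enrichment factor, the cap keeps
Euclidean distances finite when p-values underflow, and the small-module
fraction is bounded, direction-aware and commensurate with the capped
`-log10` scale. Both branches are isolated in `signed_pef()` precisely so a
different convention can be substituted in one place. Zero measured genes
give a PEF of exactly 0, so the matrix is complete by construction. Rows
are named `<pathway>_<s|t|o>_<label>` after the module's anchoring adaptor
or transcription factor.

# Clustering with multiscale bootstrap support

PEF rows or columns are clustered agglomeratively on Euclidean distance
(average linkage by default, the common companion of multiscale bootstrap
methodology; complete and single are available). Items are ordered
lexicographically before clustering so the tree is invariant to input
order.

Cluster support uses multiscale bootstrap: for each scale `r` in
0.5–1.4 (step 0.1, the canonical grid), `B = 1000` replicates resample
`ceiling(r * m)` of the `m` features with replacement, re-cluster, and
count how often each original cluster (exact leaf-set identity) reappears.
The per-scale bootstrap probabilities are extrapolated through the
signed-distance/curvature model `qnorm(1 - BP(r)) = v*sqrt(r) + c/sqrt(r)`,
fitted by weighted least squares with binomial weights, giving the
approximately unbiased support `AU = 1 - pnorm(v - c)`. Degenerate cases
fall back deterministically: BP identically 1 → AU 1, identically 0 → AU 0,
fewer than two informative scales → the usable BP nearest scale 1. The
fitted recovery is validated against the closed form on model-generated
BPs; plain BP at scale 1 is also reported per node. Trees export to Newick
(node labels `au|bp`, matched to clades by leaf set so node renumbering
cannot misplace a label) and to GraphML with a pink-to-black support ramp
over 50–100%.

# The synthetic generator: what it emulates, and what it does not

`synth_spec()`/`synth_pathways()`/`synth_expression()` generate a closed
validation loop: pathways with the same sensing → transduction → outcome
architecture as the curated fixtures (shared adaptor, per-module processes,
one two-member complex per transduction module, findings drawn from a small
human-DC / mouse-DC / human-macrophage context set), plus an expression
experiment in which a known set of modules is activated. Defaults encode
the reference validation design: 2 pathways, 1/2/1 modules, 8 genes per
module, 2 treated conditions with 3 replicates against a shared control,
4-fold activation, lognormal baseline (mean 8, sd 1 on the log2 scale),
multiplicative replicate noise with sd 0.25 (log2 scale), and 300
background genes so the Fisher background is realistic. Everything is
seeded and byte-reproducible.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: probe-level artefacts and normalization error,
correlated noise between genes, partially activated modules, cross-talk
between pathways sharing genes, and the long-tailed module-size
distribution of a curated database. Recovery results on this generator
validate the statistical machinery, not the biology.

Problem sizes used by the shipped validation runs were chosen to keep the
loop desk-scale: 200 random pathways for round-trip checks, 500 random
small pathways (≤ 12 glyphs) against the filter oracle, the full
hypergeometric lattice up to `N = 30` against tail enumeration, AU recovery
from `B = 1e5` model-generated BPs, and 20-seed module-recovery and
cluster-support runs at `B = 1000`.

# Numerical and design notes

* Fisher p-values come from `stats::phyper`; the independent check in the
  test suite enumerates the tail sum directly.
* `k = 0` gives `p = 1` exactly, and `signed_pef(1, +1, n, 0)` is exactly 0
  on the Fisher branch (`-log10 1 = 0`), so null conditions produce
  all-zero columns rather than numerical dust.
* Bootstrap identity of a cluster across replicates is exact leaf-set
  equality — the standard BP counting rule; no partial credit.
* The TLR5 fixture stores the 24 unique curated genes; the originally
  printed count of 25 double-counts IL18, and the discrepancy is recorded
  machine-readably in the document's extension note rather than silently
  reproduced.
* Fixture wiring (one process per module, catalysis arcs from member genes,
  boundary chaining through adaptor and transcription factor) is a minimal
  synthetic scaffold: the curation source prints module memberships, not
  reaction wiring, and the scaffold exists to make the documents valid and
  chained, not to model mechanism.

# Worked example

```{r example, eval = FALSE}
library(bcml)

# curated fixtures
tlr3 <- table1_fixture("TLR3")
length(gene_list(tlr3, scope = "new_only"))   # 23

# context filtering: what of this map is demonstrated in macrophages?
crit <- filter_criteria(cell_type = "CL:0000235")
res <- apply_filter(tlr3, crit)
table(res$status$status)

# synthetic validation loop
spec <- synth_spec(seed = 1)
pws <- synth_pathways(spec)
expr <- synth_expression(pws, spec)
pef <- pef_matrix(pws, compute_ratios(expr))
autoplot(pef)

tree <- cluster_with_support(pef, axis = "columns", B = 1000, seed = 1)
tidy(tree)
write_support_newick(tree)
```

# Known limitations

* Validation covers the structural PD rules listed on the `validate` page,
  not the full semantic constraint set of the SBGN specification (clone
  markers, multimers and units of information are out of scope, as are the
  Entity Relationship and Activity Flow languages).
* The filter is categorical; there is no probabilistic or partial
  inclusion.
* The PEF transform and small-module score are this package's pinned
  conventions (see above); comparisons against PEF matrices produced by
  other tools should expect monotone agreement, not equality.
* Array preprocessing is out of scope: expression input is assumed
  background-corrected and normalized, on a positive absolute scale.
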