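---
title: "Classifying the evolutionary origin of plastid-pathway proteins"
author: "plastidorigin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying the evolutionary origin of plastid-pathway proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Dinoflagellates with "non-canonical" plastids — the haptophyte-derived
plastids of *Karenia*/*Karlodinium* and the green-alga-derived plastid of
*Lepidodinium* — run their plastid metabolism with nucleus-encoded
enzymes of mixed ancestry. For a given enzyme, the encoding gene may have
been (i) inherited vertically from the ancestral, peridinin-plastid
dinoflagellate (**VI-type**), (ii) transferred from the algal
endosymbiont that became the current plastid (**EA-type**, endosymbiotic
gene transfer), or (iii) acquired laterally from some other lineage
(**LA-type**). Some genes cannot be placed (**UNCERTAIN**), and some
copies are cytosolic paralogs that never see the plastid at all.

`plastidorigin` turns the decision procedure used in this kind of
phylogenomic survey into a tested, reusable pipeline. It covers three
plastid-localized pathways: the C5 heme pathway (glutamyl-tRNA to
protoheme, 9 steps), the chlorophyll *a* pathway (protoporphyrin IX to
Chl *a*, 6 steps) and the non-mevalonate (MEP) pathway for IPP (7 steps),
encoded as a queryable registry with KEGG Orthology identifiers,
isofunctional alternatives (hemN/hemF, hemY/hemJ, N-DVR/F-DVR,
light-dependent/-independent POR, the two MgPME-cyclase types) and
plastid-encoded components (ChlI; chlB/chlL/chlN).

## The decision procedure

Inputs are a gene tree in newick with per-clade support — a
maximum-likelihood bootstrap percentage (MLBP), a Bayesian posterior
probability (BPP), or both as an `"MLBP/BPP"` node label — and a taxon
map assigning each tip to a group and each group to a role:
`host_vertical` (peridinin dinoflagellates), `endosymbiont`, `donor`,
`heterotroph`, or `outgroup`.

For a query tip the classifier:

1. roots the tree on the outgroup role (the edge maximizing outgroup
   tips on one side, then minimizing non-outgroup tips, ties broken on
   the lexicographically smallest tip set);
2. walks rootward from the query to the smallest enclosing clade whose
   subtending edge passes the support rule;
3. reads the clade's composition (ignoring the query and any declared
   co-query tips): pure host lineage gives VI, pure endosymbiont EA,
   pure single donor group LA, pure heterotrophs UNCERTAIN with a
   cytosolic-paralog flag;
4. if the smallest supported clade is mixed or absent, an LA call is
   still made *by exclusion* when both the host clade and the
   endosymbiont clade are supported and query-free (donor recorded as
   unknown); if only one of the two reference clades is supported the
   call stays UNCERTAIN — this mirrors the published distinction between
   exclusion-based LA calls and genuinely unresolved ones;
5. anything else is UNCERTAIN. Trees with fewer than four tips, or with
   no informative non-query tips, are UNCERTAIN with a note rather than
   an error.

### Support thresholds

The source analyses report MLBP and BPP per clade but state no numeric
cut-off. The package default — accept when MLBP ≥ 50 **or** BPP ≥ 0.95,
absent values failing their sub-test — was chosen because it reproduces
the accepted pairs (66/0.99, 73/0.83, 76/0.95, 81/0.68) and the rejected
pairs (47/0.67, 38/–, 8/–) seen in the published calls. Both thresholds
and the combination rule (`or`, `and`, `mlbp_only`, `bpp_only`) are
`classification_config()` fields, as are:

* `max_foreign_tips` (default 0): intruding tips tolerated in an
  otherwise pure clade. Published calls occasionally tolerate a single
  stray taxon ("except *Pavlova*"); set 1 to mimic.
* `allow_exclusion_la` (default TRUE), `outgroup_required`
  (default TRUE).
* `long_branch_factor` (default off): before classification, drop
  non-query tips whose terminal branch exceeds this multiple of the
  median terminal branch — the long-branch exclusion re-analysis used
  for rapidly evolving sequences (e.g. apicomplexan IspH).

### Design choices where the procedure was genuinely open

* **Co-query transparency.** Paralogs of the focal lineage (or the
  sister kareniacean genus) are declared `coquery_tips` and ignored in
  composition tests. A supported clade containing *only* query/co-query
  tips is skipped and the walk continues rootward; without this, a pair
  of focal paralogs nesting inside the endosymbiont clade could never be
  called EA.
* **Exclusion reference clades.** "The host tips form a supported clade
  excluding the query" is operationalized as: the smallest clade
  containing *all* tips of the role must be supported, query-free, and
  contain at most `max_foreign_tips` non-role tips.
* **Purity order.** When `max_foreign_tips > 0` several categories can
  qualify simultaneously; they are tested in the fixed order host,
  endosymbiont, donor groups (largest first, then by name),
  heterotroph. With the default of 0 the order is immaterial.
* **Rooting reads clades on the rooted tree**, so an evidence clade can
  never span the root; whether the original analysis required this is
  unstated, and requiring it is the conservative choice.

### N-terminal extensions

Plastid-targeted proteins in these lineages carry a bipartite
presequence (signal peptide, then transit-peptide-like region). The
extension boundary relative to bacterial homologs is not defined
algorithmically in the source; the package fixes it as the **median
first-aligned column of the reference rows** (lower median on ties),
robust to one aberrant homolog, and counts the query's non-gap residues
before it. `has_extension` uses a configurable minimum length
(default 10 residues — no threshold is stated in the source).
SignalP/ChloroP are not reimplemented: their verdicts are ingested from
a TSV, and a transit-peptide verdict is only stored when a signal
peptide was predicted (the conditional SP-then-TP order); a TP claim
without SP is demoted to unknown with a warning.

## The synthetic world

`scenario_params()`/`build_scenario_tree()` generate gene families with
a known truth: balanced clades for the host (default 6 tips),
endosymbiont (6), donor groups (2 × 4), heterotrophs (2) and a bacterial
outgroup (3), on a shallow backbone
`(outgroup, heterotrophs, (donors, (host, endosymbiont)))`. The query is
grafted inside (or sister to) the clade matching the scenario — VI into
the host clade, EA into the endosymbiont, LA into the first donor group.
Internal branches default to 0.3 expected substitutions/site (the
setting used for the end-to-end recovery benchmark); terminal branches
default to 0.1, a realistic within-group divergence chosen once before
any benchmark was run. Balanced clade shapes keep the tree diameter
small enough (~2.6 substitutions/site at the defaults) that pairwise
distances rarely saturate.

Sequences evolve under the **Poisson (equal-rate, 20-state) model**: the
root is i.i.d. uniform over the amino acids and along a branch of length
*d* a site changes with probability (19/20)(1 − e^(−20d/19)), uniformly
into the other 19 residues. This model was chosen over LG/GTR because it
admits an exact closed-form distance inversion,
d = −(19/20) ln(1 − 20p/19), making the simulator/reconstruction pair
self-consistent and testable. There is no rate heterogeneity and there
are no indels; real alignments violate both, so a green recovery test
establishes that the *decision logic* is sound, not that the pipeline
matches ML/Bayesian inference on real data.

## Reconstruction

`neighbor_joining()` is standard NJ (Q-criterion, Studier–Keppler
updates) with two deterministic conventions: ties in the Q matrix are
broken on the lexicographically smallest joined id pair, and negative
branch-length estimates are clamped to zero.
`bootstrap_support()` resamples alignment columns, re-estimates the tree
per replicate, and writes the bipartition frequency (×100) into the
**MLBP slot only** — an NJ bootstrap proportion is not a posterior
probability, so the BPP slot stays absent. Replicates with saturated
distances are skipped and counted (warning above 10%). Gap handling is
pairwise deletion. NJ replaces the ML/Bayesian stage only at desk scale;
externally inferred newick files feed the classifier through the same
`parse_newick()` path (the `label_as` argument maps single-label support
conventions without code changes).

## Aggregation

`aggregate_calls()` folds per-query calls into a
species × pathway × step matrix: each cell carries the multiplicity and
per-type counts of the non-cytosolic paralogs assigned to that step;
cytosolic calls are tallied separately; steps with no calls stay at zero
multiplicity, which the renderer distinguishes from "identified but
uncertain". In synthetic pipeline runs families have no natural pathway
assignment, so they are assigned round-robin over the registry steps
under the species name `synthetic` — this exercises the aggregation
contract while `recovery_summary.tsv` carries the scientifically
meaningful output. The run configuration is a flat sectioned key-value
file parsed by `parse_run_config()`; unknown sections or keys are
startup errors.

## Numerical conventions and degenerate inputs

* Supports are validated on parse (MLBP ∈ [0,100], BPP ∈ [0,1]); a bare
  numeric label is MLBP when > 1, BPP otherwise; `-` marks an absent
  value (the figure convention for BPP < 0.50). A bare MLBP ≤ 1 is
  written back as `M/-` to keep the round trip unambiguous.
* Distance saturation (p ≥ 19/20) is a flagged non-value, never a
  number.
* Q-matrix minima are compared with a 1e-12 relative tolerance before
  the lexicographic tie-break.
* `p_distance()` errors when a pair shares no gap-free column.

## Known limitations

* The simulator has no among-site rate variation, no indels, and one
  exchangeability class; the Poisson inversion is exact only under that
  model.
* NJ bootstrap percentages are not comparable to ML bootstrap values on
  real data; thresholds tuned on one should not be blindly applied to
  the other.
* Taxon-sampling caveats in published calls ("more red algal sequences
  are needed") have no algorithmic counterpart; they surface only in
  the free-text notes.
* The registry records the MgPME-cyclase step as present but "not
  detected in study taxa" (neither cyclase type has been found in the
  relevant algae), rather than dropping the step.
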