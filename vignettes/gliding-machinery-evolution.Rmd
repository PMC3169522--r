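---
title: "Tracing the emergence of a bacterial gliding machinery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the emergence of a bacterial gliding machinery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

*Myxococcus xanthus* glides over surfaces without flagella or pili, powered
by an envelope-spanning machinery (the Agl/Glt proteins) whose components
were delimited by comparative genomics before any of them had been
characterised biochemically.  The inference chain is the interesting
object: two unsaturated transposon screens yield overlapping gene lists;
re-annotation keeps the genes whose products look like envelope or
scaffolding proteins (signal peptides, lipoprotein signals, transmembrane
segments, TPR/coiled-coil motifs); the survivors cluster into a few
chromosomal regions; homologue searches across a genome panel show that
the cluster genes split into a *clade-restricted* set (recently emerged)
and a *broadly distributed* core that non-gliding bacteria carry as a
single operon-like unit; concatenated alignments of co-inherited core
genes give better-resolved trees than single genes; and the tree/species
incongruences plus Dollo parsimony yield a gain/loss/duplication/transfer
scenario for the machinery's emergence.

This package implements that chain as reusable, tested functions, and
pairs it with a genome-evolution simulator that emits every pipeline
input *plus the true event history*, so each inference step can be scored
for recovery.  The bundled worked example (`gliding_fixture()`,
`fixture_report()`) re-derives the published screen narrative
(35/23 mutant hits with 7 shared; 28 feature candidates; 13 hits in 4
regions; the 8+4+3 = 15-gene G1/G2/M1 clusters; the single 4.66-fold
polar-effect flag; the 7/7 Group A/B split) from the printed tables.
Gene identities for the unclustered mutant hits and the screen-negative
genes are *synthetic fill* constructed to the printed counts; their
identities live in supplementary material not bundled here.

# Pipeline stages and their parameters

**Feature screen** (`screen_candidates`).  A locus is kept iff
signal peptide OR lipoprotein signal OR `tm_count >= 1` OR
interaction motif.  TPR and coiled-coil are collapsed into one
`interaction_motif` flag because the screen never distinguishes them.

**Cluster detection** (`detect_clusters`, `extend_cluster`).  Hits are
clustered by locus-tag order: two hits are linked when at most `max_gap`
loci lie between them (default 3, the smallest value under which all four
published regions form from their printed locus tags); clusters are
connected components, then extended to every locus between their extreme
hits.  Pseudogene handling is data-driven (`merge_rules` fuses curated
fragment pairs such as MXAN_4864/65; automating pseudogene calls is out
of scope).  Chromosomes are treated as linear; ordinal indices are
0-based and ranges half-open.

**Homologue families** (`find_homologues`).  A desk-scale stand-in for
iterative blastp/PSI-BLAST: Smith–Waterman local alignment with affine
gaps (BLOSUM62, gap open −10, extend −1; C implementation) and a
*normalized score* — raw score over the smaller self-score — replacing
E-values with a database-size-independent similarity in [0, 1].  The
default acceptance threshold is 0.3; random unrelated sequence pairs of
length 200 score below it in >95% of draws, while homologues at the
simulator's divergences score ≈0.4–1.  Families grow by single-linkage
expansion from the seed; for tractability each round aligns unassigned
candidates against at most `max_reps` representatives (seeds first, then
the most divergent members; `max_reps = Inf` restores exact
single-linkage and is used in the correctness tests), and a BLAST-like
shared-word prefilter (k = 4, threshold scaled to the chance expectation
`n·m/20^k`) skips alignment of pairs with no word-level signal.  Members
whose length differs from the family's modal length are dropped: with no
indel process, fragments cannot enter the gap-free alignments.
Families smaller than `min_family_size` (default 2) are not pursued,
mirroring the original study's focus on multi-member families.

**Profile and classification** (`build_profile`,
`classify_distribution`).  Copy counts per family × genome; a family is
*Group A* iff every carrier genome lies inside the focal clades
(clade-path membership, no taxonomy database), *Group B* iff at least one
carrier is outside.

**Trees** (`pairwise_distance`, `neighbor_joining`,
`bootstrap_support`).  Distances use pairwise deletion and the uniform
20-state correction `d = −(19/20)·ln(1 − (20/19)p)` — exactly the inverse
of the simulator's substitution model, so distance estimates are
consistent by construction (`gamma` adds a Γ-rate generalization with
shape `gamma_alpha`).  Saturated pairs are capped at 5 substitutions/site
with a warning.  Neighbour joining is the classical Saitou–Nei/Studier–
Keppler algorithm; ties in Q break towards the lexicographically smallest
label pair and negative branch lengths are clamped to zero with the
deficit recorded.  Supports come from `n_bootstrap = 100` column
resamples (the standard nonparametric procedure).  Maximum-likelihood and
Bayesian inference are deliberately out of scope: distance+NJ is exact on
additive matrices, fast enough for dense bootstrapping, and sufficient
for recovery testing against the simulator; published topologies are
qualitative references, not bit targets.

**Rooting.**  Gene trees are rooted on a configured outgroup clade when
its copies are monophyletic, otherwise by midpoint — appropriate for the
clock-like simulated data, and the analogue of rooting "according to the
phylogenies of the individual proteins", which cannot be automated.

**Displacement (HGT) test** (`displacement_test`).  A leaf is displaced
iff its smallest enclosing clade with ≥3 leaves and support ≥
`support_min` (default 50, the conventional display threshold for
bootstrap values) consists otherwise entirely of leaves from *other*
top-level clades.  When those foreign leaves come from one clade it is
reported as the source; when they are mixed — several transfers landing
in the same gene-tree neighbourhood — the displacement is still called
with source `"unresolved"`.  We chose this reading deliberately: requiring
a *single* foreign clade makes concurrent transfers mask one another and
halves detection in simulation, while the ≥3-leaf requirement already
provides two witnesses.  Transfers into an internal branch whose
descendants survive as a block are undetectable by construction (the
block looks like a native monophyletic group); this is a stated
limitation, shared with the original visual analysis.

**Supermatrices** (`congruence_groups`, `link_paralogues`,
`concatenate_alignments`).  Families are grouped when they co-occur in a
detected cluster in ≥1 genome AND their trees, restricted to genomes
carrying exactly one copy of each (≥ `min_shared_taxa` = 4 of them),
differ by Robinson–Foulds ≤ `rf_congruence_max` = 2; groups are
transitive closures.  Multi-copy rows are resolved by physical linkage:
copies in one chromosomal cluster form one row tuple; clusters lacking a
complete single-copy set of the group yield no row (no gap padding — this
mirrors building rows only from complete linked triplets and avoids
pairwise-deletion artifacts).

**Scenario** (`dollo_reconstruct`, `infer_duplications`,
`infer_transfers`, `assemble_scenario`).  Transfers are inferred only
from displacement, never from patchy presence; genomes whose every copy
is transfer-derived are removed from the presence profile before
single-gain Dollo parsimony places the origin (MRCA branch of the
remaining carriers) and the minimal loss set (maximal carrier-free
subtrees below the origin).  Duplications use the species-overlap rule on
the rooted gene tree after pruning displaced leaves — without that
pruning, a transferred copy and its native counterpart share a species
across a deep node and masquerade as an ancient duplication.  Dollo
reports the MRCA branch and does not attempt finer placement of recent
gains.

# The simulator

`simulate_dataset()` emulates the study's data-generating world at desk
scale:

* **Species panel.**  20 taxa in 5 top-level clades (sizes 6/4/4/3/3,
  the largest being the focal, gliding-clade stand-in).  The tree is
  radiation-shaped: inter-clade splits in depth [0, 0.06], within-clade
  splits in [0.22, 0.34], tips at depth 1 — the shape of a sparse
  cross-phylum genome sample, where ordinal divergences are ancient and
  sampled representatives sit on long terminal branches.  A generic
  coalescent generator (`simulate_species_tree`) is also provided.
* **Gene content.**  Per-copy Gillespie simulation of duplication, loss
  and additive horizontal transfer along the tree
  (`sim_family_history`), with full copy ancestry (the true gene tree)
  and a replayable event log.  Six *core* families originate at the root
  (duplication 0.03, loss 0.05, transfer 0.05 events per copy per unit
  depth) and are wholesale-duplicated on the focal subclade stem (the
  whole-genome-duplication analogue, applied at the branch midpoint to
  every copy alive there); three *accessory* families are gained on
  three nested focal branches (duplication 0.03, loss 0.03, no
  transfer), emulating the staged appearance of the clade-restricted
  components.  Transfer recipients are drawn uniformly among
  contemporaneous branches outside the donor's top-level clade
  (`transfer_recipients = "cross_clade"`; a plain uniform mode exists).
  Cross-clade recency is the observable HGT regime for a
  displacement-based test — within-clade transfers are undetectable in
  principle — and matches the kind of events the original analysis
  reports (distant lineages acquiring the core complex).  Rates were
  chosen once for signal strength, not realism; the true history's rates
  are unknown.
* **Sequences.**  Uniform 20-state substitution (0.3 substitutions per
  site per unit depth, 2000 residues; no indels, so alignments are exact
  by construction), root sequences uniform.  The per-branch kernel is
  the exact CTMC transition `P(change) = (19/20)(1 − e^{−(20/19) r t})`
  with uniform replacement, so the expected tip-pair difference obeys the
  closed form the distance correction inverts.
* **Genomes.**  Family copies are grouped into module copy-sets (the
  co-duplicated cluster copies) and placed as contiguous blocks with
  probability `p_linkage = 0.9` per genome among 60 background genes
  (random 60-residue proteins); the focal genome is always linked — the
  study organism is studied *because* it displays the clustered
  machinery.  Content is likewise conditioned on the focal genome
  carrying every family (rejection resampling).
* **Screens and features.**  Two synthetic transposon-hit lists cover the
  focal genome (machinery loci hit at 0.7/0.4, background at 0.12/0.08,
  with every machinery block guaranteed two hits — unsaturated but not
  blind screens); features copy per-family envelope-style templates with
  5% flip noise over stated background frequencies.

What the simulator does **not** model: indels and alignment error, rate
heterogeneity across sites and lineages, codon/DNA-level processes, gene
conversion, circular chromosomes, operon transcription, and
database-scale homology search (filler proteins are short random
sequences, not a realistic fold space).  Passing recovery tests therefore
demonstrates the *logic* of the inference chain under its own model
assumptions, not performance on real proteomes.

# Event-recovery scoring

Inferred families are matched to truth families by maximal Jaccard
overlap; membership precision/recall are micro-averaged over loci.
Gains, losses and duplications match on exact (family, branch) identity.
Transfers match on the recipient branch only, and an inferred recipient
on or below the true recipient branch counts: displacement localizes a
transfer to the displaced *tip*, so a transfer into an internal branch
that is detected via one surviving descendant is a recovered event, and
several displaced descendants of one internal-branch transfer are
manifestations of that single event.  Timing is never compared —
inference cannot recover it.

# Problem sizes and reproducibility

All randomness flows from one seed through named substreams
(`substream_seed`), so every dataset, bootstrap and pipeline run is
exactly reproducible; identical configuration implies byte-identical
outputs.  The shipped analyses use: 20 replicate datasets for the
recovery benchmark (the acceptance tests), 10 shared-history datasets
with 200-residue genes for the supermatrix-resolution comparison (the
scale of the cleaned single-gene alignments behind the published
supermatrices, where concatenation has something to add; at 2000
residues single genes are already saturated at 100% support), 100 random
6–10-leaf trees for NJ exactness, all 63 presence profiles on each of 20
random 6-leaf trees for the Dollo oracle, and 2000 birth–death
replicates for the copy-number expectation.  The supermatrix comparison
is pre-committed as: the supermatrix median support is at least the
median single-family median support in ≥9 of 10 datasets.

# Known limitations

* Homologue absence means "no proteome hit"; there is no second-pass
  nucleotide-level verification of absences.
* The representative cap in family expansion can, in principle, miss a
  chain of divergence that exact single-linkage would follow; the exact
  mode is available and used in tests.
* Displacement cannot see transfers whose descendants form intact
  multi-tip blocks, nor within-clade transfers; recall targets are set
  with this in mind.
* Published homologue counts and supermatrix dimensions depend on a
  historical database snapshot and manual curation, and are treated as
  shape references only (the fixture reproduces printed *counts*, not
  database content).
* Dollo assumes a single gain; families that were truly gained twice
  would be misread as gain-plus-losses.
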