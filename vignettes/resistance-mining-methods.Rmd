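---
title: "Resistance-gene-guided BGC mining: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resistance-gene-guided BGC mining: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resMiner)
```

## The biological model

Many fungal natural products inhibit an essential housekeeping enzyme. A
producer protects itself by keeping, inside the biosynthetic gene cluster
(BGC) itself, a second copy of the target gene whose product resists the
toxin — a *self-resistance gene*. This inverts the usual discovery logic:
instead of asking "what does this cluster make?", one asks "which clusters
carry a diverged duplicate of an essential enzyme?" — those are enriched
for bioactive compounds, and the duplicated gene immediately proposes the
compound's target.

resMiner implements this screen. A panel of conserved housekeeping
proteins (*hooks*) serves as bait. A candidate cluster is **flagged**
when:

1. some member gene encodes a *close homologue* of a hook, and
2. the genome carries at least one additional qualifying copy of that hook
   **outside** the cluster — the cell's intact essential copy.

The second condition is the duplication rule. We deliberately do not count
the in-cluster copy itself toward "duplicated": the self-resistance logic
requires an essential copy *beyond* the cluster, and counting the cluster
copy would flag every cluster that happens to encode a hook homologue,
including ordinary single-copy genes swept into a candidate window.

Flagged clusters from many genomes are then grouped into gene-cluster
families, refined so that every family shares the same core-enzyme
signature and the same hook, and families confined to a single genus are
discarded: a cluster family maintained across genera is much less likely
to be an artifact of one lineage's gene arrangement.

## Pipeline stages and their parameters

All thresholds below are exposed through `runConfig(thresholds = ...)`;
identities are percentages over aligned columns, coverages are aligned
span / sequence length in (0, 1].

**Local alignment.** All homology decisions use affine-gap Smith-Waterman
(Gotoh) with BLOSUM62, gap open 11, gap extend 1 (a gap of length *k*
costs `11 + k`). `X` (ambiguous translation) scores 0 against everything,
so it neither rewards nor penalises a column. The traceback is
deterministic: among equally scoring end cells the smallest row then
column wins; within a cell the preference is diagonal, up, left. The
engine is written in C++; it locates the optimal alignment with two
linear-memory passes and builds the traceback matrix only on the spanned
subrectangle, which keeps genome-scale scans affordable. An optional
k-mer prefilter exists conceptually in this design space but is not used:
it is not lossless at low identity, and every search here is exhaustive.

**Hook hits** (`searchPanel`): identity >= 50, coverage of the *hook* >=
0.7. The coverage is tested on the hook side so that a short local match
inside a long multidomain protein cannot qualify; the identity floor is
strict enough to separate a planted resistance copy (60-80% identity in
the synthetic suite) from generic distant paralogs.

**Core-enzyme detection** (`detectCoreGenes`): identity >= 30, coverage
of the *reference* >= 0.5 against a class-labelled reference FASTA. The
shipped reference set is synthetic (fixed-seed stand-in sequences, one per
class: HR-PKS, NR-PKS, NRPS, NRPS-like, terpene synthase,
prenyltransferase) — it is a placeholder with the right shape, not real
enzymes, and file names say so. A gene hitting both a PKS and an NRPS
reference on query segments whose overlap is below 20% of either segment
is called a PKS-NRPS hybrid: the two halves of a genuine fusion protein
align to different references on disjoint stretches of the query.

**Region assembly** (`assembleRegions`): every core gene seeds a window
grown gene-by-gene while at most 4 genes have been added on that side and
the intergenic gap stays <= 10 kb; overlapping windows merge. Fungal BGCs
are tightly packed and rarely exceed ~15 genes, so these defaults keep a
planted cluster intact while absorbing only a few flanking genes.

**Boundary delineation** (`delineateBoundaries`): for the genes of
flagged regions, the occurrence index measures in what fraction of the
*other* input genomes a gene has a homologue (identity >= 50, coverage of
the gene >= 0.6). Genuine cluster genes show restricted occurrence;
housekeeping flanks are widely distributed. From each flank inward, genes
with occurrence >= 0.5 are trimmed until the first restricted gene; core
and hook genes are never trimmed. The operation is idempotent and runs
only in multi-genome mode — with one genome the notion of occurrence is
empty, and the run reports that trimming was skipped.

A consequence worth stating plainly: a genome-*unique* gene adjacent to a
cluster is indistinguishable from a cluster gene under this rule, and it
shields anything beyond it from trimming. In the synthetic benchmark the
boundary-exactness diagnostic is therefore well below 1 under default
conditions, by design; exact trimming is demonstrated (and tested) on
regions flanked by genes planted at 0.8 occurrence.

**Family grouping** (`clusterFamilies`): genes of two regions are matched
by reciprocal best alignment at >= 40% identity with >= 0.6 coverage of
*both* genes. The coverage condition is essential: short local matches
between unrelated proteins routinely exceed 40% identity over a handful
of columns, and without it disjoint regions acquire phantom shared genes.
Similarity then combines the
Jaccard index of matched content (weight 0.3), an adjacency index — the
Jaccard of unordered adjacent matched-pair sets, so wholesale gene-order
reversal is neutral (weight 0.2) — and mean matched identity (weight
0.5). Regions join a family by single linkage when distance
`1 - combined <= 0.3`. This in-package similarity replaces an external
clustering tool so that the pipeline is self-contained and its clustering
testable; `importFamilyAssignments()` can ingest an external tool's
assignment for parity runs. Family ids are deterministic (ordered by
smallest member region id), so numbering is reproducible but
run-specific.

**Refinement and the genus filter** (`refineFamilies`,
`dropSingleGenus`): families are partitioned by the key (core-class
multiset, hook id) — never merged — and families whose members all share
one genus are removed.

## The synthetic data generator

`generateGenomes()` emulates exactly what the screen needs to see, and
nothing more:

* background genes are random ORFs, 300-1500 bp, intron-free; half of
  them (configurable) come from a pool shared by all genomes at ~88%
  identity, emulating the widely distributed housekeeping complement that
  boundary trimming relies on;
* planted clusters carry a core gene mutated from the class reference at
  ~70% identity, accessory genes, and — for the two kinds that should
  have one — an in-cluster hook homologue at the plant's target identity;
* plants sharing a family label derive from one template (members at 96%
  of it), so they form a recoverable cross-genome family;
* intact outside copies of the hook (88% identity) go on a second contig,
  far outside any assembled window;
* planted genes are reverse-translated with uniformly random synonymous
  codons and may receive 0-2 introns, exercising the splicing path of the
  readers; codon-usage bias is deliberately not modelled;
* every emitted file set is self-audited: the generator re-reads its own
  FASTA + GFF3 through `readGenome()` and verifies each planted protein.

Four plant kinds encode the screen's truth table: `true_resistant_bgc`
(hook in cluster + outside copy: flag), `decoy_no_duplicate` (hook in
cluster, no outside copy: no flag), `decoy_no_hook` (cluster without a
hook homologue: no flag), and `decoy_duplicate_outside_only` (intact
outside copies but no cluster copy: no flag).

The default conditions (`defaultSimConfig()`) are five genomes — three
*Aspergillus* (Eurotiomycetes), two *Hypoxylon* (Sordariomycetes) — with
four true clusters at 70-75% hook identity forming two truth families
(one spanning both genera, one confined to *Aspergillus*) plus three
decoys of each decoy kind, 40 background genes per genome. These sizes
keep a full run around a minute on one core while leaving every decision
the screen makes non-trivial.

What passing on this generator does **not** show: robustness to
annotation errors, fragmented assemblies, transposon-riddled flanks, real
PKS/NRPS domain architecture, or hooks whose paralog structure is itself
complex (e.g. tubulin families). Results on real genomes depend on the
quality of the annotations and of the hook panel in a way the synthetic
suite cannot probe.

## Numerical and design choices

* **Coordinates.** All intervals are 1-based closed `IRanges`/`GRanges`
  internally — the native convention of the container library, mapping
  1:1 onto GFF3 and GenBank I/O and delegating interval arithmetic to
  IRanges.
* **Ties.** Panel hits tie-break on score then lexicographic hook id;
  RBH matching ties on partner id; family numbering orders by smallest
  member region id. Every tie in the system has a documented, tested
  resolution so that reruns are byte-identical.
* **Determinism.** `report.json` contains no timestamps; the MANIFEST
  carries run status instead. Two runs with identical inputs and seed
  produce byte-identical reports — this is asserted in the test suite.
* **Degenerate inputs.** Empty genomes yield empty proteomes and no
  regions; a single-genome run skips boundary trimming with a notice;
  zero flagged regions produce an empty (but valid and schema-complete)
  report; precision over zero flags is reported as 1 with an explicit
  notice.
* **Hook panel construction.** The criteria by which a "highly conserved"
  housekeeping set should be derived are genuinely open; `buildPanel()`
  operationalizes it as reciprocal-best-hit conservation (identity >= 40,
  coverage >= 0.6 both sides) in at least `ceiling(0.8 x comparators)`
  proteomes. This is a standard orthology proxy, fully testable, and all
  three knobs are exposed. Hooks under 50 aa are rejected outright —
  identity/coverage thresholds are meaningless for very short baits.
* **Annotated genomes required.** The package reads existing gene models
  (FASTA + GFF3, or GenBank); it does not predict genes on unannotated
  assemblies. This keeps the tool honest about where its inputs come
  from; ab initio prediction would silently dominate every downstream
  result.

## Known limitations

* Core detection is similarity-based against a small reference set;
  profile/HMM models would generalise better across enzyme families and
  can be slotted in behind `detectCoreGenes()` without changing its
  contract.
* The duplication rule counts qualifying copies only; it does not check
  that the outside copy is intact (full-length, expressed), which real
  self-resistance logic would care about.
* Family similarity ignores domain-level architecture; two NRPS clusters
  with different module counts can look more similar than they are.
* E-value statistics are intentionally absent; all thresholds are raw
  identity/coverage, which is transparent but corpus-size-blind.

## A worked example

```{r example, eval = FALSE}
library(resMiner)

sim <- generateGenomes(defaultSimConfig(seed = 1), "sim")
cfg <- runConfig(
  genomeTable = data.frame(fasta = sim$fasta, gff = sim$gff),
  taxonTsv = sim$taxonTsv, outDir = "out", seed = 1)
report <- runMine(cfg)

evaluateRecovery(report, sim$truth)[c("flagRecall", "flagPrecision")]
familyTable(report$familiesFinal)
```

The run writes per-genome region tables, the flagged-region table, family
and taxonomy tables, one GenBank file per flagged region, `report.json`
and a MANIFEST under `out/`.
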