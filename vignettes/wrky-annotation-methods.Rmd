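---
title: "Methods: WRKY family annotation with wrkyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WRKY family annotation with wrkyscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wrkyscan annotates WRKY transcription-factor gene families: it detects WRKY
domains in protein sequences, classifies genes into the family's standard
groups, types the introns that interrupt domain-coding DNA, scans promoters
and protein sequences for regulatory motifs, finds tandem-duplication
clusters, summarizes tissue expression, and builds bootstrapped
neighbour-joining trees. This vignette explains the models and rules behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design choices made where conventions in
the literature are underspecified.

## The WRKY domain grammar

A WRKY domain is a roughly 60-residue DNA-binding module with two parts:

* a seven-residue core ("heptamer") whose canonical sequence is `WRKYGQK`;
  the consensus for the first four residues is `W(R/K)(K/R)Y`, and real
  families carry variants such as `WRKYGKK`, `WKKYGQK`, or rarer forms like
  `WRMCGQK` and `WVKYGQK`;
* a zinc finger a short linker downstream, either
  C2H2 (`C-X4-5-C-X22-23-H-X1-H`) or C2HC (`C-X5-7-C-X23-H-X1-C`).

`scan_heptamers()` reports all matches of the four-residue consensus
(canonical tier) plus exact matches from a configurable variant table
(default `WSKY`, `WVKY`, `WRMC`; variants that already satisfy the
consensus, such as `WKKY`, need no table entry). `scan_zinc_fingers()`
matches both finger patterns left to right, trying shorter admissible
spacers first, with ties preferring C2H2; matches consume their span, so
the scan is deterministic. `assemble_domains()` pairs each heptamer with
the nearest unused finger starting within a **linkage window** downstream.

Two policies deserve justification:

* **Linkage window (default 30 aa).** The linker between the heptamer and
  the finger's first cysteine is short in real domains (usually under 15
  residues); published surveys never state a numeric bound. 30 residues
  accepts every plausible linker while preventing a heptamer from pairing
  with a finger half a protein away. It is a parameter of
  `assemble_domains()` and of the pipeline configuration.
* **Variant tier gate.** A variant heptamer is only reported when a
  confirming zinc finger pairs with it. Canonical heptamers are specific
  enough to stand alone (and unpaired ones define group IV candidates),
  but four-residue variants like `WRMC` would otherwise litter scans with
  false positives. This mirrors how surveys accept variant-motif loci only
  when the rest of the domain is intact.

## Group and subgroup classification

The family's standard taxonomy is applied by `classify_protein()`:

| Condition | Label |
|---|---|
| ≥ 2 complete domains, all C2H2 fingers | Ia |
| ≥ 2 complete domains, all C2HC fingers | Ib |
| 1 complete domain, C2HC finger | III |
| 1 complete domain, C2H2, spacer `CX4C` | IIc |
| 1 complete domain, C2H2, `CX5C` + trailing signature | IIa / IIb / IId / IIe |
| no complete domain | IV |

The trailing signatures are anchored immediately after the second cysteine:
IIa `PVKKK(L/V)Q`, IIb `PVRKQVQ`, IId `PARKHVE`, IIe `PARK(Q/M)V(E/D)`.
Signature matching tries an exact match first, then a fuzzy match within a
Hamming budget (default 1 mismatch) that is aware of the positional
alternations. The fuzzy fallback exists because real sequences drift and a
survey classifies every gene; the budget is configurable and every fuzzy
firing is recorded in the evidence column.

Three open points were decided here:

* **Mixed-finger two-domain proteins** are labelled by the C-terminal
  finger, with an evidence note. The C-terminal domain is the one
  functionally conserved (it is the DNA-binding domain in group I
  proteins), and domain trees treat the N- and C-terminal domains
  separately anyway.
* **Unresolvable single-C2H2 proteins** (spacer 5, no signature within the
  budget) are labelled IIe with a warning in the evidence trail rather than
  given a new label, keeping the closed label set.
* **Group IV secondary labels.** Proteins without a complete domain are
  group IV; when an intact zinc finger survives, it is classified by the
  same signature table and reported as a secondary label, matching how
  surveys re-assign incomplete-domain genes by their finger structure.

Isoform handling follows the usual convention: `select_isoforms()` keeps,
per locus, the transcript encoding the longest protein, breaking ties by
the lexicographically smallest transcript id so reruns are identical.

## Intron phases and PR/VQR typing

Intron **phase** is the intron's position relative to codon boundaries:
phase 0 between codons, phase 1 after the first nucleotide of a codon,
phase 2 after the second — equivalently, the number of coding nucleotides
upstream of the intron modulo 3. `intron_phases()` computes the coding
offset of every intron in translation orientation; UTR introns are reported
but never phased or typed.

Within domain-coding DNA, two recurring intron classes are typed by
`type_domain_introns()`:

* **PR type**: a phase-1/2 intron interrupting the codon of an arginine
  inside the domain span (phase 2 in almost all known cases; the phase-1
  variant occurs and is handled).
* **VQR type**: a phase-0 intron immediately 5' of a valine codon. By
  default the full V-Q-R residue context is required after the intron; the
  check can be relaxed to the valine alone, because the type's name comes
  from the context but published definitions only pin the valine.

PR detection accepts any arginine within the domain span. The conserved
position is a fixed column of the domain alignment, but its offset varies
with spacer lengths; the report includes the residue's offset so downstream
analysis can restrict to the conserved position if an alignment is at hand.
Counts of domains harbouring neither intron type can be produced at both
per-domain and per-gene granularity from the typed table, since the two
conventions are both used in the literature.

## Linear motifs: MAPK sites and docking motifs

MAPKs are proline-directed kinases; the scanner's default grammar uses the
literature-standard patterns: minimal site `(S/T)P`, preferred site
`P-X-(S/T)-P`, the docking D-motif `(K/R)1-3 - X1-6 - Φ-X-Φ` with Φ in
{L, I, V}, and the F-site `F-X-F-P`. The grammar ships as data
(`motif_grammar()`, overridable from TSV) because cohort-level percentages
are grammar-dependent and users may want the exact pattern set of a
particular source. Within a class, matches are non-overlapping and
leftmost-first, taking the longest admissible match at each position —
a deterministic rule that an independent brute-force matcher can reproduce
exactly (and does, in the test suite). Classes are scanned independently,
so a D-motif may overlap a phosphosite.

## Promoter cis-elements and responsiveness categories

Promoters (default: 1,500 bp upstream of the gene's
translation-orientation start; the window length is configurable because
published surveys rarely state theirs) are scanned on both strands for
IUPAC consensus elements. The default table — ABRE `ACGTG(G/T)C`, coupling
elements CE1 `TGCCACCGG` and CE3 `ACGCGTGTC`, DRE `(A/G)CCGAC`, SARE
`TTCGACC`, W-box `TTGAC(C/T)` — ships as a TSV config, not code, because
element definitions vary across sources and should be replaceable without
touching the scanner.

Responsiveness flags implement the ABA-coupling rule: a lone ABRE confers
nothing; ABA responsiveness requires ABRE together with a coupling element,
a second ABRE, or a DRE. SA responsiveness is SARE presence, drought
responsiveness DRE presence, and WRKY autoregulation W-box presence. The
six promoter categories are evaluated from an ordered, data-driven rule
table (`promoter_categories.yaml`): all-flags (5), SA + coupled ABA +
drought (4), SA + coupled ABA (2), SA + drought without coupled ABA (3),
SA only (1), residual (6). The table is data because the category
definitions in the source literature live in supplementary material with
varying conventions; the defaults reconstruct the category examples that
are stated in prose.

## Chromosome distribution and tandem clusters

Gene density is genes per million base pairs. A tandem-duplication
**cluster** is a maximal run of consecutive family genes on one chromosome
whose span — gene start of the first member to gene end of the last — is
at most `max_span` (default 400 kb) with at least `min_genes` members
(default 4), the thresholds used for rice-family cluster descriptions.
"Maximal" means extending the run either way violates the span bound;
`detect_clusters()` finds these with a two-pointer sweep whose output is
verified against exhaustive window enumeration in the tests. Cross-genome
cluster comparison translates members to orthologue names and reports
shared names, order identity (allowing a whole-cluster reversal, which
absorbs strand and assembly flips), and one-sided losses; ambiguous
many-to-many matches are reported, never resolved silently.

## Expression summaries

The expression module consumes an RPKM matrix (genes × tissues). The
baseline tissue is the one with the lowest mean expression; the
conventional expression threshold is 50 RPKM, and
`expression_threshold_grid()` re-derives that choice by reporting the
smallest grid value `{10, 20, 50, 100}` for which more than 95% of genes
sit below it in the baseline tissue. Comparisons follow the survey
phrasing exactly: strictly below for the baseline fraction, at least for
the expressed set. Peak-tissue calls are per-gene arg-max with first-tissue
tie-breaks, flagged.

## Phylogeny

Trees are distance-based: p-distance (mismatches over comparable sites,
pairwise gap deletion by default — the common default in MEGA-style
analyses; complete deletion is available) followed by neighbour joining.
Negative NJ branch-length estimates are clamped to zero and counted,
matching common practice. Bootstrap support resamples alignment columns
with replacement, rebuilds the tree per replicate, and scores each
original bipartition by its replicate percentage; the seed is explicit and
supports are invariant to row order because columns, not rows, are
resampled. The N- and C-terminal domains of two-domain proteins enter
domain trees as separate `.N`/`.C` rows. `clade_composition()` asks, per
group and for the conventional unions IIa+b, IId+e and III+Ib, whether an
edge bipartition isolates exactly that label set, and otherwise reports the
minimum number of maximal pure subtrees covering it — the "split into two
clades" statistic used to discuss subgroup IIc.

Alignment computation itself is out of scope: the package consumes aligned
FASTA produced by any aligner.

## The synthetic-data generator

`gen_cohort()` produces a complete, internally consistent dataset — genome
FASTA, GFF3 gene models, proteins, promoters, an RPKM matrix, an orthologue
map — together with machine-readable truth for every planted feature.
Its defaults emulate the conditions of a genome-wide rice-family survey:

* 97 genes with the empirical group histogram (III 28, IIc 22, Ia and IIe
  11 each, IIb and IId 7, IIa 4, Ib 2, IV 5), scalable via `n_genes`;
* 12 chromosomes with three planted tandem clusters (6, 4 and 7 genes over
  roughly 308, 220 and 199 kb) populated preferentially with group III
  genes; scattered genes sit 420 kb apart, beyond the cluster threshold;
* PR introns planted in the designated domain arginine of most
  single-domain genes (phase 2, occasionally phase 1), VQR introns before
  the designated valine of IIa/IIb genes, PR in the C-terminal (Ia) or
  both (Ib) domains of group I genes;
* promoters carrying planted element sets realizing each of the six
  categories;
* a four-tissue RPKM matrix (root, shoot, flag leaf, panicle) in which the
  panicle is globally lowest and the root highest.

Design choices that make truth recovery exact rather than probabilistic:

* Flanks and spacers are drawn from an alphabet without C, H or W, so no
  spurious heptamer or finger can arise; each planted finger carries a
  designated `VQR` triplet in its second spacer so intron plans always
  have a valid arginine and valine inside the domain.
* Promoter backgrounds are scrubbed of chance element matches by
  rescanning and resampling before planting, and the planted plan is
  verified by a scan; junction artefacts trigger a fresh background.
* Reverse translation uses a fixed most-frequent-codon table, and all
  randomness flows from a single seed, so regeneration from
  `(seed, config)` is identical.
* Expression values are a per-gene base level times a tissue scale times
  bounded multiplicative noise (`exp(σz)`, `z` truncated to ±1, σ = 0.3);
  the planted peak tissue receives the maximum scale times a 2.5× effect,
  which strictly dominates every other tissue because
  `2.5 > exp(2σ) ≈ 1.82`. Expressed genes draw base levels in a range
  ([40, 140] RPKM, log-normal) that keeps every gene below 50 RPKM in the
  lowest-scaled tissue while commonly exceeding the smaller candidate
  cutoffs, so the 50-RPKM convention re-emerges from the grid computation;
  genes peaking in the baseline tissue are kept below the expression
  threshold, mirroring a baseline chosen precisely because little is
  expressed there.

What the generator does **not** emulate: real codon usage, GC structure and
repeats; intron length distributions; UTRs (gene spans equal CDS spans);
HMM-score ambiguity around marginal domains; promoter element densities of
real genomes (backgrounds are scrubbed clean, so scanner false-positive
rates on real sequence are probed separately via the GC-configurable
background, not by the truth-recovery tests). Passing truth-recovery tests
therefore demonstrates the correctness of the annotation logic, not
robustness to the full messiness of real genomes.

## Numerical and procedural details

* Coordinates are 1-based inclusive throughout (the GFF3 convention);
  BED export converts to 0-based half-open at the boundary. Round-trip and
  strand-mirroring property tests guard the off-by-one surface.
* Ambiguity codes other than N are rejected at FASTA parse time; N
  translates to X.
* Ties: isoform selection → smallest transcript id; peak tissue and
  baseline tissue → first tissue in column order, flagged or logged;
  zinc-finger pattern ties → shorter match, then C2H2.
* Degenerate inputs: empty FASTA, orphan GFF3 features, CDS lengths not
  divisible by three (error unless flagged partial), proteins with internal
  stops (flagged, never silently truncated), alignment pairs with no
  comparable sites (error naming the pair), distance matrices that are not
  symmetric (error).
* Problem sizes in the shipped tests: the end-to-end cohort uses 200
  genes; oracle-equivalence suites use 1,000 random layouts of up to 50
  genes for clusters, 100 random proteins up to 200 aa for motifs,
  quartets plus 5-6-taxon trees for NJ; the bootstrap check uses two
  6-sequence clades at B = 200. These sizes exercise every code path while
  keeping the default test run fast.

## Known limitations

* Domain detection is pattern-based, not profile-based; an adapter for
  external HMMER tabular hits can stand in as an alternative hit source,
  but HMM scoring itself is out of scope.
* Orthologue nomenclature is consumed from a mapping table, never
  computed; BLAST-based naming is a separate concern.
* The promoter element table and category rules are reconstructions of
  conventions whose authoritative definitions vary; both ship as editable
  config files.
* Trees on real alignments depend on alignment quality; manually curated
  alignments are not reproducible by the package and will differ in
  detail.
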