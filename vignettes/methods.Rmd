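---
title: "Methods: frameshift detection, hub ranking and quantification in ciliome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frameshift detection, hub ranking and quantification in ciliome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliome)
```

# Scope and model organisms

`ciliome` analyses cilia-associated genes in hypotrich ciliates
(*Euplotes*, *Oxytricha*, *Stylonychia*). Two genomic peculiarities shape
every component. First, the somatic (macronuclear) genome consists of
gene-sized nanochromosomes capped by short telomeric repeats — in
*Euplotes*, C4A4 at the 5' end and its reverse complement G4T4 at the 3'
end — so assembly contigs are expected to be telomere-capped single-gene
units, and assembly clean-up amounts to removing fragments of longer
contigs and sub-minimal scraps. Second, these lineages use variant
nuclear genetic codes: the Euplotid code reads UGA as cysteine (stops UAA,
UAG), while the *Oxytricha*/*Stylonychia* code reads UAA/UAG as glutamine
(stop UGA). All translation in the package goes through an explicit
`GeneticCode` object built on the Biostrings code tables; a codon
containing an ambiguity letter translates to `X` and can never terminate
an ORF.

# Programmed ribosomal frameshift detection

## The procedure

A +1/+2 PRF gene is modelled as a transcript whose initial reading frame
terminates at an internal UAA/UAG while its conceptual translation, after
removing the first one ("T", a +1 shift) or two ("TA", +2) bases of that
stop from the reading frame, continues in register with a homologous
reference protein (the *C-terminal extension*). Detection proceeds in
three stages:

1. **Candidates** (`findCandidates()`): translated-search hits of each
   transcript against the reference set are grouped; a transcript whose
   hits to the *same* reference fall in two or more reading frames, with
   the downstream hit covering a more C-terminal region of the reference,
   is a candidate pair.
2. **Event classification** (`classifyEvent()`): at the terminal stop of
   the current frame both excisions are applied to a working copy and the
   edited transcript is re-translated in the original frame. An excision
   is accepted when the translation downstream of the stop matches the
   reference with at least `minExtensionAa` identical residues
   *contiguous with the stop*.
3. **Iteration** (`detectPrf()`): the winning excision is applied and the
   scan repeats — next terminal stop, classify, excise — until the
   reference C-terminus is reached, no excision validates, or `maxEvents`
   accumulate (the gene is then flagged `truncated`). Event positions are
   reported in original transcript coordinates.

## Numerical and design choices

* **Contiguous-run scoring.** The extension score is the length of the
  identity run immediately following the excised stop, not the total
  number of matching positions downstream. The distinction matters for
  multi-event genes: excising two bases where one was inserted leaves the
  frame off by one until the *next* frameshift site, where it
  re-synchronises — total-match scoring can then favour the wrong
  excision, while the contiguous run (which for the wrong excision dies
  at the first residue with ~94 % probability) cannot. This also mirrors
  the biological criterion: the extended protein continues directly from
  the frameshift site.
* **`minExtensionAa = 10`** guards against spurious 1–2-residue
  "extensions" from chance matches; at a ~6 % per-residue background
  identity, ten contiguous matches by chance are vanishingly unlikely.
* **Ties resolve to +1**, the dominant model among validated *Euplotes*
  PRF genes. In practice the contiguous-run scores of the two excisions
  are never equal on validating events unless both run to the end of a
  very short reference.
* **Slippery context is recorded, never filtered.** The canonical context
  is 5'-AAA-UAR-3', and it dominates, but validated genes carry many
  other contexts (TGTTAG, TTCTAA, GGATAA, ATATAA, ...). The optional
  strict mode (`requireAaatar = TRUE`) restricts acceptance to AAATAR for
  users who want the conservative rule.
* **ORFs are stop-to-stop, not ATG-anchored** (`findOrfs()`): ciliate
  transcripts are gene-sized, poly(A) units, and the PRF procedure
  reasons about the terminal stop of a reading frame rather than a start
  codon. An ATG-anchored mode is available by flag.

# Contig filtering

`filterContigs()` removes (a) contigs shorter than 100 bp
unconditionally, and (b) contigs shorter than 500 bp that align to a
contig of at least 500 bp with percent identity ≥ 90 and coverage ≥ 80.
Coverage is computed on the **query** (the short contig): the rule
targets short redundant fragments of longer nanochromosomes, so the
relevant question is how much of the *fragment* is explained. Each
removed contig carries exactly one machine-readable reason, with the hard
length minimum taking precedence. The filter is idempotent by
construction (kept contigs are re-evaluated against the same rules).
Telomere detection defaults to the *Euplotes* C4A4 unit with at least two
tandem copies inside a 60-nt terminal window; both the unit and the
window are configurable since related lineages differ.

# Homology search and family assignment

`searchProtein()` computes Smith–Waterman local alignments (Biostrings,
BLOSUM62, gap open 11 / extend 1) and converts raw scores to bits with
the standard gapped Karlin–Altschul parameters for that scoring system
(λ = 0.267, K = 0.041), then to E-values as E = m·n·2^−S' with m the
query length and n the total database length. Effective-length
corrections are not applied; for desk-scale databases the difference is
immaterial against the 1e-5 acceptance cutoff, and externally produced
tabular hit files can be imported wherever exactness against a production
search engine matters. Families are assigned by best exemplar hit
(bitscore, then E-value, then lexicographic exemplar id) — a deliberate
simplification matching how curated query sets define families, not a
clustering. Conservation partitioning (`vennPartition()`) is a true
partition of distinct families by their exact species set; the conserved
core is exposed at both family and gene granularity because either
reading of a cross-species core is defensible.

# Centrality scores and consensus hubs

The twelve scores follow their standard published formulations (Degree;
MNC as the largest connected component of the open neighborhood; DMNC as
|E|/|V|^1.7 of that component; MCC as Σ(|C|−1)! over maximal cliques;
harmonic Closeness; Radiality; Betweenness; Stress; local clustering
coefficient; EcCentricity as component diameter minus eccentricity so
larger is central; EPC as the mean component size of a node under
independent edge survival at p = 0.5, Monte Carlo with a caller-supplied
seed and `epcReps` replicates). Distance-based scores are computed per
connected component. Exact parity with any particular plugin build is a
non-goal; each definition is validated against independent brute-force
oracles in the test suite instead.

**BottleNeck** deserves a note: formulations based on a single
shortest-path tree per source are not well defined on graphs with tied
shortest paths — any tie-break makes the score depend on node labels,
violating the basic requirement that a topological score be invariant
under relabeling. The package therefore uses the label-invariant
dominator form: for each source s, a node v ≠ s scores one point when it
lies on *every* shortest path from s to more than a quarter of s's
component. On trees this reduces exactly to the subtree-size rule.

Rank ties share the minimum rank ("1224"), so the top-k boundary is
inclusive and tied candidates are never dropped arbitrarily. A node is a
consensus hub when at least `m = 6` of the twelve methods rank it within
the top `k = 50`.

# Quantification

Fold changes use the 2^−ΔΔCq model: ΔCq = Cq(target gene) − Cq(reference
gene) per sample, ΔΔCq across samples, fc = 2^−ΔΔCq. Replicate wells are
combined by arithmetic mean of Cq; any replicate with Cq ≥ 30 is excluded
as invalid before averaging. Replicate-level ΔCq values (each well minus
the sample's mean reference Cq) feed a Welch unequal-variance t-test and
the ΔΔCq standard error; the significance level follows the conservative
p < 0.01 convention. Track kinematics use consecutive-frame displacements
at the nominal 0.3 s sampling interval without smoothing (an optional
moving-average window exists for jittery recordings); straightness is net
displacement over path length; circles are fitted by the algebraic
least-squares (Kåsa) method, with exactly collinear input flagged as
radius ∞ via rank detection in the normal equations.

# The synthetic-data generators

`synthSpec()` fixes every tunable; each generator is a pure function of
the spec (identical seeds give byte-identical outputs, and the caller's
RNG stream is left untouched). Defaults encode the study conditions the
package targets:

* stop usage 77 % TAA / 23 % TAG; intron mix 79 % intron-free, 13.4 %
  single-intron, the remainder spread over 2–4 introns;
* ~30 % of transcripts carry 1–3 PRF events whose contexts are sampled
  from the repertoire observed in validated genes
  (`prfContextRepertoire()`), AAATAA-dominated, with +2 events at their
  observed contexts; reference proteins are 400 aa with a
  BLOSUM62-background composition (avoiding accidental homology);
* PRF planting inserts the first one or two bases of a stop codon at a
  codon boundary — the exact inverse of the detector's excision — with
  sites at least 40 codons apart and 40 codons from either end, so every
  extension is long enough to validate;
* the interaction network plants hubs as nodes attaching to 60 % of the
  members of 8 of 12 dense 20-node modules over a p = 0.02 background
  (300 nodes, 10 hubs);
* tracks sample a straight line (100 µm/s) and a 50 µm circle at 0.3 s
  with 0.5 µm Gaussian jitter; Cq tables plant known ΔΔCq values with
  0.05-cycle replicate noise.

The generators also emit the translated-search hit table the upstream
alignment stage would produce, derived from the planted frame segments.
What passing tests show is therefore that the *procedures* are correct on
data satisfying their assumptions: noise-free frame segments, exact
reference match outside frameshift sites, modular network structure,
Gaussian track noise. Real transcriptomes add sequencing error, paralogy,
incomplete references and alignment ambiguity; real networks add hubs
that are hubs only under some score families; recovery rates on such data
will be lower and are not claimed here.

# Problem sizes and runtime choices

The shipped test suite runs at desk scale, chosen to exercise every code
path while keeping a full run in the low minutes: 200-transcript PRF
recovery, 100 random graphs of ≤ 7 nodes against exhaustive oracles (with
exact EPC enumeration restricted to ≤ 10 edges) plus 12 graphs of ≤ 30
nodes against independent library routines, a 300-node hub-recovery
network with 500 EPC replicates, and 150-gene synthetic genomes. EPC's
Monte-Carlo error scales as reps^(−1/2); the default `epcReps = 1000` puts
the standard error well below typical score gaps on networks of a few
hundred nodes.

# Known limitations

* The PRF detector validates extensions against the supplied reference
  set only; genes whose true homolog is absent are invisible.
* −1 frameshifts and reverse-strand genes are out of scope by default
  (reverse-complement scanning is available in `findOrfs()` and
  `searchTranslated()`).
* E-values are approximations sufficient for thresholding at 1e-5, not
  replacements for a production search engine on large databases.
* Family assignment is best-hit, not orthology inference; gene trees and
  reciprocal-best graphs are out of scope.
* Fold-change values from field data depend on amplification efficiency,
  which the 2^−ΔΔCq model assumes to be 2 exactly.
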