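---
title: "Discovering nitrogen-cycle auxiliary metabolic genes in viral metagenomes"
author: "amgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering nitrogen-cycle auxiliary metabolic genes in viral metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amgkit)
```

## The problem

Marine oxygen minimum zones (OMZs) host intense microbial nitrogen cycling —
denitrification, nitrification, anammox — and dense viral communities.
Phages infecting these microbes sometimes carry host-derived metabolic genes
("auxiliary metabolic genes", AMGs) such as nitrite reductases (*nirA*,
*nirK*), nitric oxide reductase (*norB*), ammonia monooxygenase subunit C
(*amoC*), the formate/nitrite transporter *focA*, and the nitrogen regulator
*glnK*. Establishing that a candidate AMG is genuinely viral, genuinely a
nitrogen-cycle gene, and genuinely functional requires a chain of genomic
evidence: the contig must be confidently viral, the annotation confidently
assigned, the gene placed in a regulatory context (promoters, terminators,
NtcA-binding sites), its population ecology quantified across samples, and
its coding sequence shown to evolve under purifying selection. `amgkit`
implements each link of that chain as a reusable, tested module, plus a
synthetic-virome generator so the whole pipeline can be validated against
known ground truth without any external dataset.

## Population clustering

Viral "populations" are defined by average nucleotide identity (ANI):
scaffolds belong to the same population when they align at >= 95% identity
over >= 80% of the shorter sequence.

`pairwise_ani()` estimates ANI from consolidated ungapped local alignments:

* exact k-mer anchors (default k = 13) shared between the two sequences are
  collected on both strands and grouped by alignment diagonal;
* anchor runs are extended outward under an X-drop rule (match +1, mismatch
  −3, stop when the running score falls 20 below its maximum), which places
  alignment boundaries within a few bases of the true homology edges;
* segments shorter than 65 aligned columns are discarded — random 10-kb
  sequence pairs share a handful of chance 13-mers, and this floor removes
  them, so unrelated sequences report an aligned fraction near zero;
* segments are projected onto the shorter sequence and overlapping columns
  are counted once; ANI is matches over aligned columns, and the aligned
  fraction is aligned columns over the shorter length.

`N` never counts as a match. The approach assumes homologous segments are
co-linear without internal indels, which holds for the package's own
simulations (substitution-only mutation, plus a fragment-rearrangement option
that produces multiple diagonals); for real assemblies with indels a
dedicated whole-genome aligner remains the tool of choice, and the clustering
functions accept its output as a plain edge list via `cluster_populations()`.

Clustering is greedy and longest-first: scaffolds are visited in order of
decreasing length (ties broken lexicographically for determinism) and join
the first cluster whose *representative* they match at both thresholds,
otherwise they found a new cluster. This representative-centric rule keeps
every member directly linked to the longest member, matching how population
representatives are used downstream (the linkage rule is a design choice of
this package; single-linkage over all edges would admit chains of members
that never meet the representative thresholds). Scaffolds from CsCl-purified
samples are retained only when they are their cluster's representative
(`apply_cscl_retention()`).

Scaffolds assigned the same AMG that overlap by more than 1 kb at >= 99%
identity are merged into a single sequence (`merge_amg_scaffolds()`); within
the overlap, `N` positions are filled from the partner's base, and merged
identifiers carry a terminal `E`. Identity over the overlap treats `N` as
fillable rather than mismatching, since those positions are assembly gaps,
not disagreements.

## Viral triage

Classifier internals (VirSorter's category model, VirFinder's k-mer model)
are published tools and are consumed as score tables, never recomputed. The
decision rule in `classify_viral()` is:

* size-eligible if length > 5,000 bases, or circular and length > 1,500
  bases (both read as strict inequalities);
* viral if size-eligible and (VirSorter category 1 or 2, or VirFinder score
  > 0.9 with p < 0.05);
* reportable for AMG analysis if viral and length >= 10,000 bases.

Circularity is detected from a terminal direct repeat of at least 20 exact
bases (`detect_circularity()`). The rate of coding-strand switching between
consecutive genes (`strand_switch_rate()`) — low in phage-like genome
architectures — is reported as supporting evidence only; no cutoff is
applied because none is established.

## Annotation confidence ranking

`assign_rank()` codifies a five-level confidence scale over homology hits to
KEGG, Uniref90 and InterPro: A = reciprocal best hit (RBH) to KEGG with
bitscore > 350; B = RBH to Uniref90 with bitscore > 350; C = one-way
Uniref90 hit; D = hits only to InterPro; E = best bitscore < 60 to any
scored database. Rules apply in order, first match wins. Two gaps in that
scale required decisions: a one-way KEGG hit scoring 60–350 has no stated
rank and is treated like other one-way database evidence (rank C, basis tag
`gap-rule`); and rank C is read as requiring bitscore >= 60, because the E
rule explicitly assigns sub-60 hits regardless of database. Nitrogen-cycle
genes are short-listed by matching annotations against an editable catalog
of KEGG orthologs and keyword patterns (`ncycle_catalog()`), making the
"manual curation" step reproducible.

## Regulatory motifs

NtcA-binding sites are scanned with the consensus adapted for marine
cyanobacteria, 5'-GTA-N8-TAC-3' (`scan_motif()`). The richer probabilistic
NtcA models in the literature are deliberately reduced to this consensus,
which is the form the analysis actually constrains on; the scanner accepts
any fixed-length IUPAC pattern, so a position-weight-matrix front-end can be
added without changing the call sites. The consensus is reverse-complement
symmetric, so a forward scan finds every double-stranded site — the test
suite asserts this by scanning both strands and comparing coordinates.

Motif, promoter and terminator calls must be intergenic or within 10 bases
of an ORF boundary. "Within 10 bases" is interpreted as: for every gene the
call overlaps, one end of the call lies within 10 bases (inclusive) of that
gene's start or stop coordinate. A call wholly between genes always passes.
External promoter calls are kept at LDF > 2.75 and terminator calls at
confidence > 90% (both strict); score columns that look like the wrong unit
(promoter "LDF" above 30, terminator "confidence" at or below 30) trigger a
warning rather than silent misfiltering.

## Abundance profiling

Coverage per scaffold and sample is summarized as the trimmed mean of
per-base depths (`tpmean()`): depths are sorted and 10% of positions are
removed from each end (trim count rounded down) before averaging — the
default trim matches common practice for this statistic; it is
configurable. Normalized coverage is tpmean × 10^9 / (total bases sequenced
in the sample), i.e. per gigabase; the constant is arbitrary and cancels in
cross-sample ratios. A population is *detected* — and only then reported in
the abundance matrix — when breadth (fraction of positions with depth >= 1)
is at least 0.80 and tpmean is at least 5. Breadth uses a depth floor of 1;
no higher floor is established. Alignments are accepted as plain placement
tables or SAM text (secondary and supplementary records excluded, reference
span from the CIGAR string).

## Selection analysis (pN/pS)

For each reference codon, the expected synonymous site count is the number
of the nine single-base substitutions that preserve the amino acid, divided
by 3; non-synonymous sites are the complement, so N + S = 3 per sense codon
(`expected_sites()`). Reference stop codons are excluded from totals;
substitutions *creating* a stop count as non-synonymous. SNPs are called
from pileups at sites with depth >= 10 where an alternate allele has >= 2
supporting reads and >= 1% frequency (`call_variants()`); the depth gate
mirrors the >10× gene-coverage requirement, while the allele-support
thresholds are this package's defaults in the spirit of population-level
SNP calling from metagenomes — they are explicit arguments, not hidden
constants. Each qualifying alternate allele counts as its own SNP, so SNP
totals are per-allele, not per-site. No coverage downsampling is performed.

pN/pS = (n_obs / N_sites) / (s_obs / S_sites). The ratio is exactly 0 when
only synonymous SNPs are observed, and undefined (NA, never coerced to a
number) when no synonymous SNP is observed — including the no-SNP case. A
defined ratio below 0.3 flags strong purifying selection. Genes whose
minimum per-site coverage is <= 10× are *suppressed* (statistics returned
as NA), not zeroed, since absence of coverage is not absence of
polymorphism.

## The synthetic virome

`generate_scaffolds()`, `mutate_to_ani()` and `simulate_reads()` produce
every input the pipeline consumes, with truth tables:

* genes are real ORFs (ATG start, in-frame, no internal stop on the
  annotated strand); AMGs embed back-translated reference proteins bundled
  as synthetic amino-acid fixtures, so no database is required;
* circular scaffolds carry a 30-base terminal direct repeat;
* population variants are substitution-only at a target identity, giving an
  exact Hamming oracle for ANI (the fragment-rearrangement option exercises
  multi-segment alignment without indels);
* strain SNPs are biallelic: each read draws one latent haplotype
  coordinate, so equal-frequency sites are perfectly linked (a two-haplotype
  mixture), and synonymous/non-synonymous composition is controlled exactly;
  injected sites avoid start and stop codons so the ORF stays intact;
* sequencing error is uniform per base (no quality model, no amplification
  or GC bias), and reads are placed uniformly without wrapping the origin
  even on circular scaffolds.

Because the generator omits indels, chimeras, uneven coverage and real error
profiles, green tests demonstrate correctness of the *decision rules and
statistics*, not robustness to assembly artifacts. SNP-recovery analyses are
run at error rate 0 so strain variation is isolated from sequencing error;
with errors enabled the allele-support thresholds are the guard, and both
knobs are exposed.

Test problem sizes are deliberately desk-scale: 30 scaffolds of 10–12.5 kb
for cluster recovery, a 999-nt gene at 50× depth for pN/pS recovery, 1,000
random 5-kb sequences for the motif-scanner oracle, and two simulated
samples for the detection rule.

## Denitrification bioenergetics

`half_reaction()`, `couple()`, `delta_g()` and `pathway_sum()` implement
standard half-reaction thermodynamics: half-reactions are written as
reductions and checked for mass and charge balance; coupling scales the
donor so electrons cancel and standardizes the net reaction to one mol of
the electron acceptor; energies are sums of formation energies weighted by
stoichiometry; pathway totals weight each step by the moles of its acceptor
produced per mol of the initial acceptor (the N2O step counts ½ per mol
nitrate). Conventions: transformed standard state at pH 7 and 25 °C (the
proton entry carries RT·ln 10⁻⁷), and the electron donor is pyruvate
oxidized completely to CO₂ (10 electrons per pyruvate) — the per-step
energies are mutually consistent with a single donor potential only under
complete oxidation.

```{r thermo}
denitrification_energetics()[, c("step", "acceptor", "electrons",
                                 "delta_g_kJ_per_mol")]
```

**On the constants file.** The shipped formation energies
(`inst/extdata/denitrification_constants.tsv`) anchor H₂O, H⁺, NO₃⁻, CO₂ and
N₂ at standard microbial-bioenergetics values and *calibrate* the remaining
species (NO₂⁻, NO, N₂O, pyruvate) so the four step energies match the
published stepwise table this pipeline accompanies. Calibration is
unavoidable: no single donor potential reconciles that table with standard
formation-energy compilations — most visibly the nitrite → NO step, whose
reported −105 kJ/mol per single electron implies an effective NO₂⁻/NO
potential near +0.84 V, far from the commonly tabulated +0.35 V couple. The
deviations are recorded per species in the constants file (e.g. NO₂⁻
calibrated to −16.5 vs. literature ≈ −32.2 kJ/mol; pyruvate −488.1 vs.
−474.6) rather than silently absorbed, and the computation itself — balance
checking, electron cancellation, Hess additivity — is independent of the
constants and is what the test suite verifies. Users with a preferred
constants compilation can pass their own TSV everywhere.

## Known limitations

* ANI estimation is ungapped within segments; indel-rich homology is out of
  scope (use a whole-genome aligner and feed `cluster_populations()` its
  edge list).
* The motif scanner is consensus-based; information-content scoring is an
  extension point.
* The read simulator has no insert-size, quality or bias models, so it
  cannot benchmark assembly or mapping tools — it validates decision rules.
* pN/pS here is a within-sample polymorphism statistic, not a phylogenetic
  dN/dS; no codon-usage or multiple-hit corrections are applied.
* Thermodynamics covers standard-state step energetics only; no
  proton-motive-force or ATP-yield modeling, and no temperature or
  ionic-strength corrections.
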