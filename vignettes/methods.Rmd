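---
title: "Methods: long-read proteogenomics at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read proteogenomics at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrproteo)
library(data.table)
```

# What this package computes

`lrproteo` implements a long-read proteogenomic analysis as a connected
pipeline: full-length transcript models are compared structurally against a
reference annotation, their reading frames are inferred and filtered, the
predicted novel proteins are combined with the reference proteome into a
target-decoy peptide search database, peptide-spectrum matches are screened
for peptides that can only originate from a novel protein isoform, and
candidate spectra are validated against theoretical fragment ions.
Quantification and a small set of standard statistical tests, plus a
rule-based variant prioritizer for gene panels, complete the workflow.

Because the real inputs of such a study (millions of long reads, raw MS
runs) are not reproducible at desk scale, the package ships a seeded
synthetic-data generator that emulates the study design — a multi-isoform
reference catalog, query transcripts with *planted* structural events,
log-normal expression over three replicates, and PSMs with complete b/y
spectra — together with machine-readable ground truth. Every pipeline stage
is tested against what the generator planted.

# Structural transcript classification

A transcript model is an ordered set of exons on a strand; its *intron
chain* (the ordered splice junctions) is the unit of comparison.

* **FSM** (full splice match): the query's intron chain equals some
  reference transcript's chain exactly; the transcript ends may differ.
* **NIC** (novel in catalog): every donor and every acceptor site the query
  uses is annotated for its gene, but the chain is new.
* **NNIC** (novel not in catalog): at least one splice site is unannotated.

The NIC/NNIC boundary is deliberately drawn at splice **sites**, not whole
junctions. The canonical NIC example — exon skipping — creates a junction
absent from the catalog while both of its sites are annotated; a
junction-level rule would contradict that example, a site-level rule (the
SQANTI-family convention) does not.

Queries are assigned to the gene sharing the most splice junctions, ties
broken by exonic overlap bases and then lexicographically, so assignment is
deterministic. Queries overlapping no annotated gene on their strand receive
a stable `novelGene.<chrom>.<strand>.<tss>` sentinel and are NNIC with the
`novel_exon` subcategory. Mono-exon queries — for which the chain-based
definitions are vacuous — are FSM when fully contained in a mono-exon
reference transcript, NIC when contained in any reference exon, else NNIC;
the annotation literature states no standard rule here, so the package uses
this conservative, testable one.

## Novel-element subcategories

Novel transcripts carry operational labels, each a deterministic interval
predicate against the assigned gene's reference structures:

| label | rule |
|---|---|
| `intron_retention` | a query exon fully spans a reference intron whose flanking exons both overlap that query exon |
| `extra_intron` | a (novel) query intron lies fully inside a reference exon |
| `intron_shift` | a novel query intron overlaps exactly one distinct reference intron interval |
| `exon_elongation` | a terminal query exon extends beyond every overlapping reference terminal exon by > `elong_bp` |
| `alt_polyA` / `alt_TSS` | the 3'/5' end is farther than `w_tes`/`w_tss` from every reference TES/TSS of the gene |
| `novel_exon` | a query exon overlaps no reference exon of the gene |
| `alternative_structure` | fallback when the chain is novel and nothing above fires |

Thresholds default to `elong_bp = 10` and `w_tss = w_tes = 50` bp and are
arguments everywhere; upstream annotation tools do not publish their
equivalents, so the values must be explicit and tunable rather than
inherited. FSM transcripts can only carry the end-variation labels.
Exon-skipping deliberately has no label of its own: its junction fires no
interval predicate, so it lands in `alternative_structure`, matching how
such transcripts are reported in practice. CAGE TSS support uses a 50 bp
strand-aware upstream window by default, and reports the signed distance so
any other window can be re-binned after the fact.

# ORF inference

ORFs are called by a deterministic rule: scan the three forward frames for
ATG-initiated runs, and keep the longest one that reaches an in-frame stop
with at least `min_aa = 25` residues (ties: 5'-most start). Codons
containing N translate to X and never start an ORF. This replaces the
trained coding-potential model used with real data; it is exact, has no
model file, and recovers every worked construction downstream (a longest-ORF
rule finds the planted CDS whenever the UTRs are short relative to the
coding region, which the generator guarantees). One ORF is retained per
transcript.

Filtering assigns each ORF a status, in precedence order: `truncated` (no
stop codon within the transcript), `nmd`, `unlikely` (protein shorter than
`min_aa`), `retained`. The NMD rule is the canonical 50-nt rule: a stop
codon more than `rule_nt = 50` nucleotides upstream of the last exon-exon
junction (measured in transcript coordinates from the end of the stop codon;
mono-exon transcripts are never flagged) predicts a nonsense-mediated decay
substrate. Only retained ORFs enter the search database.

The projection of transcript-coordinate ORFs to genomic CDS blocks is exact
and invertible (`tx_interval_to_genomic()` / `genomic_blocks_to_tx()`), and
UTR blocks are the exonic complement of the CDS, so block lengths always
reconcile with the transcript length — both properties are asserted in the
test suite.

# Protein-level classification

An ORF is compared with the reference ORFs of its gene on three structural
elements: the genomic start codon (N-terminus), the genomic stop codon
(C-terminus) and the chain of CDS splice junctions. Equality of the full
triple is **pFSM**; all elements individually known but the combination new
is **pNIC**; any novel element is **pNNIC**, with the novel elements listed.
Comparison happens at genomic codon positions, not protein sequence, so a
novel transcript whose variation is confined to the UTRs classifies pFSM
even though its transcript is NIC/NNIC — sequence-level deduplication is the
database builder's job, not the classifier's. Reference element sets are
pooled per gene, never genome-wide, to avoid cross-gene artifacts. Where 5'
degradation makes N-termini uncertain in real data, this package still
compares start codons only; that is the only comparison the inputs support.

# Hybrid database, digestion and peptide uniqueness

The search database concatenates the reference proteome with the retained
novel proteins: novel sequences identical to a reference protein are
dropped, identical novel sequences collapse to one entry listing all source
transcripts, and accessions are `ref|<name>` / `nov|<transcript>`. Decoys
are full sequence reversals, one per target, prefixed `rev_`.

In-silico digestion supports the search-engine enzyme identifiers
`stricttrypsin` (after K/R, including before P), `trypsin` (after K/R, not
before P), `chymotrypsin` (after F/W/Y/L, not before P), `aspn` (before D),
`lysc-p` (after K, including before P) and the site union `aspn+lysc`.
Peptides are all runs across at most 2 missed cleavage sites with at least
7 residues, protein-terminal peptides included; no maximum length is imposed
at the index level (a search engine, not the index, bounds it). Whether
chymotrypsin honours proline blocking differs between published digests, so
it is a flag. The digestion is verified against brute-force substring
enumeration under the cleavage predicates — exact set equality per enzyme.

Peptide uniqueness is the three-way partition `unique_novel` /
`unique_reference` / `shared` over the union of all enzyme schemes. Because
isoleucine and leucine are isobaric, a peptide whose I/L-collapsed form
occurs in a reference protein is *not* novel: I/L equivalence is ON by
default for the novelty call (flag `il_collapse`), OFF for plain indexing.

# PSM validation

Theoretical fragments are b- and y-ions at charge 1–2, monoisotopic masses,
proton 1.007276 Da; fixed carbamidomethyl-C (+57.02146) and variable
oxidation-M (+15.9949) / N-terminal acetylation (+42.01057). a/x/c/z ions
and neutral losses are out of scope — b/y is what spectrum annotation of
novel peptides uses. Observed peaks match the nearest theoretical ion within
20 ppm, one-to-one, closest ppm error first.

A PSM validates when all of: at least 8 matched ions; at least one b and one
y ion; identification probability strictly greater than 0.95; and at least
half of the 50 most intense peaks explained by b/y ions. The last criterion
operationalizes "the majority of peaks accounted for"; both knobs are
arguments. Validation is monotone: adding matched ions can never turn a pass
into a fail. An override list can force-include peptides that fail
validation but have independent support; they stay flagged.

Reported novel peptides are PSM peptides whose uniqueness is `unique_novel`,
excluding PSMs whose every listed parent is a decoy; peptides absent from
the index are flagged `unindexed` rather than dropped. Each reported peptide
carries the novel-event labels of its parent transcripts and can be emitted
as a BED12 genome-browser record (junction-spanning peptides become
multi-block records; all occurrences in the protein are reported).

# Quantification and statistics

TPM is computed without length normalization — full-length read counts
already count molecules, so `tpm = count / total * 1e6`. Relative isoform
abundance aggregates counts across samples before computing per-gene
fractions, giving one value per isoform. A gene is "novel-dominant" when its
top-abundance isoform carries a novel (non-pFSM) retained ORF; genes whose
longest reference transcript exceeds 8 kb are excluded from that report,
since full-length coverage of very long transcripts is incomplete.

The tests are standard and delegated to R's own machinery behind a uniform
result shape: Pearson chi-squared without continuity correction,
Mann-Whitney U with midranks (exact enumeration when `n*m <= 1e4` and no
ties, normal approximation otherwise; U counts x-over-y pairs), Spearman as
Pearson on midranks, Benjamini-Hochberg step-up adjustment, and one-sided
hypergeometric over-representation with BH across terms. The test suite
checks each against an independent brute-force oracle (fixed-margin
permutation null via `r2dtable`, exhaustive rank-sum enumeration via
`combn`, hand-computed midranks, exact hypergeometric enumeration). Note
that on small 2x2 tables the asymptotic chi-squared p and the exact
conditional null differ by the discreteness of the latter; the
permutation-agreement test therefore uses a table large enough for the
asymptotics to hold.

# Variant prioritization

SNVs/indels: population allele frequency above 0.5% discards (strict
inequality); protein-disrupting and splice-site consequences prioritize
directly; deep-intronic and exonic splice-region variants require
SpliceAI ≥ 0.2; missense requires phyloP ≥ 2.7 OR CADD_PHRED ≥ 15 OR
Grantham ≥ 80; silent requires phyloP ≥ 2.7 OR CADD_PHRED ≥ 15. SVs/CNVs:
in-house frequency at most 0.5% (inclusive — the two gates are worded
asymmetrically on purpose) and either spanning a panel exon entirely or, for
inversions, placing a breakpoint inside a panel gene body. Rules are
evaluated independently per variant, so decisions are order-independent, and
a variant whose applicable rule needs a missing score is returned as
indeterminate rather than silently dropped. The "near-splice missense"
consequence is taken as given in the input vocabulary; when deriving it from
annotations a 3 bp exonic distance is the documented assumption.

# The synthetic-data generator

`sim_config()` fixes the study conditions; all stages derive their seeds
from `seed` by fixed offsets so each stage is independently reproducible.

Genes are built transcript-first: a master isoform of 4–8 exons with a
designed CDS (5' UTR free of ATG, an in-frame ATG at every exon start,
internal exon lengths divisible by 3, a single stop in the last exon),
introns written GT..AG, then placed on the genome with 2 kb gaps —
minus-strand genes as the reverse complement of the designed locus.
Additional reference isoforms are 5'-truncated chains, and ~25% of genes
annotate a short in-frame cassette exon in a secondary isoform. These
construction rules guarantee that every reference isoform carries a valid
ORF (the multiple-of-3 internal exons mean truncation and skipping preserve
frame) and that every isoform's chain is unique, so self-classification is
exactly FSM. Each isoform's annotated CDS is its longest-ORF call, which
keeps transcript-level and protein-level reference structures consistent by
construction.

Planted novel isoforms draw from an event mix (defaults: end variation 20%,
alternative poly(A) 15%, novel splice site 15%, intron retention 15%, exon
skip 10%, known-site recombination 10%, terminal elongation 10%, novel exon
5% — end variation, poly(A) and intron retention lead, as they do in real
long-read catalogs). Every draw is checked for unambiguity before
acceptance: a planted "novel" chain must not coincide with an annotated
chain (retaining the first intron would otherwise reproduce a 5'-truncated
isoform), novel sites must be unused gene-wide, and events whose label
depends on disjoint reference introns avoid cassette genes. Ambiguous draws
are resampled, so planted truth is exact and classifier accuracy on it is a
meaningful 100%-or-bug signal. The expected subcategory set of each event is
derived from the label rules at planting time and stored as truth.

Expression is log-normal (meanlog 3, sdlog 1.2) with multinomial sampling of
50,000 reads per sample over 3 samples — depths at which presence/absence
across replicates is nearly saturated, unlike the real study's sparser
tail. Designated dominant-novel genes get a novel isoform abundance 1.5x the
rest of the gene. PSMs sample tryptic peptides (0 missed, 7–25 aa) from all
novel and 30 reference proteins, 3 peptides each; spectra are the complete
singly-charged b/y series with uniform intensities, plus optional uniform
noise peaks; true-hit probabilities are uniform on (0.96, 0.999), noise and
decoy hits on (0.2, 0.9). The noiseless default makes the end-to-end novelty
check exact: reported novel peptides must equal planted unique-novel
peptides with zero false positives and negatives.

A dedicated deterministic construction, `frameshift_case()`, builds the
field's classic worked example: a reference-annotated 17-nt exon newly
combined before the last exon. The internal exons sum to 1 mod 3 and the
cassette adds 2 mod 3, so the query, the full reference isoform and the
cassette-carrying reference isoform read the last exon in three different
frames; the query is NIC (all sites known), its ORF is frameshifted
downstream of the insertion, and a C-terminal tryptic peptide unique to the
novel ORF exists. The last-exon sequence satisfying the frame constraints is
found by a seeded search at construction time; the assertions the case
supports (NIC call, frameshift, unique-peptide detection) do not depend on
which satisfying sequence was found.

## What passing tests do and do not show

The generator plants *unambiguous* events into *clean* structures: no
alignment noise, no degraded 5' ends, no mono-exon fragments, no
heteroallelic loci, uniform spectra with no co-eluting precursors. Perfect
recovery therefore certifies the classification, digestion, indexing and
validation *logic*, not performance on noisy real data — on real inputs the
upstream aligner/collapser and search engine dominate error rates, and both
are out of scope here.

# Problem sizes and numerical choices

The test suite and the acceptance script run the generator at 200 genes
(~450 multi-exon isoforms) for self-classification, 600 planted novel
isoforms for recovery, and the 20-gene default study for the end-to-end MS
stages — sizes chosen so the whole suite completes in about a minute while
every code path is exercised at non-trivial scale. Fragment-mass arithmetic
is double precision throughout; b/y complementarity holds to 1e-6 Da. Peak
assignment breaks ties by smallest ppm error; gene assignment and FSM
matching break ties lexicographically; all random draws flow from a single
seed per stage. Genomic coordinates are 0-based half-open everywhere inside
the package, converted only at the GTF boundary — one convention internally
removes the off-by-one class of bugs entirely.

# Known limitations

* The ORF caller is longest-ATG-ORF: no Kozak context, non-ATG starts,
  selenoproteins or multi-ORF retention; a transcript whose true reading
  frame is not its longest ORF will be misassigned.
* Digestion is fully specific; semi-tryptic peptides are not indexed.
* Spectrum validation considers b/y ions only, without neutral losses or
  isotope peaks; spectra dominated by other ion series under-validate.
* The variant module consumes annotated tables; it computes no scores and
  performs no clinical (ACMG/AMP) classification.
* The generator does not model read-level error, intra-sample isoform
  correlation, retention time or intensity realism.
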