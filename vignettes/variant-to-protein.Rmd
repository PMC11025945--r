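---
title: "From curated variants to protein isoform databases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From curated variants to protein isoform databases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Monogenic diabetes (MODY, neonatal diabetes and related Mendelian forms) is
driven by rare, highly penetrant coding variants scattered across a panel of
several dozen to ~100 genes. Evidence about these variants is fragmented:
genome annotation resources enumerate every variant overlapping the genes'
exons; clinical archives assert per-variant significance for specific
phenotypes; and many variants exist only in the literature, often without
standardized identifiers or coordinates. Downstream proteomic and structural
work needs something none of these sources provide directly: a deduplicated,
confidence-tiered variant set and, for each variant, the protein sequence it
produces on *every* isoform of its gene.

`vartoprot` implements that workflow as an offline, fully testable toolkit:

1. **Harmonize** three source dialects into one normalized variant table.
2. **Classify** each variant's consequence on each transcript and filter by
   the consequence types enriched in (likely) pathogenic assertions.
3. **Consolidate** all sources into a two-level evidence ledger, with Venn
   accounting and VCF output.
4. **Translate** each retained variant onto every isoform of its gene into a
   protein FASTA database.
5. **Visualize** per-gene variant density on the protein sequences.

## Variant representation and normalization

All coordinates are 1-based inclusive (the GFF3/VCF convention) everywhere
inside the package; nothing is converted except at file boundaries.

Sources spell indels incompatibly: exon-overlap exports use `"G/-"` and
`"-/A"` with the empty side marking a pure deletion/insertion, while archive
exports use VCF-style anchored alleles. Deduplication across sources is only
sound on a canonical form, so every variant is reduced to the classic
left-aligned parsimonious anchor-base representation: empty alleles are
anchored on the base immediately 5' of the event, the shared last base is
trimmed (shifting left through repeat runs), and any shared prefix beyond
one anchor base is removed. Two spellings of the same event always collapse
to the same `(chrom, pos, ref, alt)` key; the test suite enforces this with
a whole-chromosome diff oracle on randomly planted indels.

A reference-allele mismatch against the genome is a hard error naming the
site: it indicates a wrong genome build or a corrupt row, and silently
accepting it would corrupt every downstream coordinate.

Indels whose combined allele length exceeds the anchor plus 30 nt are routed
to a rejected side list rather than processed: events above that bound
cannot be meaningfully translated to a protein sequence by direct
substitution, and larger rearrangements (whole-gene deletions and similar)
are out of scope by design.

## The join cascade

Identifiers are joined in a fixed priority: dbSNP rsIDs first, exact
normalized coordinate keys second, and an offline manual mapping table last.
Archive rows carrying an rsID but no coordinates are resolved against the
rsID index of the exon-mined reference table; literature rows are resolved
through the mapping table (rsID or `GENE:p.xxx` protein-level labels), and
rows resolved only by entries flagged `manual` are credited to a separate
MANUAL source. Rows that resolve nowhere are *returned* (as
`needs_manual`/`unmapped` side lists with reasons), never silently dropped;
every reader satisfies `mapped + unmapped + rejected = input rows`.

## Consequence classification

`classify_variant()` assigns exactly one Sequence Ontology term per
(variant, transcript) with the precedence

splice > start_lost > stop_gained > stop_lost > frameshift >
inframe insertion/deletion > missense > synonymous > UTR > intron,

mirroring the "most severe consequence" convention of standard effect
predictors. Splice windows are defined in transcription orientation: donor =
intron bases +1/+2, acceptor = −1/−2, plus the donor 5th base, which is
carried as its own term because it is part of the retained-term vocabulary.
A variant spanning a region boundary is classified by the most severe
overlapped category. Two deliberate choices:

* For indels, `start_lost` is decided by whether the annotated ATG survives
  the actual edit, not by positional overlap alone. Left-alignment can slide
  an equivalent base into the start codon (deleting one G of a GG run that
  straddles the codon boundary leaves a perfectly good ATG), and a purely
  positional rule would over-call start loss and contradict the translator.
* The catch-all terms `protein_altering_variant` and
  `coding_sequence_variant` are accepted on input (external annotation uses
  them) but never produced internally: the classifier always has enough
  information to resolve a specific term.

The classifier is validated against an independent brute-force oracle that
edits the chromosome string, re-splices, translates with its own
arithmetically indexed codon table, and diffs the products — 100% agreement
is required over 1000 random planted variants per run.

### Consequence × significance cross-tab

The cross-tabulation counts variants over (term, significance) pairs and
normalizes to percentages. Both normalization axes are supported because the
two readings ("distribution of terms within significance categories" vs
"distribution of significance within each term") answer different
questions; the default is per consequence term. Variants lacking a
significance are tallied under `other`.

The retained-term filter keeps a variant if *any* of its terms is in the
retained list (default: missense, protein-altering, coding-sequence,
frameshift, the three splice terms, start_lost, stop_gained, stop_lost and
the in-frame indels). Variants with *no* consequence annotation — typically
archive short indels exported without predictions — are kept and flagged
`unclassified`, passing straight through to consolidation: dropping them
would silently discard exactly the class of event the archive contributes
most uniquely. `stop_lost` is retained by default although external
annotation sources disagree about its pathogenicity enrichment; the list is
a single configuration field for users who disagree.

## Evidence levels

* **Level 1**: every variant backed by a disease-evidence source (clinical
  archive, literature, or manual mapping), *regardless of reported
  significance*. This is the "anything ever linked to the disease" tier.
* **Level 2** (always a subset): archive variants with merged significance
  pathogenic or likely pathogenic, plus literature variants outside the
  excluded genes (default `BLK`, `KLF11`, `PAX4`, genes reported to lack
  MODY pathogenicity in recent re-evaluations). A row backed by both
  sources qualifies if either criterion holds, since the tier is defined as
  the union of the two filtered sets.

When sources disagree, significance merges to the most severe value
(pathogenic > likely_pathogenic > conflicting > uncertain_significance >
likely_benign > benign > other — the placement of `conflicting` is this
package's choice, as the tier rules only consume the pathogenic side), and
a `sig_conflicting` flag records that a pathogenic-side and a benign-side
assertion coexisted. Rows excluded from level 2 carry machine-readable
`exclusion_reason`s so the tier accounting is reproducible from the ledger
alone.

Exon-mined reference variants that match no disease source stay in the
ledger with `level1 = FALSE` (they are the background reference set), but
are excluded from the VCF output, which exists to describe the disease
tiers; a user can re-emit them by filtering the ledger table directly.
Archive review status ("stars") is deliberately ignored.

## Translation onto isoforms

For each ledger variant and each coding isoform of its gene, the alternate
allele is substituted into the spliced cDNA (reverse-complemented for
minus-strand genes) and the CDS bounds are remapped through the edit.
Translation starts at the annotated start codon and runs to the first
in-frame stop wherever it falls, so frameshift and stop-loss products
naturally extend into the 3' UTR; if the transcript ends without a stop the
record is flagged `no_terminal_stop` (plus `incomplete_codon` for a
trailing partial codon). A destroyed start codon yields an empty,
`no_product`-flagged record — no downstream ATG rescanning is attempted,
because without experimental evidence any such product would be
speculative.

Intronic, splice-site and out-of-locus variants are carried in the ledger
and VCF but not translated: their effect on the protein is not predictable
from the transcript sequence alone. Each skip is logged per transcript with
a reason (`non_exonic`, `no_CDS`, `outside_transcript`), which is what
makes the "fraction of variants with a predicted protein effect" statistic
reproducible from the outputs.

FASTA headers follow a stable grammar
(`>{gene}|{transcript}|{chrom}:{pos}:{ref}:{alt}|{protein_change}|L{level}|{flags}`),
sequences wrap at 60 columns, and record order is deterministic.

## The synthetic cohort generator

`generate_fixture()` exists so that every stage — including failure paths —
is testable with no network or downloads. It emulates the statistical
structure of a curated rare-disease cohort, not real gene architecture:

* One three-exon gene per chromosome; GT..AG introns long enough to hold
  all splice windows. The middle exon holds whole codons, so the
  exon-skipping second isoform stays in frame by construction; an optional
  third isoform is non-coding, mirroring transcripts without an annotated
  protein product.
* Gene symbols come from a monogenic-diabetes panel (HNF1A, GCK, ...,
  including BLK/KLF11/PAX4 so the level-2 gene exclusion is exercised).
* Per-gene burden is deliberately unequal (weights ∝ 1/rank), mirroring the
  strong disparities seen in curated disease gene panels.
* Planted variant types follow a fixed mix dominated by missense, with
  frameshift/in-frame indels, splice, UTR, intron and start/stop events at
  minority rates; archive significance follows a configurable mix (default
  40% pathogenic-side, 35% uncertain, 25% benign-side, roughly the shape of
  phenotype-restricted archive queries).
* Source membership is assigned by exact integer quota from the configured
  overlap fractions (so planted Venn counts are recoverable exactly); the
  remainder of the cohort becomes exonic background present only in the
  reference table, mirroring the role of the large exon-mined set relative
  to its disease-linked subset.
* Dialect quirks are injected at fixed rates: "-"-spelled indels, missing
  rsIDs (10%), multi-allelic rows (5%), archive rows with an rsID but no
  coordinates (5%).

Every planted variant is verified at generation time by genome-level
surgery (edit the chromosome, shift the geometry, re-splice, re-translate);
a candidate whose realized consequence differs from the intended type is
re-drawn. The manifest therefore records *verified* truth: normalized key,
consequence, sources, significance, level membership and the per-isoform
protein product. What passing truth-recovery tests shows is that the
pipeline's bookkeeping and translation are exact on data with known
answers; it does not show robustness to real-world annotation noise
(mis-annotated CDSs, non-canonical splice sites, build mismatches), which
the generator does not emulate.

A single integer seed drives all draws; regeneration is byte-identical.

## Numerical and degenerate-input choices

* Genetic code fixed to standard table 1; codons containing N translate to
  `X`; no selenocysteine handling.
* Transcripts whose spliced CDS length is not a multiple of 3 are retained
  (flagged at translation time), since real annotation contains such cases.
* Intron offsets count positive from the donor exon end and negative from
  the acceptor exon start, in transcription orientation; ties go to the
  donor side.
* Chromosome sorting in VCF output is numeric-aware with a lexicographic
  fallback (warning) for non-numeric names.
* Unknown chromosomes and out-of-bounds slices are errors, never empty
  strings.
* An empty CDS input to the translator returns an empty protein with an
  `empty_input` flag.

## Problem sizes used in the checks

The bundled acceptance checks run the full pipeline at two scales: a
20-variant, 2-gene cohort (every number inspectable by hand) and a
2000-variant, 12-gene cohort with the archive/literature overlap structure
described above. The property suites check 1000 random variants against
each of the two independent oracles per run. These sizes keep a complete
run in the low minutes on a single CPU while leaving every code path
exercised; they are the package's chosen test conditions, and all counts
reported by `scripts/acceptance.R` are computed fresh from these runs.

## Known limitations

* Protein-level HGVS strings are resolved by exact lookup in the mapping
  table only; there is no HGVS parser.
* Multi-variant (haplotype) protein sequences are out of scope; each
  variant is applied alone.
* Insertions anchored on the last base of the 5' UTR are classified as CDS
  indels (both the classifier and its oracle use the same boundary
  convention); a fully HGVS-faithful treatment of such boundary insertions
  is not attempted.
* The overlay figures are static PNGs without domain annotation tracks.
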