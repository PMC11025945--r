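# vartoprot

Harmonize clinical variants from heterogeneous sources and translate them
onto every protein isoform of their genes.

## The problem

Monogenic diabetes (MODY, neonatal diabetes and related Mendelian forms) is
caused by rare, highly penetrant coding variants in a panel of disease
genes. The evidence is scattered across three kinds of sources that do not
share a common representation:

* **exon-overlap exports** from genome annotation (every variant touching
  the genes' exons, with predicted consequences and reported significance),
* **clinical-archive exports** queried per phenotype (per-variant
  significance assertions: pathogenic … benign),
* **literature tables** (gene + an rsID, a protein-level label, or nothing
  machine-readable at all).

Proteomic and structural follow-up needs a deduplicated, confidence-tiered
variant set and, for each variant, the protein sequence it produces on
*every* isoform of its gene. `vartoprot` builds exactly that, offline:

1. parse the three dialects and normalize every variant to a left-aligned,
   parsimonious, anchor-base `(chrom, pos, ref, alt)` key;
2. classify each variant's consequence on each transcript (one Sequence
   Ontology term per variant × transcript, "most severe" precedence) and
   filter to the consequence types enriched in pathogenic assertions;
3. consolidate all sources into an evidence ledger with two tiers —
   **level 1** (any reported disease link, regardless of significance) and
   **level 2** (archive pathogenic/likely-pathogenic, plus literature
   variants outside the excluded genes BLK/KLF11/PAX4) — with Venn source
   accounting and VCF v4.2 output per tier;
4. apply each variant to the spliced cDNA of every coding isoform
   (strand-aware) and translate to protein FASTA databases, logging a
   reason for every variant that cannot be translated;
5. draw per-gene overlays of variant positions on the protein sequences
   (level-2 dots above, level-1 dots below) and per-gene count charts.

A seeded synthetic-cohort generator (`generate_fixture()`) produces
genomes, gene models and all three source dialects with planted,
generation-time-verified ground truth, so the entire pipeline is testable
with no downloads.

## Worked example

```r
library(vartoprot)

wf <- worked_fixtures()          # tiny hand-built loci
g  <- wf$genome
f1 <- wf$transcripts$F1          # chrT:1-15, CDS 4-12, "+": protein "MA"

# a missense variant, classified and translated
classify_variant(list(chrom = "chrT", pos = 8L, ref = "C", alt = "A"),
                 f1, g)$term
#> [1] "missense_variant"
translate_variant(f1, g,
                  list(chrom = "chrT", pos = 8L, ref = "C", alt = "A"))
#> <protein_record> G1|F1|chrT:8:C:A|p.A2D|L.|
#>   MD

# dialect spellings collapse to one canonical key
normalize_variant("chrT", 7, "G", "-", g)$key    # a "G/-" deletion row
#> [1] "chrT:5:TG:T"
```

The missense call says codon 2 changes Ala→Asp, so the reference product
`MA` becomes `MD`; the deletion spelled `"G/-"` at position 7 left-aligns
through the GG run to the anchored key `chrT:5:TG:T`.

Running the whole pipeline on a simulated cohort:

```r
cfg <- default_config(out_dir = "run1")
cfg$simulate <- list(n_genes = 6L, isoforms_per_gene = 2L,
                     n_variants = 100L)
cfg <- run_pipeline("simulate", cfg)
cfg <- run_pipeline("all", cfg)
readLines("run1/pipeline.log")
#> ingest ens: in=91 kept=95 rejected=0 unmapped=0
#> ingest clin: in=65 kept=65 rejected=0 unmapped=0
#> ingest lit: in=15 kept=15 rejected=0 unmapped=0
#> classify: in=95 kept=81 removed=14
#> consolidate: ledger=99 level1=70 level2=37 venn=none:29,CLINVAR:55,...
#> translate level1: variants=70 records=108
```

`run1/` then contains the ledger TSV, `level1.vcf`/`level2.vcf`, the
protein FASTAs, the consequence × significance cross-tab (TSV + heat map),
Venn counts, per-gene counts and overlay PNGs. The same stages are
available from a shell via `inst/cli/vartoprot.R`.

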