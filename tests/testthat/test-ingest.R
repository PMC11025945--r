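# Ingestion: normalization and the three dialect readers.

wf <- worked_fixtures()
G <- wf$genome

write_table <- function(df, sep = "\t") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

test_that("normalization leaves SNVs fixed and anchors/left-aligns indels to
          the oracle's leftmost parsimonious key", {
  n <- normalize_variant("chrT", 8, "C", "A", G)
  expect_equal(n[c("pos", "ref", "alt")], list(pos = 8L, ref = "C",
                                               alt = "A"))
  # deletion spelled with '-' : oracle decides the canonical key
  o <- oracle_normalize(G$sequences[["chrT"]], 7, "G", "-")
  n <- normalize_variant("chrT", 7, "G", "-", G)
  expect_equal(list(n$pos, n$ref, n$alt), list(o$pos, o$ref, o$alt))
  expect_equal(o, list(pos = 5, ref = "TG", alt = "T"))
  # insertion into the A-run left-aligns to the run start
  o <- oracle_normalize(G$sequences[["chrT"]], 13, "-", "A")
  n <- normalize_variant("chrT", 13, "-", "A", G)
  expect_equal(list(n$pos, n$ref, n$alt), list(o$pos, o$ref, o$alt))
  expect_equal(o, list(pos = 10, ref = "T", alt = "TA"))
})

test_that("normalization errors on reference mismatch, naming the site", {
  expect_error(normalize_variant("chrT", 8, "G", "A", G),
               "reference mismatch at chrT:8")
  expect_error(normalize_variant("chrT", 8, "C", "C", G), "identical")
})

test_that("normalization is idempotent and collapses dialect spellings of
          the same planted event to one key", {
  set.seed(11)
  bad <- character(0)
  for (i in 1:200) {
    L <- 40
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    g1 <- reference_genome(c(c1 = s))
    p <- sample(5:(L - 8), 1); len <- sample(1:4, 1)
    if (sample(c(TRUE, FALSE), 1)) {
      # deletion: '-' spelling vs anchored spelling
      del <- substr(s, p, p + len - 1)
      k_dash <- normalize_variant("c1", p, del, "-", g1)
      k_anch <- normalize_variant("c1", p - 1,
                                  paste0(substr(s, p - 1, p - 1), del),
                                  substr(s, p - 1, p - 1), g1)
      o <- oracle_normalize(s, p, del, "-")
    } else {
      # insertion: '-' spelling vs anchored spelling
      ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      k_dash <- normalize_variant("c1", p, "-", ins, g1)
      k_anch <- normalize_variant("c1", p - 1, substr(s, p - 1, p - 1),
                                  paste0(substr(s, p - 1, p - 1), ins), g1)
      o <- oracle_normalize(s, p, "", ins)
    }
    renorm <- normalize_variant("c1", k_dash$pos, k_dash$ref, k_dash$alt,
                                g1)
    ok <- k_dash$key == k_anch$key &&
      k_dash$key == variant_key("c1", o$pos, o$ref, o$alt) &&
      renorm$key == k_dash$key
    if (!ok) bad <- c(bad, sprintf("%s | anchored %s | oracle %s:%s:%s",
                                   k_dash$key, k_anch$key, o$pos, o$ref,
                                   o$alt))
  }
  expect_length(bad, 0)
})

test_that("significance harmonization is case-insensitive, resolves combined
          values to the more severe term and defaults to 'other'", {
  expect_equal(harmonize_significance("Likely pathogenic"),
               "likely_pathogenic")
  expect_equal(harmonize_significance("PATHOGENIC"), "pathogenic")
  expect_equal(harmonize_significance("Pathogenic/Likely pathogenic"),
               "pathogenic")
  expect_equal(harmonize_significance(
    "Conflicting interpretations of pathogenicity"), "conflicting")
  expect_equal(harmonize_significance("drug response"), "other")
  expect_equal(harmonize_significance("Benign"), "benign")
  expect_true(is.na(harmonize_significance("")))
})

test_that("the Ensembl reader splits multi-allelic rows, normalizes '-'
          spellings and rejects bad rows without stopping", {
  path <- write_table(data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "chrT",
    pos = c(8, 7, 8, 8),
    alleles = c("C/A/T", "G/-", "C/QQ", "C/G"),
    consequences = c("missense_variant", "frameshift_variant",
                     "missense_variant", "missense_variant"),
    significance = c("Pathogenic", "Benign", "", "Likely benign"),
    gene = "G1"))
  res <- read_ensembl_table(path, G)
  expect_equal(res$n_input, 4L)
  # multi-allelic row -> one variant per alternative allele, same site
  rs1 <- res$variants[res$variants$rsid == "rs1", ]
  expect_equal(nrow(rs1), 2)
  expect_setequal(rs1$alt, c("A", "T"))
  expect_equal(unique(rs1$pos), 8L)
  # '-' deletion normalized to the oracle key
  o <- oracle_normalize(G$sequences[["chrT"]], 7, "G", "-")
  expect_true(variant_key("chrT", o$pos, o$ref, o$alt) %in%
                res$variants$key)
  # unparseable allele row rejected with reason, others still processed
  expect_equal(nrow(res$rejected), 1)
  expect_equal(res$rejected$reason, "unparseable_alleles")
  expect_true(all(res$variants$sources == "ENSEMBL"))
  # accounting: every input row is accounted for
  expect_equal(nrow(res$rejected) + length(unique(
    res$variants$rsid)), res$n_input)
})

test_that("an empty Ensembl table yields an empty result, not an error", {
  path <- write_table(data.frame(rsid = character(0), chrom = character(0),
                                 pos = integer(0), alleles = character(0),
                                 consequences = character(0),
                                 significance = character(0),
                                 gene = character(0)))
  res <- read_ensembl_table(path, G)
  expect_equal(nrow(res$variants), 0)
  expect_equal(res$n_input, 0L)
})

test_that("indels beyond the configured cap are routed to the rejected
          list", {
  s <- paste(rep("ACGT", 30), collapse = "")
  g1 <- reference_genome(c(c1 = s))
  path <- write_table(data.frame(
    rsid = "rs9", chrom = "c1", pos = 5,
    alleles = paste0(substr(s, 5, 44), "/-"),
    consequences = "frameshift_variant", significance = "", gene = "G1"))
  res <- read_ensembl_table(path, g1)
  expect_equal(nrow(res$variants), 0)
  expect_match(res$rejected$reason, "indel_cap")
  res2 <- read_ensembl_table(path, g1, indel_cap = 60L)
  expect_equal(nrow(res2$variants), 1)
})

test_that("the ClinVar reader harmonizes significance, attaches the
          phenotype, resolves rsID-only rows through the cascade and routes
          hopeless rows to the needs-manual list", {
  ens <- read_ensembl_table(write_table(data.frame(
    rsid = "rs2", chrom = "chrT", pos = 8, alleles = "C/A",
    consequences = "missense_variant", significance = "", gene = "G1")), G)
  rmap <- rsid_index(ens$variants)
  path <- write_table(data.frame(
    accession = c("VCV1", "VCV2", "VCV3", "VCV4"),
    rsid = c("rs2", "", "rs777", ""),
    chrom = c("", "chrT", "", ""),
    pos = c("", "8", "", ""),
    ref = c("", "C", "", ""),
    alt = c("", "A", "", ""),
    significance = c("Likely pathogenic", "Benign", "Pathogenic",
                     "Pathogenic"),
    gene = "G1"))
  res <- read_clinvar_table(path, "MODY", G, rsid_map = rmap)
  # rsID-only row resolved by the rsID-first join
  expect_equal(nrow(res$variants), 2)
  expect_equal(res$variants$significance,
               c("likely_pathogenic", "benign"))
  expect_true(all(res$variants$phenotypes == "MODY"))
  expect_true(all(res$variants$sources == "CLINVAR"))
  # coordinate row keeps no rsid
  expect_true(is.na(res$variants$rsid[res$variants$significance ==
                                        "benign"]))
  # rows with neither resolvable rsID nor coordinates -> needs-manual list
  expect_equal(nrow(res$unmapped), 2)
  expect_setequal(res$unmapped$accession, c("VCV3", "VCV4"))
  expect_equal(unique(res$unmapped$reason), "no_rsid_or_coordinates")
  # accounting
  expect_equal(nrow(res$variants) + nrow(res$unmapped) +
                 nrow(res$rejected), res$n_input)
})

test_that("ClinVar rows without consequence annotation keep empty terms
          (the indel pass-through)", {
  path <- write_table(data.frame(
    accession = "VCV9", rsid = "", chrom = "chrT", pos = 6, ref = "GG",
    alt = "G", significance = "Pathogenic", gene = "G1"))
  res <- read_clinvar_table(path, "MODY", G)
  expect_equal(nrow(res$variants), 1)
  expect_equal(res$variants$consequence_terms, "")
})

test_that("the literature reader joins rsID, HGVS and direct-coordinate
          identifiers, marks manual resolutions and returns unmapped rows", {
  lit <- write_table(data.frame(
    gene = c("G1", "G1", "G1", "G1"),
    identifier = c("rs1", "p.Ala2Asp", "chrT:8:C:T", "rs404"),
    pmid = c("111", "222", "333", "444")))
  map <- write_table(data.frame(
    key = c("rs1", "G1:p.Ala2Asp"),
    chrom = "chrT", pos = c(8, 8), ref = "C", alt = c("A", "G"),
    manual = c("0", "1")))
  res <- read_literature_table(lit, map, G)
  expect_equal(nrow(res$variants), 3)
  expect_equal(res$variants$sources[res$variants$alt == "A"], "LITERATURE")
  # manual-mapping resolution is credited to the MANUAL source
  expect_equal(res$variants$sources[res$variants$alt == "G"], "MANUAL")
  expect_equal(res$variants$sources[res$variants$alt == "T"], "LITERATURE")
  expect_equal(res$variants$pmids[res$variants$alt == "A"], "111")
  expect_equal(nrow(res$unmapped), 1)
  expect_equal(res$unmapped$identifier, "rs404")
  expect_equal(nrow(res$variants) + nrow(res$unmapped) +
                 nrow(res$rejected), res$n_input)
})

test_that("conflicting duplicate keys in the mapping table are an error
          listing the keys", {
  lit <- write_table(data.frame(gene = "G1", identifier = "rs1",
                                pmid = "1"))
  map <- write_table(data.frame(
    key = c("rs1", "rs1"), chrom = "chrT", pos = c(8, 9), ref = c("C", "T"),
    alt = c("A", "A"), manual = "0"))
  expect_error(read_literature_table(lit, map, G), "rs1")
})

test_that("comma-delimited source tables are accepted", {
  path <- write_table(data.frame(
    rsid = "rs1", chrom = "chrT", pos = 8, alleles = "C/A",
    consequences = "missense_variant", significance = "Pathogenic",
    gene = "G1"), sep = ",")
  res <- read_ensembl_table(path, G)
  expect_equal(nrow(res$variants), 1)
  expect_equal(res$variants$key, "chrT:8:C:A")
})
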