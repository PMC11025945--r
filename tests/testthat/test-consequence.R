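# Consequence classification, cross-tab and retained-term filter.

wf <- worked_fixtures()
G <- wf$genome
TT <- wf$transcripts

vv <- function(chrom, pos, ref, alt)
  list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)

test_that("classification reproduces the worked single-base examples", {
  cl <- classify_variant(vv("chrT", 8, "C", "A"), TT$F1, G)
  expect_equal(cl$term, "missense_variant")
  expect_equal(cl$protein_pos, 2L)
  expect_equal(cl$ref_aa, "A")
  expect_equal(cl$alt_aa, "D")
  expect_equal(classify_variant(vv("chrT", 10, "T", "A"), TT$F1, G)$term,
               "stop_lost")
  expect_equal(classify_variant(vv("chrT", 5, "T", "C"), TT$F1, G)$term,
               "start_lost")
  expect_equal(classify_variant(vv("chrT", 9, "T", "C"), TT$F1, G)$term,
               "synonymous_variant")
  expect_equal(classify_variant(vv("chrT3", 5, "C", "A"), TT$F1B, G)$term,
               "stop_gained")
  expect_equal(classify_variant(vv("chrT", 2, "A", "C"), TT$F1, G)$term,
               "5_prime_UTR_variant")
  expect_equal(classify_variant(vv("chrT", 14, "A", "C"), TT$F1, G)$term,
               "3_prime_UTR_variant")
})

test_that("splice windows are classified in transcription orientation", {
  # F4 intron is genomic 10-29 on the plus strand
  expect_equal(classify_variant(vv("chrT4", 10, "G", "A"), TT$F4, G)$term,
               "splice_donor_variant")
  expect_equal(classify_variant(vv("chrT4", 11, "T", "A"), TT$F4, G)$term,
               "splice_donor_variant")
  expect_equal(classify_variant(vv("chrT4", 14, "G", "A"), TT$F4, G)$term,
               "splice_donor_5th_base_variant")
  expect_equal(classify_variant(vv("chrT4", 29, "G", "A"), TT$F4, G)$term,
               "splice_acceptor_variant")
  expect_equal(classify_variant(vv("chrT4", 28, "A", "C"), TT$F4, G)$term,
               "splice_acceptor_variant")
  expect_equal(classify_variant(vv("chrT4", 20, "T", "A"), TT$F4, G)$term,
               "intron_variant")
})

test_that("a variant outside the transcript span yields no call", {
  expect_null(classify_variant(vv("chrT4", 40, "A", "C"), TT$F4, G))
  expect_null(classify_variant(vv("chrOther", 5, "A", "C"), TT$F4, G))
})

test_that("a non-coding transcript yields non_coding_transcript_variant", {
  nc <- transcript_model("NC", "G1", "G1", "chrT", "+", cbind(1L, 15L))
  expect_equal(classify_variant(vv("chrT", 8, "C", "A"), nc, G)$term,
               "non_coding_transcript_variant")
})

test_that("indels in the CDS are classified by frame and start-codon
          overlap", {
  # single-base deletion (normalized) -> frameshift
  n <- normalize_variant("chrT", 7, "G", "-", G)
  expect_equal(classify_variant(n, TT$F1, G)$term, "frameshift_variant")
  # 3-base codon-aligned deletion on F4 -> inframe_deletion
  g4 <- G$sequences[["chrT4"]]
  n <- normalize_variant("chrT4", 4, substr(g4, 4, 6), "-", G)
  expect_equal(classify_variant(n, TT$F4, G)$term, "inframe_deletion")
  # 3-base insertion at a codon boundary -> inframe_insertion
  n <- normalize_variant("chrT4", 4, "-", "AAA", G)
  expect_equal(classify_variant(n, TT$F4, G)$term, "inframe_insertion")
  # deletion overlapping the start codon -> start_lost
  n <- normalize_variant("chrT", 5, "TG", "-", G)
  expect_equal(classify_variant(n, TT$F1, G)$term, "start_lost")
})

test_that("classification is deterministic", {
  v <- vv("chrT", 8, "C", "A")
  a <- classify_variant(v, TT$F1, G)
  b <- classify_variant(v, TT$F1, G)
  expect_identical(a, b)
})

test_that("classification agrees with the edit-and-translate oracle on 1000
          random planted variants", {
  fx <- property_fixture()
  canon <- Filter(function(t) t$canonical, fx$transcripts)
  set.seed(99)
  n_checked <- 0
  mismatches <- character(0)
  while (n_checked < 1000) {
    t <- canon[[sample(length(canon), 1)]]
    ev <- random_event(t, fx$genome)
    n <- tryCatch(normalize_variant(t$chrom, ev$pos, ev$ref, ev$alt,
                                    fx$genome),
                  error = function(e) NULL)
    if (is.null(n)) next
    got <- classify_variant(n, t, fx$genome)
    want <- oracle_classify(fx$genome$sequences[[t$chrom]], t$exons,
                            t$cds_start, t$cds_end, t$strand,
                            n$pos, n$ref, n$alt)
    gt <- if (is.null(got)) NA_character_ else got$term
    if (!identical(gt, want))
      mismatches <- c(mismatches,
                      sprintf("%s on %s: got %s want %s", n$key,
                              t$transcript_id, gt, want))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 1000)
  expect_length(mismatches, 0)
})

test_that("the cross-tab normalizes per term or per significance and keeps
          zero rows all-zero", {
  v <- empty_variants()
  add <- function(v, term, sig) {
    r <- v[0, ]
    row <- data.frame(chrom = "c", pos = 1L, ref = "A", alt = "C",
                      key = paste0("k", nrow(v)), rsid = NA,
                      other_ids = "", gene_symbols = "",
                      consequence_terms = term, significance = sig,
                      phenotypes = "", sources = "ENSEMBL", pmids = "",
                      flags = "")
    rbind(v, row)
  }
  v <- add(v, "missense_variant", "pathogenic")
  v <- add(v, "missense_variant", "benign")
  v <- add(v, "synonymous_variant", "benign")
  v <- add(v, "synonymous_variant", "benign")
  ct <- consequence_crosstab(v, "term")
  expect_equal(ct$percent["missense_variant", "pathogenic"], 50)
  expect_equal(ct$percent["missense_variant", "benign"], 50)
  expect_equal(ct$percent["synonymous_variant", "benign"], 100)
  expect_equal(ct$percent["synonymous_variant", "pathogenic"], 0)
  expect_true(all(abs(rowSums(ct$percent) - 100) < 1e-6 |
                    rowSums(ct$counts) == 0))
  ct2 <- consequence_crosstab(v, "significance")
  expect_equal(ct2$percent["missense_variant", "pathogenic"], 100)
  expect_equal(ct2$percent["missense_variant", "benign"], 100 / 3,
               tolerance = 1e-9)
  expect_equal(ct2$percent["synonymous_variant", "benign"], 200 / 3,
               tolerance = 1e-9)
  # empty input
  ct0 <- consequence_crosstab(empty_variants())
  expect_equal(sum(ct0$counts), 0)
})

test_that("missing significance is tallied under 'other'", {
  v <- empty_variants()
  v[1, ] <- list("c", 1L, "A", "C", "k", NA, "", "", "missense_variant",
                 NA, "", "ENSEMBL", "", "")
  ct <- consequence_crosstab(v)
  expect_equal(ct$counts["missense_variant", "other"], 1L)
})

test_that("the retained-term filter keeps any-match variants, removes
          synonymous-only rows and passes unclassified rows through with a
          flag", {
  v <- empty_variants()
  v[1, ] <- list("c", 1L, "A", "C", "k1", NA, "", "", "synonymous_variant",
                 NA, "", "ENSEMBL", "", "")
  v[2, ] <- list("c", 2L, "A", "C", "k2", NA, "", "",
                 "missense_variant;intron_variant", NA, "", "ENSEMBL", "",
                 "")
  v[3, ] <- list("c", 3L, "AT", "A", "k3", NA, "", "", "", NA, "",
                 "CLINVAR", "", "")
  res <- filter_by_consequence(v)
  expect_setequal(res$kept$key, c("k2", "k3"))
  expect_equal(res$removed$key, "k1")
  expect_match(res$kept$flags[res$kept$key == "k3"], "unclassified")
  # partition
  expect_equal(sort(c(res$kept$key, res$removed$key)), sort(v$key))
  expect_length(intersect(res$kept$key, res$removed$key), 0)
})

test_that("annotation fills consequence terms and gene symbols from the
          gene models", {
  v <- empty_variants()
  v[1, ] <- list("chrT", 8L, "C", "A", "chrT:8:C:A", NA, "", "", "", NA, "",
                 "CLINVAR", "", "")
  ann <- annotate_consequences(v, TT, G)
  expect_equal(ann$variants$consequence_terms[1], "missense_variant")
  expect_equal(ann$variants$gene_symbols[1], "G1")
  expect_equal(nrow(ann$calls), 1)
  expect_equal(ann$calls$protein_pos, 2L)
})
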