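# Variant application to spliced cDNA and protein translation.

wf <- worked_fixtures()
G <- wf$genome
TT <- wf$transcripts

vv <- function(chrom, pos, ref, alt)
  list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)

test_that("variants are substituted into the spliced cDNA strand-aware", {
  ap <- apply_variant_to_cdna(TT$F1, G, vv("chrT", 8, "C", "A"))
  expect_true(ap$applied)
  expect_equal(ap$cdna, "AAAATGGATTAAAAA")
  # minus strand: genomic G>T complements into the transcript
  ap <- apply_variant_to_cdna(TT$F2, G, vv("chrT2", 5, "G", "T"))
  expect_true(ap$applied)
  expect_equal(ap$cdna, "ATGGATTAA")
  # intronic/splice variants are skipped with a reason, not applied
  ap <- apply_variant_to_cdna(TT$F4, G, vv("chrT4", 10, "G", "A"))
  expect_false(ap$applied)
  expect_equal(ap$reason, "non_exonic")
  # outside the locus
  ap <- apply_variant_to_cdna(TT$F4, G, vv("chrT4", 40, "A", "C"))
  expect_equal(ap$reason, "outside_transcript")
  # non-coding transcript
  nc <- transcript_model("NC", "G1", "G1", "chrT", "+", cbind(1L, 15L))
  expect_equal(apply_variant_to_cdna(nc, G, vv("chrT", 8, "C", "A"))$reason,
               "no_CDS")
})

test_that("a wrong reference allele on the transcript is a reference
          mismatch error", {
  expect_error(apply_variant_to_cdna(TT$F1, G, vv("chrT", 8, "G", "A")),
               "reference mismatch")
})

test_that("translation handles missense, stop-loss readthrough, frameshift,
          stop-gain truncation and start-loss exactly as the worked
          examples", {
  r <- translate_variant(TT$F1, G, vv("chrT", 8, "C", "A"))
  expect_equal(r$sequence, "MD")
  expect_equal(r$ref_sequence, "MA")
  expect_equal(r$protein_change, "p.A2D")
  # stop lost: translation runs into the 3' UTR
  r <- translate_variant(TT$F1, G, vv("chrT", 10, "T", "A"))
  expect_equal(r$sequence, "MAKK")
  expect_true("no_terminal_stop" %in% r$flags)
  # frameshift from the normalized single-base deletion
  del <- normalize_variant("chrT", 7, "G", "-", G)
  r <- translate_variant(TT$F1, G, del)
  expect_equal(r$sequence, "MLK")
  expect_setequal(r$flags, c("no_terminal_stop", "incomplete_codon"))
  # stop gained truncates
  r <- translate_variant(TT$F1B, G, vv("chrT3", 5, "C", "A"))
  expect_equal(r$sequence, "M")
  # start lost: no product, no downstream rescanning
  r <- translate_variant(TT$F1, G, vv("chrT", 5, "T", "C"))
  expect_true("no_product" %in% r$flags)
  expect_equal(r$sequence, "")
  expect_equal(r$protein_change, "p.0")
  # minus strand missense
  r <- translate_variant(TT$F2, G, vv("chrT2", 5, "G", "T"))
  expect_equal(r$sequence, "MD")
})

test_that("a synonymous substitution reproduces the reference product
          exactly", {
  r <- translate_variant(TT$F1, G, vv("chrT", 9, "T", "C"))
  expect_equal(r$sequence, r$ref_sequence)
  expect_equal(r$protein_change, "p.=")
})

test_that("translation agrees with the genome-surgery oracle on 1000 random
          exonic variants", {
  fx <- property_fixture()
  coding <- Filter(function(t) !is.na(t$cds_start), fx$transcripts)
  set.seed(123)
  n_checked <- 0
  mismatches <- character(0)
  while (n_checked < 1000) {
    t <- coding[[sample(length(coding), 1)]]
    ev <- random_event(t, fx$genome)
    n <- tryCatch(normalize_variant(t$chrom, ev$pos, ev$ref, ev$alt,
                                    fx$genome),
                  error = function(e) NULL)
    if (is.null(n)) next
    want <- oracle_edit_translate(fx$genome$sequences[[t$chrom]], t$exons,
                                  t$cds_start, t$cds_end, t$strand,
                                  n$pos, n$ref, n$alt)
    got <- translate_variant(t, fx$genome, n)
    if (is.null(want)) {
      # oracle says non-exonic: the package must skip it too
      if (got$applied) mismatches <- c(mismatches,
                                       paste("applied non-exonic", n$key))
      next  # only exonic events count towards the 1000
    }
    ok <- identical(got$sequence, want$protein) &&
      identical("no_product" %in% got$flags, "no_product" %in% want$flags) &&
      identical("no_terminal_stop" %in% got$flags,
                "no_terminal_stop" %in% want$flags)
    if (!ok) mismatches <- c(mismatches,
                             sprintf("%s on %s: got %s want %s", n$key,
                                     t$transcript_id, got$sequence,
                                     want$protein))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 1000)
  expect_length(mismatches, 0)
})

test_that("in-frame indels of length 3k change the protein length by k when
          no new stop appears", {
  fx <- property_fixture()
  canon <- Filter(function(t) t$canonical, fx$transcripts)
  set.seed(31)
  checked <- 0
  while (checked < 60) {
    t <- canon[[sample(length(canon), 1)]]
    cdna <- spliced_cdna(t, fx$genome)
    b_lo <- genomic_to_cdna(t, if (t$strand == "+") t$cds_start else
      t$cds_end)$cdna_pos
    # deletion of one interior codon, spelled genomically
    map_len <- sum(t$exons[, 2] - t$exons[, 1] + 1)
    ci <- sample(3:10, 1)
    j <- b_lo + 3 * (ci - 1)
    gp <- sort(vapply(j:(j + 2), function(x) cdna_to_genomic(t, x),
                      integer(1)))
    if (gp[3] - gp[1] != 2) next   # codon straddles an intron; re-draw
    ref <- genome_slice(fx$genome, t$chrom, gp[1], gp[3])
    n <- normalize_variant(t$chrom, gp[1], ref, "-", fx$genome)
    got <- translate_variant(t, fx$genome, n)
    if (!got$applied || "no_product" %in% got$flags) next
    if (grepl("\\*", got$sequence)) next
    if (nchar(got$sequence) != nchar(got$ref_sequence) - 1) {
      # a new stop may legitimately shorten the product further
      expect_lte(nchar(got$sequence), nchar(got$ref_sequence) - 1)
    } else {
      expect_equal(nchar(got$sequence), nchar(got$ref_sequence) - 1)
    }
    checked <- checked + 1
  }
  expect_gte(checked, 60)
})

test_that("isoform expansion produces one record per compatible coding
          isoform and preserves skip reasons", {
  fx <- property_fixture(seed = 77)
  # build a 3-isoform gene: canonical, exon-skipping, non-coding
  fx3 <- generate_fixture(seed = 78, n_genes = 1, isoforms_per_gene = 3,
                          n_variants = 0, out_dir = tempfile())
  tts <- fx3$transcripts
  expect_length(tts, 3)
  t1 <- tts[[1]]
  # plant a missense in the FIRST exon (shared by canonical and skip
  # isoforms, absent from the non-coding isoform's exon set only if dropped)
  b_lo <- genomic_to_cdna(t1, if (t1$strand == "+") t1$cds_start else
    t1$cds_end)$cdna_pos
  gp <- cdna_to_genomic(t1, b_lo + 4)
  refb <- genome_slice(fx3$genome, t1$chrom, gp, gp)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  v <- list(chrom = t1$chrom, pos = gp, ref = refb, alt = altb)
  ex <- expand_all_isoforms(v, tts, fx3$genome, level = 2)
  # coding isoforms sharing the exon give records; the non-coding isoform is
  # skipped with reason no_CDS (or non_exonic if the exon is absent)
  expect_gte(length(ex$records), 1)
  expect_true(nrow(ex$skipped) >= 1)
  expect_true(all(ex$skipped$reason %in%
                    c("no_CDS", "non_exonic", "outside_transcript")))
  # canonical-only filter
  exc <- expand_all_isoforms(v, tts, fx3$genome, canonical_only = TRUE)
  expect_true(all(vapply(exc$records, `[[`, character(1),
                         "transcript_id") ==
                    t1$transcript_id))
})

test_that("protein FASTA writing follows the header grammar, wraps at 60
          columns, orders deterministically and round-trips", {
  rec <- translate_variant(TT$F1, G, vv("chrT", 8, "C", "A"), level = 2L)
  path <- tempfile(fileext = ".fasta")
  write_protein_fasta(list(rec), path)
  lines <- readLines(path)
  expect_equal(lines[1], ">G1|F1|chrT:8:C:A|p.A2D|L2|")
  expect_equal(lines[2], "MD")
  back <- read_protein_fasta(path)
  expect_equal(unname(back), "MD")
  # empty record list -> empty file
  path2 <- tempfile(fileext = ".fasta")
  write_protein_fasta(list(), path2)
  expect_equal(file.size(path2), 0)
  # long sequences wrap at 60 columns and re-parse identically
  fake <- rec
  fake$sequence <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 8), collapse = "")
  write_protein_fasta(list(fake), path2)
  lines <- readLines(path2)
  expect_true(all(nchar(lines[-1]) <= 60))
  expect_equal(unname(read_protein_fasta(path2)), fake$sequence)
  # duplicate headers get ordinal suffixes with a warning
  expect_warning(write_protein_fasta(list(rec, rec), path2), "duplicate")
  expect_length(read_protein_fasta(path2), 2)
})

test_that("emitted sequences use only the twenty amino-acid letters plus X", {
  fx <- generate_fixture(seed = 3, n_genes = 3, isoforms_per_gene = 2,
                         n_variants = 30, out_dir = tempfile())
  models <- list(genome = fx$genome, transcripts = fx$transcripts)
  tv <- fx$truth$variants[fx$truth$variants$level1, ]
  recs <- list()
  for (i in seq_len(nrow(tv))) {
    r <- tv[i, ]
    tts <- Filter(function(t) t$gene_symbol == r$gene, models$transcripts)
    v <- list(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt)
    recs <- c(recs, expand_all_isoforms(v, tts, models$genome)$records)
  }
  seqs <- vapply(recs, `[[`, character(1), "sequence")
  seqs <- seqs[nzchar(seqs)]
  expect_gt(length(seqs), 0)
  expect_false(any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)))
})
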