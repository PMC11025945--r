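# Synthetic-data generation: seeded genomes, gene models and the three
# source-table dialects with complete planted ground truth, so that every
# pipeline stage is testable offline.
#
# Design of a generated gene: three exons on its own chromosome. The CDS is
# a clean ORF (ATG + sense codons + stop); the middle exon holds whole
# codons, so the second isoform (which skips it) stays in frame with no new
# stop by construction. Introns are GT..AG. The third isoform, when
# requested, is non-coding (no CDS), mirroring transcripts without an
# annotated protein product.

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  all <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           c("A", "C", "G", "T")), 1, paste, collapse = "")
  setdiff(all, STOP_CODONS)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Hand-built worked loci
#'
#' Four tiny reference loci used throughout the unit tests: a plus-strand
#' single-exon gene with UTRs (F1), a compact start-to-stop ORF (F1B), a
#' minus-strand gene (F2) and a two-exon gene with a 20-nt intron (F4).
#'
#' @return list with `genome` (a `reference_genome`) and `transcripts`
#'   (named list of `transcript_model`).
#' @export
worked_fixtures <- function() {
  genome <- reference_genome(c(
    chrT = "AAAATGGCTTAAAAA",
    chrT2 = "TTAAGCCAT",
    chrT3 = "ATGTCATAA",
    chrT4 = paste0("ATGGCTGGA", "GTAAGTCTTTTTTTTTCTAG", "AGCTTTTAA", "AA")))
  transcripts <- list(
    F1 = transcript_model("F1", "G1", "G1", "chrT", "+",
                          cbind(1L, 15L), 4L, 12L, canonical = TRUE),
    F1B = transcript_model("F1B", "G1B", "G1B", "chrT3", "+",
                           cbind(1L, 9L), 1L, 9L, canonical = TRUE),
    F2 = transcript_model("F2", "G2", "G2", "chrT2", "-",
                          cbind(1L, 9L), 1L, 9L, canonical = TRUE),
    F4 = transcript_model("F4", "G4", "G4", "chrT4", "+",
                          rbind(c(1L, 9L), c(30L, 38L)), 1L, 38L,
                          canonical = TRUE))
  list(genome = genome, transcripts = transcripts)
}

#' Write a reference genome as FASTA
#' @param g a `reference_genome`.
#' @param path output path (plain text; wraps at 70 columns).
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(g, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (chrom in names(g$sequences)) {
    writeLines(paste0(">", chrom), con)
    s <- g$sequences[[chrom]]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}

#' Write transcript models as GFF3
#'
#' Emits gene / mRNA / exon / CDS features with ID/Parent links; canonical
#' isoforms carry `canonical=1`. CDS rows are split per exon with proper
#' phase.
#'
#' @param transcripts list of `transcript_model`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  genes_done <- character(0)
  for (t in transcripts) {
    if (!t$gene_id %in% genes_done) {
      peers <- Filter(function(x) identical(x$gene_id, t$gene_id),
                      transcripts)
      glo <- min(vapply(peers, function(x) x$exons[1, 1], integer(1)))
      ghi <- max(vapply(peers, function(x) x$exons[nrow(x$exons), 2],
                        integer(1)))
      lines <- c(lines, paste(t$chrom, "vartoprot", "gene", glo, ghi, ".",
                              t$strand, ".",
                              sprintf("ID=%s;Name=%s", t$gene_id,
                                      t$gene_symbol), sep = "\t"))
      genes_done <- c(genes_done, t$gene_id)
    }
    attrs <- sprintf("ID=%s;Parent=%s%s", t$transcript_id, t$gene_id,
                     if (t$canonical) ";canonical=1" else "")
    lines <- c(lines, paste(t$chrom, "vartoprot", "mRNA", t$exons[1, 1],
                            t$exons[nrow(t$exons), 2], ".", t$strand, ".",
                            attrs, sep = "\t"))
    for (i in seq_len(nrow(t$exons)))
      lines <- c(lines, paste(t$chrom, "vartoprot", "exon", t$exons[i, 1],
                              t$exons[i, 2], ".", t$strand, ".",
                              sprintf("ID=%s.exon%d;Parent=%s",
                                      t$transcript_id, i, t$transcript_id),
                              sep = "\t"))
    if (has_cds(t)) {
      segs <- list()
      for (i in seq_len(nrow(t$exons))) {
        lo <- max(t$exons[i, 1], t$cds_start)
        hi <- min(t$exons[i, 2], t$cds_end)
        if (lo <= hi) segs[[length(segs) + 1]] <- c(lo, hi)
      }
      if (t$strand == "-") segs <- rev(segs)
      cum <- 0L
      for (j in seq_along(segs)) {
        phase <- (3L - cum %% 3L) %% 3L
        lines <- c(lines, paste(t$chrom, "vartoprot", "CDS", segs[[j]][1],
                                segs[[j]][2], ".", t$strand, phase,
                                sprintf("ID=%s.cds%d;Parent=%s",
                                        t$transcript_id, j, t$transcript_id),
                                sep = "\t"))
        cum <- cum + (segs[[j]][2] - segs[[j]][1] + 1L)
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- genome-surgery truth computation -------------------------------------

# Apply a normalized variant at the genome level, shift the transcript
# geometry and re-translate. Used at generation time to verify the planted
# consequence and record the true per-isoform protein product. Returns NULL
# when the variant is not exonic on the transcript.
surgery_protein <- function(t, g, pos, ref, alt) {
  map <- cdna_map(t)
  nr <- nchar(ref); na <- nchar(alt)
  if (!all(seq.int(pos, pos + nr - 1L) %in% map)) return(NULL)
  if (na > nr && !((pos + 1L) %in% map) && pos != map[length(map)])
    return(NULL)
  if (!has_cds(t)) return(list(protein = "", flags = "no_CDS"))
  seqs <- g$sequences
  s <- seqs[[t$chrom]]
  stopifnot(substr(s, pos, pos + nr - 1L) == ref)
  seqs[[t$chrom]] <- paste0(substr(s, 1L, pos - 1L), alt,
                            substr(s, pos + nr, nchar(s)))
  net <- na - nr
  del_end <- pos + nr - 1L
  # coordinates past the edited region shift by the net length; coordinates
  # inside a deleted region collapse onto its surviving left edge
  shift <- function(x) ifelse(x > del_end, x + net,
                              pmin(x, pos + na - 1L))
  t2 <- transcript_model(t$transcript_id, t$gene_id, t$gene_symbol, t$chrom,
                         t$strand, cbind(shift(t$exons[, 1]),
                                         shift(t$exons[, 2])),
                         shift(t$cds_start), shift(t$cds_end), t$canonical)
  g2 <- reference_genome(seqs)
  b <- cds_cdna_bounds(t2)
  cdna <- spliced_cdna(t2, g2)
  if (substr(cdna, b["lo"], b["lo"] + 2L) != "ATG")
    return(list(protein = "", flags = c("no_product", "start_lost")))
  tr <- translate_cds(substr(cdna, b["lo"], nchar(cdna)))
  list(protein = tr$protein, flags = tr$flags)
}

# Consequence of a normalized variant derived from genome surgery plus
# geometry; used to verify planted variants at generation time.
surgery_term <- function(t, g, pos, ref, alt) {
  aff <- affected_positions(pos, ref, alt)
  sw <- splice_windows(t)
  if (any(aff %in% sw$donor)) return("splice_donor_variant")
  if (any(aff %in% sw$acceptor)) return("splice_acceptor_variant")
  if (any(aff %in% sw$donor5)) return("splice_donor_5th_base_variant")
  map <- cdna_map(t)
  if (!any(aff %in% map)) return("intron_variant")
  if (!has_cds(t)) return("non_coding_transcript_variant")
  b <- cds_cdna_bounds(t)
  idx <- sort(match(aff[aff %in% map], map))
  if (all(idx < b["lo"])) return("5_prime_UTR_variant")
  if (all(idx > b["hi"])) return("3_prime_UTR_variant")
  nr <- nchar(ref); na <- nchar(alt)
  # reference product, straight from the unedited transcript
  cdna <- spliced_cdna(t, g)
  rp <- translate_cds(substr(cdna, b["lo"], nchar(cdna)))
  vp <- surgery_protein(t, g, pos, ref, alt)
  if (is.null(vp)) return(NA_character_)
  if (nr != na) {
    if (!is.null(vp) && "start_lost" %in% vp$flags) return("start_lost")
    if ((na - nr) %% 3L != 0L) return("frameshift_variant")
    return(if (na > nr) "inframe_insertion" else "inframe_deletion")
  }
  if ("start_lost" %in% vp$flags) return("start_lost")
  if (identical(rp$protein, vp$protein) &&
      identical("no_terminal_stop" %in% rp$flags,
                "no_terminal_stop" %in% vp$flags)) return("synonymous_variant")
  if (nchar(vp$protein) < nchar(rp$protein) &&
      startsWith(rp$protein, vp$protein)) return("stop_gained")
  if ("no_terminal_stop" %in% vp$flags &&
      !("no_terminal_stop" %in% rp$flags)) return("stop_lost")
  "missense_variant"
}

# ---- gene construction ----------------------------------------------------

build_fixture_gene <- function(gene_idx, gene_symbol, isoforms_per_gene,
                               strand) {
  codons <- sense_codons()
  u5 <- sample(6:12, 1); u3 <- sample(6:12, 1)
  na_cod <- sample(8:14, 1); nb_cod <- sample(5:10, 1)
  nc_cod <- sample(8:14, 1)
  cod_a <- c("ATG", sample(codons, na_cod - 1, replace = TRUE))
  cod_b <- sample(codons, nb_cod, replace = TRUE)
  cod_c <- c(sample(codons, nc_cod, replace = TRUE),
             sample(STOP_CODONS, 1))
  e1 <- paste0(rand_dna(u5), paste(cod_a, collapse = ""))
  e2 <- paste(cod_b, collapse = "")
  e3 <- paste0(paste(cod_c, collapse = ""), rand_dna(u3))
  i1 <- paste0("GT", rand_dna(sample(10:20, 1)), "AG")
  i2 <- paste0("GT", rand_dna(sample(10:20, 1)), "AG")
  fl5 <- rand_dna(15); fl3 <- rand_dna(15)
  fwd <- paste0(fl5, e1, i1, e2, i2, e3, fl3)
  # forward-space coordinates
  s1 <- 16L; e1e <- s1 + nchar(e1) - 1L
  s2 <- e1e + nchar(i1) + 1L; e2e <- s2 + nchar(e2) - 1L
  s3 <- e2e + nchar(i2) + 1L; e3e <- s3 + nchar(e3) - 1L
  cds_f_start <- s1 + u5
  cds_f_end <- e3e - u3
  L <- nchar(fwd)
  chrom <- paste0("chr", gene_idx)
  if (strand == "+") {
    chrom_seq <- fwd
    ex <- rbind(c(s1, e1e), c(s2, e2e), c(s3, e3e))
    cds <- c(cds_f_start, cds_f_end)
  } else {
    chrom_seq <- revcomp(fwd)
    mirror <- function(x) L - x + 1L
    ex <- rbind(c(mirror(e3e), mirror(s3)), c(mirror(e2e), mirror(s2)),
                c(mirror(e1e), mirror(s1)))
    cds <- c(mirror(cds_f_end), mirror(cds_f_start))
  }
  gid <- paste0("GENE", gene_idx)
  tts <- list(transcript_model(paste0("T", gene_idx, ".1"), gid, gene_symbol,
                               chrom, strand, ex, cds[1], cds[2],
                               canonical = TRUE))
  if (isoforms_per_gene >= 2)
    tts <- c(tts, list(transcript_model(
      paste0("T", gene_idx, ".2"), gid, gene_symbol, chrom, strand,
      ex[-2, , drop = FALSE], cds[1], cds[2], canonical = FALSE)))
  if (isoforms_per_gene >= 3)
    tts <- c(tts, list(transcript_model(
      paste0("T", gene_idx, ".3"), gid, gene_symbol, chrom, strand,
      ex[-1, , drop = FALSE], canonical = FALSE)))
  list(chrom = chrom, seq = chrom_seq, transcripts = tts)
}

# ---- variant planting -----------------------------------------------------

DEFAULT_TYPE_MIX <- c(missense_variant = 0.38, synonymous_variant = 0.08,
                      stop_gained = 0.08, stop_lost = 0.02, start_lost = 0.02,
                      frameshift_variant = 0.12, inframe_deletion = 0.05,
                      inframe_insertion = 0.05, splice_donor_variant = 0.05,
                      splice_acceptor_variant = 0.04,
                      splice_donor_5th_base_variant = 0.01,
                      intron_variant = 0.04, `5_prime_UTR_variant` = 0.03,
                      `3_prime_UTR_variant` = 0.03)

EXONIC_TYPES <- c("missense_variant", "synonymous_variant", "stop_gained",
                  "stop_lost", "start_lost", "frameshift_variant",
                  "inframe_deletion", "inframe_insertion",
                  "5_prime_UTR_variant", "3_prime_UTR_variant")

complement1 <- function(b) chartr("ACGTN", "TGCAN", b)

# Raw (dialect-level) spelling of one planted event of the given type on the
# canonical transcript. Returns list(pos, ref, alt, kind) in genomic
# coordinates where kind is one of snv/del/ins; del/ins carry the dialect
# fields del_pos/del_seq or ins_pos/ins_seq for "-" spellings.
plant_event <- function(type, t, g) {
  map <- cdna_map(t)
  b <- cds_cdna_bounds(t)
  chrom_seq <- g$sequences[[t$chrom]]
  cdna <- spliced_cdna(t, g)
  cds_len <- unname(b["hi"] - b["lo"] + 1L)
  ncod <- cds_len %/% 3L
  code <- Biostrings::GENETIC_CODE
  gpos_of <- function(cdna_idx) map[cdna_idx]
  gbase <- function(p) substr(chrom_seq, p, p)
  tx_to_genomic_snv <- function(cdna_idx, tx_alt) {
    p <- gpos_of(cdna_idx)
    list(pos = p, ref = gbase(p),
         alt = if (t$strand == "-") complement1(tx_alt) else tx_alt,
         kind = "snv")
  }
  codon_at <- function(i) substr(cdna, b["lo"] + 3L * (i - 1L),
                                 b["lo"] + 3L * i - 1L)
  aa_of <- function(cd) unname(code[cd])
  pick_sub <- function(pred, codon_range) {
    for (try in 1:200) {
      i <- if (length(codon_range) == 1) codon_range else
        sample(codon_range, 1)
      k <- sample(1:3, 1)
      cd <- codon_at(i)
      refb <- substr(cd, k, k)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      cd2 <- cd
      substr(cd2, k, k) <- altb
      if (pred(cd, cd2))
        return(tx_to_genomic_snv(b["lo"] + 3L * (i - 1L) + (k - 1L), altb))
    }
    NULL
  }
  interior <- 2:(ncod - 1)
  switch(type,
    missense_variant = pick_sub(function(a, bb)
      aa_of(a) != "*" && aa_of(bb) != "*" && aa_of(a) != aa_of(bb), interior),
    synonymous_variant = pick_sub(function(a, bb)
      aa_of(a) != "*" && aa_of(a) == aa_of(bb), interior),
    stop_gained = pick_sub(function(a, bb)
      aa_of(a) != "*" && aa_of(bb) == "*", interior),
    stop_lost = pick_sub(function(a, bb)
      aa_of(a) == "*" && aa_of(bb) != "*", ncod),
    start_lost = pick_sub(function(a, bb) bb != "ATG", 1L),
    frameshift_variant = {
      len <- sample(c(1L, 2L, 4L), 1)
      j <- sample(seq.int(b["lo"] + 3L, b["hi"] - 6L - len), 1)
      gp <- sort(gpos_of(seq.int(j, j + len - 1L)))
      if (gp[len] - gp[1] + 1L != len) return(NULL)   # straddles an intron
      list(pos = gp[1], ref = substr(chrom_seq, gp[1], gp[len]),
           alt = "", kind = "del")
    },
    inframe_deletion = {
      ci <- sample(interior[-length(interior)], 1)
      j <- b["lo"] + 3L * (ci - 1L)
      gp <- sort(gpos_of(seq.int(j, j + 2L)))
      if (gp[3] - gp[1] != 2L) return(NULL)           # straddles an intron
      list(pos = gp[1], ref = substr(chrom_seq, gp[1], gp[3]),
           alt = "", kind = "del")
    },
    inframe_insertion = {
      ci <- sample(interior, 1)
      j <- b["lo"] + 3L * (ci - 1L) - 1L   # insert at a codon boundary
      if (abs(gpos_of(j + 1L) - gpos_of(j)) != 1L) return(NULL)
      ins_tx <- sample(sense_codons(), 1)
      if (t$strand == "+") {
        list(pos = gpos_of(j) + 1L, ref = "", alt = ins_tx, kind = "ins")
      } else {
        list(pos = gpos_of(j), ref = "", alt = revcomp(ins_tx), kind = "ins")
      }
    },
    frameshift_insertion = {
      j <- sample(seq.int(b["lo"] + 3L, b["hi"] - 6L), 1)
      if (abs(gpos_of(j + 1L) - gpos_of(j)) != 1L) return(NULL)
      ins_tx <- rand_dna(sample(c(1L, 2L), 1))
      if (t$strand == "+") {
        list(pos = gpos_of(j) + 1L, ref = "", alt = ins_tx, kind = "ins")
      } else {
        list(pos = gpos_of(j), ref = "", alt = revcomp(ins_tx), kind = "ins")
      }
    },
    splice_donor_variant = {
      sw <- splice_windows(t)
      p <- sample(sw$donor, 1)
      list(pos = p, ref = gbase(p),
           alt = sample(setdiff(c("A", "C", "G", "T"), gbase(p)), 1),
           kind = "snv")
    },
    splice_acceptor_variant = {
      sw <- splice_windows(t)
      p <- sample(sw$acceptor, 1)
      list(pos = p, ref = gbase(p),
           alt = sample(setdiff(c("A", "C", "G", "T"), gbase(p)), 1),
           kind = "snv")
    },
    splice_donor_5th_base_variant = {
      sw <- splice_windows(t)
      p <- sample(sw$donor5, 1)
      list(pos = p, ref = gbase(p),
           alt = sample(setdiff(c("A", "C", "G", "T"), gbase(p)), 1),
           kind = "snv")
    },
    intron_variant = {
      ex <- t$exons
      k <- sample(nrow(ex) - 1, 1)
      lo <- ex[k, 2] + 1L; hi <- ex[k + 1, 1] - 1L
      cand <- seq.int(lo + 6L, hi - 3L)
      sw <- splice_windows(t)
      cand <- setdiff(cand, c(sw$donor, sw$donor5, sw$acceptor))
      p <- if (length(cand) == 1) cand else sample(cand, 1)
      list(pos = p, ref = gbase(p),
           alt = sample(setdiff(c("A", "C", "G", "T"), gbase(p)), 1),
           kind = "snv")
    },
    `5_prime_UTR_variant` = {
      j <- sample(seq_len(b["lo"] - 1L), 1)
      tx_to_genomic_snv(j, sample(setdiff(c("A", "C", "G", "T"),
                                          substr(cdna, j, j)), 1))
    },
    `3_prime_UTR_variant` = {
      j <- sample(seq.int(b["hi"] + 1L, nchar(cdna)), 1)
      tx_to_genomic_snv(j, sample(setdiff(c("A", "C", "G", "T"),
                                          substr(cdna, j, j)), 1))
    },
    stop("unknown planted type: ", type))
}

quota_counts <- function(n, fractions) {
  target <- round(n * sum(fractions))
  base <- floor(n * fractions)
  rem <- min(target - sum(base), length(fractions))
  if (rem > 0) {
    frac <- n * fractions - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Builds a seeded random genome with one three-exon gene per chromosome,
#' 1-3 isoforms per gene (canonical, a middle-exon-skipping isoform, and
#' optionally a non-coding isoform), plants `n_variants` variants of mixed
#' consequence types, assigns them to evidence sources by exact quota, and
#' writes the genome FASTA, the GFF3, the three source-dialect tables and the
#' manual mapping table. The complete truth (normalized key, verified
#' consequence, sources, significance, level membership and per-isoform
#' protein product computed by genome-level surgery) is returned and written
#' as a manifest. Regenerating with the same seed reproduces byte-identical
#' files.
#'
#' @param seed integer seed for all randomness.
#' @param n_genes number of genes (default 10; the first symbols come from a
#'   monogenic-diabetes panel so the level-2 gene exclusions are exercised).
#' @param isoforms_per_gene 1-3.
#' @param n_variants number of planted variants.
#' @param source_overlap named fractions `clinvar`, `literature`, `both`
#'   (of `n_variants`; must sum to at most 1). The remainder becomes
#'   Ensembl-table-only background, mirroring the role of the large exonic
#'   reference set relative to the disease-linked subset.
#' @param significance_mix named fractions over the significance vocabulary
#'   for archive-backed variants.
#' @param strand_mix probability that a gene lies on the minus strand.
#' @param type_mix named fractions over planted consequence types.
#' @param quirks list: `rsid_missing` (fraction of variants without an
#'   rsID), `multiallelic` (fraction of exonic SNV rows gaining a second
#'   alternative allele), `clinvar_rsid_only` (fraction of eligible archive
#'   rows spelled with an rsID but no coordinates).
#' @param out_dir output directory (created).
#' @return invisible list with `paths`, `truth`, `genome`, `transcripts`.
#' @export
generate_fixture <- function(seed, n_genes = 10, isoforms_per_gene = 2,
                             n_variants = 200,
                             source_overlap = c(clinvar = 0.55,
                                                literature = 0.05,
                                                both = 0.10),
                             significance_mix = c(pathogenic = 0.25,
                                                  likely_pathogenic = 0.15,
                                                  uncertain_significance = 0.35,
                                                  likely_benign = 0.10,
                                                  benign = 0.15),
                             strand_mix = 0.5,
                             type_mix = DEFAULT_TYPE_MIX,
                             quirks = list(rsid_missing = 0.10,
                                           multiallelic = 0.05,
                                           clinvar_rsid_only = 0.05),
                             out_dir = tempfile("fixture")) {
  stopifnot(n_genes >= 1, n_variants >= 0, isoforms_per_gene %in% 1:3,
            sum(source_overlap) <= 1 + 1e-9)
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  panel <- c("HNF1A", "GCK", "HNF1B", "HNF4A", "ABCC8", "KCNJ11", "BLK",
             "KLF11", "PAX4", "INS", "PDX1", "NEUROD1", "CEL", "APPL1")
  symbols <- c(panel, paste0("GENE", seq_len(max(0, n_genes - length(panel)))))
  symbols <- symbols[seq_len(n_genes)]

  genes <- lapply(seq_len(n_genes), function(i)
    build_fixture_gene(i, symbols[i],
                       isoforms_per_gene,
                       if (stats::runif(1) < strand_mix) "-" else "+"))
  seqs <- stats::setNames(vapply(genes, `[[`, character(1), "seq"),
                          vapply(genes, `[[`, character(1), "chrom"))
  genome <- reference_genome(seqs)
  transcripts <- unlist(lapply(genes, `[[`, "transcripts"), recursive = FALSE)
  names(transcripts) <- vapply(transcripts, `[[`, character(1),
                               "transcript_id")

  # per-gene burden: heavier weight on the first genes (unequal burden)
  gene_weights <- 1 / seq_len(n_genes)

  quotas <- quota_counts(n_variants, source_overlap)
  src_class <- c(rep("clinvar", quotas[1]), rep("literature", quotas[2]),
                 rep("both", quotas[3]),
                 rep("background", n_variants - sum(quotas)))
  if (length(src_class) > 1) src_class <- sample(src_class)

  truth_rows <- list()
  used_keys <- character(0)
  for (i in seq_len(n_variants)) {
    cls <- src_class[i]
    ok <- FALSE
    for (try in 1:100) {
      gi <- sample.int(n_genes, 1, prob = gene_weights)
      tcanon <- genes[[gi]]$transcripts[[1]]
      type <- if (cls == "background")
        sample(EXONIC_TYPES, 1,
               prob = type_mix[EXONIC_TYPES] / sum(type_mix[EXONIC_TYPES]))
      else sample(names(type_mix), 1, prob = type_mix)
      if (type == "frameshift_variant" && stats::runif(1) < 0.4)
        type_plant <- "frameshift_insertion"
      else type_plant <- type
      ev <- plant_event(type_plant, tcanon, genome)
      if (is.null(ev)) next
      norm <- tryCatch(normalize_variant(genes[[gi]]$chrom, ev$pos, ev$ref,
                                         ev$alt, genome),
                       error = function(e) NULL)
      if (is.null(norm)) next
      if (norm$key %in% used_keys) next
      got <- surgery_term(tcanon, genome, norm$pos, norm$ref, norm$alt)
      if (is.na(got) || got != type) next
      ok <- TRUE
      break
    }
    if (!ok) stop("could not plant a variant of type ", type,
                  " (infeasible parameter combination?)")
    used_keys <- c(used_keys, norm$key)
    truth_rows[[i]] <- list(idx = i, gene = symbols[gi], gene_idx = gi,
                            chrom = norm$chrom, pos = norm$pos,
                            ref = norm$ref, alt = norm$alt, key = norm$key,
                            raw = ev, type = type, src_class = cls)
  }

  # identifiers, significance, quirk routing
  disease <- vapply(truth_rows, function(r) r$src_class != "background",
                    logical(1))
  exonic <- vapply(truth_rows, function(r)
    !r$type %in% c("splice_donor_variant", "splice_acceptor_variant",
                   "splice_donor_5th_base_variant", "intron_variant"),
    logical(1))
  n <- length(truth_rows)
  rsid_missing <- stats::runif(n) < (quirks$rsid_missing %||% 0.1)
  sig_levels <- names(significance_mix)
  for (i in seq_len(n)) {
    r <- truth_rows[[i]]
    r$rsid <- if (rsid_missing[i]) NA_character_ else
      paste0("rs", 100000 + i)
    r$in_clinvar <- r$src_class %in% c("clinvar", "both")
    r$in_literature <- r$src_class %in% c("literature", "both")
    r$in_ensembl <- exonic[i]
    r$significance <- if (r$in_clinvar)
      sample(sig_levels, 1, prob = significance_mix) else NA_character_
    truth_rows[[i]] <- r
  }
  # a clinvar row without coordinates must be resolvable by rsID through the
  # Ensembl reference table, so the quirk only applies to exonic rows with an
  # rsID
  for (i in seq_len(n)) {
    r <- truth_rows[[i]]
    r$clinvar_rsid_only <- r$in_clinvar && r$in_ensembl &&
      !is.na(r$rsid) &&
      stats::runif(1) < (quirks$clinvar_rsid_only %||% 0)
    truth_rows[[i]] <- r
  }

  # level truth
  excluded_genes <- c("BLK", "KLF11", "PAX4")
  for (i in seq_len(n)) {
    r <- truth_rows[[i]]
    r$level1 <- r$in_clinvar || r$in_literature
    clin_ok <- r$in_clinvar &&
      r$significance %in% c("pathogenic", "likely_pathogenic")
    lit_ok <- r$in_literature && !(r$gene %in% excluded_genes)
    r$level2 <- r$level1 && (clin_ok || lit_ok)
    truth_rows[[i]] <- r
  }

  # per-isoform protein truth for level-1 variants (genome surgery)
  prot_rows <- list()
  for (r in truth_rows) {
    if (!r$level1) next
    for (t in genes[[r$gene_idx]]$transcripts) {
      sp <- surgery_protein(t, genome, r$pos, r$ref, r$alt)
      if (is.null(sp) || "no_CDS" %in% sp$flags) next
      prot_rows[[length(prot_rows) + 1]] <- data.frame(
        key = r$key, gene = r$gene, transcript_id = t$transcript_id,
        protein = sp$protein, flags = paste(sp$flags, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  protein_truth <- if (length(prot_rows)) do.call(rbind, prot_rows) else
    data.frame(key = character(0), gene = character(0),
               transcript_id = character(0), protein = character(0),
               flags = character(0))

  # ---- write the dialect tables -------------------------------------------
  dialect_alleles <- function(r) {
    # Ensembl spelling: slash-separated, "-" for the empty side, position of
    # the event itself (first deleted base / base after the insertion point)
    if (r$raw$kind == "snv")
      list(pos = r$raw$pos, alleles = paste0(r$raw$ref, "/", r$raw$alt))
    else if (r$raw$kind == "del")
      list(pos = r$raw$pos, alleles = paste0(r$raw$ref, "/-"))
    else
      list(pos = r$raw$pos, alleles = paste0("-/", r$raw$alt))
  }
  ens_rows <- list(); extra_alt_truth <- list()
  extra_keys <- character(0)
  for (r in truth_rows) {
    if (!r$in_ensembl) next
    da <- dialect_alleles(r)
    alleles <- da$alleles
    # multi-allelic quirk: add a second alternative allele at the same site
    # (skipped if that allele would collide with another planted variant)
    if (r$raw$kind == "snv" &&
        stats::runif(1) < (quirks$multiallelic %||% 0)) {
      third <- setdiff(c("A", "C", "G", "T"), c(r$raw$ref, r$raw$alt))
      alt2 <- sample(third, 1)
      k2 <- variant_key(r$chrom, r$raw$pos, r$raw$ref, alt2)
      if (!k2 %in% c(used_keys, extra_keys)) {
        alleles <- paste0(alleles, "/", alt2)
        extra_keys <- c(extra_keys, k2)
        extra_alt_truth[[length(extra_alt_truth) + 1]] <-
          data.frame(key = k2, gene = r$gene, stringsAsFactors = FALSE)
      }
    }
    ens_rows[[length(ens_rows) + 1]] <- data.frame(
      rsid = ifelse(is.na(r$rsid), ".", r$rsid), chrom = r$chrom,
      pos = da$pos, alleles = alleles, consequences = r$type,
      significance = ifelse(is.na(r$significance), "",
                            gsub("_", " ", r$significance)),
      gene = r$gene, stringsAsFactors = FALSE)
  }
  ens_df <- if (length(ens_rows)) do.call(rbind, ens_rows) else
    data.frame(rsid = character(0), chrom = character(0), pos = integer(0),
               alleles = character(0), consequences = character(0),
               significance = character(0), gene = character(0))

  clin_rows <- list()
  for (r in truth_rows) {
    if (!r$in_clinvar) next
    if (r$clinvar_rsid_only) {
      clin_rows[[length(clin_rows) + 1]] <- data.frame(
        accession = paste0("VCV", 10000 + r$idx), rsid = r$rsid,
        chrom = "", pos = "", ref = "", alt = "",
        significance = gsub("_", " ", r$significance), gene = r$gene,
        stringsAsFactors = FALSE)
    } else {
      clin_rows[[length(clin_rows) + 1]] <- data.frame(
        accession = paste0("VCV", 10000 + r$idx),
        rsid = ifelse(is.na(r$rsid), "", r$rsid),
        chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
        significance = gsub("_", " ", r$significance), gene = r$gene,
        stringsAsFactors = FALSE)
    }
  }
  clin_df <- if (length(clin_rows)) do.call(rbind, clin_rows) else
    data.frame(accession = character(0), rsid = character(0),
               chrom = character(0), pos = character(0), ref = character(0),
               alt = character(0), significance = character(0),
               gene = character(0))

  lit_rows <- list(); map_rows <- list()
  for (r in truth_rows) {
    if (!r$in_literature) next
    mode <- if (!is.na(r$rsid)) sample(c("rsid", "hgvs"), 1,
                                       prob = c(0.7, 0.3)) else "hgvs"
    if (mode == "rsid") {
      ident <- r$rsid; manual <- "0"
    } else {
      ident <- paste0("p.", r$gene, r$idx)   # synthetic protein-level label
      manual <- if (stats::runif(1) < 0.5) "1" else "0"
    }
    key_map <- if (mode == "rsid") ident else paste0(r$gene, ":", ident)
    lit_rows[[length(lit_rows) + 1]] <- data.frame(
      gene = r$gene, identifier = ident,
      pmid = paste0(30000000 + r$idx), stringsAsFactors = FALSE)
    map_rows[[length(map_rows) + 1]] <- data.frame(
      key = key_map, chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
      manual = manual, stringsAsFactors = FALSE)
  }
  lit_df <- if (length(lit_rows)) do.call(rbind, lit_rows) else
    data.frame(gene = character(0), identifier = character(0),
               pmid = character(0))
  map_df <- if (length(map_rows)) do.call(rbind, map_rows) else
    data.frame(key = character(0), chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0), manual = character(0))

  truth_df <- do.call(rbind, lapply(truth_rows, function(r) data.frame(
    idx = r$idx, key = r$key, chrom = r$chrom, pos = r$pos, ref = r$ref,
    alt = r$alt, gene = r$gene, type = r$type, src_class = r$src_class,
    rsid = ifelse(is.na(r$rsid), "", r$rsid),
    significance = ifelse(is.na(r$significance), "", r$significance),
    in_ensembl = r$in_ensembl, in_clinvar = r$in_clinvar,
    in_literature = r$in_literature, level1 = r$level1, level2 = r$level2,
    stringsAsFactors = FALSE)))
  if (is.null(truth_df))
    truth_df <- data.frame(idx = integer(0), key = character(0),
                           src_class = character(0), level1 = logical(0),
                           level2 = logical(0))

  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "genes.gff3"),
    ensembl = file.path(out_dir, "ensembl_variants.tsv"),
    clinvar = file.path(out_dir, "clinvar_variants.tsv"),
    literature = file.path(out_dir, "literature_variants.tsv"),
    mapping = file.path(out_dir, "manual_mapping.tsv"),
    manifest = file.path(out_dir, "truth_variants.tsv"),
    protein_manifest = file.path(out_dir, "truth_proteins.tsv"))
  write_genome_fasta(genome, paths$genome)
  write_gff3(transcripts, paths$gff3)
  write_tsv(ens_df, paths$ensembl)
  write_tsv(clin_df, paths$clinvar)
  write_tsv(lit_df, paths$literature)
  write_tsv(map_df, paths$mapping)
  write_tsv(truth_df, paths$manifest)
  write_tsv(protein_truth, paths$protein_manifest)

  venn <- c(clinvar = sum(truth_df$src_class == "clinvar"),
            literature = sum(truth_df$src_class == "literature"),
            both = sum(truth_df$src_class == "both"))
  truth <- list(variants = truth_df, proteins = protein_truth, venn = venn,
                extra_alts = if (length(extra_alt_truth))
                  do.call(rbind, extra_alt_truth) else
                    data.frame(key = character(0), gene = character(0)),
                seed = seed)
  invisible(list(paths = paths, truth = truth, genome = genome,
                 transcripts = transcripts))
}
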