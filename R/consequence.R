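# Consequence classification, the consequence x pathogenicity cross-tab and
# the retained-term filter.
#
# classify_variant() is a deterministic, purely coordinate-arithmetic variant
# effect predictor over the term vocabulary below; one term per
# (variant, transcript), resolved by severity precedence. The catch-all
# terms protein_altering_variant and coding_sequence_variant are accepted on
# input (external annotation) but never produced here.

CONSEQUENCE_VOCABULARY <- c(
  "missense_variant", "synonymous_variant", "stop_gained", "stop_lost",
  "start_lost", "frameshift_variant", "inframe_insertion", "inframe_deletion",
  "splice_donor_variant", "splice_acceptor_variant",
  "splice_donor_5th_base_variant", "protein_altering_variant",
  "coding_sequence_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
  "intron_variant", "non_coding_transcript_variant")

#' Default retained consequence terms
#'
#' The consequence types enriched in pathogenic / likely pathogenic variants
#' that are kept when filtering the reference variant table.
#'
#' @return character vector of term strings.
#' @export
default_retained_terms <- function() {
  c("missense_variant", "protein_altering_variant",
    "coding_sequence_variant", "frameshift_variant", "splice_donor_variant",
    "splice_acceptor_variant", "splice_donor_5th_base_variant", "start_lost",
    "stop_gained", "stop_lost", "inframe_deletion", "inframe_insertion")
}

# Genomic positions touched by a normalized variant. Indels share a leading
# anchor base: the event proper starts after it. An insertion "affects" the
# two bases flanking the insertion point.
affected_positions <- function(pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) return(seq.int(pos, pos + nr - 1L))
  if (nr > na) return(seq.int(pos + 1L, pos + nr - 1L))   # deletion
  c(pos, pos + 1L)                                        # insertion
}

# Splice windows of a transcript in genomic coordinates, computed in
# transcription orientation: donor = intron bases +1,+2; donor 5th base =
# intron +5; acceptor = intron bases -1,-2.
splice_windows <- function(t) {
  ex <- t$exons
  n <- nrow(ex)
  donors <- integer(0); donor5 <- integer(0); acceptors <- integer(0)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      lo <- ex[k, 2] + 1L; hi <- ex[k + 1, 1] - 1L   # intron, genomic
      ilen <- hi - lo + 1L
      if (ilen <= 0) next
      if (t$strand == "+") {
        donors <- c(donors, lo, if (ilen >= 2) lo + 1L)
        if (ilen >= 5) donor5 <- c(donor5, lo + 4L)
        acceptors <- c(acceptors, hi, if (ilen >= 2) hi - 1L)
      } else {
        donors <- c(donors, hi, if (ilen >= 2) hi - 1L)
        if (ilen >= 5) donor5 <- c(donor5, hi - 4L)
        acceptors <- c(acceptors, lo, if (ilen >= 2) lo + 1L)
      }
    }
  }
  list(donor = unname(donors), donor5 = unname(donor5),
       acceptor = unname(acceptors))
}

# Strand-adjusted allele as it appears in the spliced cDNA.
tx_allele <- function(allele, strand) {
  if (strand == "-") revcomp(allele) else toupper(allele)
}

#' Classify a variant's effect on one transcript
#'
#' Deterministic single-term consequence call for a normalized variant on one
#' transcript, with precedence splice > start_lost > stop_gained > stop_lost >
#' frameshift > inframe insertion/deletion > missense > synonymous > UTR >
#' intron. A variant lying entirely outside the transcript span yields `NULL`
#' (no call). Variants spanning region boundaries are classified by the most
#' severe overlapped category.
#'
#' @param v one-row variant (list or data.frame row) with chrom, pos, ref,
#'   alt in normalized form.
#' @param t a `transcript_model`.
#' @param g a `reference_genome`.
#' @return `NULL`, or a list with `variant_key`, `transcript_id`, `term`,
#'   `cds_pos`, `protein_pos`, `ref_aa`, `alt_aa`.
#' @export
classify_variant <- function(v, t, g) {
  if (v$chrom != t$chrom) return(NULL)
  pos <- as.integer(v$pos); ref <- toupper(v$ref); alt <- toupper(v$alt)
  aff <- affected_positions(pos, ref, alt)
  span <- c(t$exons[1, 1], t$exons[nrow(t$exons), 2])
  if (all(aff < span[1]) || all(aff > span[2])) return(NULL)

  call <- list(variant_key = variant_key(v$chrom, pos, ref, alt),
               transcript_id = t$transcript_id, term = NA_character_,
               cds_pos = NA_integer_, protein_pos = NA_integer_,
               ref_aa = NA_character_, alt_aa = NA_character_)
  done <- function(term) { call$term <- term; call }

  sw <- splice_windows(t)
  if (any(aff %in% sw$donor)) return(done("splice_donor_variant"))
  if (any(aff %in% sw$acceptor)) return(done("splice_acceptor_variant"))
  if (any(aff %in% sw$donor5)) return(done("splice_donor_5th_base_variant"))

  map <- cdna_map(t)
  exonic <- aff[aff %in% map]
  if (length(exonic) == 0) return(done("intron_variant"))
  if (!has_cds(t)) return(done("non_coding_transcript_variant"))

  b <- cds_cdna_bounds(t)
  cdna_idx <- sort(match(exonic, map))
  in_cds <- cdna_idx >= b["lo"] & cdna_idx <= b["hi"]
  if (!any(in_cds)) {
    if (all(cdna_idx < b["lo"])) return(done("5_prime_UTR_variant"))
    if (all(cdna_idx > b["hi"])) return(done("3_prime_UTR_variant"))
  }

  # CDS path
  cds_len <- unname(b["hi"] - b["lo"] + 1L)
  first_cds_idx <- cdna_idx[which(in_cds)[1]] %||% cdna_idx[1]
  cds_pos <- max(1L, min(cds_len, unname(first_cds_idx - b["lo"] + 1L)))
  nr <- nchar(ref); na <- nchar(alt)

  if (nr != na) {
    # indel: start_lost iff the start codon does not survive the edit
    # (left-alignment can slide an equivalent base into the codon, so a
    # purely positional overlap test would over-call)
    ap <- tryCatch(apply_variant_to_cdna(t, g, list(chrom = v$chrom,
                                                    pos = pos, ref = ref,
                                                    alt = alt)),
                   error = function(e) NULL)
    if (!is.null(ap) && isTRUE(ap$applied) &&
        substr(ap$cdna, ap$cds_lo, ap$cds_lo + 2L) != "ATG") {
      call$cds_pos <- cds_pos; call$protein_pos <- 1L
      call$term <- "start_lost"; return(call)
    }
    net <- na - nr
    # first residue touched: for insertions the new bases land after the
    # anchor, so the affected residue starts at the base following it
    eff_cds_pos <- if (na > nr) min(cds_pos + 1L, cds_len) else cds_pos
    call$cds_pos <- eff_cds_pos
    call$protein_pos <- (eff_cds_pos - 1L) %/% 3L + 1L
    if (net %% 3L != 0L) { call$term <- "frameshift_variant"; return(call) }
    call$term <- if (na > nr) "inframe_insertion" else "inframe_deletion"
    return(call)
  }

  # substitution (SNV or MNV): compare reference and edited CDS products
  cdna <- spliced_cdna(t, g)
  tx_ref <- tx_allele(ref, t$strand)
  tx_altA <- tx_allele(alt, t$strand)
  idx0 <- if (t$strand == "+") match(pos, map) else match(pos + nr - 1L, map)
  stopifnot(substr(cdna, idx0, idx0 + nr - 1L) == tx_ref)
  cdna_alt <- paste0(substr(cdna, 1L, idx0 - 1L), tx_altA,
                     substr(cdna, idx0 + nr, nchar(cdna)))
  cds_ref <- substr(cdna, b["lo"], b["hi"])
  cds_alt <- substr(cdna_alt, b["lo"], b["hi"])
  cds_pos <- unname(max(idx0, b["lo"]) - b["lo"] + 1L)
  call$cds_pos <- cds_pos
  codon_i <- (cds_pos - 1L) %/% 3L + 1L
  call$protein_pos <- codon_i
  ref_codon <- substr(cds_ref, 3L * codon_i - 2L, 3L * codon_i)
  alt_codon <- substr(cds_alt, 3L * codon_i - 2L, 3L * codon_i)
  code <- Biostrings::GENETIC_CODE
  aa_of <- function(codon) {
    if (nchar(codon) < 3) return(NA_character_)
    if (grepl("N", codon, fixed = TRUE)) return("X")
    unname(code[codon]) %||% "X"
  }
  call$ref_aa <- aa_of(ref_codon); call$alt_aa <- aa_of(alt_codon)

  if (codon_i == 1L && alt_codon != "ATG" && ref_codon == "ATG") {
    call$term <- "start_lost"; return(call)
  }
  if (nr == 1L) {
    if (!is.na(call$ref_aa) && !is.na(call$alt_aa)) {
      if (call$ref_aa != "*" && call$alt_aa == "*") {
        call$term <- "stop_gained"; return(call)
      }
      if (call$ref_aa == "*" && call$alt_aa != "*") {
        call$term <- "stop_lost"; return(call)
      }
      call$term <- if (call$ref_aa == call$alt_aa) "synonymous_variant"
        else "missense_variant"
      return(call)
    }
  }
  # multi-base substitution: diff the translated CDS products
  rp <- translate_cds(cds_ref); ap <- translate_cds(cds_alt)
  if (identical(rp$protein, ap$protein) &&
      identical("no_terminal_stop" %in% rp$flags,
                "no_terminal_stop" %in% ap$flags))
    return(done("synonymous_variant"))
  if (nchar(ap$protein) < nchar(rp$protein) &&
      startsWith(rp$protein, ap$protein))
    return(done("stop_gained"))
  if ("no_terminal_stop" %in% ap$flags && !("no_terminal_stop" %in% rp$flags))
    return(done("stop_lost"))
  done("missense_variant")
}

#' Annotate a variant table with consequence calls
#'
#' Classifies every variant against every transcript of its gene(s) (or, when
#' the variant carries no gene symbol, against every transcript on its
#' chromosome) and fills `consequence_terms` with the union of per-transcript
#' terms. Existing terms are kept unless `overwrite = TRUE`.
#'
#' @param variants a normalized variant table.
#' @param transcripts list of `transcript_model`.
#' @param g a `reference_genome`.
#' @param overwrite replace pre-existing consequence annotation.
#' @return list with `variants` (annotated table) and `calls` (one row per
#'   (variant, transcript) call).
#' @export
annotate_consequences <- function(variants, transcripts, g,
                                  overwrite = FALSE) {
  calls <- list()
  by_chrom <- split(transcripts,
                    vapply(transcripts, `[[`, character(1), "chrom"))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    cand <- by_chrom[[v$chrom]] %||% list()
    genes <- split_multi(v$gene_symbols)
    if (length(genes) > 0)
      cand <- Filter(function(t) t$gene_symbol %in% genes ||
                       t$gene_id %in% genes, cand)
    terms <- character(0); genes_hit <- character(0)
    for (t in cand) {
      cl <- classify_variant(v, t, g)
      if (is.null(cl)) next
      terms <- c(terms, cl$term)
      genes_hit <- c(genes_hit, t$gene_symbol)
      calls[[length(calls) + 1]] <- data.frame(
        key = cl$variant_key, transcript_id = cl$transcript_id,
        gene_symbol = t$gene_symbol, term = cl$term,
        cds_pos = cl$cds_pos %||% NA_integer_,
        protein_pos = cl$protein_pos %||% NA_integer_,
        ref_aa = cl$ref_aa %||% NA_character_,
        alt_aa = cl$alt_aa %||% NA_character_,
        stringsAsFactors = FALSE)
    }
    if (overwrite || !nzchar(variants$consequence_terms[i] %||% ""))
      variants$consequence_terms[i] <- join_multi(terms)
    if (!nzchar(variants$gene_symbols[i] %||% ""))
      variants$gene_symbols[i] <- join_multi(genes_hit)
  }
  list(variants = as_variant_table(variants),
       calls = if (length(calls)) do.call(rbind, calls) else
         data.frame(key = character(0), transcript_id = character(0),
                    gene_symbol = character(0), term = character(0),
                    cds_pos = integer(0), protein_pos = integer(0),
                    ref_aa = character(0), alt_aa = character(0)))
}

#' Consequence x significance cross-tabulation
#'
#' Counts variants over (consequence term, significance category) pairs; a
#' variant with several terms contributes to each of its term rows once.
#' Missing significance is counted under "other". The percentage matrix is
#' normalized along the chosen axis: per consequence term (each row sums to
#' 100) or per significance category (each column sums to 100); zero-count
#' rows/columns stay all-zero.
#'
#' @param variants a variant table with consequence terms.
#' @param normalize_axis `"term"` (default) or `"significance"`.
#' @return list of class `consequence_crosstab` with `counts` and `percent`
#'   matrices (rows = terms, columns = significance categories).
#' @export
consequence_crosstab <- function(variants, normalize_axis = c("term",
                                                              "significance")) {
  normalize_axis <- match.arg(normalize_axis)
  sigs <- SIGNIFICANCE_LEVELS
  terms_all <- sort(unique(unlist(lapply(variants$consequence_terms,
                                         split_multi))))
  counts <- matrix(0L, nrow = length(terms_all), ncol = length(sigs),
                   dimnames = list(terms_all, sigs))
  for (i in seq_len(nrow(variants))) {
    sg <- variants$significance[i]
    if (is.na(sg) || !nzchar(sg)) sg <- "other"
    for (tm in split_multi(variants$consequence_terms[i]))
      counts[tm, sg] <- counts[tm, sg] + 1L
  }
  percent <- counts * 0
  if (normalize_axis == "term") {
    rs <- rowSums(counts)
    nz <- rs > 0
    percent[nz, ] <- sweep(counts[nz, , drop = FALSE], 1, rs[nz], "/") * 100
  } else {
    cs <- colSums(counts)
    nz <- cs > 0
    percent[, nz] <- sweep(counts[, nz, drop = FALSE], 2, cs[nz], "/") * 100
  }
  structure(list(counts = counts, percent = percent,
                 normalize_axis = normalize_axis),
            class = "consequence_crosstab")
}

#' @export
print.consequence_crosstab <- function(x, ...) {
  cat("<consequence_crosstab> normalized per", x$normalize_axis, "\n")
  print(round(x$percent, 2))
  invisible(x)
}

#' Export a cross-tab as a heat map
#'
#' @param ct a `consequence_crosstab`.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
plot_crosstab <- function(ct, path) {
  m <- ct$percent
  grDevices::png(path, width = 900, height = 200 + 40 * nrow(m), res = 96)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(8, 14, 2, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::hcl.colors(50, "YlOrRd", rev = TRUE),
                  axes = FALSE, zlim = c(0, 100))
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)), labels = colnames(m),
                 las = 2, cex.axis = 0.8)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                 labels = rev(rownames(m)), las = 2, cex.axis = 0.8)
  invisible(path)
}

#' Filter variants by retained consequence terms
#'
#' A variant is kept iff any of its consequence terms is in the retained
#' list. Variants with empty consequence annotation (e.g. archive short
#' indels without predicted consequences) are kept and flagged
#' `"unclassified"` — the pass-through that hands them directly to
#' consolidation.
#'
#' @param variants a variant table.
#' @param retained_terms character vector (default
#'   [default_retained_terms()]).
#' @return list with `kept` and `removed` variant tables;
#'   `kept` + `removed` partition the input.
#' @export
filter_by_consequence <- function(variants,
                                  retained_terms = default_retained_terms()) {
  if (nrow(variants) == 0)
    return(list(kept = variants, removed = variants))
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    terms <- split_multi(variants$consequence_terms[i])
    if (length(terms) == 0) {
      keep[i] <- TRUE
      variants$flags[i] <- union_multi(variants$flags[i], "unclassified")
    } else {
      keep[i] <- any(terms %in% retained_terms)
    }
  }
  list(kept = as_variant_table(variants[keep, , drop = FALSE]),
       removed = as_variant_table(variants[!keep, , drop = FALSE]))
}
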