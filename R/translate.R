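# Variant-to-protein translation: apply each ledger variant to the spliced
# cDNA of every isoform of its gene and emit the variant protein sequences.

#' Apply a normalized variant to a spliced cDNA
#'
#' Substitutes the alternate allele into the spliced transcript sequence
#' (strand-aware complementation for minus-strand transcripts) and shifts the
#' CDS interval by the net indel length when the edit lies 5' of a bound.
#' Intronic, splice-site and outside variants are not applied (their protein
#' product is not predictable from the transcript sequence alone); the record
#' is skipped with a reason instead.
#'
#' @param t a `transcript_model`.
#' @param g a `reference_genome`.
#' @param v one-row variant with normalized chrom, pos, ref, alt.
#' @return list with `applied` (logical), `reason` (when not applied),
#'   `cdna` (edited sequence), `cds_lo`, `cds_hi` (edited CDS bounds in cDNA
#'   coordinates) and `edit_cdna_pos` (first edited cDNA index).
#' @export
apply_variant_to_cdna <- function(t, g, v) {
  skip <- function(reason) list(applied = FALSE, reason = reason)
  if (v$chrom != t$chrom) return(skip("other_chromosome"))
  if (!has_cds(t)) return(skip("no_CDS"))
  pos <- as.integer(v$pos); ref <- toupper(v$ref); alt <- toupper(v$alt)
  map <- cdna_map(t)
  nr <- nchar(ref); na <- nchar(alt)
  ref_positions <- seq.int(pos, pos + nr - 1L)
  if (!all(ref_positions %in% map)) {
    aff <- affected_positions(pos, ref, alt)
    span <- c(t$exons[1, 1], t$exons[nrow(t$exons), 2])
    if (all(aff < span[1]) || all(aff > span[2]))
      return(skip("outside_transcript"))
    return(skip("non_exonic"))
  }
  if (na > nr && !((pos + 1L) %in% map) && pos != map[length(map)])
    return(skip("non_exonic"))   # insertion point at an exon/intron boundary
  cdna <- spliced_cdna(t, g)
  b <- cds_cdna_bounds(t)
  if (t$strand == "+") {
    idx <- match(pos, map)
    tx_ref <- ref; tx_alt <- alt
  } else {
    idx <- match(pos + nr - 1L, map)
    tx_ref <- revcomp(ref); tx_alt <- revcomp(alt)
  }
  if (substr(cdna, idx, idx + nr - 1L) != tx_ref)
    stop(sprintf("reference mismatch on transcript %s at %s:%d",
                 t$transcript_id, v$chrom, pos))
  edited <- paste0(substr(cdna, 1L, idx - 1L), tx_alt,
                   substr(cdna, idx + nr, nchar(cdna)))
  lo <- unname(b["lo"]); hi <- unname(b["hi"])
  # remap the CDS bounds through the edit. The replaced cDNA window is
  # [idx, idx + nr - 1]; on the minus strand the surviving anchor sits at its
  # 3' end, so deleted/inserted bases lie 5' of it in transcript space.
  if (nr > na) {
    k <- nr - na
    d1 <- if (t$strand == "+") idx + na else idx   # first deleted cDNA base
    d2 <- d1 + k - 1L
    remap <- function(x) ifelse(x < d1, x, ifelse(x > d2, x - k, d1))
    lo <- remap(lo); hi <- remap(hi)
  } else if (na > nr) {
    k <- na - nr
    ip <- if (t$strand == "+") idx + nr - 1L else idx - 1L
    remap <- function(x) ifelse(x <= ip, x, x + k)
    lo <- remap(lo); hi <- remap(hi)
  }
  hi <- min(hi, nchar(edited))
  list(applied = TRUE, reason = NA_character_, cdna = edited,
       cds_lo = lo, cds_hi = hi, edit_cdna_pos = idx)
}

# Compact protein-change descriptor from the reference and variant products.
protein_change_string <- function(refp, altp, frameshift = FALSE) {
  if (identical(refp, altp)) return("p.=")
  if (!nzchar(altp) && nzchar(refp)) return("p.0")
  rp <- strsplit(refp, "")[[1]]; ap <- strsplit(altp, "")[[1]]
  n <- min(length(rp), length(ap))
  i <- 1L
  while (i <= n && rp[i] == ap[i]) i <- i + 1L
  raa <- if (i <= length(rp)) rp[i] else "*"
  aaa <- if (i <= length(ap)) ap[i] else "*"
  if (frameshift) return(sprintf("p.%s%dfs", raa, i))
  if (length(ap) < length(rp) && i > length(ap))
    return(sprintf("p.%s%d*", raa, i))
  if (length(rp) == length(ap)) return(sprintf("p.%s%d%s", raa, i, aaa))
  if (length(ap) > length(rp)) return(sprintf("p.%s%dins", raa, i))
  sprintf("p.%s%ddel", raa, i)
}

#' Translate a variant on one transcript
#'
#' Applies the variant to the spliced cDNA and translates from the annotated
#' start codon. Translation runs to the first in-frame stop codon wherever it
#' falls — for frameshift and stop-loss products it continues past the
#' annotated CDS end into the 3' UTR, flagged `no_terminal_stop` when the
#' transcript ends without one. A disrupted start codon yields an empty
#' sequence flagged `no_product` (no downstream start rescanning). The
#' matching reference product is computed alongside for comparison.
#'
#' @param t a `transcript_model`.
#' @param g a `reference_genome`.
#' @param v one-row normalized variant.
#' @param level evidence level recorded in the output header fields.
#' @return a `protein_record`: list with gene_symbol, transcript_id,
#'   variant_key, protein_change, level, flags, sequence, ref_sequence,
#'   applied, reason.
#' @export
translate_variant <- function(t, g, v, level = NA_integer_) {
  key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  rec <- list(gene_symbol = t$gene_symbol, transcript_id = t$transcript_id,
              variant_key = key, protein_change = NA_character_,
              level = level, flags = character(0), sequence = "",
              ref_sequence = NA_character_, applied = FALSE,
              reason = NA_character_)
  class(rec) <- "protein_record"
  ap <- apply_variant_to_cdna(t, g, v)
  if (!ap$applied) {
    rec$reason <- ap$reason
    rec$flags <- "no_product"
    return(rec)
  }
  rec$applied <- TRUE
  # reference product
  b <- cds_cdna_bounds(t)
  cdna_ref <- spliced_cdna(t, g)
  ref_tr <- translate_cds(substr(cdna_ref, b["lo"], nchar(cdna_ref)))
  rec$ref_sequence <- ref_tr$protein
  # variant product: start codon must survive the edit
  start_codon <- substr(ap$cdna, ap$cds_lo, ap$cds_lo + 2L)
  if (!identical(start_codon, "ATG")) {
    rec$flags <- c("no_product", "start_lost")
    rec$protein_change <- "p.0"
    return(rec)
  }
  alt_tr <- translate_cds(substr(ap$cdna, ap$cds_lo, nchar(ap$cdna)))
  rec$sequence <- alt_tr$protein
  rec$flags <- alt_tr$flags
  net <- nchar(v$alt) - nchar(v$ref)
  rec$protein_change <- protein_change_string(ref_tr$protein, alt_tr$protein,
                                              frameshift = net %% 3L != 0L)
  rec
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s|%s|%s|%s|L%s|%s\n  %s\n",
              x$gene_symbol, x$transcript_id,
              gsub(":", ":", x$variant_key), x$protein_change,
              x$level %||% ".", paste(x$flags, collapse = ","),
              if (nzchar(x$sequence)) x$sequence else "(no product)"))
  invisible(x)
}

#' Expand a variant over all isoforms of its gene
#'
#' Produces one protein record per coding transcript on which the variant is
#' exonic; per-transcript skip reasons (non-coding transcript, non-exonic
#' variant, outside span) are preserved, never silently dropped. With
#' `canonical_only = TRUE` only transcripts flagged canonical are considered.
#'
#' @param v one-row normalized variant.
#' @param transcripts list of `transcript_model` for the gene of `v`.
#' @param g a `reference_genome`.
#' @param level evidence level stamped on the records.
#' @param canonical_only restrict to canonical isoforms.
#' @return list with `records` (list of `protein_record` with a product) and
#'   `skipped` (data.frame transcript_id, reason).
#' @export
expand_all_isoforms <- function(v, transcripts, g, level = NA_integer_,
                                canonical_only = FALSE) {
  if (canonical_only)
    transcripts <- Filter(function(t) isTRUE(t$canonical), transcripts)
  records <- list(); skipped <- list()
  for (t in transcripts) {
    rec <- translate_variant(t, g, v, level = level)
    if (rec$applied && !"no_product" %in% rec$flags) {
      records[[length(records) + 1]] <- rec
    } else if (rec$applied) {
      # start-lost product: applied but empty; keep as record (flagged)
      records[[length(records) + 1]] <- rec
    } else {
      skipped[[length(skipped) + 1]] <-
        data.frame(transcript_id = t$transcript_id, reason = rec$reason,
                   stringsAsFactors = FALSE)
    }
  }
  list(records = records,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(transcript_id = character(0), reason = character(0)))
}

#' Write protein records as FASTA
#'
#' Header grammar:
#' `>{gene}|{transcript}|{chrom}:{pos}:{ref}:{alt}|{protein_change}|L{level}|{flags}`.
#' Sequences are wrapped at 60 columns; records are written in a
#' deterministic order (gene, transcript, variant key). Records without a
#' product (`no_product` flag) are omitted from the file. Duplicate identical
#' headers are suffixed with an ordinal, with a warning.
#'
#' @param records list of `protein_record`.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  records <- Filter(function(r) nzchar(r$sequence), records)
  if (length(records) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ord <- order(vapply(records, `[[`, character(1), "gene_symbol"),
               vapply(records, `[[`, character(1), "transcript_id"),
               vapply(records, `[[`, character(1), "variant_key"))
  records <- records[ord]
  headers <- vapply(records, function(r)
    sprintf(">%s|%s|%s|%s|L%s|%s", r$gene_symbol, r$transcript_id,
            r$variant_key, r$protein_change,
            if (is.na(r$level)) "." else r$level,
            paste(r$flags, collapse = ",")), character(1))
  if (anyDuplicated(headers)) {
    warning("duplicate FASTA headers suffixed with an ordinal")
    dup <- stats::ave(seq_along(headers), headers, FUN = seq_along)
    headers[dup > 1] <- paste0(headers[dup > 1], "#", dup[dup > 1])
  }
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(headers[i], con)
    s <- records[[i]]$sequence
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' Read a protein FASTA written by [write_protein_fasta()]
#'
#' @param path FASTA path.
#' @return named character vector of sequences (names = headers without
#'   `>`); empty files yield an empty vector.
#' @export
read_protein_fasta <- function(path) {
  if (file.size(path) == 0) return(stats::setNames(character(0),
                                                   character(0)))
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}
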