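# Reference genome and transcript models: strand-aware coordinate projection
# and CDS translation primitives that every later stage builds on.

#' Construct a reference genome
#'
#' A reference genome is a named set of chromosome sequences held in memory as
#' uppercase DNA strings. Soft-masked (lowercase) input is uppercased.
#'
#' @param sequences named character vector or list, chromosome name -> DNA
#'   string over A/C/G/T/N.
#' @return an object of class `reference_genome`.
#' @export
reference_genome <- function(sequences) {
  sequences <- vapply(sequences, function(s) toupper(as.character(s)),
                      character(1))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all chromosome sequences must be named")
  structure(list(sequences = sequences), class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome> ", length(x$sequences), " sequence(s): ",
      paste(sprintf("%s (%d bp)", names(x$sequences), nchar(x$sequences)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Chromosome length lookup
#' @param g a `reference_genome`.
#' @param chrom chromosome name.
#' @return integer length.
#' @export
chrom_length <- function(g, chrom) {
  if (!chrom %in% names(g$sequences))
    stop("unknown chromosome: ", chrom)
  nchar(g$sequences[[chrom]])
}

#' Extract a genomic subsequence
#'
#' 1-based inclusive coordinates. Requesting an unknown chromosome or an
#' out-of-bounds window is an error, never an empty string.
#'
#' @param g a `reference_genome`.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return DNA string of length `end - start + 1`.
#' @export
genome_slice <- function(g, chrom, start, end) {
  len <- chrom_length(g, chrom)
  if (start < 1 || end > len || start > end)
    stop(sprintf("slice %s:%d-%d outside chromosome bounds (1-%d)",
                 chrom, start, end, len))
  substr(g$sequences[[chrom]], start, end)
}

#' Construct a transcript model
#'
#' One isoform's exon/CDS geometry on a named chromosome. Exons are 1-based
#' inclusive genomic intervals, sorted ascending and non-overlapping. CDS
#' bounds are genomic; they are `NA` for non-coding transcripts. A spliced CDS
#' whose length is not a multiple of 3 is tolerated (flagged downstream), not
#' rejected.
#'
#' @param transcript_id,gene_id,gene_symbol identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of exon intervals.
#' @param cds_start,cds_end genomic CDS bounds or `NA`.
#' @param canonical logical flag marking the gene's canonical isoform.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_symbol, chrom,
                             strand, exons, cds_start = NA_integer_,
                             cds_end = NA_integer_, canonical = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1]))
    stop("exon with end < start in transcript ", transcript_id)
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  if (!is.na(cds_start) &&
      (cds_start < exons[1, 1] || cds_end > exons[nrow(exons), 2]))
    stop("CDS outside exon span in transcript ", transcript_id)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 gene_symbol = gene_symbol, chrom = chrom, strand = strand,
                 exons = exons,
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 canonical = isTRUE(canonical)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s, gene %s) %s:%s %d exon(s)%s\n",
              x$transcript_id, if (x$canonical) "canonical" else "alt",
              x$gene_symbol, x$chrom, x$strand, nrow(x$exons),
              if (is.na(x$cds_start)) ", non-coding"
              else sprintf(", CDS %d-%d", x$cds_start, x$cds_end)))
  invisible(x)
}

has_cds <- function(t) !is.na(t$cds_start)

# Genomic positions of the spliced transcript in transcription order
# (descending for minus strand). The workhorse behind every projection.
cdna_map <- function(t) {
  pos <- unlist(lapply(seq_len(nrow(t$exons)), function(i)
    seq.int(t$exons[i, 1], t$exons[i, 2])), use.names = FALSE)
  if (t$strand == "-") rev(pos) else pos
}

# cDNA indices (transcription order) of the CDS bounds; NULL if non-coding.
cds_cdna_bounds <- function(t) {
  if (!has_cds(t)) return(NULL)
  map <- cdna_map(t)
  g5 <- if (t$strand == "+") t$cds_start else t$cds_end
  g3 <- if (t$strand == "+") t$cds_end else t$cds_start
  lo <- match(g5, map); hi <- match(g3, map)
  if (is.na(lo) || is.na(hi))
    stop("CDS bound of ", t$transcript_id, " not covered by an exon")
  c(lo = lo, hi = hi)
}

#' Spliced cDNA of a transcript
#'
#' Exon sequences concatenated in transcription order; for minus-strand
#' transcripts the reverse complement of the ascending-coordinate
#' concatenation. Output is uppercase.
#'
#' @param t a `transcript_model`.
#' @param g a `reference_genome`.
#' @return DNA string whose length is the sum of exon lengths.
#' @export
spliced_cdna <- function(t, g) {
  pieces <- vapply(seq_len(nrow(t$exons)), function(i)
    genome_slice(g, t$chrom, t$exons[i, 1], t$exons[i, 2]), character(1))
  s <- paste(pieces, collapse = "")
  if (t$strand == "-") revcomp(s) else s
}

#' Project a genomic position onto a transcript
#'
#' Returns the transcript-space location of a genomic position: the region
#' category plus the spliced-cDNA and CDS coordinates when exonic, or the
#' signed intron offset when intronic. Intron offsets are counted in
#' transcription orientation: positive from the donor (5') exon end, negative
#' from the acceptor (3') exon start; ties go to the donor side. Positions
#' outside the locus map to `UPSTREAM`/`DOWNSTREAM` (never an error). Exonic
#' positions of a non-coding transcript get category `EXON`.
#'
#' @param t a `transcript_model`.
#' @param genomic_pos 1-based genomic position.
#' @return list with `category` (one of CDS, UTR5, UTR3, INTRON, UPSTREAM,
#'   DOWNSTREAM, EXON), `cdna_pos`, `cds_pos`, `intron_offset`.
#' @export
genomic_to_cdna <- function(t, genomic_pos) {
  stopifnot(genomic_pos >= 1)
  span <- c(t$exons[1, 1], t$exons[nrow(t$exons), 2])
  loc <- list(category = NA_character_, cdna_pos = NA_integer_,
              cds_pos = NA_integer_, intron_offset = NA_integer_)
  if (genomic_pos < span[1]) {
    loc$category <- if (t$strand == "+") "UPSTREAM" else "DOWNSTREAM"
    return(loc)
  }
  if (genomic_pos > span[2]) {
    loc$category <- if (t$strand == "+") "DOWNSTREAM" else "UPSTREAM"
    return(loc)
  }
  map <- cdna_map(t)
  idx <- match(genomic_pos, map)
  if (!is.na(idx)) {
    loc$cdna_pos <- idx
    b <- cds_cdna_bounds(t)
    if (is.null(b)) {
      loc$category <- "EXON"
    } else if (idx < b["lo"]) {
      loc$category <- "UTR5"
    } else if (idx > b["hi"]) {
      loc$category <- "UTR3"
    } else {
      loc$category <- "CDS"
      loc$cds_pos <- idx - unname(b["lo"]) + 1L
    }
    return(loc)
  }
  # intronic: distance to flanking exon boundaries in transcription sense
  ex <- t$exons
  k <- max(which(ex[, 2] < genomic_pos))   # exon immediately left (genomic)
  d_left <- genomic_pos - ex[k, 2]          # from left exon end
  d_right <- ex[k + 1, 1] - genomic_pos     # to right exon start
  if (t$strand == "+") {
    donor_d <- d_left; acceptor_d <- d_right
  } else {
    donor_d <- d_right; acceptor_d <- d_left
  }
  loc$category <- "INTRON"
  loc$intron_offset <- unname(if (donor_d <= acceptor_d) donor_d
                              else -acceptor_d)
  loc
}

#' Inverse projection: spliced-cDNA index to genomic position
#'
#' @param t a `transcript_model`.
#' @param cdna_pos 1-based position in the spliced transcript.
#' @return 1-based genomic position.
#' @export
cdna_to_genomic <- function(t, cdna_pos) {
  map <- cdna_map(t)
  if (cdna_pos < 1 || cdna_pos > length(map))
    stop("cdna_pos outside transcript of length ", length(map))
  map[cdna_pos]
}

#' Translate a coding sequence
#'
#' Standard genetic code (translation table 1). Translation stops at the first
#' stop codon (stop symbol not included); a codon containing N yields `X`; a
#' trailing incomplete codon is dropped with flag `incomplete_codon`; if no
#' stop codon is encountered the flag `no_terminal_stop` is raised. An empty
#' input returns an empty string with flag `empty_input`.
#'
#' @param cds_sequence DNA string over A/C/G/T/N.
#' @return list with `protein` (amino-acid string) and `flags` (character
#'   vector).
#' @export
translate_cds <- function(cds_sequence) {
  s <- toupper(cds_sequence)
  if (!nzchar(s)) return(list(protein = "", flags = "empty_input"))
  n <- nchar(s)
  ncod <- n %/% 3L
  code <- Biostrings::GENETIC_CODE
  aa <- character(0)
  terminated <- FALSE
  for (i in seq_len(ncod)) {
    codon <- substr(s, 3L * i - 2L, 3L * i)
    a <- if (grepl("N", codon, fixed = TRUE)) "X" else unname(code[codon])
    if (is.na(a)) a <- "X"
    if (a == "*") { terminated <- TRUE; break }
    aa <- c(aa, a)
  }
  flags <- character(0)
  if (!terminated) {
    flags <- c(flags, "no_terminal_stop")
    if (n %% 3L != 0L) flags <- c(flags, "incomplete_codon")
  }
  list(protein = paste(aa, collapse = ""), flags = flags)
}

#' Load a reference genome and gene models
#'
#' Reads a genome FASTA and a GFF3 of gene models (features `gene`, `mRNA`,
#' `exon`, `CDS` linked by `ID`/`Parent`) into a `reference_genome` and one
#' `transcript_model` per mRNA. Transcripts without CDS features carry no CDS
#' bounds and are retained. Both files may be gzip-compressed.
#'
#' @param gff3_path path to the GFF3 file.
#' @param fasta_path path to the genome FASTA.
#' @return list with `genome` and `transcripts` (list of `transcript_model`).
#' @export
load_gene_models <- function(gff3_path, fasta_path) {
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- toupper(as.character(dna))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome <- reference_genome(seqs)

  gr <- rtracklayer::import(gff3_path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  ty <- tolower(as.character(df$type))
  first_parent <- function(p) if (length(p) == 0) NA_character_ else p[[1]]
  df$parent1 <- vapply(df$Parent, first_parent, character(1))

  genes <- df[ty == "gene", , drop = FALSE]
  mrnas <- df[ty %in% c("mrna", "transcript"), , drop = FALSE]
  if (nrow(mrnas) == 0) stop("no mRNA/transcript features in ", gff3_path)
  gene_symbol <- function(gid) {
    row <- genes[genes$ID == gid, , drop = FALSE]
    if (nrow(row) == 0) return(gid)
    nm <- row$Name[1] %||% NA_character_
    if (is.na(nm) || !nzchar(nm)) gid else nm
  }
  exons <- df[ty == "exon", , drop = FALSE]
  cdss <- df[ty == "cds", , drop = FALSE]
  bad_parent <- setdiff(stats::na.omit(c(exons$parent1, cdss$parent1)),
                        mrnas$ID)
  if (length(bad_parent) > 0)
    stop("GFF3 parse error: exon/CDS Parent(s) reference unknown mRNA id(s): ",
         paste(bad_parent, collapse = ", "))

  transcripts <- lapply(seq_len(nrow(mrnas)), function(i) {
    m <- mrnas[i, , drop = FALSE]
    ex <- exons[!is.na(exons$parent1) & exons$parent1 == m$ID, , drop = FALSE]
    if (nrow(ex) == 0)
      stop("mRNA ", m$ID, " has no exon features")
    cd <- cdss[!is.na(cdss$parent1) & cdss$parent1 == m$ID, , drop = FALSE]
    clen <- chrom_length(genome, m$seqnames)
    if (any(ex$start < 1) || any(ex$end > clen))
      stop("exon of ", m$ID, " outside chromosome ", m$seqnames,
           " bounds (1-", clen, ")")
    canon <- FALSE
    if ("canonical" %in% names(m)) {
      v <- m$canonical[[1]]
      canon <- !is.na(v) && as.character(v) %in% c("1", "true", "TRUE", "yes")
    }
    transcript_model(
      transcript_id = m$ID,
      gene_id = m$parent1 %||% NA_character_,
      gene_symbol = gene_symbol(m$parent1 %||% ""),
      chrom = m$seqnames, strand = m$strand,
      exons = cbind(ex$start, ex$end),
      cds_start = if (nrow(cd) > 0) min(cd$start) else NA_integer_,
      cds_end = if (nrow(cd) > 0) max(cd$end) else NA_integer_,
      canonical = canon)
  })
  names(transcripts) <- vapply(transcripts, `[[`, character(1),
                               "transcript_id")
  list(genome = genome, transcripts = transcripts)
}

#' Transcripts of a gene
#'
#' @param transcripts list of `transcript_model`.
#' @param gene gene symbol or gene id.
#' @return the matching subset (possibly empty).
#' @export
transcripts_of_gene <- function(transcripts, gene) {
  Filter(function(t) identical(t$gene_symbol, gene) ||
           identical(t$gene_id, gene), transcripts)
}
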