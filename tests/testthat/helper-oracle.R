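# Independent oracles used to check the package implementation by a second
# route: a hard-coded codon table indexed arithmetically, whole-chromosome
# string surgery for variant application, and a whole-chromosome diff for
# indel normalization. Nothing here calls the package's own translation,
# splicing or normalization code paths.

# Codon table in TCAG order: aa[16*i1 + 4*i2 + i3 + 1] with T=0,C=1,A=2,G=3.
ORACLE_AA <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "")[[1]]

oracle_codon_aa <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  idx <- match(strsplit(codon, "")[[1]], c("T", "C", "A", "G")) - 1L
  ORACLE_AA[16L * idx[1] + 4L * idx[2] + idx[3] + 1L]
}

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  aa <- character(0)
  stopped <- FALSE
  for (i in seq_len(n)) {
    a <- oracle_codon_aa(substr(seq, 3 * i - 2, 3 * i))
    if (a == "*") { stopped <- TRUE; break }
    aa <- c(aa, a)
  }
  flags <- character(0)
  if (!stopped) {
    flags <- "no_terminal_stop"
    if (nchar(seq) %% 3 != 0) flags <- c(flags, "incomplete_codon")
  }
  list(protein = paste(aa, collapse = ""), flags = flags)
}

oracle_revcomp <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

# Spliced transcript straight from slices of the chromosome string.
oracle_splice <- function(chrom_seq, exons, strand) {
  s <- paste(vapply(seq_len(nrow(exons)), function(i)
    substr(chrom_seq, exons[i, 1], exons[i, 2]), character(1)),
    collapse = "")
  if (strand == "-") oracle_revcomp(s) else s
}

# Edit the chromosome, shift the gene geometry and re-translate from the
# annotated start codon to the transcript end. Returns NULL when the edit is
# not entirely exonic.
oracle_edit_translate <- function(chrom_seq, exons, cds_start, cds_end,
                                  strand, pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  exonic <- function(p) any(p >= exons[, 1] & p <= exons[, 2])
  if (!all(vapply(seq.int(pos, pos + nr - 1), exonic, logical(1))))
    return(NULL)
  if (na > nr && !exonic(pos + 1) && pos != max(exons[, 2])) return(NULL)
  stopifnot(substr(chrom_seq, pos, pos + nr - 1) == ref)
  edited <- paste0(substr(chrom_seq, 1, pos - 1), alt,
                   substr(chrom_seq, pos + nr, nchar(chrom_seq)))
  net <- na - nr
  del_end <- pos + nr - 1
  shift <- function(x) ifelse(x > del_end, x + net, pmin(x, pos + na - 1))
  ex2 <- cbind(shift(exons[, 1]), shift(exons[, 2]))
  cs <- shift(cds_start); ce <- shift(cds_end)
  cdna <- oracle_splice(edited, ex2, strand)
  # cDNA index of the CDS 5' end
  map <- unlist(lapply(seq_len(nrow(ex2)), function(i)
    seq.int(ex2[i, 1], ex2[i, 2])))
  if (strand == "-") map <- rev(map)
  lo <- match(if (strand == "+") cs else ce, map)
  if (substr(cdna, lo, lo + 2) != "ATG")
    return(list(protein = "", flags = c("no_product", "start_lost")))
  oracle_translate(substr(cdna, lo, nchar(cdna)))
}

# Leftmost parsimonious anchored representation, from the whole-chromosome
# diff of the reference and edited sequences (maximal common suffix, then
# maximal common prefix, then anchor).
oracle_normalize <- function(chrom_seq, pos, ref, alt) {
  ref <- if (ref %in% c("-", ".", "")) "" else toupper(ref)
  alt <- if (alt %in% c("-", ".", "")) "" else toupper(alt)
  s1 <- chrom_seq
  s2 <- paste0(substr(s1, 1, pos - 1), alt,
               substr(s1, pos + nchar(ref), nchar(s1)))
  n1 <- nchar(s1); n2 <- nchar(s2)
  k <- 0
  while (k < min(n1, n2) &&
         substr(s1, n1 - k, n1 - k) == substr(s2, n2 - k, n2 - k))
    k <- k + 1
  i <- 1
  while (i <= min(n1, n2) - k && substr(s1, i, i) == substr(s2, i, i))
    i <- i + 1
  r <- substr(s1, i, n1 - k); a <- substr(s2, i, n2 - k)
  if (nchar(r) == 0 || nchar(a) == 0) {
    i <- i - 1
    r <- paste0(substr(s1, i, i), r)
    a <- paste0(substr(s1, i, i), a)
  }
  list(pos = i, ref = r, alt = a)
}

# Rule-based consequence oracle over the same precedence contract, driven by
# geometry computed from scratch plus the edit-and-translate comparison.
oracle_classify <- function(chrom_seq, exons, cds_start, cds_end, strand,
                            pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  aff <- if (nr == na) seq.int(pos, pos + nr - 1) else
    if (nr > na) seq.int(pos + 1, pos + nr - 1) else c(pos, pos + 1)
  span <- c(min(exons[, 1]), max(exons[, 2]))
  if (all(aff < span[1]) || all(aff > span[2])) return(NA_character_)
  donors <- c(); donor5 <- c(); acceptors <- c()
  if (nrow(exons) > 1) {
    for (kk in seq_len(nrow(exons) - 1)) {
      lo <- exons[kk, 2] + 1; hi <- exons[kk + 1, 1] - 1
      if (strand == "+") {
        donors <- c(donors, lo, lo + 1); donor5 <- c(donor5, lo + 4)
        acceptors <- c(acceptors, hi - 1, hi)
      } else {
        donors <- c(donors, hi, hi - 1); donor5 <- c(donor5, hi - 4)
        acceptors <- c(acceptors, lo, lo + 1)
      }
    }
  }
  if (any(aff %in% donors)) return("splice_donor_variant")
  if (any(aff %in% acceptors)) return("splice_acceptor_variant")
  if (any(aff %in% donor5)) return("splice_donor_5th_base_variant")
  exonic <- aff[vapply(aff, function(p)
    any(p >= exons[, 1] & p <= exons[, 2]), logical(1))]
  if (length(exonic) == 0) return("intron_variant")
  if (is.na(cds_start)) return("non_coding_transcript_variant")
  # cDNA coordinates from scratch
  map <- unlist(lapply(seq_len(nrow(exons)), function(i)
    seq.int(exons[i, 1], exons[i, 2])))
  if (strand == "-") map <- rev(map)
  b_lo <- match(if (strand == "+") cds_start else cds_end, map)
  b_hi <- match(if (strand == "+") cds_end else cds_start, map)
  idx <- sort(match(exonic, map))
  if (all(idx < b_lo)) return("5_prime_UTR_variant")
  if (all(idx > b_hi)) return("3_prime_UTR_variant")
  if (nr != na) {
    vp <- oracle_edit_translate(chrom_seq, exons, cds_start, cds_end,
                                strand, pos, ref, alt)
    if (!is.null(vp) && "start_lost" %in% vp$flags) return("start_lost")
    if ((na - nr) %% 3 != 0) return("frameshift_variant")
    return(if (na > nr) "inframe_insertion" else "inframe_deletion")
  }
  # substitution: edit-and-translate comparison against the reference product
  cdna0 <- oracle_splice(chrom_seq, exons, strand)
  rp <- oracle_translate(substr(cdna0, b_lo, nchar(cdna0)))
  vp <- oracle_edit_translate(chrom_seq, exons, cds_start, cds_end, strand,
                              pos, ref, alt)
  if ("start_lost" %in% vp$flags) return("start_lost")
  if (identical(rp$protein, vp$protein) &&
      identical("no_terminal_stop" %in% rp$flags,
                "no_terminal_stop" %in% vp$flags))
    return("synonymous_variant")
  if (nchar(vp$protein) < nchar(rp$protein) &&
      startsWith(rp$protein, vp$protein)) return("stop_gained")
  if ("no_terminal_stop" %in% vp$flags &&
      !("no_terminal_stop" %in% rp$flags)) return("stop_lost")
  "missense_variant"
}

# Random event generator used by the property suites: draws an SNV or short
# indel somewhere on (or near) a transcript and returns the raw spelling.
random_event <- function(t, g) {
  chrom_seq <- g$sequences[[t$chrom]]
  span <- c(t$exons[1, 1], t$exons[nrow(t$exons), 2])
  pos <- sample(max(2, span[1] - 3):min(nchar(chrom_seq) - 6, span[2] + 3), 1)
  kind <- sample(c("snv", "del", "ins"), 1, prob = c(0.6, 0.2, 0.2))
  if (kind == "snv") {
    refb <- substr(chrom_seq, pos, pos)
    list(pos = pos, ref = refb,
         alt = sample(setdiff(c("A", "C", "G", "T"), refb), 1))
  } else if (kind == "del") {
    len <- sample(1:5, 1)
    list(pos = pos, ref = substr(chrom_seq, pos, pos + len - 1), alt = "")
  } else {
    len <- sample(1:4, 1)
    list(pos = pos, ref = "",
         alt = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""))
  }
}

# Shared small fixture geometry for the property suites.
property_fixture <- function(seed = 42, n_genes = 4) {
  generate_fixture(seed = seed, n_genes = n_genes, isoforms_per_gene = 2,
                   n_variants = 0, out_dir = tempfile("propfx"))
}
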