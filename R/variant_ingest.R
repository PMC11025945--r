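# Ingestion of the three source dialects into one normalized variant table.
#
# The unified representation is a data.frame (class "variant_table") with one
# row per (chrom, pos, ref, alt) event and ";"-joined multi-valued fields.
# Indels are held in VCF anchor-base form, left-aligned and parsimonious, so
# that identical events spelled differently by different dialects collapse to
# the same key.

SIGNIFICANCE_LEVELS <- c("pathogenic", "likely_pathogenic", "conflicting",
                         "uncertain_significance", "likely_benign", "benign",
                         "other")

variant_columns <- c("chrom", "pos", "ref", "alt", "key", "rsid", "other_ids",
                     "gene_symbols", "consequence_terms", "significance",
                     "phenotypes", "sources", "pmids", "flags")

#' An empty normalized variant table
#' @return zero-row data.frame with the standard variant columns.
#' @export
empty_variants <- function() {
  df <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), key = character(0), rsid = character(0),
                   other_ids = character(0), gene_symbols = character(0),
                   consequence_terms = character(0),
                   significance = character(0), phenotypes = character(0),
                   sources = character(0), pmids = character(0),
                   flags = character(0), stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

as_variant_table <- function(df) {
  for (col in variant_columns)
    if (!col %in% names(df))
      df[[col]] <- if (col == "pos") integer(nrow(df)) else
        rep(NA_character_, nrow(df))
  df <- df[, variant_columns, drop = FALSE]
  df$pos <- as.integer(df$pos)
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Variant key string
#' @param chrom,pos,ref,alt normalized fields.
#' @return `"chrom:pos:ref:alt"` key.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Harmonize a clinical-significance label
#'
#' Case-insensitive mapping of archive significance strings onto the
#' vocabulary pathogenic, likely_pathogenic, uncertain_significance,
#' likely_benign, benign, conflicting, other. Combined values such as
#' "Pathogenic/Likely pathogenic" map to the more severe term; unrecognized
#' strings map to "other"; empty/NA stays NA.
#'
#' @param x character vector of raw labels.
#' @return character vector over the harmonized vocabulary (or NA).
#' @export
harmonize_significance <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    s <- tolower(trimws(s))
    parts <- trimws(strsplit(s, "[/;,]")[[1]])
    map_one <- function(p) {
      p <- gsub("[ _-]+", " ", p)
      if (grepl("^conflicting", p)) return("conflicting")
      switch(p,
             "pathogenic" = "pathogenic",
             "likely pathogenic" = "likely_pathogenic",
             "uncertain significance" = "uncertain_significance",
             "variant of uncertain significance" = "uncertain_significance",
             "vus" = "uncertain_significance",
             "likely benign" = "likely_benign",
             "benign" = "benign",
             "other")
    }
    terms <- vapply(parts, map_one, character(1))
    SIGNIFICANCE_LEVELS[min(match(terms, SIGNIFICANCE_LEVELS))]
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize a variant to its canonical VCF-style key
#'
#' Converts dialect spellings ("-" or empty alleles for indels) to anchor-base
#' form using the base immediately 5' of the event, then left-aligns and makes
#' the representation parsimonious (classic shift-and-trim normalization).
#' The reference allele is checked against the genome; a mismatch is an error
#' naming chrom/pos, signalling a wrong genome build or a corrupt row.
#'
#' @param chrom chromosome name.
#' @param pos 1-based position. For a "-"-ref insertion this is the position
#'   of the base immediately 3' of the insertion point (the event occurs
#'   between `pos - 1` and `pos`); for a "-"-alt deletion it is the first
#'   deleted base.
#' @param ref,alt allele strings; "-", "." and "" denote the empty allele.
#' @param g a `reference_genome`.
#' @return list `(chrom, pos, ref, alt, key)` in normalized form.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, g) {
  clean <- function(a) {
    a <- toupper(trimws(a))
    if (a %in% c("-", ".", "")) "" else a
  }
  ref <- clean(ref); alt <- clean(alt)
  pos <- as.integer(pos)
  if (identical(ref, alt))
    stop("ref and alt alleles are identical at ", chrom, ":", pos)
  seq_len_chrom <- chrom_length(g, chrom)
  # check ref against genome before any transformation
  if (nzchar(ref)) {
    obs <- genome_slice(g, chrom, pos, pos + nchar(ref) - 1L)
    if (obs != ref)
      stop(sprintf("reference mismatch at %s:%d: table says '%s', genome has '%s'",
                   chrom, pos, ref, obs))
  }
  # anchor-base conversion for empty-allele spellings
  if (!nzchar(ref) || !nzchar(alt)) {
    if (pos <= 1 && !nzchar(ref)) {
      # insertion before position 1: right-anchor (VCF convention at pos 1)
      b <- genome_slice(g, chrom, 1L, 1L)
      ref <- paste0(ref, b); alt <- paste0(alt, b); pos <- 1L
    } else {
      anchor_pos <- pos - 1L
      if (anchor_pos < 1) {
        b <- genome_slice(g, chrom, pos + nchar(ref), pos + nchar(ref))
        ref <- paste0(ref, b); alt <- paste0(alt, b)
      } else {
        b <- genome_slice(g, chrom, anchor_pos, anchor_pos)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        pos <- anchor_pos
      }
    }
  }
  last <- function(a) substr(a, nchar(a), nchar(a))
  drop_last <- function(a) substr(a, 1L, nchar(a) - 1L)
  # left-align + parsimony (vt-style): trim the shared last base; when that
  # would empty an allele, shift left by prepending the genome base instead.
  # At position 1 no further left shift is possible and the loop stops.
  repeat {
    if (!(nzchar(ref) && nzchar(alt) && last(ref) == last(alt))) break
    if (nchar(ref) > 1L && nchar(alt) > 1L) {
      ref <- drop_last(ref); alt <- drop_last(alt)
    } else if (pos > 1L) {
      b <- genome_slice(g, chrom, pos - 1L, pos - 1L)
      ref <- paste0(b, drop_last(ref))
      alt <- paste0(b, drop_last(alt))
      pos <- pos - 1L
    } else break
  }
  # trim shared prefix beyond one remaining base
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (pos + nchar(ref) - 1L > seq_len_chrom)
    stop("normalized variant extends beyond chromosome ", chrom)
  list(chrom = chrom, pos = pos, ref = ref, alt = alt,
       key = variant_key(chrom, pos, ref, alt))
}

# One normalized variant row; returns NULL (with attr "reason") on rejection.
make_variant_row <- function(chrom, pos, ref, alt, g, source,
                             rsid = NA_character_, other_ids = "",
                             gene_symbols = "", consequence_terms = "",
                             significance = NA_character_, phenotypes = "",
                             pmids = "", indel_cap = 30L) {
  n <- normalize_variant(chrom, pos, ref, alt, g)
  if (nchar(n$ref) + nchar(n$alt) > 2L + indel_cap)
    stop("over_indel_cap")
  data.frame(chrom = n$chrom, pos = n$pos, ref = n$ref, alt = n$alt,
             key = n$key,
             rsid = if (is.na(rsid) || !nzchar(rsid) || rsid == ".")
               NA_character_ else rsid,
             other_ids = other_ids, gene_symbols = gene_symbols,
             consequence_terms = consequence_terms,
             significance = significance, phenotypes = phenotypes,
             sources = source, pmids = pmids, flags = "",
             stringsAsFactors = FALSE)
}

finish_ingest <- function(rows, rejected, unmapped = NULL, n_input = NA) {
  variants <- if (length(rows) > 0) do.call(rbind, rows) else empty_variants()
  res <- list(variants = as_variant_table(variants),
              rejected = rejected,
              unmapped = unmapped %||% data.frame(),
              n_input = n_input)
  class(res) <- "ingest_result"
  res
}

#' @export
print.ingest_result <- function(x, ...) {
  cat(sprintf("<ingest_result> %d input row(s) -> %d variant(s), %d rejected, %d unmapped\n",
              x$n_input, nrow(x$variants), nrow(x$rejected), nrow(x$unmapped)))
  invisible(x)
}

empty_reject_df <- function() {
  data.frame(row = integer(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Read an Ensembl-style exon-overlap variant export
#'
#' Expected columns (names configurable): rsID, chromosome, position, a
#' slash-separated allele string (`"C/A/T"`, `"G/-"`, `"-/AT"`), consequence
#' terms, clinical significance, gene symbol. Multi-allelic rows yield one
#' variant per alternative allele. Rows whose alleles cannot be parsed or
#' normalized are rejected with a reason and processing continues.
#'
#' @param path delimited text file (tab or comma, optionally gzipped).
#' @param g a `reference_genome` for normalization.
#' @param columns named list mapping the roles rsid, chrom, pos, alleles,
#'   consequences, significance, gene to column names.
#' @param indel_cap maximum combined indel allele length beyond the two
#'   anchor-level bases (default 30); over-cap events are routed to the
#'   rejected list.
#' @return an `ingest_result` with `$variants` (sources = ENSEMBL),
#'   `$rejected` and the input row count.
#' @export
read_ensembl_table <- function(path, g,
                               columns = list(rsid = "rsid", chrom = "chrom",
                                              pos = "pos", alleles = "alleles",
                                              consequences = "consequences",
                                              significance = "significance",
                                              gene = "gene"),
                               indel_cap = 30L) {
  tab <- read_delim_auto(path)
  if (nrow(tab) == 0) return(finish_ingest(list(), empty_reject_df(),
                                           n_input = 0L))
  rows <- list(); rejected <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, , drop = FALSE]
    alleles <- strsplit(as.character(r[[columns$alleles]]), "/",
                        fixed = TRUE)[[1]]
    alleles <- trimws(alleles)
    if (length(alleles) < 2 ||
        !all(grepl("^([ACGTNacgtn]+|-)$", alleles))) {
      rejected[[length(rejected) + 1]] <-
        data.frame(row = i, reason = "unparseable_alleles")
      next
    }
    ref <- alleles[1]
    terms <- join_multi(strsplit(as.character(
      r[[columns$consequences]] %||% ""), "[;,]")[[1]])
    for (alt in alleles[-1]) {
      row <- tryCatch(
        make_variant_row(
          chrom = as.character(r[[columns$chrom]]),
          pos = as.integer(r[[columns$pos]]),
          ref = ref, alt = alt, g = g, source = "ENSEMBL",
          rsid = as.character(r[[columns$rsid]] %||% NA),
          gene_symbols = join_multi(as.character(r[[columns$gene]] %||% "")),
          consequence_terms = terms,
          significance = harmonize_significance(
            as.character(r[[columns$significance]] %||% NA)),
          indel_cap = indel_cap),
        error = function(e) e)
      if (inherits(row, "error")) {
        rejected[[length(rejected) + 1]] <-
          data.frame(row = i, reason = conditionMessage(row))
      } else rows[[length(rows) + 1]] <- row
    }
  }
  finish_ingest(rows,
                if (length(rejected)) do.call(rbind, rejected)
                else empty_reject_df(),
                n_input = nrow(tab))
}

#' Build an rsID -> normalized coordinates index
#'
#' Used for the rsID-first join cascade: archive rows that carry an rsID but
#' no coordinates are resolved against this index.
#'
#' @param variants a normalized variant table (e.g. the Ensembl reference
#'   table).
#' @return data.frame with columns rsid, chrom, pos, ref, alt (unique rsids;
#'   a multi-allelic rsid keeps its first key for coordinate recovery).
#' @export
rsid_index <- function(variants) {
  v <- variants[!is.na(variants$rsid), , drop = FALSE]
  v <- v[!duplicated(v$rsid), c("rsid", "chrom", "pos", "ref", "alt")]
  rownames(v) <- NULL
  v
}

#' Read a ClinVar-style phenotype export
#'
#' Expected columns: variant accession, optional rsID, chromosome, position,
#' ref and alt alleles, clinical significance, optionally consequence terms.
#' Rows with coordinates are normalized directly; rows with only an rsID are
#' resolved through `rsid_map` (rsID join has priority in the cascade); rows
#' with neither complete coordinates nor a resolvable rsID are routed to the
#' `needs_manual` side list, never raised as an error. Rows without
#' consequence annotation keep empty `consequence_terms` (the short-indel
#' pass-through that goes straight to consolidation).
#'
#' @param path delimited text file.
#' @param phenotype_label phenotype the export was queried for; attached to
#'   every variant.
#' @param g a `reference_genome`.
#' @param rsid_map optional data.frame from [rsid_index()].
#' @param columns named list of column roles.
#' @param indel_cap see [read_ensembl_table()].
#' @return an `ingest_result`; `$unmapped` holds the needs-manual rows.
#' @export
read_clinvar_table <- function(path, phenotype_label, g, rsid_map = NULL,
                               columns = list(accession = "accession",
                                              rsid = "rsid", chrom = "chrom",
                                              pos = "pos", ref = "ref",
                                              alt = "alt",
                                              significance = "significance",
                                              consequences = "consequences",
                                              gene = "gene"),
                               indel_cap = 30L) {
  tab <- read_delim_auto(path)
  if (nrow(tab) == 0) return(finish_ingest(list(), empty_reject_df(),
                                           n_input = 0L))
  rows <- list(); rejected <- list(); manual <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, , drop = FALSE]
    chrom <- as.character(r[[columns$chrom]] %||% NA)
    pos <- suppressWarnings(as.integer(r[[columns$pos]] %||% NA))
    ref <- as.character(r[[columns$ref]] %||% NA)
    alt <- as.character(r[[columns$alt]] %||% NA)
    rsid <- as.character(r[[columns$rsid]] %||% NA)
    if (!is.na(rsid) && (!nzchar(rsid) || rsid == ".")) rsid <- NA_character_
    have_coords <- !is.na(chrom) && nzchar(chrom) && !is.na(pos) &&
      !is.na(ref) && nzchar(ref) && !is.na(alt) && nzchar(alt)
    if (!have_coords && !is.na(rsid) && !is.null(rsid_map)) {
      hit <- rsid_map[rsid_map$rsid == rsid, , drop = FALSE]
      if (nrow(hit) >= 1) {
        chrom <- hit$chrom[1]; pos <- hit$pos[1]
        ref <- hit$ref[1]; alt <- hit$alt[1]
        have_coords <- TRUE
      }
    }
    if (!have_coords) {
      manual[[length(manual) + 1]] <-
        data.frame(row = i,
                   accession = as.character(r[[columns$accession]] %||% NA),
                   rsid = rsid, reason = "no_rsid_or_coordinates",
                   stringsAsFactors = FALSE)
      next
    }
    terms <- ""
    if (!is.null(columns$consequences) &&
        columns$consequences %in% names(r))
      terms <- join_multi(strsplit(as.character(
        r[[columns$consequences]] %||% ""), "[;,]")[[1]])
    row <- tryCatch(
      make_variant_row(
        chrom = chrom, pos = pos, ref = ref, alt = alt, g = g,
        source = "CLINVAR", rsid = rsid,
        other_ids = join_multi(as.character(r[[columns$accession]] %||% "")),
        gene_symbols = join_multi(as.character(r[[columns$gene]] %||% "")),
        consequence_terms = terms,
        significance = harmonize_significance(
          as.character(r[[columns$significance]] %||% NA)),
        phenotypes = phenotype_label, indel_cap = indel_cap),
      error = function(e) e)
    if (inherits(row, "error")) {
      rejected[[length(rejected) + 1]] <-
        data.frame(row = i, reason = conditionMessage(row))
    } else rows[[length(rows) + 1]] <- row
  }
  finish_ingest(rows,
                if (length(rejected)) do.call(rbind, rejected)
                else empty_reject_df(),
                unmapped = if (length(manual)) do.call(rbind, manual)
                else data.frame(),
                n_input = nrow(tab))
}

#' Read a literature variant table with an offline mapping table
#'
#' Literature rows carry a gene symbol plus at least one identifier: an rsID,
#' direct genomic coordinates + alleles, or a protein-level HGVS-like string.
#' Identifiers are resolved through the mapping table (columns: key, chrom,
#' pos, ref, alt, manual), the offline stand-in for coordinate annotation and
#' manual variant formatting. HGVS strings are looked up as
#' `"GENE:p.xxx"`. Rows resolved only via rows flagged `manual` get source
#' MANUAL instead of LITERATURE. Unresolvable rows are returned as unmapped,
#' never silently dropped. Conflicting duplicate keys in the mapping table
#' (same key, different coordinates) are an error listing the keys.
#'
#' @param path literature table (columns gene, identifier, pmid).
#' @param mapping_table_path the join table.
#' @param g a `reference_genome`.
#' @param indel_cap see [read_ensembl_table()].
#' @return an `ingest_result`; `$unmapped` holds unmapped literature rows.
#' @export
read_literature_table <- function(path, mapping_table_path, g,
                                  indel_cap = 30L) {
  tab <- read_delim_auto(path)
  map <- read_delim_auto(mapping_table_path)
  if (nrow(map) > 0) {
    dup <- unique(map$key[duplicated(map$key)])
    for (k in dup) {
      sub <- map[map$key == k, c("chrom", "pos", "ref", "alt")]
      if (nrow(unique(sub)) > 1)
        stop("conflicting duplicate key(s) in mapping table: ",
             paste(dup, collapse = ", "))
    }
    map <- map[!duplicated(map$key), , drop = FALSE]
  }
  if (nrow(tab) == 0) return(finish_ingest(list(), empty_reject_df(),
                                           n_input = 0L))
  rows <- list(); unmapped <- list(); rejected <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, , drop = FALSE]
    gene <- as.character(r$gene %||% NA)
    ident <- trimws(as.character(r$identifier %||% ""))
    pmid <- as.character(r$pmid %||% "")
    hit <- NULL; manual_hit <- FALSE; rsid <- NA_character_
    if (grepl("^rs[0-9]+$", ident)) {
      rsid <- ident
      hit <- map[map$key == ident, , drop = FALSE]
    } else if (grepl("^p\\.", ident)) {
      hit <- map[map$key == paste0(gene, ":", ident), , drop = FALSE]
    } else if (grepl("^[^:]+:[0-9]+:[ACGTN-]+:[ACGTN-]+$", ident)) {
      parts <- strsplit(ident, ":", fixed = TRUE)[[1]]
      hit <- data.frame(chrom = parts[1], pos = as.integer(parts[2]),
                        ref = parts[3], alt = parts[4], manual = "0",
                        stringsAsFactors = FALSE)
    }
    if (is.null(hit) || nrow(hit) == 0) {
      unmapped[[length(unmapped) + 1]] <-
        data.frame(row = i, gene = gene, identifier = ident,
                   reason = "no_mapping_entry", stringsAsFactors = FALSE)
      next
    }
    manual_hit <- as.character(hit$manual[1] %||% "0") %in%
      c("1", "TRUE", "true", "yes")
    row <- tryCatch(
      make_variant_row(
        chrom = hit$chrom[1], pos = as.integer(hit$pos[1]),
        ref = hit$ref[1], alt = hit$alt[1], g = g,
        source = if (manual_hit) "MANUAL" else "LITERATURE",
        rsid = rsid, gene_symbols = join_multi(gene),
        pmids = join_multi(pmid), indel_cap = indel_cap),
      error = function(e) e)
    if (inherits(row, "error")) {
      rejected[[length(rejected) + 1]] <-
        data.frame(row = i, reason = conditionMessage(row))
    } else rows[[length(rows) + 1]] <- row
  }
  finish_ingest(rows,
                if (length(rejected)) do.call(rbind, rejected)
                else empty_reject_df(),
                unmapped = if (length(unmapped)) do.call(rbind, unmapped)
                else data.frame(),
                n_input = nrow(tab))
}
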