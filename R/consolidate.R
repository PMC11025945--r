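# Consolidation: merge the per-source variant tables into one evidence
# ledger, count source overlaps, assign the two evidence levels and emit VCF.

DISEASE_SOURCES <- c("CLINVAR", "LITERATURE", "MANUAL")

sig_rank <- function(x) {
  r <- match(x, SIGNIFICANCE_LEVELS)
  r[is.na(x)] <- length(SIGNIFICANCE_LEVELS) + 1L
  r
}

#' Merge per-source variant tables into an evidence ledger
#'
#' Rows are deduplicated on the normalized (chrom, pos, ref, alt) key;
#' identifiers, gene symbols, consequence terms, phenotypes, sources, PMIDs
#' and flags are unioned. Significance is merged to the most severe observed
#' value (pathogenic > likely_pathogenic > conflicting >
#' uncertain_significance > likely_benign > benign > other); when both a
#' pathogenic-side and a benign-side assertion occur, the row is additionally
#' flagged `sig_conflicting`.
#'
#' @param tables list of normalized variant tables.
#' @return an `evidence_ledger` data.frame, one row per unique key.
#' @export
merge_sources <- function(tables) {
  all <- do.call(rbind, lapply(tables, as_variant_table))
  if (is.null(all) || nrow(all) == 0) {
    led <- empty_variants()
    led$sig_conflicting <- logical(0)
    led$level1 <- logical(0); led$level2 <- logical(0)
    led$exclusion_reason <- character(0)
    class(led) <- c("evidence_ledger", "data.frame")
    return(led)
  }
  bad <- !nzchar(all$ref) | !nzchar(all$alt) | all$ref == "-" | all$alt == "-"
  if (any(bad))
    stop("unnormalized variant(s) with empty/'-' alleles at key(s): ",
         paste(utils::head(all$key[bad], 5), collapse = ", "),
         "; run normalize_variant() first")
  pieces <- lapply(split(seq_len(nrow(all)), all$key), function(idx) {
    sub <- all[idx, , drop = FALSE]
    out <- sub[1, , drop = FALSE]
    for (col in c("other_ids", "gene_symbols", "consequence_terms",
                  "phenotypes", "sources", "pmids", "flags"))
      out[[col]] <- Reduce(union_multi, sub[[col]])
    rs <- sub$rsid[!is.na(sub$rsid)]
    out$rsid <- if (length(rs)) rs[1] else NA_character_
    sigs <- sub$significance[!is.na(sub$significance)]
    out$significance <- if (length(sigs))
      SIGNIFICANCE_LEVELS[min(sig_rank(sigs))] else NA_character_
    patho_side <- any(sigs %in% c("pathogenic", "likely_pathogenic"))
    benign_side <- any(sigs %in% c("benign", "likely_benign"))
    out$sig_conflicting <- patho_side && benign_side
    out
  })
  led <- do.call(rbind, pieces)
  led <- led[order(led$chrom, led$pos, led$ref, led$alt), , drop = FALSE]
  rownames(led) <- NULL
  led$level1 <- FALSE; led$level2 <- FALSE
  led$exclusion_reason <- NA_character_
  class(led) <- c("evidence_ledger", "data.frame")
  led
}

has_source <- function(ledger, sources) {
  vapply(ledger$sources, function(s)
    any(split_multi(s) %in% sources), logical(1), USE.NAMES = FALSE)
}

#' Source-overlap (Venn) counts
#'
#' Counts ledger rows over the power set of the two disease-evidence source
#' classes: the clinical archive (CLINVAR) and the literature (LITERATURE
#' pooled with MANUAL). Rows backed by neither (reference-table-only rows)
#' are counted under `none`. The counts always sum to the ledger size.
#'
#' @param ledger an `evidence_ledger`.
#' @return named integer vector `c(none, CLINVAR, LITERATURE,
#'   CLINVAR_LITERATURE)`.
#' @export
overlap_counts <- function(ledger) {
  cv <- has_source(ledger, "CLINVAR")
  lit <- has_source(ledger, c("LITERATURE", "MANUAL"))
  c(none = sum(!cv & !lit),
    CLINVAR = sum(cv & !lit),
    LITERATURE = sum(!cv & lit),
    CLINVAR_LITERATURE = sum(cv & lit))
}

#' Export Venn counts as a two-circle diagram
#'
#' @param counts output of [overlap_counts()].
#' @param path output PNG path.
#' @param main plot title.
#' @return the path, invisibly.
#' @export
plot_venn <- function(counts, path, main = "Variant sources") {
  grDevices::png(path, width = 640, height = 480, res = 96)
  on.exit(grDevices::dev.off())
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 10), ylim = c(0, 8), asp = 1)
  graphics::title(main = main)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(4 + 2.2 * cos(th), 4 + 2.2 * sin(th), col = "steelblue",
                  lwd = 2)
  graphics::lines(6 + 2.2 * cos(th), 4 + 2.2 * sin(th), col = "darkgreen",
                  lwd = 2)
  graphics::text(3, 4, counts[["CLINVAR"]])
  graphics::text(7, 4, counts[["LITERATURE"]])
  graphics::text(5, 4, counts[["CLINVAR_LITERATURE"]])
  graphics::text(3, 6.6, "ClinVar", col = "steelblue")
  graphics::text(7, 6.6, "Literature", col = "darkgreen")
  invisible(path)
}

#' Assign the two evidence levels
#'
#' Level 1: every row backed by any disease-evidence source (clinical
#' archive, literature or manual mapping), regardless of reported clinical
#' significance. Level 2 (always a subset of level 1): rows that either (a)
#' carry archive evidence with merged significance pathogenic or
#' likely_pathogenic, or (b) carry literature/manual evidence in a gene
#' outside the excluded list (genes reported to lack pathogenicity, default
#' BLK, KLF11, PAX4). Rows that are level 1 but not level 2 get an
#' `exclusion_reason` (`clinvar_not_pathogenic` and/or `gene_excluded`).
#'
#' @param ledger an `evidence_ledger`.
#' @param excluded_genes genes whose literature-only variants are dropped
#'   from level 2.
#' @return the ledger with `level1`, `level2`, `exclusion_reason` filled.
#' @export
assign_levels <- function(ledger,
                          excluded_genes = c("BLK", "KLF11", "PAX4")) {
  if (nrow(ledger) == 0) return(ledger)
  cv <- has_source(ledger, "CLINVAR")
  lit <- has_source(ledger, c("LITERATURE", "MANUAL"))
  ledger$level1 <- cv | lit
  patho <- !is.na(ledger$significance) &
    ledger$significance %in% c("pathogenic", "likely_pathogenic")
  gene_ok <- vapply(ledger$gene_symbols, function(gs)
    !any(split_multi(gs) %in% excluded_genes), logical(1), USE.NAMES = FALSE)
  clinvar_ok <- cv & patho
  lit_ok <- lit & gene_ok
  ledger$level2 <- ledger$level1 & (clinvar_ok | lit_ok)
  ledger$exclusion_reason <- NA_character_
  drop <- ledger$level1 & !ledger$level2
  for (i in which(drop)) {
    reasons <- character(0)
    if (cv[i] && !clinvar_ok[i]) reasons <- c(reasons,
                                              "clinvar_not_pathogenic")
    if (lit[i] && !lit_ok[i]) reasons <- c(reasons, "gene_excluded")
    ledger$exclusion_reason[i] <- paste(reasons, collapse = ";")
  }
  ledger
}

vcf_info_headers <- c(
  "##INFO=<ID=SOURCES,Number=.,Type=String,Description=\"Evidence sources for this variant\">",
  "##INFO=<ID=SIG,Number=1,Type=String,Description=\"Merged clinical significance\">",
  "##INFO=<ID=GENES,Number=.,Type=String,Description=\"Gene symbols\">",
  "##INFO=<ID=LEVEL,Number=1,Type=Integer,Description=\"Evidence level of the record\">")

#' Write an evidence level as VCF
#'
#' Emits VCF v4.2 with one record per ledger row carrying the requested
#' level flag. ID is the rsID, else the first archive accession, else ".".
#' INFO carries SOURCES, SIG, GENES and LEVEL. Records are sorted by
#' chromosome (numeric-aware, lexicographic fallback with a warning) then
#' position. The file round-trips through [read_vcf()].
#'
#' @param ledger an `evidence_ledger` with levels assigned.
#' @param level 1 or 2.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(ledger, level, path) {
  stopifnot(level %in% c(1, 2))
  rows <- ledger[if (level == 1) ledger$level1 else ledger$level2, ,
                 drop = FALSE]
  header <- c("##fileformat=VCFv4.2",
              "##source=vartoprot",
              vcf_info_headers,
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  if (nrow(rows) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  ord <- order(match(rows$chrom,
                     unique(rows$chrom)[chrom_order(unique(rows$chrom))]),
               rows$pos)
  rows <- rows[ord, , drop = FALSE]
  id <- mapply(function(rs, oid) {
    if (!is.na(rs) && nzchar(rs)) return(rs)
    ids <- split_multi(oid)
    if (length(ids)) ids[1] else "."
  }, rows$rsid, rows$other_ids, USE.NAMES = FALSE)
  info <- mapply(function(src, sig, genes) {
    paste0("SOURCES=", gsub(";", ",", src %||% "."),
           ";SIG=", if (is.na(sig) || !nzchar(sig)) "." else sig,
           ";GENES=", if (nzchar(genes %||% "")) gsub(";", ",", genes)
           else ".",
           ";LEVEL=", level)
  }, rows$sources, rows$significance, rows$gene_symbols, USE.NAMES = FALSE)
  recs <- paste(rows$chrom, rows$pos, id, rows$ref, rows$alt, ".", ".",
                info, sep = "\t")
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' Minimal VCF v4.2 text reader for round-tripping the package's own output:
#' returns one row per record with the variant key and the parsed INFO
#' fields.
#'
#' @param path VCF path.
#' @return data.frame with chrom, pos, id, ref, alt, key, sources,
#'   significance, genes, level.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), key = character(0),
                      sources = character(0), significance = character(0),
                      genes = character(0), level = integer(0)))
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info_field <- function(info, tag) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", tag, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  info <- parts[, 8]
  data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
             id = parts[, 3], ref = parts[, 4], alt = parts[, 5],
             key = variant_key(parts[, 1], as.integer(parts[, 2]),
                               parts[, 4], parts[, 5]),
             sources = gsub(",", ";", info_field(info, "SOURCES")),
             significance = info_field(info, "SIG"),
             genes = gsub(",", ";", info_field(info, "GENES")),
             level = as.integer(info_field(info, "LEVEL")),
             stringsAsFactors = FALSE)
}
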