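# Per-gene overlay of variant positions on protein isoforms, plus the
# per-gene level-1/level-2 tallies.

#' Residue index of a variant on one isoform
#'
#' The 1-based protein position of the first affected residue, or NA when
#' the variant is not translatable on this transcript (non-exonic, outside,
#' non-coding transcript or UTR-only edit).
#'
#' @param t a `transcript_model`.
#' @param g a `reference_genome`.
#' @param v one-row normalized variant.
#' @return integer residue index or NA.
#' @export
variant_protein_pos <- function(t, g, v) {
  cl <- classify_variant(v, t, g)
  if (is.null(cl) || is.na(cl$protein_pos)) return(NA_integer_)
  cl$protein_pos
}

#' Build a per-gene overlay track
#'
#' For every coding isoform of the gene, collects the residue positions of
#' the translatable level-1 and level-2 ledger variants. Indel positions use
#' the first affected residue. A gene absent from the ledger yields an empty
#' track.
#'
#' @param gene gene symbol.
#' @param ledger an `evidence_ledger` with levels assigned.
#' @param transcripts list of `transcript_model` (all genes; filtered here).
#' @param g a `reference_genome`.
#' @return an `overlay_track`: list with `gene_symbol` and `isoforms`, each
#'   isoform a list (transcript_id, protein_length, level1_positions,
#'   level2_positions).
#' @export
build_overlay <- function(gene, ledger, transcripts, g) {
  tts <- Filter(has_cds, transcripts_of_gene(transcripts, gene))
  in_gene <- vapply(ledger$gene_symbols, function(gs)
    gene %in% split_multi(gs), logical(1), USE.NAMES = FALSE)
  lvl1 <- ledger[in_gene & ledger$level1, , drop = FALSE]
  isoforms <- lapply(tts, function(t) {
    b <- cds_cdna_bounds(t)
    refp <- translate_cds(substr(spliced_cdna(t, g), b["lo"], b["hi"]))
    plen <- nchar(refp$protein)
    p1 <- integer(0); p2 <- integer(0)
    for (i in seq_len(nrow(lvl1))) {
      pp <- variant_protein_pos(t, g, lvl1[i, , drop = FALSE])
      if (is.na(pp) || pp < 1 || pp > plen) next
      p1 <- c(p1, pp)
      if (lvl1$level2[i]) p2 <- c(p2, pp)
    }
    list(transcript_id = t$transcript_id, protein_length = plen,
         level1_positions = sort(unique(p1)),
         level2_positions = sort(unique(p2)))
  })
  structure(list(gene_symbol = gene, isoforms = isoforms),
            class = "overlay_track")
}

#' Render an overlay track
#'
#' One panel per isoform: the protein drawn as a horizontal line with the
#' level-2 variant positions as a top row of blue dots and the level-1
#' positions as a bottom row of green dots. The level-2 set must be a subset
#' of the level-1 set on every isoform (asserted before rendering).
#' Zero-length proteins are skipped with a warning. Output is deterministic
#' for fixed input.
#'
#' @param track an `overlay_track`.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
render_overlay <- function(track, path) {
  for (iso in track$isoforms)
    if (!all(iso$level2_positions %in% iso$level1_positions))
      stop("overlay invariant violated for ", iso$transcript_id,
           ": level-2 positions not a subset of level-1 positions")
  isoforms <- track$isoforms
  drop <- vapply(isoforms, function(x) x$protein_length == 0, logical(1))
  if (any(drop)) {
    warning("skipping zero-length protein panel(s): ",
            paste(vapply(isoforms[drop], `[[`, character(1),
                         "transcript_id"), collapse = ", "))
    isoforms <- isoforms[!drop]
  }
  n <- max(1, length(isoforms))
  grDevices::png(path, width = 900, height = 160 * n, res = 96)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(n, 1), mar = c(3, 4, 2, 1))
  if (length(isoforms) == 0) graphics::plot.new()
  for (iso in isoforms) {
    graphics::plot(NA, xlim = c(1, max(2, iso$protein_length)),
                   ylim = c(0, 3), yaxt = "n", xlab = "residue",
                   ylab = "", bty = "n",
                   main = sprintf("%s  %s (%d aa)", track$gene_symbol,
                                  iso$transcript_id, iso$protein_length))
    graphics::segments(1, 1, iso$protein_length, 1, lwd = 3, col = "grey40")
    if (length(iso$level1_positions))
      graphics::points(iso$level1_positions,
                       rep(1.4, length(iso$level1_positions)),
                       pch = 16, col = "darkgreen", cex = 0.8)
    if (length(iso$level2_positions))
      graphics::points(iso$level2_positions,
                       rep(2.0, length(iso$level2_positions)),
                       pch = 16, col = "steelblue", cex = 0.8)
    graphics::axis(2, at = c(1.4, 2.0), labels = c("L1", "L2"), las = 2,
                   tick = FALSE)
  }
  invisible(path)
}

#' Per-gene variant tallies
#'
#' Counts, per gene, the ledger rows flagged level 1 and level 2 (a variant
#' annotated to several genes counts once in each; counting is at the ledger
#' level, not per transcript). Optionally keeps only genes whose level-1
#' count exceeds a threshold.
#'
#' @param ledger an `evidence_ledger` with levels assigned.
#' @param threshold if not NULL, keep genes with `level1_count > threshold`
#'   (the headline figure uses 20).
#' @return data.frame (gene, level1_count, level2_count) sorted by
#'   decreasing level-1 count.
#' @export
variants_per_gene <- function(ledger, threshold = NULL) {
  empty <- data.frame(gene = character(0), level1_count = integer(0),
                      level2_count = integer(0), stringsAsFactors = FALSE)
  if (nrow(ledger) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(ledger))) {
    if (!ledger$level1[i]) next
    for (gsym in split_multi(ledger$gene_symbols[i]))
      rows[[length(rows) + 1]] <- data.frame(
        gene = gsym, l1 = 1L, l2 = as.integer(ledger$level2[i]))
  }
  if (length(rows) == 0) return(empty)
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(l1, l2) ~ gene, data = long, FUN = sum)
  out <- data.frame(gene = agg$gene, level1_count = agg$l1,
                    level2_count = agg$l2, stringsAsFactors = FALSE)
  if (!is.null(threshold)) out <- out[out$level1_count > threshold, ,
                                      drop = FALSE]
  out <- out[order(-out$level1_count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bar chart of per-gene variant counts
#'
#' Full bars show the level-1 count; the overlaid darker part shows the
#' level-2 count.
#'
#' @param counts output of [variants_per_gene()].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
plot_gene_counts <- function(counts, path) {
  grDevices::png(path, width = 200 + 60 * max(1, nrow(counts)), height = 480,
                 res = 96)
  on.exit(grDevices::dev.off())
  if (nrow(counts) == 0) {
    graphics::plot.new(); graphics::title("no genes above threshold")
    return(invisible(path))
  }
  mids <- graphics::barplot(counts$level1_count, names.arg = counts$gene,
                            las = 2, col = "wheat",
                            ylab = "variants", border = NA)
  graphics::barplot(counts$level2_count, add = TRUE, col = "tan4",
                    axes = FALSE, border = NA)
  graphics::legend("topright", fill = c("wheat", "tan4"),
                   legend = c("level 1", "level 2"), bty = "n")
  invisible(path)
}
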