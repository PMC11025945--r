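# Pipeline driver: chains the stages through files under a single config,
# with per-stage row accounting in a log. Each stage reads its inputs from
# disk and writes its outputs to disk, so stages can be run separately or as
# one chain with identical results.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the package defaults: the
#' retained consequence-term list, the level-2 excluded genes (BLK, KLF11,
#' PAX4), the 30-nt indel cap, per-term cross-tab normalization and no
#' canonical-only restriction.
#'
#' @param out_dir output directory.
#' @return named list; see the fields in the source.
#' @export
default_config <- function(out_dir = "vartoprot_out") {
  list(
    genome = NULL, gff3 = NULL,
    ensembl_table = NULL,
    clinvar_table = NULL, clinvar_phenotype = "MODY",
    literature_table = NULL, mapping_table = NULL,
    out_dir = out_dir,
    genes = NULL,
    retained_terms = default_retained_terms(),
    excluded_genes = c("BLK", "KLF11", "PAX4"),
    indel_cap = 30L,
    crosstab_axis = "term",
    canonical_only = FALSE,
    overlay_genes = NULL,
    gene_count_threshold = 20L,
    seed = 1L,
    simulate = list(n_genes = 10L, isoforms_per_gene = 2L,
                    n_variants = 200L))
}

#' Load a pipeline configuration
#'
#' Accepts a config list or a path to a YAML file; unset fields fall back to
#' [default_config()] values. Unknown fields are an error naming the field.
#'
#' @param config list or YAML path.
#' @return validated config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

pipeline_paths <- function(cfg) {
  d <- cfg$out_dir
  list(
    log = file.path(d, "pipeline.log"),
    ingested_ensembl = file.path(d, "ingested_ensembl.tsv"),
    ingested_clinvar = file.path(d, "ingested_clinvar.tsv"),
    ingested_literature = file.path(d, "ingested_literature.tsv"),
    side_rejected = file.path(d, "rejected_rows.tsv"),
    side_unmapped = file.path(d, "unmapped_rows.tsv"),
    classified = file.path(d, "classified_ensembl.tsv"),
    removed = file.path(d, "removed_by_consequence.tsv"),
    crosstab_counts = file.path(d, "crosstab_counts.tsv"),
    crosstab_percent = file.path(d, "crosstab_percent.tsv"),
    crosstab_png = file.path(d, "crosstab.png"),
    ledger = file.path(d, "ledger.tsv"),
    venn = file.path(d, "venn_counts.tsv"),
    venn_png = file.path(d, "venn.png"),
    vcf_level1 = file.path(d, "level1.vcf"),
    vcf_level2 = file.path(d, "level2.vcf"),
    fasta_level1 = file.path(d, "proteins_level1.fasta"),
    fasta_level2 = file.path(d, "proteins_level2.fasta"),
    skip_reasons = file.path(d, "translation_skips.tsv"),
    gene_counts = file.path(d, "gene_counts.tsv"),
    gene_counts_png = file.path(d, "gene_counts.png"))
}

log_line <- function(cfg, ...) {
  line <- paste0(...)
  cat(line, "\n", file = pipeline_paths(cfg)$log, append = TRUE, sep = "")
  invisible(line)
}

need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop("missing input for this stage: ", what, " (",
         path %||% "not configured", ")")
  path
}

read_variant_tsv <- function(path) {
  df <- read_delim_auto(path)
  if (nrow(df) == 0) return(empty_variants())
  df$pos <- as.integer(df$pos)
  for (col in c("rsid", "significance"))
    df[[col]][!nzchar(df[[col]] %||% "")] <- NA_character_
  as_variant_table(df)
}

write_variant_tsv <- function(v, path) write_tsv(as.data.frame(v), path)

load_models_cfg <- function(cfg) {
  load_gene_models(need_file(cfg$gff3, "gene models GFF3"),
                   need_file(cfg$genome, "genome FASTA"))
}

stage_simulate <- function(cfg) {
  sim <- cfg$simulate
  fx <- generate_fixture(seed = cfg$seed,
                         n_genes = sim$n_genes %||% 10L,
                         isoforms_per_gene = sim$isoforms_per_gene %||% 2L,
                         n_variants = sim$n_variants %||% 200L,
                         out_dir = file.path(cfg$out_dir, "simulated"))
  cfg$genome <- fx$paths$genome
  cfg$gff3 <- fx$paths$gff3
  cfg$ensembl_table <- fx$paths$ensembl
  cfg$clinvar_table <- fx$paths$clinvar
  cfg$literature_table <- fx$paths$literature
  cfg$mapping_table <- fx$paths$mapping
  log_line(cfg, "simulate: wrote fixture with ",
           nrow(fx$truth$variants), " planted variants to ",
           file.path(cfg$out_dir, "simulated"))
  cfg
}

stage_ingest <- function(cfg) {
  p <- pipeline_paths(cfg)
  models <- load_models_cfg(cfg)
  g <- models$genome
  ens <- read_ensembl_table(need_file(cfg$ensembl_table, "Ensembl table"), g,
                            indel_cap = cfg$indel_cap)
  rmap <- rsid_index(ens$variants)
  clin <- read_clinvar_table(need_file(cfg$clinvar_table, "ClinVar table"),
                             cfg$clinvar_phenotype, g, rsid_map = rmap,
                             indel_cap = cfg$indel_cap)
  lit <- read_literature_table(
    need_file(cfg$literature_table, "literature table"),
    need_file(cfg$mapping_table, "mapping table"), g,
    indel_cap = cfg$indel_cap)
  write_variant_tsv(ens$variants, p$ingested_ensembl)
  write_variant_tsv(clin$variants, p$ingested_clinvar)
  write_variant_tsv(lit$variants, p$ingested_literature)
  rej <- rbind(
    if (nrow(ens$rejected)) cbind(source = "ENSEMBL", ens$rejected),
    if (nrow(clin$rejected)) cbind(source = "CLINVAR", clin$rejected),
    if (nrow(lit$rejected)) cbind(source = "LITERATURE", lit$rejected))
  write_tsv(rej %||% data.frame(source = character(0), row = integer(0),
                                reason = character(0)), p$side_rejected)
  unm <- rbind(
    if (nrow(clin$unmapped)) data.frame(source = "CLINVAR",
                                        reason = clin$unmapped$reason),
    if (nrow(lit$unmapped)) data.frame(source = "LITERATURE",
                                       reason = lit$unmapped$reason))
  write_tsv(unm %||% data.frame(source = character(0),
                                reason = character(0)), p$side_unmapped)
  for (nm in c("ens", "clin", "lit")) {
    r <- get(nm)
    log_line(cfg, "ingest ", nm, ": in=", r$n_input, " kept=",
             nrow(r$variants), " rejected=", nrow(r$rejected),
             " unmapped=", nrow(r$unmapped))
  }
  invisible(cfg)
}

stage_classify <- function(cfg) {
  p <- pipeline_paths(cfg)
  ens <- read_variant_tsv(need_file(p$ingested_ensembl,
                                    "ingested Ensembl variants"))
  models <- load_models_cfg(cfg)
  ann <- annotate_consequences(ens, models$transcripts, models$genome)
  flt <- filter_by_consequence(ann$variants, cfg$retained_terms)
  write_variant_tsv(flt$kept, p$classified)
  write_variant_tsv(flt$removed, p$removed)
  log_line(cfg, "classify: in=", nrow(ens), " kept=", nrow(flt$kept),
           " removed=", nrow(flt$removed))
  invisible(cfg)
}

stage_crosstab <- function(cfg) {
  p <- pipeline_paths(cfg)
  ens <- read_variant_tsv(need_file(p$ingested_ensembl,
                                    "ingested Ensembl variants"))
  ct <- consequence_crosstab(ens, normalize_axis = cfg$crosstab_axis)
  write_tsv(data.frame(term = rownames(ct$counts), ct$counts,
                       check.names = FALSE), p$crosstab_counts)
  write_tsv(data.frame(term = rownames(ct$percent), round(ct$percent, 4),
                       check.names = FALSE), p$crosstab_percent)
  plot_crosstab(ct, p$crosstab_png)
  log_line(cfg, "crosstab: ", nrow(ct$counts), " terms x ",
           ncol(ct$counts), " significance categories")
  invisible(cfg)
}

stage_consolidate <- function(cfg) {
  p <- pipeline_paths(cfg)
  kept <- read_variant_tsv(need_file(p$classified,
                                     "consequence-filtered variants"))
  clin <- read_variant_tsv(need_file(p$ingested_clinvar,
                                     "ingested ClinVar variants"))
  lit <- read_variant_tsv(need_file(p$ingested_literature,
                                    "ingested literature variants"))
  ledger <- merge_sources(list(kept, clin, lit))
  ledger <- assign_levels(ledger, cfg$excluded_genes)
  write_variant_tsv(ledger, p$ledger)
  oc <- overlap_counts(ledger)
  write_tsv(data.frame(combination = names(oc), count = as.integer(oc)),
            p$venn)
  plot_venn(oc, p$venn_png)
  log_line(cfg, "consolidate: ledger=", nrow(ledger), " level1=",
           sum(ledger$level1), " level2=", sum(ledger$level2),
           " venn=", paste(names(oc), oc, sep = ":", collapse = ","))
  invisible(cfg)
}

read_ledger_tsv <- function(path) {
  led <- read_variant_tsv(path)
  raw <- read_delim_auto(path)
  led$sig_conflicting <- raw$sig_conflicting == "TRUE"
  led$level1 <- raw$level1 == "TRUE"
  led$level2 <- raw$level2 == "TRUE"
  led$exclusion_reason <- raw$exclusion_reason
  class(led) <- c("evidence_ledger", "data.frame")
  led
}

stage_vcf <- function(cfg) {
  p <- pipeline_paths(cfg)
  ledger <- read_ledger_tsv(need_file(p$ledger, "consolidated ledger"))
  suppressWarnings({
    write_vcf(ledger, 1, p$vcf_level1)
    write_vcf(ledger, 2, p$vcf_level2)
  })
  log_line(cfg, "vcf: level1=", sum(ledger$level1), " level2=",
           sum(ledger$level2))
  invisible(cfg)
}

stage_translate <- function(cfg) {
  p <- pipeline_paths(cfg)
  ledger <- read_ledger_tsv(need_file(p$ledger, "consolidated ledger"))
  models <- load_models_cfg(cfg)
  skips <- list()
  for (level in 1:2) {
    rows <- ledger[if (level == 1) ledger$level1 else ledger$level2, ,
                   drop = FALSE]
    records <- list()
    for (i in seq_len(nrow(rows))) {
      v <- rows[i, , drop = FALSE]
      genes <- split_multi(v$gene_symbols)
      tts <- Filter(function(t) t$gene_symbol %in% genes || length(genes) == 0,
                    models$transcripts)
      ex <- expand_all_isoforms(v, tts, models$genome, level = level,
                                canonical_only = cfg$canonical_only)
      records <- c(records, ex$records)
      if (level == 1 && nrow(ex$skipped) > 0)
        skips[[length(skips) + 1]] <- cbind(key = v$key, ex$skipped)
    }
    write_protein_fasta(records,
                        if (level == 1) p$fasta_level1 else p$fasta_level2)
    log_line(cfg, "translate level", level, ": variants=", nrow(rows),
             " records=", length(Filter(function(r) nzchar(r$sequence),
                                        records)))
  }
  write_tsv(if (length(skips)) do.call(rbind, skips) else
    data.frame(key = character(0), transcript_id = character(0),
               reason = character(0)), p$skip_reasons)
  invisible(cfg)
}

stage_overlay <- function(cfg) {
  p <- pipeline_paths(cfg)
  ledger <- read_ledger_tsv(need_file(p$ledger, "consolidated ledger"))
  models <- load_models_cfg(cfg)
  counts <- variants_per_gene(ledger)
  write_tsv(counts, p$gene_counts)
  plot_gene_counts(counts[counts$level1_count > cfg$gene_count_threshold, ,
                          drop = FALSE], p$gene_counts_png)
  genes <- cfg$overlay_genes %||% utils::head(counts$gene, 3)
  for (gene in genes) {
    track <- build_overlay(gene, ledger, models$transcripts, models$genome)
    render_overlay(track, file.path(cfg$out_dir,
                                    paste0("overlay_", gene, ".png")))
  }
  log_line(cfg, "overlay: genes=", paste(genes, collapse = ","))
  invisible(cfg)
}

#' Run the pipeline
#'
#' Executes one stage or the whole chain. Stages communicate through files in
#' `out_dir`, so running them one at a time is equivalent to running
#' `"all"`. Every stage appends row-fate counts to `pipeline.log`. Missing
#' inputs raise an error naming the file.
#'
#' @param subcommand one of `"simulate"`, `"ingest"`, `"classify"`,
#'   `"crosstab"`, `"consolidate"`, `"vcf"`, `"translate"`, `"overlay"`,
#'   `"all"`.
#' @param config config list or YAML path (see [default_config()]).
#' @return invisibly, the effective config (with simulated paths filled in
#'   when simulating).
#' @export
run_pipeline <- function(subcommand = "all", config = default_config()) {
  subcommand <- match.arg(subcommand,
                          c("all", "simulate", "ingest", "classify",
                            "crosstab", "consolidate", "vcf", "translate",
                            "overlay"))
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (subcommand == "all")
    c("ingest", "classify", "crosstab", "consolidate", "vcf", "translate",
      "overlay")
  else subcommand
  if (identical(subcommand, "simulate")) stages <- "simulate"
  for (s in stages) {
    cfg2 <- switch(s,
                   simulate = stage_simulate(cfg),
                   ingest = stage_ingest(cfg),
                   classify = stage_classify(cfg),
                   crosstab = stage_crosstab(cfg),
                   consolidate = stage_consolidate(cfg),
                   vcf = stage_vcf(cfg),
                   translate = stage_translate(cfg),
                   overlay = stage_overlay(cfg))
    if (s == "simulate") cfg <- cfg2
  }
  invisible(cfg)
}
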