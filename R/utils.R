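# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || (length(a) == 1 && is.na(a))) b else a

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement over the alphabet A/C/G/T/N
#' (case-insensitive input, uppercase output).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- toupper(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# ";"-joined multi-valued fields used throughout the variant tables.
split_multi <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character(0))
  unique(strsplit(x, ";", fixed = TRUE)[[1]])
}

join_multi <- function(x) {
  x <- unique(x[!is.na(x) & nzchar(x)])
  if (length(x) == 0) "" else paste(sort(x), collapse = ";")
}

union_multi <- function(a, b) join_multi(c(split_multi(a), split_multi(b)))

# Delimited-table reader: tab or comma, sniffed from the header line;
# transparent gzip via the connection layer.
read_delim_auto <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (length(first) == 0) return(data.frame())
  sep <- if (grepl("\t", first)) "\t" else ","
  close(con); on.exit()
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  utils::read.table(con, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE, colClasses = "character")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Chromosome ordering for VCF output: numeric-aware where possible,
# lexicographic fallback with a warning otherwise.
chrom_order <- function(chroms) {
  stripped <- sub("^chr", "", chroms)
  num <- suppressWarnings(as.numeric(stripped))
  if (any(is.na(num))) {
    warning("chromosome names are not uniformly numeric; ",
            "falling back to lexicographic order")
    order(chroms)
  } else {
    order(num)
  }
}
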