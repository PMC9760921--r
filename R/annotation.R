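#' Normalize a chromosome label
#'
#' Strips an optional `chr` prefix and upper-cases sex chromosomes, mapping
#' onto the 24-chromosome nuclear universe `1..22, X, Y`. Mitochondrial
#' (`chrM`, `MT`) and alt/random/scaffold contigs (anything else) are
#' rejected: the function returns `NA` for them rather than erroring, since
#' rejection is an expected state when scanning an annotation.
#'
#' @param raw_label character vector of chromosome names as found in a GTF.
#' @return character vector of normalized labels, `NA` where rejected.
#' @examples
#' normalize_chromosome(c("chr18", "18", "chrX", "MT", "chr18_random"))
#' @export
normalize_chromosome <- function(raw_label) {
  lab <- sub("^[Cc][Hh][Rr]", "", as.character(raw_label))
  lab <- toupper(lab)
  lab[!lab %in% CHROMOSOMES] <- NA_character_
  lab
}

# Strip an Ensembl-style ".version" suffix from gene/transcript identifiers.
strip_version <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Build a protein-coding gene catalog from a GTF annotation
#'
#' Reads a GENCODE/Ensembl-dialect GTF and returns the gene universe used as
#' the denominator of every coverage statistic: unique genes of the requested
#' biotype on the 24 nuclear chromosomes. The biotype is read from the
#' `gene_type` attribute (GENCODE) with fallback to `gene_biotype` (Ensembl).
#' Gene identity is the `gene_id` with any `.version` suffix stripped; gene
#' symbols are retained for reporting but never used as keys.
#'
#' The longest annotated transcript length per gene is recorded
#' (`max_transcript_length`); it is used only by the platform simulator's
#' read-length model. When a gene has no transcript features the span of the
#' gene feature itself is used.
#'
#' @param gtf_path path to a GTF file (tab-separated, 9 columns, attributes
#'   in `key "value";` form).
#' @param biotype_filter biotype to keep (default `"protein_coding"`).
#' @return a `gene_catalog`: a data.frame with columns `gene_id`,
#'   `gene_name`, `chromosome`, `biotype`, `max_transcript_length`, plus a
#'   `per_chromosome_counts` attribute.
#' @export
load_annotation <- function(gtf_path, biotype_filter = "protein_coding") {
  if (!file.exists(gtf_path))
    stop("GTF file not found: ", gtf_path)
  validate_gtf_lines(gtf_path)
  gr <- tryCatch(
    suppressWarnings(rtracklayer::import(gtf_path, format = "gtf")),
    error = function(e) stop("GTF parse error in ", gtf_path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop("empty gene catalog: no features in ", gtf_path)

  biotype <- df$gene_type %||% df$gene_biotype
  if (is.null(biotype))
    stop("GTF has neither 'gene_type' nor 'gene_biotype' attributes")
  df$biotype <- as.character(biotype)
  df$chromosome <- normalize_chromosome(df$seqnames)
  df$gene_id_clean <- strip_version(df$gene_id)

  genes <- df[df$type == "gene" &
                !is.na(df$chromosome) &
                df$biotype == biotype_filter, , drop = FALSE]
  if (nrow(genes) == 0)
    stop("empty gene catalog: no '", biotype_filter,
         "' genes on chromosomes 1-22/X/Y in ", gtf_path)
  genes <- genes[!duplicated(genes$gene_id_clean), , drop = FALSE]

  # longest isoform per gene from transcript features; gene span fallback
  tx <- df[df$type == "transcript" &
             df$gene_id_clean %in% genes$gene_id_clean, , drop = FALSE]
  max_len <- genes$width
  names(max_len) <- genes$gene_id_clean
  if (nrow(tx) > 0) {
    tx_max <- tapply(tx$width, tx$gene_id_clean, max)
    max_len[names(tx_max)] <- pmax(tx_max, 0L)
  }

  gene_name <- genes$gene_name %||% genes$gene_id_clean
  out <- data.frame(
    gene_id = genes$gene_id_clean,
    gene_name = as.character(gene_name),
    chromosome = genes$chromosome,
    biotype = genes$biotype,
    max_transcript_length = as.integer(max_len[genes$gene_id_clean]),
    stringsAsFactors = FALSE
  )
  new_gene_catalog(out)
}

# Cheap structural pass so malformed input fails with the offending line
# number; rtracklayer's own errors do not carry one.
validate_gtf_lines <- function(gtf_path) {
  lines <- readLines(gtf_path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body) == 0)
    stop("empty gene catalog: ", gtf_path, " contains no feature lines")
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfields != 9L]
  if (length(bad) > 0)
    stop("GTF parse error at line ", bad[1], " of ", gtf_path,
         ": expected 9 tab-separated fields, found ",
         nfields[match(bad[1], body)])
  invisible(TRUE)
}

new_gene_catalog <- function(df) {
  stopifnot(all(c("gene_id", "gene_name", "chromosome", "biotype",
                  "max_transcript_length") %in% names(df)))
  if (anyDuplicated(df$gene_id))
    stop("gene_id values must be unique within a catalog")
  df$chromosome <- factor(df$chromosome, levels = CHROMOSOMES)
  df <- df[order(df$chromosome, df$gene_id), , drop = FALSE]
  df$chromosome <- as.character(df$chromosome)
  rownames(df) <- NULL
  counts <- table(factor(df$chromosome, levels = CHROMOSOMES))
  counts <- counts[counts > 0]
  attr(df, "per_chromosome_counts") <-
    stats::setNames(as.integer(counts), names(counts))
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Per-chromosome gene counts of a catalog
#' @param catalog a `gene_catalog`.
#' @return named integer vector, one entry per chromosome present.
#' @export
per_chromosome_counts <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  attr(catalog, "per_chromosome_counts")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cnt <- per_chromosome_counts(x)
  cat("Gene catalog:", nrow(x), "genes (biotype ",
      paste(unique(x$biotype), collapse = ","), ") on ",
      length(cnt), " chromosomes\n", sep = "")
  print(cnt)
  invisible(x)
}

#' Write / read a gene catalog as TSV
#'
#' Plain five-column TSV; `read_catalog(write_catalog(x))` reproduces the
#' catalog exactly.
#'
#' @param catalog a `gene_catalog`.
#' @param path output file path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` returns
#'   a `gene_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chromosome = "character"))
  new_gene_catalog(df)
}
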