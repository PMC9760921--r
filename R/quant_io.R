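PLATFORM_UNITS <- c(illumina = "FPKM", ont = "TPM", qpcr = "copies_per_cell")

#' Construct a quantification table
#'
#' One platform-by-donor measurement set: gene-level abundance in the
#' platform's native unit (FPKM for short-read RNA-Seq, TPM for nanopore,
#' copies per cell for qPCR), with the qPCR threshold cycle (Ct) carried
#' alongside when available. One record per gene; aggregation to gene level
#' is assumed already applied.
#'
#' @param platform `"illumina"`, `"ont"` or `"qpcr"`.
#' @param donor sample label (e.g. `"donor1"`, or `"pooled"`).
#' @param gene_id character vector of gene identifiers.
#' @param abundance non-negative numeric abundances in the platform unit.
#' @param ct optional numeric threshold-cycle values (qPCR only).
#' @return a `quant_table`.
#' @export
quant_table <- function(platform, donor, gene_id, abundance, ct = NULL) {
  platform <- match.arg(platform, names(PLATFORM_UNITS))
  gene_id <- as.character(gene_id)
  abundance <- as.numeric(abundance)
  stopifnot(length(gene_id) == length(abundance))
  if (anyDuplicated(gene_id))
    stop("one record per gene_id required; found duplicates")
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundance must be non-negative")
  if (!is.null(ct)) {
    ct <- as.numeric(ct)
    stopifnot(length(ct) == length(gene_id))
    if (any(ct <= 0, na.rm = TRUE))
      stop("ct, when present, must be positive")
  }
  data <- data.frame(gene_id = gene_id, abundance = abundance,
                     stringsAsFactors = FALSE)
  data$ct <- if (is.null(ct)) rep(NA_real_, nrow(data)) else ct
  structure(
    list(platform = platform, donor = as.character(donor),
         unit = unname(PLATFORM_UNITS[platform]), data = data),
    class = "quant_table"
  )
}

#' @export
print.quant_table <- function(x, ...) {
  cat("Quant table: ", x$platform, " / ", x$donor, " (", x$unit, "), ",
      nrow(x$data), " genes, ", sum(x$data$abundance > 0),
      " with non-zero abundance\n", sep = "")
  invisible(x)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("format error in ", path, ": missing required column(s) ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Load a Salmon quant.sf transcript quantification as gene-level TPM
#'
#' Reads the `quant.sf` TSV dialect (columns `Name`, `Length`,
#' `EffectiveLength`, `TPM`, `NumReads`) and aggregates to genes by summing
#' member-transcript TPM, the standard gene-level convention for
#' transcript-level quantifiers. Transcript and gene identifiers have
#' `.version` suffixes stripped before mapping. Transcripts absent from the
#' `tx2gene` map are dropped; the number dropped is recorded in the
#' `n_unmapped` attribute of the result.
#'
#' @param path path to a quant.sf-style TSV.
#' @param tx2gene two-column data.frame (transcript id, gene id), or path to
#'   a headerless two-column TSV.
#' @param donor sample label for the resulting table.
#' @return a `quant_table` with unit TPM (platform `"ont"`).
#' @export
load_salmon_quant <- function(path, tx2gene, donor = "sample") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("Name", "Length", "EffectiveLength", "TPM",
                        "NumReads"), path)
  if (is.character(tx2gene) && length(tx2gene) == 1)
    tx2gene <- utils::read.delim(tx2gene, header = FALSE,
                                 stringsAsFactors = FALSE)
  stopifnot(ncol(tx2gene) >= 2)
  map <- stats::setNames(strip_version(as.character(tx2gene[[2]])),
                         strip_version(as.character(tx2gene[[1]])))
  tx <- strip_version(df$Name)
  gene <- unname(map[tx])
  n_unmapped <- sum(is.na(gene))
  if (n_unmapped == nrow(df) && nrow(df) > 0)
    stop("empty table: no transcript in ", path, " is covered by tx2gene")
  keep <- !is.na(gene)
  agg <- tapply(df$TPM[keep], gene[keep], sum)
  out <- quant_table("ont", donor,
                     gene_id = names(agg), abundance = as.numeric(agg))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Load a gene-level FPKM table
#'
#' TSV with columns `gene_id`, `fpkm`. Duplicate gene rows are aggregated by
#' sum with a warning; a negative abundance is a validation error naming the
#' offending row.
#'
#' @param path path to the TSV.
#' @param donor sample label.
#' @return a `quant_table` with unit FPKM (platform `"illumina"`).
#' @export
load_fpkm_table <- function(path, donor = "sample") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("gene_id", "fpkm"), path)
  bad <- which(df$fpkm < 0)
  if (length(bad) > 0)
    stop("validation error in ", path, ": negative fpkm at data row ",
         bad[1], " (gene ", df$gene_id[bad[1]], ")")
  gene <- strip_version(as.character(df$gene_id))
  if (anyDuplicated(gene)) {
    warning("duplicate gene_id rows in ", path, " aggregated by sum")
    agg <- tapply(df$fpkm, gene, sum)
    gene <- names(agg); fpkm <- as.numeric(agg)
  } else {
    fpkm <- df$fpkm
  }
  quant_table("illumina", donor, gene_id = gene, abundance = fpkm)
}

#' Load a qPCR table
#'
#' CSV with columns `gene_id`, `ct`, `copies_per_cell`. Genes whose Ct
#' exceeds the detection limit may have no copy estimate; such rows are
#' retained with abundance 0 (and their Ct kept) rather than dropped, so
#' that denominators stay catalog-driven and the detection decision is made
#' downstream by the cut-off rule.
#'
#' @param path path to the CSV.
#' @param donor sample label.
#' @return a `quant_table` with unit copies_per_cell (platform `"qpcr"`).
#' @export
load_qpcr_table <- function(path, donor = "sample") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("gene_id", "ct"), path)
  copies <- if ("copies_per_cell" %in% names(df))
    df$copies_per_cell else rep(NA_real_, nrow(df))
  copies[is.na(copies)] <- 0
  quant_table("qpcr", donor,
              gene_id = strip_version(as.character(df$gene_id)),
              abundance = copies, ct = df$ct)
}

#' Write / read a quant_table in its platform's file dialect
#'
#' Illumina tables round-trip through the gene-level FPKM TSV, qPCR tables
#' through the qPCR CSV, and ONT tables through a gene-level TSV of the
#' quant.sf dialect (one synthetic transcript per gene).
#'
#' @param quant a `quant_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  stopifnot(inherits(quant, "quant_table"))
  d <- quant$data
  switch(quant$platform,
    illumina = utils::write.table(
      data.frame(gene_id = d$gene_id, fpkm = d$abundance),
      path, sep = "\t", quote = FALSE, row.names = FALSE),
    qpcr = utils::write.csv(
      data.frame(gene_id = d$gene_id, ct = d$ct,
                 copies_per_cell = d$abundance),
      path, quote = FALSE, row.names = FALSE),
    ont = utils::write.table(
      data.frame(Name = paste0(d$gene_id, "T1"),
                 Length = 1000L, EffectiveLength = 800,
                 TPM = d$abundance, NumReads = NA_real_),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  )
  invisible(path)
}

#' @rdname write_quant_table
#' @param platform platform of the file being read.
#' @param donor sample label.
#' @export
read_quant_table <- function(path, platform, donor = "sample") {
  platform <- match.arg(platform, names(PLATFORM_UNITS))
  switch(platform,
    illumina = load_fpkm_table(path, donor),
    qpcr = load_qpcr_table(path, donor),
    ont = {
      df <- utils::read.delim(path, stringsAsFactors = FALSE)
      require_columns(df, c("Name", "TPM"), path)
      t2g <- data.frame(tx = df$Name, gene = sub("T1$", "", df$Name))
      load_salmon_quant(path, t2g, donor)
    })
}
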