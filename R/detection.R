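#' Platform detection cut-off rules
#'
#' A rule is a (metric, comparator, threshold) triple deciding whether a
#' gene counts as detected. The canonical minimum cut-offs are strict
#' `FPKM > 0` for short-read RNA-Seq, strict `TPM > 0` for nanopore, and
#' inclusive `Ct <= 40` for qPCR — the threshold cycle limit below which an
#' amplification signal is trusted.
#'
#' @param metric one of `"FPKM"`, `"TPM"`, `"copies_per_cell"`, `"Ct"`.
#' @param comparator `"greater_than"` (strict) or `"at_most"` (inclusive).
#' @param threshold numeric cut-off value.
#' @return a `cutoff_rule`.
#' @examples
#' cutoff_rule("FPKM", "greater_than", 0)
#' platform_rule("qpcr")   # Ct <= 40
#' @export
cutoff_rule <- function(metric, comparator, threshold) {
  metric <- match.arg(metric, c("FPKM", "TPM", "copies_per_cell", "Ct"))
  comparator <- match.arg(comparator, c("greater_than", "at_most"))
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  structure(list(metric = metric, comparator = comparator,
                 threshold = threshold),
            class = "cutoff_rule")
}

#' @rdname cutoff_rule
#' @param platform platform name for the canonical rule.
#' @export
platform_rule <- function(platform) {
  switch(match.arg(platform, names(PLATFORM_UNITS)),
         illumina = cutoff_rule("FPKM", "greater_than", 0),
         ont = cutoff_rule("TPM", "greater_than", 0),
         qpcr = cutoff_rule("Ct", "at_most", 40))
}

#' @export
print.cutoff_rule <- function(x, ...) {
  op <- if (x$comparator == "greater_than") ">" else "<="
  cat("Cut-off rule: ", x$metric, " ", op, " ", x$threshold, "\n", sep = "")
  invisible(x)
}

rule_values <- function(quant, rule) {
  compatible <- switch(rule$metric,
    FPKM = quant$platform == "illumina",
    TPM = quant$platform == "ont",
    copies_per_cell = quant$platform == "qpcr",
    Ct = quant$platform == "qpcr")
  if (!compatible)
    stop("configuration error: rule metric ", rule$metric,
         " is incompatible with platform ", quant$platform)
  if (rule$metric == "Ct") quant$data$ct else quant$data$abundance
}

apply_rule <- function(values, rule) {
  ok <- if (rule$comparator == "greater_than")
    values > rule$threshold else values <= rule$threshold
  ok & !is.na(values)
}

#' Derive the detection set of a quantification table under a cut-off rule
#'
#' A gene is detected when its metric passes the rule's comparator
#' (`greater_than` is strict, so a value exactly at the threshold does not
#' pass; `at_most` is inclusive). The set is restricted to the catalog:
#' genes quantified but absent from the catalog are ignored, with the count
#' of ignored genes recorded in the `n_outside_catalog` attribute.
#'
#' @param quant a `quant_table`.
#' @param rule a `cutoff_rule` compatible with the platform's unit.
#' @param catalog a non-empty `gene_catalog`.
#' @return a `detection_set`: platform, donor, rule, and the character
#'   vector of detected gene ids.
#' @export
detect <- function(quant, rule, catalog) {
  stopifnot(inherits(quant, "quant_table"), inherits(rule, "cutoff_rule"),
            inherits(catalog, "gene_catalog"))
  if (nrow(catalog) == 0) stop("catalog is empty")
  values <- rule_values(quant, rule)
  passed <- quant$data$gene_id[apply_rule(values, rule)]
  in_catalog <- passed %in% catalog$gene_id
  structure(
    list(platform = quant$platform, donor = quant$donor, rule = rule,
         genes = sort(passed[in_catalog])),
    n_outside_catalog = sum(!in_catalog),
    class = "detection_set"
  )
}

#' @export
print.detection_set <- function(x, ...) {
  cat("Detection set: ", x$platform, " / ", x$donor, ", ",
      length(x$genes), " genes under ", sep = "")
  print(x$rule)
  invisible(x)
}

#' Sweep detection counts over an ascending ladder of cut-offs
#'
#' Counts detected genes at each threshold. For strict `greater_than` rules
#' the counts are non-increasing along an ascending ladder: raising the
#' cut-off can only remove genes.
#'
#' @param quant a `quant_table`.
#' @param catalog a `gene_catalog`.
#' @param thresholds numeric vector, sorted ascending, non-empty.
#' @param comparator comparator applied at each threshold
#'   (default `"greater_than"`).
#' @param metric metric to threshold; defaults to the platform's abundance
#'   unit.
#' @return data.frame with columns `threshold`, `n_detected`.
#' @export
cutoff_sweep <- function(quant, catalog, thresholds,
                         comparator = "greater_than",
                         metric = NULL) {
  if (length(thresholds) == 0)
    stop("validation error: thresholds must be non-empty")
  if (is.unsorted(thresholds, strictly = FALSE))
    stop("validation error: thresholds must be sorted ascending")
  metric <- metric %||% unname(PLATFORM_UNITS[quant$platform])
  counts <- vapply(thresholds, function(th) {
    length(detect(quant, cutoff_rule(metric, comparator, th),
                  catalog)$genes)
  }, integer(1))
  data.frame(threshold = thresholds, n_detected = counts)
}

#' Per-chromosome coverage table for two platforms
#'
#' For each chromosome of the catalog: the number of genes, the number
#' detected by each platform, their intersection, and the three coverage
#' proportions — per-platform and the two-platform union obtained by
#' inclusion–exclusion (|A| + |B| − |A∩B|), each divided by the chromosome's
#' gene count and formatted by [truncate_proportion()]. A summary row
#' (`chromosome = "total"`) carries the column sums of the counts; its
#' proportions are the unweighted mean of the per-chromosome raw
#' proportions (not the ratio of totals), rounded to the same number of
#' decimals. Raw (unformatted) proportions are kept in the `raw_proportions`
#' attribute so formatting never destroys information.
#'
#' @param sets_by_platform named list of exactly two `detection_set`s.
#' @param catalog the `gene_catalog` defining rows and denominators.
#' @param decimals decimals of the truncated proportion columns (default 2).
#' @return a `coverage_table` data.frame with columns `chromosome`,
#'   `n_genes`, `n_a`, `n_b`, `n_both`, `prop_a`, `prop_b`, `prop_union`.
#' @export
coverage_table <- function(sets_by_platform, catalog, decimals = 2L) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (length(sets_by_platform) != 2)
    stop("coverage_table expects exactly two platform detection sets")
  a <- sets_by_platform[[1]]; b <- sets_by_platform[[2]]
  stopifnot(inherits(a, "detection_set"), inherits(b, "detection_set"))

  chroms <- names(per_chromosome_counts(catalog))
  rows <- lapply(chroms, function(ch) {
    genes <- catalog$gene_id[catalog$chromosome == ch]
    in_a <- genes %in% a$genes
    in_b <- genes %in% b$genes
    data.frame(chromosome = ch, n_genes = length(genes),
               n_a = sum(in_a), n_b = sum(in_b),
               n_both = sum(in_a & in_b), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  raw_a <- ifelse(tab$n_genes > 0, tab$n_a / tab$n_genes, 0)
  raw_b <- ifelse(tab$n_genes > 0, tab$n_b / tab$n_genes, 0)
  raw_u <- ifelse(tab$n_genes > 0,
                  (tab$n_a + tab$n_b - tab$n_both) / tab$n_genes, 0)
  tab$prop_a <- truncate_proportion(raw_a, decimals)
  tab$prop_b <- truncate_proportion(raw_b, decimals)
  tab$prop_union <- truncate_proportion(raw_u, decimals)

  total <- data.frame(
    chromosome = "total",
    n_genes = sum(tab$n_genes), n_a = sum(tab$n_a), n_b = sum(tab$n_b),
    n_both = sum(tab$n_both),
    prop_a = round(mean(raw_a), decimals),
    prop_b = round(mean(raw_b), decimals),
    prop_union = round(mean(raw_u), decimals),
    stringsAsFactors = FALSE
  )
  out <- rbind(tab, total)
  rownames(out) <- NULL
  attr(out, "platforms") <- c(a = a$platform, b = b$platform)
  attr(out, "raw_proportions") <-
    data.frame(chromosome = chroms, prop_a = raw_a, prop_b = raw_b,
               prop_union = raw_u, stringsAsFactors = FALSE)
  class(out) <- c("coverage_table", "data.frame")
  out
}

#' Build a coverage table directly from printed count quadruples
#'
#' Convenience path for desk-checking published per-chromosome counts:
#' constructs synthetic gene sets with exactly the stated cardinalities and
#' intersections, then delegates to [coverage_table()], so the printed
#' counts flow through the same inclusion–exclusion and truncation
#' machinery as real data.
#'
#' @param quads data.frame with columns `chromosome`, `n_genes`, `n_a`,
#'   `n_b`, `n_both`.
#' @param decimals decimals of the truncated proportion columns.
#' @return a `coverage_table`.
#' @export
coverage_from_counts <- function(quads, decimals = 2L) {
  stopifnot(all(c("chromosome", "n_genes", "n_a", "n_b", "n_both") %in%
                  names(quads)))
  with(quads, stopifnot(n_a <= n_genes, n_b <= n_genes,
                        n_both <= pmin(n_a, n_b),
                        n_a + n_b - n_both <= n_genes))
  genes_a <- character(0); genes_b <- character(0); cat_rows <- list()
  for (i in seq_len(nrow(quads))) {
    ch <- as.character(quads$chromosome[i])
    ids <- sprintf("G%s_%05d", ch, seq_len(quads$n_genes[i]))
    # A = first n_a genes; B overlaps A on its last n_both genes
    a_ids <- ids[seq_len(quads$n_a[i])]
    b_start <- quads$n_a[i] - quads$n_both[i] + 1L
    b_ids <- ids[seq(b_start, length.out = quads$n_b[i])]
    genes_a <- c(genes_a, a_ids)
    genes_b <- c(genes_b, b_ids)
    cat_rows[[i]] <- data.frame(
      gene_id = ids, gene_name = ids, chromosome = ch,
      biotype = "protein_coding", max_transcript_length = 1000L,
      stringsAsFactors = FALSE)
  }
  catalog <- new_gene_catalog(do.call(rbind, cat_rows))
  mk <- function(platform, genes) structure(
    list(platform = platform, donor = "pooled",
         rule = platform_rule(platform), genes = sort(genes)),
    class = "detection_set")
  coverage_table(list(a = mk("illumina", genes_a), b = mk("ont", genes_b)),
                 catalog, decimals = decimals)
}

#' @export
print.coverage_table <- function(x, ...) {
  plats <- attr(x, "platforms")
  cat("Gene-centric coverage (A = ", plats[["a"]], ", B = ", plats[["b"]],
      ")\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Write a coverage table as TSV
#' @param tab a `coverage_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coverage_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
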