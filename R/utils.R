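#' genecov: gene-centric transcriptome coverage across platforms
#'
#' Tools for asking, per chromosome and genome-wide, what fraction of
#' protein-coding genes have at least one detectable transcript on each
#' quantification platform (short-read RNA-Seq, nanopore direct RNA
#' sequencing, qPCR), how the platforms' detection sets overlap, and how
#' detection varies between donors.
#'
#' @keywords internal
"_PACKAGE"

# Ordered chromosome universe: the 24 nuclear chromosomes. Mitochondrial
# and scaffold/alt contigs are outside every denominator.
CHROMOSOMES <- c(as.character(1:22), "X", "Y")

# Approximate census of human protein-coding genes per nuclear chromosome
# (GENCODE-style annotation; total 19,593). Used as the default gene-count
# profile of the synthetic study generator.
CHR_GENE_CENSUS <- c(
  "1" = 2022, "2" = 1247, "3" = 1059, "4" = 755, "5" = 856, "6" = 972,
  "7" = 962, "8" = 675, "9" = 778, "10" = 720, "11" = 1281, "12" = 1013,
  "13" = 326, "14" = 662, "15" = 589, "16" = 822, "17" = 1126, "18" = 275,
  "19" = 1396, "20" = 537, "21" = 209, "22" = 459, "X" = 812, "Y" = 40
)

#' Truncate a proportion to a fixed number of decimals
#'
#' Truncation toward zero (not rounding): `floor(x * 10^d) / 10^d`. This is
#' the convention of the coverage tables this package produces; e.g.
#' 453/812 = 0.5578 prints as 0.55, where rounding would print 0.56.
#' A tiny epsilon guards against ratios that are exact at `d` decimals being
#' pushed below the floor by binary floating point.
#'
#' @param x numeric vector of proportions in \[0, 1\].
#' @param decimals number of decimal places to keep (default 2).
#' @return numeric vector, truncated.
#' @examples
#' truncate_proportion(186 / 275)      # 0.67
#' truncate_proportion(453 / 812)      # 0.55, not 0.56
#' @export
truncate_proportion <- function(x, decimals = 2L) {
  stopifnot(is.numeric(x), decimals >= 0)
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  p <- 10^decimals
  floor(x * p + 1e-9) / p
}

#' Format a proportion as a percentage
#'
#' Decimal percentages (`decimals >= 1`) are truncated, matching
#' [truncate_proportion()]: 224/275 prints as 81.4%, not 81.5%. Integer
#' percentages (`decimals = 0`) are rounded by default, the common convention
#' for whole-percent figures in print (63/275 prints as 23%); set
#' `mode = "truncate"` to truncate instead.
#'
#' @param x numeric vector of proportions in \[0, 1\].
#' @param decimals decimal places of the percentage (default 1).
#' @param mode `"truncate"` or `"round"`; the default depends on `decimals`
#'   as described above.
#' @return numeric vector on the percent scale.
#' @examples
#' format_percent(224 / 275)       # 81.4
#' format_percent(63 / 275, 0)     # 23
#' @export
format_percent <- function(x, decimals = 1L,
                           mode = if (decimals == 0) "round" else "truncate") {
  mode <- match.arg(mode, c("truncate", "round"))
  if (mode == "truncate") {
    truncate_proportion(x, decimals + 2L) * 100
  } else {
    round(x * 100, decimals)
  }
}

# Derive a child RNG seed from a master seed and a stream index, keeping the
# result a valid 32-bit integer. One stream per (donor, platform) so adding a
# platform never perturbs the draws of another.
derive_seed <- function(master, stream) {
  as.integer((as.numeric(master) * 48271 + as.numeric(stream) * 16807) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
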