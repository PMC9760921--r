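#' Configuration of the synthetic multi-platform study
#'
#' Describes a multi-donor liver-style expression study measured on three
#' platforms. True absolute expression is drawn per gene on the log10
#' copies-per-cell scale, either unimodal (Normal) or bimodal (two-component
#' Normal mixture); each donor's copies are the truth jittered by a
#' lognormal factor. Platform observations are then generated per donor:
#'
#' * short-read RNA-Seq: reads ~ Poisson(depth x copies x length in kb); a
#'   gene is detected when at least `min_reads` reads are sampled; reported
#'   FPKM is proportional to copies with lognormal measurement noise, and 0
#'   for undetected genes.
#' * nanopore direct RNA: identical sampling with a much smaller depth
#'   factor (one flow cell yields on the order of a gigabase), and a length
#'   floor: transcripts shorter than `l_min` nucleotides have their
#'   sampling rate multiplied by `short_penalty`, reflecting the platform's
#'   inability to capture short fragments. Reported values are renormalized
#'   to TPM (summing to 1e6 over reported genes).
#' * qPCR: Ct = ct_intercept − ct_slope x log10(copies) + Normal(0, ct_sd);
#'   a gene is detected when Ct ≤ `ct_limit` (default 40 cycles); reported
#'   copies per cell are the true copies with lognormal noise, 0 when
#'   undetected (the Ct is still reported).
#'
#' Expected detection probability is non-decreasing in true copies on every
#' platform. One RNG stream per (donor, platform) is derived from the
#' master seed, so adding a platform never perturbs another's draws.
#'
#' @param n_genes_per_chromosome named integer vector over chromosomes
#'   1–22, X, Y; defaults to a census of human protein-coding genes scaled
#'   by `size_factor`.
#' @param size_factor multiplier applied to the default census (default 1).
#' @param profile `"unimodal"` or `"bimodal"` log10-copies distribution.
#' @param unimodal list(mean, sd) of the Normal on log10 copies per cell.
#' @param bimodal list(weights, means, sds) of the two-component mixture.
#' @param platforms per-platform detection/noise parameters; see Details.
#' @param n_donors number of donors (default 3).
#' @param donor_effect_sd per-gene log10 jitter of copies across donors.
#' @param length_model list(meanlog, sdlog, chrY_meanlog, chrY_sdlog) of the
#'   lognormal transcript-length draw (nucleotides); chrY genes are drawn
#'   short to exercise the nanopore length floor.
#' @param seed master RNG seed; fully determines the output.
#' @return a validated `simulation_config`.
#' @export
simulation_config <- function(
    n_genes_per_chromosome = NULL,
    size_factor = 1,
    profile = c("unimodal", "bimodal"),
    unimodal = list(mean = 0.5, sd = 1.0),
    bimodal = list(weights = c(0.5, 0.5), means = c(0.5, 2.5),
                   sds = c(0.6, 0.6)),
    platforms = list(
      illumina = list(depth = 17, min_reads = 3, noise_sd = 0.15),
      ont = list(depth = 2.5, min_reads = 8, l_min = 500,
                 short_penalty = 0.05, noise_sd = 0.2),
      qpcr = list(ct_intercept = 38.7, ct_slope = 3.32, ct_sd = 0.3,
                  ct_limit = 40, noise_sd = 0.1)),
    n_donors = 3,
    donor_effect_sd = 0.1,
    length_model = list(meanlog = log(2000), sdlog = 0.6,
                        chrY_meanlog = log(400), chrY_sdlog = 0.5),
    seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(n_genes_per_chromosome)) {
    n_genes_per_chromosome <- round(CHR_GENE_CENSUS * size_factor)
    n_genes_per_chromosome[n_genes_per_chromosome < 1] <- 1
  }
  if (is.null(names(n_genes_per_chromosome)) ||
      !all(names(n_genes_per_chromosome) %in% CHROMOSOMES))
    stop("invalid config: unknown chromosome labels in ",
         "n_genes_per_chromosome")
  if (any(n_genes_per_chromosome < 1))
    stop("invalid config: chromosome gene counts must be positive")
  if (abs(sum(bimodal$weights) - 1) > 1e-8)
    stop("invalid config: mixture weights must sum to 1")
  if (any(c(unimodal$sd, bimodal$sds) <= 0))
    stop("invalid config: all sigma values must be positive")
  if (n_donors < 1) stop("invalid config: n_donors must be >= 1")
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(
    list(n_genes_per_chromosome = n_genes_per_chromosome,
         profile = profile, unimodal = unimodal, bimodal = bimodal,
         platforms = platforms, n_donors = n_donors,
         donor_effect_sd = donor_effect_sd, length_model = length_model,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Named presets of the study generator
#'
#' `"liver"`: unimodal log10-copies profile with low inter-donor
#' variability, emulating differentiated tissue from healthy donors — the
#' regime in which short-read coverage dominates, qPCR sits in between, and
#' shallow nanopore sequencing trails. `"hepg2"`: bimodal profile with an
#' elevated high-expression component, emulating an actively proliferating
#' hepatoblastoma cell line.
#'
#' @param name `"liver"` or `"hepg2"`.
#' @param ... overrides passed on to [simulation_config()].
#' @return a `simulation_config`.
#' @examples
#' preset("liver")$profile    # "unimodal"
#' preset("hepg2")$profile    # "bimodal"
#' @export
preset <- function(name, ...) {
  switch(name,
         liver = simulation_config(profile = "unimodal", ...),
         hepg2 = simulation_config(profile = "bimodal", ...),
         stop("unknown preset: '", name,
              "' (available: liver, hepg2)"))
}

#' Draw the ground-truth expression table
#'
#' Genes are laid out per chromosome with synthetic stable identifiers,
#' lognormal transcript lengths (short on chrY), true copies per cell from
#' the configured profile, and per-donor copies equal to the truth times a
#' lognormal donor factor. Deterministic given the config seed.
#'
#' @param config a `simulation_config`.
#' @return a `truth_table` data.frame: `gene_id`, `gene_name`,
#'   `chromosome`, `length`, `copies`, and one `copies_donorN` column per
#'   donor. The generating config is attached as an attribute.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  counts <- config$n_genes_per_chromosome
  chrom <- rep(names(counts), counts)
  n <- length(chrom)
  set.seed(derive_seed(config$seed, 0L))

  lm_ <- config$length_model
  len <- round(stats::rlnorm(n, lm_$meanlog, lm_$sdlog))
  on_y <- chrom == "Y"
  if (any(on_y))
    len[on_y] <- round(stats::rlnorm(sum(on_y), lm_$chrY_meanlog,
                                     lm_$chrY_sdlog))

  log10_copies <- if (config$profile == "unimodal") {
    stats::rnorm(n, config$unimodal$mean, config$unimodal$sd)
  } else {
    comp <- sample(seq_along(config$bimodal$weights), n, replace = TRUE,
                   prob = config$bimodal$weights)
    stats::rnorm(n, config$bimodal$means[comp], config$bimodal$sds[comp])
  }
  copies <- 10^log10_copies

  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  out <- data.frame(
    gene_id = sprintf("SYNG%s_%05d", chrom, idx),
    gene_name = sprintf("Sg%s.%d", chrom, idx),
    chromosome = chrom, length = as.integer(pmax(len, 50)),
    copies = copies, stringsAsFactors = FALSE)
  if (config$profile == "bimodal") out$component <- comp

  for (d in seq_len(config$n_donors)) {
    set.seed(derive_seed(config$seed, 1000L + d))
    out[[paste0("copies_donor", d)]] <-
      copies * 10^stats::rnorm(n, 0, config$donor_effect_sd)
  }
  attr(out, "config") <- config
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Gene catalog of a simulated truth table
#' @param truth a `truth_table`.
#' @return a `gene_catalog` covering the simulated genes.
#' @export
truth_catalog <- function(truth) {
  stopifnot(inherits(truth, "truth_table"))
  new_gene_catalog(data.frame(
    gene_id = truth$gene_id, gene_name = truth$gene_name,
    chromosome = truth$chromosome, biotype = "protein_coding",
    max_transcript_length = truth$length, stringsAsFactors = FALSE))
}

#' Generate per-donor platform quantification tables from a truth table
#'
#' Applies each platform's observation model (see [simulation_config()]) to
#' every donor's true copies. All gene ids of the truth table appear in
#' every output table; undetected genes carry abundance 0.
#'
#' @param truth a `truth_table` from [simulate_truth()].
#' @param config the generating `simulation_config` (defaults to the one
#'   attached to `truth`).
#' @return nested list: `tables[[platform]][[donor]]` of `quant_table`s,
#'   donors named `donor1..donorN`.
#' @export
simulate_platform_tables <- function(truth, config = attr(truth, "config")) {
  stopifnot(inherits(truth, "truth_table"),
            inherits(config, "simulation_config"))
  n <- nrow(truth)
  len_kb <- truth$length / 1000
  platforms <- names(config$platforms)
  out <- stats::setNames(vector("list", length(platforms)), platforms)
  for (p in seq_along(platforms)) {
    plat <- platforms[p]
    pm <- config$platforms[[plat]]
    donors <- list()
    for (d in seq_len(config$n_donors)) {
      set.seed(derive_seed(config$seed, 100L * p + d))
      cd <- truth[[paste0("copies_donor", d)]]
      donor <- paste0("donor", d)
      donors[[donor]] <- switch(plat,
        illumina = {
          reads <- stats::rpois(n, pm$depth * cd * len_kb)
          detected <- reads >= pm$min_reads
          fpkm <- ifelse(detected,
                         cd * 10^stats::rnorm(n, 0, pm$noise_sd), 0)
          quant_table("illumina", donor, truth$gene_id, fpkm)
        },
        ont = {
          penalty <- ifelse(truth$length < pm$l_min, pm$short_penalty, 1)
          reads <- stats::rpois(n, pm$depth * cd * len_kb * penalty)
          detected <- reads >= pm$min_reads
          raw <- ifelse(detected,
                        cd * 10^stats::rnorm(n, 0, pm$noise_sd), 0)
          tpm <- if (sum(raw) > 0) raw / sum(raw) * 1e6 else raw
          quant_table("ont", donor, truth$gene_id, tpm)
        },
        qpcr = {
          ct <- pm$ct_intercept - pm$ct_slope * log10(cd) +
            stats::rnorm(n, 0, pm$ct_sd)
          ct <- pmax(ct, 1)
          detected <- ct <= pm$ct_limit
          copies <- ifelse(detected,
                           cd * 10^stats::rnorm(n, 0, pm$noise_sd), 0)
          quant_table("qpcr", donor, truth$gene_id, copies, ct = ct)
        },
        stop("unknown platform in config: ", plat))
    }
    out[[plat]] <- donors
  }
  out
}

#' Simulate a full study and write it to disk in the standard dialects
#'
#' Runs [simulate_truth()] and [simulate_platform_tables()], then writes a
#' catalog TSV, a truth TSV, and one quantification file per (platform,
#' donor) in exactly the dialects the loaders read: gene-level FPKM TSV
#' (short-read), quant.sf-style TSV plus a tx2gene map (nanopore), and a
#' qPCR CSV.
#'
#' @param config a `simulation_config` (e.g. from [preset()]).
#' @param out_dir output directory, created if missing.
#' @return invisibly, a manifest list of the written paths.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth(config)
  tables <- simulate_platform_tables(truth, config)
  catalog <- truth_catalog(truth)

  paths <- list(catalog = file.path(out_dir, "catalog.tsv"),
                truth = file.path(out_dir, "truth.tsv"),
                tx2gene = file.path(out_dir, "tx2gene.tsv"))
  write_catalog(catalog, paths$catalog)
  utils::write.table(as.data.frame(truth), paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(tx = paste0(truth$gene_id, "T1"), gene = truth$gene_id),
    paths$tx2gene, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)

  for (plat in names(tables)) {
    for (donor in names(tables[[plat]])) {
      ext <- if (plat == "qpcr") "csv" else "tsv"
      f <- file.path(out_dir, sprintf("%s_%s.%s", plat, donor, ext))
      if (plat == "ont") {
        q <- tables[[plat]][[donor]]
        utils::write.table(
          data.frame(Name = paste0(q$data$gene_id, "T1"),
                     Length = truth$length,
                     EffectiveLength = pmax(truth$length - 200, 50),
                     TPM = q$data$abundance, NumReads = NA_real_),
          f, sep = "\t", quote = FALSE, row.names = FALSE)
      } else {
        write_quant_table(tables[[plat]][[donor]], f)
      }
      paths[[paste(plat, donor, sep = "_")]] <- f
    }
  }
  invisible(paths)
}
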