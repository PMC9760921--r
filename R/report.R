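#' Run the full coverage analysis and write a report bundle
#'
#' Composes the pipeline end to end on one study: per-donor detection sets
#' under the canonical platform cut-offs, pooled (cross-donor union)
#' detection per platform, the two-platform per-chromosome coverage table,
#' pairwise pooled Tanimoto similarities, per-platform donor Venn
#' decompositions and inter-donor variability, cut-off sweeps, and a
#' log–log calibration of each sequencing platform against qPCR (when a
#' qPCR table is present). All results are written under `out_dir` as
#' TSV/JSON, raw counts alongside formatted proportions, plus a
#' machine-readable manifest carrying the package version and a checksum of
#' the run configuration. Logging goes to stderr; files carry no
#' timestamps, so a rerun on the same inputs is byte-identical.
#'
#' @param catalog a `gene_catalog`.
#' @param tables nested list `tables[[platform]][[donor]]` of
#'   `quant_table`s (as returned by [simulate_platform_tables()]).
#' @param out_dir output directory, created if missing.
#' @param coverage_platforms the two platforms of the coverage table
#'   (default short-read vs nanopore).
#' @param sweep_thresholds ascending cut-off ladder for the sweep
#'   (default 0, 1, 2, 5, 10).
#' @param rules named list of `cutoff_rule`s per platform; defaults to the
#'   canonical minimum cut-offs.
#' @param calibration_donor donor whose tables are paired for calibration
#'   (default the first).
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_full_analysis <- function(catalog, tables, out_dir,
                              coverage_platforms = c("illumina", "ont"),
                              sweep_thresholds = c(0, 1, 2, 5, 10),
                              rules = NULL,
                              calibration_donor = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"), is.list(tables))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  platforms <- names(tables)
  if (is.null(rules))
    rules <- stats::setNames(lapply(platforms, platform_rule), platforms)
  missing_cov <- setdiff(coverage_platforms, platforms)
  if (length(missing_cov) > 0)
    stop("stage coverage: no quantification tables for platform(s) ",
         paste(missing_cov, collapse = ", "))

  stage <- function(name, expr) {
    message("[genecov] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }

  # per-donor and pooled detection sets
  det <- stage("detect", lapply(stats::setNames(platforms, platforms),
    function(p) lapply(tables[[p]], detect, rule = rules[[p]],
                       catalog = catalog)))
  pooled <- lapply(stats::setNames(platforms, platforms), function(p) {
    genes <- sort(unique(unlist(lapply(det[[p]],
                                       function(s) s$genes))))
    structure(list(platform = p, donor = "pooled", rule = rules[[p]],
                   genes = genes), class = "detection_set")
  })

  out <- list(manifest = file.path(out_dir, "manifest.json"))

  cov <- stage("coverage", coverage_table(
    pooled[coverage_platforms], catalog))
  out$coverage <- file.path(out_dir, "coverage_table.tsv")
  write_coverage_table(cov, out$coverage)

  # pairwise pooled similarity
  sim <- list()
  for (i in seq_along(platforms)) for (j in seq_along(platforms)) {
    if (i < j) {
      key <- paste(platforms[i], platforms[j], sep = "_vs_")
      s <- tanimoto(pooled[[i]]$genes, pooled[[j]]$genes)
      sim[[key]] <- s[c("p_a", "p_b", "p_ab", "t", "band")]
    }
  }
  out$similarity <- file.path(out_dir, "similarity.json")
  jsonlite::write_json(sim, out$similarity, auto_unbox = TRUE, digits = NA)

  # per-platform donor Venn and variability
  venns <- list(); vars <- list()
  for (p in platforms) {
    sets <- lapply(det[[p]], function(s) s$genes)
    if (length(sets) >= 2 && length(sets) <= 3) {
      v <- stage(paste0("venn_", p), venn(sets))
      venns[[p]] <- as.list(v$region_counts)
    }
    if (length(sets) >= 2) {
      vr <- stage(paste0("variability_", p), donor_variability(sets))
      vars[[p]] <- list(
        per_donor_specific = as.list(vr$per_donor_specific),
        denominator = vr$denominator,
        mean_variability = vr$mean_variability)
    }
  }
  out$venn <- file.path(out_dir, "venn.json")
  jsonlite::write_json(venns, out$venn, auto_unbox = TRUE, digits = NA)
  out$variability <- file.path(out_dir, "variability.json")
  jsonlite::write_json(vars, out$variability, auto_unbox = TRUE,
                       digits = NA)

  # cut-off sweep per sequencing platform, first donor
  sweeps <- list()
  for (p in intersect(c("illumina", "ont"), platforms)) {
    sw <- stage(paste0("sweep_", p),
                cutoff_sweep(tables[[p]][[1]], catalog, sweep_thresholds))
    sw$platform <- p
    sweeps[[p]] <- sw
  }
  if (length(sweeps) > 0) {
    out$sweep <- file.path(out_dir, "sweep.tsv")
    utils::write.table(do.call(rbind, sweeps), out$sweep, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # calibration of each sequencing platform against qPCR
  if ("qpcr" %in% platforms) {
    donor <- calibration_donor %||% names(tables[[1]])[1]
    for (p in intersect(c("illumina", "ont"), platforms)) {
      fit <- stage(paste0("calibration_", p), {
        pairs <- pair_for_calibration(tables[[p]][[donor]],
                                      tables[["qpcr"]][[donor]])
        fit_calibration(pairs)
      })
      key <- paste0("calibration_", p)
      out[[key]] <- file.path(out_dir, paste0(key, ".json"))
      write_calibration(fit, out[[key]])
    }
  }

  config <- list(platforms = platforms,
                 coverage_platforms = coverage_platforms,
                 sweep_thresholds = sweep_thresholds,
                 rules = lapply(rules, unclass),
                 calibration_donor = calibration_donor,
                 n_genes = nrow(catalog))
  config_path <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tool = "genecov",
    version = as.character(utils::packageVersion("genecov")),
    config_md5 = unname(tools::md5sum(config_path)),
    outputs = lapply(out[names(out) != "manifest"], basename))
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
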