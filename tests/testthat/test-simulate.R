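small_config <- function(...) {
  simulation_config(
    n_genes_per_chromosome = c("18" = 200, "X" = 100, "Y" = 50),
    seed = 101, ...)
}

test_that("the truth table is deterministic and respects the config", {
  cfg <- small_config()
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(nrow(t1), 350L)
  expect_equal(table(t1$chromosome)[["18"]], 200L)
  expect_false(anyDuplicated(t1$gene_id) > 0)
  expect_true(all(t1$copies > 0))
  # chrY lengths are drawn short
  expect_lt(median(t1$length[t1$chromosome == "Y"]),
            median(t1$length[t1$chromosome != "Y"]))
})

test_that("zero donor effect makes all donors identical", {
  cfg <- small_config(donor_effect_sd = 0)
  tr <- simulate_truth(cfg)
  expect_equal(tr$copies_donor1, tr$copies)
  expect_equal(tr$copies_donor1, tr$copies_donor3)
})

test_that("a bimodal profile produces the configured mixture", {
  cfg <- simulation_config(
    n_genes_per_chromosome = c("18" = 5000),
    profile = "bimodal",
    bimodal = list(weights = c(0.5, 0.5), means = c(0.5, 2.5),
                   sds = c(0.3, 0.3)),
    seed = 7)
  tr <- simulate_truth(cfg)
  # component assignment counts within binomial tolerance (4 sd)
  n1 <- sum(tr$component == 1)
  expect_lt(abs(n1 - 2500), 4 * sqrt(5000 * 0.25))
  # two well-separated modes: hardly any mass between them
  lg <- log10(tr$copies)
  expect_gt(mean(lg < 1.5), 0.45)
  expect_gt(mean(lg > 1.5), 0.45)
  expect_lt(mean(lg > 1.2 & lg < 1.8), 0.05)
})

test_that("config validation rejects bad inputs and unknown presets", {
  expect_error(simulation_config(bimodal = list(weights = c(0.7, 0.6),
                                                means = c(0, 1),
                                                sds = c(1, 1)),
                                 profile = "bimodal"), "sum to 1")
  expect_error(simulation_config(unimodal = list(mean = 0, sd = -1)),
               "sigma")
  expect_error(simulation_config(
    n_genes_per_chromosome = c(weird = 5)), "unknown chromosome")
  expect_error(preset("kidney"), "unknown preset")
  expect_equal(preset("liver")$profile, "unimodal")
  expect_equal(preset("hepg2")$profile, "bimodal")
})

test_that("platform tables carry correct units and all truth genes", {
  cfg <- small_config()
  tr <- simulate_truth(cfg)
  tabs <- simulate_platform_tables(tr)
  expect_setequal(names(tabs), c("illumina", "ont", "qpcr"))
  for (plat in names(tabs)) {
    expect_length(tabs[[plat]], cfg$n_donors)
    for (q in tabs[[plat]]) {
      expect_s3_class(q, "quant_table")
      expect_setequal(q$data$gene_id, tr$gene_id)
    }
  }
  expect_equal(tabs$illumina$donor1$unit, "FPKM")
  expect_equal(tabs$ont$donor1$unit, "TPM")
  expect_equal(tabs$qpcr$donor1$unit, "copies_per_cell")
  expect_true(all(is.finite(tabs$qpcr$donor1$data$ct)))
  # reported ONT abundances are TPM: non-zero entries sum to 1e6
  expect_equal(sum(tabs$ont$donor1$data$abundance), 1e6)
})

test_that("zero nanopore depth detects nothing", {
  cfg <- small_config()
  cfg$platforms$ont$depth <- 0
  tr <- simulate_truth(cfg)
  tabs <- simulate_platform_tables(tr, cfg)
  expect_true(all(tabs$ont$donor1$data$abundance == 0))
})

test_that("short transcripts depress nanopore detection specifically", {
  cfg <- simulation_config(n_genes_per_chromosome = c("18" = 4000),
                           seed = 19)
  tr <- simulate_truth(cfg)
  # two equal-abundance groups differing only in length
  tr$length <- rep(c(300L, 2000L), length.out = nrow(tr))
  tabs <- simulate_platform_tables(tr, cfg)
  det <- tabs$ont$donor1$data$abundance > 0
  short <- tr$length < cfg$platforms$ont$l_min
  expect_lt(mean(det[short]), mean(det[!short]))
  expect_lt(mean(det[short]), 0.5 * mean(det[!short]))
})

test_that("expected detection is non-decreasing in true copies", {
  # check monotonicity platform-by-platform on a copies ladder with all
  # other gene properties held fixed, averaging over many replicate genes
  cfg <- simulation_config(n_genes_per_chromosome = c("18" = 3000),
                           donor_effect_sd = 0, n_donors = 1, seed = 29)
  tr <- simulate_truth(cfg)
  ladder <- 10^seq(-2, 2, length.out = 6)
  tr$copies <- rep(ladder, length.out = nrow(tr))
  tr$copies_donor1 <- tr$copies
  tr$length <- 1500L
  tabs <- simulate_platform_tables(tr, cfg)
  for (plat in c("illumina", "ont", "qpcr")) {
    rate <- tapply(tabs[[plat]][[1]]$data$abundance > 0, tr$copies, mean)
    rate <- rate[order(as.numeric(names(rate)))]
    expect_true(all(diff(rate) >= -0.02),
                label = paste(plat, "detection monotone in copies"))
  }
})

test_that("a written study round-trips through the package loaders", {
  cfg <- small_config()
  dir <- file.path(tempdir(), "study101")
  paths <- simulate_study(cfg, dir)
  cat <- read_catalog(paths$catalog)
  expect_equal(nrow(cat), 350L)

  tr <- simulate_truth(cfg)
  tabs <- simulate_platform_tables(tr, cfg)
  ill <- load_fpkm_table(paths$illumina_donor1, donor = "donor1")
  expect_equal(setNames(ill$data$abundance, ill$data$gene_id)[tr$gene_id],
               setNames(tabs$illumina$donor1$data$abundance,
                        tabs$illumina$donor1$data$gene_id)[tr$gene_id],
               tolerance = 1e-8)
  ont <- load_salmon_quant(paths$ont_donor1, paths$tx2gene,
                           donor = "donor1")
  expect_equal(sort(ont$data$gene_id), sort(tr$gene_id))
  qp <- load_qpcr_table(paths$qpcr_donor1, donor = "donor1")
  expect_equal(nrow(qp$data), 350L)
  expect_true(all(qp$data$abundance[qp$data$ct > 40] == 0))
})

test_that("simulated data recover the unit log-log calibration slope", {
  cfg <- simulation_config(n_genes_per_chromosome = c("18" = 2000),
                           seed = 31)
  tr <- simulate_truth(cfg)
  tabs <- simulate_platform_tables(tr, cfg)
  pairs <- pair_for_calibration(tabs$illumina$donor1, tabs$qpcr$donor1)
  fit <- fit_calibration(pairs)
  # FPKM is generated proportional to copies: log-log slope 1
  expect_lt(abs(fit$slope - 1), 0.05)
  expect_true(fit$conversion_acceptable)
})
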