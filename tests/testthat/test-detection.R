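catalog3 <- function() make_catalog(c("G1", "G2", "G3"), rep("18", 3))

test_that("detection applies strict and inclusive comparators as stated", {
  cat <- catalog3()
  q <- quant_table("illumina", "d1", c("G1", "G2", "G3"), c(0.0, 0.5, 10.0))
  expect_setequal(detect(q, cutoff_rule("FPKM", "greater_than", 0),
                         cat)$genes, c("G2", "G3"))
  # strict at the boundary: 10.0 is not > 10
  expect_length(detect(q, cutoff_rule("FPKM", "greater_than", 10),
                       cat)$genes, 0)
  # Ct rule is inclusive at the limit
  qp <- quant_table("qpcr", "d1", c("G1", "G2", "G3"), c(5, 1, 0),
                    ct = c(39.5, 40.0, 41.0))
  expect_setequal(detect(qp, platform_rule("qpcr"), cat)$genes,
                  c("G1", "G2"))
})

test_that("genes outside the catalog are ignored with a count", {
  cat <- make_catalog(c("G1", "G2"), c("18", "18"))
  q <- quant_table("illumina", "d1", c("G1", "G2", "GX"), c(1, 2, 3))
  ds <- detect(q, platform_rule("illumina"), cat)
  expect_setequal(ds$genes, c("G1", "G2"))
  expect_equal(attr(ds, "n_outside_catalog"), 1L)
})

test_that("rule/unit mismatch is a configuration error", {
  q <- quant_table("ont", "d1", "G1", 1)
  expect_error(detect(q, cutoff_rule("FPKM", "greater_than", 0),
                      catalog3()), "incompatible")
})

test_that("cut-off sweep matches direct filtering and never increases", {
  cat <- catalog3()
  q <- quant_table("illumina", "d1", c("G1", "G2", "G3"), c(1, 5, 20))
  sw <- cutoff_sweep(q, cat, c(0, 4, 10))
  expect_equal(sw$n_detected, c(3L, 2L, 1L))
  expect_equal(cutoff_sweep(quant_table("illumina", "d", character(),
                                        numeric()),
                            cat, 0)$n_detected, 0L)
  expect_error(cutoff_sweep(q, cat, c(5, 1)), "ascending")
  expect_error(cutoff_sweep(q, cat, numeric()), "non-empty")

  # property: on random tables, counts equal brute-force filtering and are
  # non-increasing along the ladder
  set.seed(11)
  for (rep in 1:20) {
    n <- 50
    ids <- sprintf("R%02d", 1:n)
    catr <- make_catalog(ids, sample(c("1", "2", "X"), n, replace = TRUE))
    ab <- round(rexp(n, 1 / 5), 2)
    qr <- quant_table("illumina", "d", ids, ab)
    th <- sort(runif(6, 0, 15))
    sw <- cutoff_sweep(qr, catr, th)
    brute <- vapply(th, function(t) sum(ab > t), integer(1))
    expect_equal(sw$n_detected, brute)
    expect_true(all(diff(sw$n_detected) <= 0))
  }
})

test_that("proportions are truncated toward zero, not rounded", {
  expect_equal(truncate_proportion(453 / 812), 0.55)   # rounding: 0.56
  expect_equal(truncate_proportion(186 / 275), 0.67)
  expect_equal(truncate_proportion(315 / 326), 0.96)
  expect_equal(truncate_proportion(0), 0)
  expect_equal(truncate_proportion(1), 1)
  expect_equal(truncate_proportion(0.129999, 2), 0.12)
  expect_error(truncate_proportion(1.2), "\\[0, 1\\]")
  # exact-at-precision values survive floating point
  expect_equal(truncate_proportion(0.97), 0.97)
  expect_equal(truncate_proportion(29 / 100), 0.29)
})

test_that("percent formatting truncates decimals and rounds integers", {
  expect_equal(format_percent(267 / 275), 97.0)
  expect_equal(format_percent(224 / 275), 81.4)   # rounding would say 81.5
  expect_equal(format_percent(63 / 275, 0), 23)   # truncation would say 22
  expect_equal(format_percent(63 / 275, 0, mode = "truncate"), 22)
})

test_that("coverage table computes counts, truncated proportions, union", {
  cat <- make_catalog(sprintf("C%03d", 1:285),
                      c(rep("18", 275), rep("19", 10)))
  on18 <- cat$gene_id[cat$chromosome == "18"]
  a <- make_set(on18[1:267], "illumina")
  b <- make_set(on18[82:267], "ont")          # 186 genes, 186 shared...
  # force intersection 185: shift one B gene outside A
  b <- make_set(c(on18[83:267], on18[270]), "ont")
  tab <- coverage_table(list(a = a, b = b), cat)
  r18 <- tab[tab$chromosome == "18", ]
  expect_equal(r18$n_genes, 275L)
  expect_equal(r18$n_a, 267L)
  expect_equal(r18$n_b, 186L)
  expect_equal(r18$n_both, 185L)
  expect_equal(r18$prop_a, 0.97)
  expect_equal(r18$prop_b, 0.67)
  expect_equal(r18$prop_union, 0.97)
  # empty chromosome row is all zeros
  r19 <- tab[tab$chromosome == "19", ]
  expect_equal(unlist(r19[c("n_a", "n_b", "n_both", "prop_a", "prop_b",
                            "prop_union")]),
               c(n_a = 0, n_b = 0, n_both = 0, prop_a = 0, prop_b = 0,
                 prop_union = 0))
  # summary row: counts are sums
  tot <- tab[tab$chromosome == "total", ]
  expect_equal(tot$n_a, 267L)
  expect_equal(tot$n_genes, 285L)
})

test_that("inclusion-exclusion equals a brute-force union on random sets", {
  set.seed(23)
  for (rep in 1:25) {
    n <- 120
    ids <- sprintf("U%03d", 1:n)
    chrom <- sample(c("1", "5", "X", "Y"), n, replace = TRUE)
    cat <- make_catalog(ids, chrom)
    a <- make_set(random_gene_set(ids, 0.6), "illumina")
    b <- make_set(random_gene_set(ids, 0.4), "ont")
    tab <- coverage_table(list(a = a, b = b), cat)
    raw <- attr(tab, "raw_proportions")
    for (ch in unique(chrom)) {
      genes <- ids[chrom == ch]
      direct_union <- length(union(intersect(a$genes, genes),
                                   intersect(b$genes, genes)))
      row <- tab[tab$chromosome == ch, ]
      expect_equal(row$n_a + row$n_b - row$n_both, direct_union)
      expect_equal(raw$prop_union[raw$chromosome == ch],
                   direct_union / length(genes))
    }
  }
})

test_that("coverage_from_counts reproduces published desk arithmetic", {
  quads <- published_coverage_counts()
  tab <- coverage_from_counts(quads)
  body <- tab[tab$chromosome != "total", ]
  expect_equal(body$n_genes, quads$n_genes)
  expect_equal(body$n_a, quads$n_a)
  expect_equal(body$n_b, quads$n_b)
  expect_equal(body$n_both, quads$n_both)
  expect_equal(body$prop_union, quads$prop_union)
})
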