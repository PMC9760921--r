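# Fixture builders shared across the suite. Everything is generated in code
# at test time; nothing binary ships with the package.

gtf_line <- function(chrom, type, start, end, attrs) {
  paste(chrom, "TEST", type, start, end, ".", "+", ".", attrs, sep = "\t")
}

gene_attrs <- function(gene_id, biotype, name = gene_id,
                       key = "gene_type") {
  sprintf('gene_id "%s"; %s "%s"; gene_name "%s";',
          gene_id, key, biotype, name)
}

tx_attrs <- function(gene_id, tx_id, biotype) {
  sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s";',
          gene_id, tx_id, biotype)
}

# Three genes on chr18: two protein-coding (one with two isoforms), one
# lincRNA; plus one protein-coding gene on a random contig that must be
# excluded by chromosome normalization.
write_fixture_gtf <- function(path = tempfile(fileext = ".gtf")) {
  lines <- c(
    "## test annotation",
    gtf_line("chr18", "gene", 100, 5099,
             gene_attrs("ENSG0001.5", "protein_coding", "AAA")),
    gtf_line("chr18", "transcript", 100, 2099,
             tx_attrs("ENSG0001.5", "ENST0001.1", "protein_coding")),
    gtf_line("chr18", "transcript", 100, 3599,
             tx_attrs("ENSG0001.5", "ENST0002.1", "protein_coding")),
    gtf_line("chr18", "gene", 6000, 6999,
             gene_attrs("ENSG0002.2", "protein_coding", "BBB")),
    gtf_line("chr18", "gene", 8000, 8999,
             gene_attrs("ENSG0003.1", "lincRNA", "CCC")),
    gtf_line("chr18_random", "gene", 100, 999,
             gene_attrs("ENSG0004.1", "protein_coding", "DDD"))
  )
  writeLines(lines, path)
  path
}

# detection_set with arbitrary content, for set-statistics tests
make_set <- function(genes, platform = "illumina", donor = "pooled") {
  structure(list(platform = platform, donor = donor,
                 rule = platform_rule(platform),
                 genes = sort(unique(as.character(genes)))),
            class = "detection_set")
}

make_catalog <- function(gene_ids, chromosomes) {
  new_gene_catalog <- getFromNamespace("new_gene_catalog", "genecov")
  new_gene_catalog(data.frame(
    gene_id = gene_ids, gene_name = gene_ids, chromosome = chromosomes,
    biotype = "protein_coding", max_transcript_length = 1000L,
    stringsAsFactors = FALSE))
}

random_gene_set <- function(universe, p = 0.5) {
  universe[stats::runif(length(universe)) < p]
}

# The published per-chromosome detection count quadruples used as desk
# inputs: gene totals, per-platform detected counts, and intersections for
# the 24 nuclear chromosomes, with the printed proportion columns.
published_coverage_counts <- function() {
  data.frame(
    chromosome = c(as.character(1:22), "X", "Y"),
    n_genes = c(2022, 1247, 1059, 755, 856, 972, 962, 675, 778, 720, 1281,
                1013, 326, 662, 589, 822, 1126, 275, 1396, 537, 209, 459,
                812, 40),
    n_a = c(1951, 1210, 1002, 726, 832, 936, 924, 659, 760, 699, 1249, 996,
            315, 643, 581, 802, 1100, 267, 1342, 508, 201, 442, 729, 37),
    n_b = c(1361, 895, 762, 507, 591, 674, 621, 451, 547, 509, 777, 708,
            226, 447, 399, 598, 766, 186, 949, 355, 137, 317, 453, 12),
    n_both = c(1330, 881, 727, 492, 580, 654, 611, 444, 539, 500, 760, 699,
               218, 443, 395, 590, 751, 185, 932, 344, 132, 309, 430, 11),
    prop_a = c(0.96, 0.97, 0.94, 0.96, 0.97, 0.96, 0.96, 0.97, 0.97, 0.97,
               0.97, 0.98, 0.96, 0.97, 0.98, 0.97, 0.97, 0.97, 0.96, 0.94,
               0.96, 0.96, 0.89, 0.92),
    prop_b = c(0.67, 0.71, 0.71, 0.67, 0.69, 0.69, 0.64, 0.66, 0.70, 0.70,
               0.60, 0.69, 0.69, 0.67, 0.67, 0.72, 0.68, 0.67, 0.67, 0.66,
               0.65, 0.69, 0.55, 0.03),
    prop_union = c(0.98, 0.98, 0.97, 0.98, 0.98, 0.98, 0.97, 0.98, 0.98,
                   0.98, 0.98, 0.99, 0.99, 0.97, 0.99, 0.98, 0.99, 0.97,
                   0.97, 0.96, 0.98, 0.98, 0.92, 0.95),
    stringsAsFactors = FALSE
  )
}
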