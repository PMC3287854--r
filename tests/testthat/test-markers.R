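test_that("synthetic map has the configured scale and rank-consistent names", {
  map <- generate_marker_map(n_snps = 2000, n_genes = 260, seed = 1)
  expect_equal(nrow(map), 2000L)
  expect_equal(length(unique(map$gene)), 260L)
  # S-index equals the marker's rank on its chromosome
  for (ch in unique(map$chrom)) {
    ids <- map$snp_id[map$chrom == ch]
    expect_equal(ids, sprintf("C%dS%d", ch, seq_along(ids)))
  }
  # positions strictly increasing within chromosome
  incr <- tapply(map$pos, map$chrom, function(p) all(diff(p) > 0))
  expect_true(all(incr))
})

test_that("gene sizes target the published mean/SD/max profile", {
  map <- generate_marker_map(n_snps = 24487, n_genes = 3205, seed = 2)
  sizes <- table(map$gene)
  expect_equal(sum(sizes), 24487L)
  expect_length(sizes, 3205L)
  expect_true(all(sizes >= 1 & sizes <= 231))
  expect_lt(abs(mean(sizes) - 7.64), 0.1)   # forced by totals
  expect_lt(abs(sd(sizes) - 14.0), 5)       # loosely targeted
})

test_that("functional map preserves published labels, MAFs and order", {
  fmap <- functional_marker_map()
  expect_equal(nrow(fmap), 160L)  # 39 + 72 + 51 minus the 2 shared variants
  expect_true(all(c("C4S1878", "C4S4935", "C14S3706") %in% fmap$snp_id))
  expect_equal(fmap$maf_ref[fmap$snp_id == "C4S1878"], 0.164993)
  incr <- tapply(fmap$pos, fmap$chrom, function(p) all(diff(p) > 0))
  expect_true(all(incr))
})

test_that("injection adds functional markers with labels and genes intact", {
  bg <- generate_marker_map(n_snps = 500, n_genes = 60, seed = 3)
  full <- inject_functional_markers(bg)
  expect_equal(nrow(full), 500L + 160L)
  expect_true(all(functional_marker_map()$snp_id %in% full$snp_id))
  expect_equal(full$gene[full$snp_id == "C4S1878"], "KDR")
  expect_false(any(duplicated(paste(full$chrom, full$pos))))
  incr <- tapply(full$pos, full$chrom, function(p) all(diff(p) > 0))
  expect_true(all(incr))
})

test_that("first-intersection gene assignment matches a brute-force scan", {
  map <- tiny_map(6)
  map$pos <- c(40, 100, 150, 151, 200, 999)
  genes <- data.frame(gene = c("A", "B"), chrom = 1L,
                      start = c(50, 90), end = c(150, 200))
  out <- assign_snps_to_genes(map, genes)
  # brute force oracle: first interval in table order containing pos
  oracle <- vapply(map$pos, function(p) {
    hit <- which(genes$start <= p & genes$end >= p)
    if (length(hit)) genes$gene[hit[1]] else NA_character_
  }, "")
  expect_equal(out$gene, oracle)
  # endpoint inclusive on both ends, overlap resolved to the first gene
  expect_equal(out$gene, c(NA, "A", "A", "B", "B", NA))
})

test_that("marker map TSV round-trips", {
  map <- generate_marker_map(n_snps = 100, n_genes = 20, seed = 4)
  map$gene[5] <- NA
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_marker_map(map, tmp)
  back <- read_marker_map(tmp)
  expect_equal(back$snp_id, map$snp_id)
  expect_equal(back$pos, map$pos)
  expect_equal(back$gene, map$gene)
})
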