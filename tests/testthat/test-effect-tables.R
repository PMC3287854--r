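tabs <- load_packaged_effect_tables()

test_that("packaged effect tables have the published dimensions and extrema", {
  expect_equal(nrow(tabs$Q1), 39L)
  expect_equal(length(unique(tabs$Q1$gene)), 9L)
  expect_equal(nrow(tabs$Q2), 72L)
  expect_equal(length(unique(tabs$Q2$gene)), 13L)
  expect_equal(nrow(tabs$LIABILITY), 51L)
  expect_equal(length(unique(tabs$LIABILITY$gene)), 15L)

  expect_equal(summarize_effects(tabs$LIABILITY)$maf_max, 0.258250)
  expect_equal(summarize_effects(tabs$Q1)$beta_max, 1.40529)
  # single minor-allele copy among 697 diploids
  expect_equal(min(tabs$Q1$maf), 0.000717)
  # 1-11 functional variants per gene for Q1
  expect_equal(range(summarize_effects(tabs$Q1)$snps_per_gene), c(1L, 11L))
})

test_that("all betas are positive and variant labels well-formed", {
  for (t in tabs) {
    expect_true(all(t$beta > 0))
    expect_true(all(t$maf > 0 & t$maf <= 0.5))
    expect_true(all(grepl("^C[0-9]+S[0-9]+$", t$snp)))
    expect_false(anyDuplicated(t$snp) > 0)
  }
})

test_that("Q1 and liability tables overlap in exactly the two ELAVL4 variants", {
  ov <- intersect(tabs$Q1$snp, tabs$LIABILITY$snp)
  expect_setequal(ov, c("C1S3181", "C1S3182"))
  expect_length(intersect(tabs$Q1$snp, tabs$Q2$snp), 0L)
  expect_equal(unique(tabs$Q1$gene[tabs$Q1$snp %in% ov]), "ELAVL4")
})

test_that("fixture files are unchanged (transcription drift guard)", {
  expect_equal(unname(tools::md5sum(effect_table_path("Q1"))),
               "a5a08d6c2d3c942ce965d2c136aae567")
  expect_equal(unname(tools::md5sum(effect_table_path("Q2"))),
               "add8aed7b595c17caa83c0910a69344d")
  expect_equal(unname(tools::md5sum(effect_table_path("LIABILITY"))),
               "30bcf72d8c96d711622869914dc287e2")
})

test_that("load/write/load round trip is exact and row order preserved", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_effect_table(tabs$Q2, tmp)
  again <- load_effect_table(tmp, "Q2")
  expect_equal(as.data.frame(again), as.data.frame(tabs$Q2))
  expect_identical(again$snp[1:3], c("C3S4834", "C3S4836", "C3S4856"))
})

test_that("malformed input is rejected with an informative error", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tsnp\tmaf\tbeta", "GENEA\tC1S1\t0.01\t0.5",
               "GENEA\tC1S2\t0.02"), tmp)
  expect_error(load_effect_table(tmp, "Q1"), "malformed.*line 3")

  writeLines(c("gene\tsnp\tmaf\tbeta", "GENEA\tC1S1\t0.01\t0.5",
               "GENEB\tC1S1\t0.02\t0.3"), tmp)
  expect_error(load_effect_table(tmp, "Q1"), "duplicate.*C1S1")

  writeLines(c("gene\tsnp\tmaf\tbeta", "GENEA\tC1S1\t0.01\t-0.5"), tmp)
  expect_error(load_effect_table(tmp, "Q1"), "> 0")

  writeLines(c("gene\tsnp\tmaf\tbeta", "GENEA\tbadid\t0.01\t0.5"), tmp)
  expect_error(load_effect_table(tmp, "Q1"), "C#S#")
})

test_that("empty table loads but cannot be summarized", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene\tsnp\tmaf\tbeta", tmp)
  empty <- load_effect_table(tmp, "Q1")
  expect_equal(nrow(empty), 0L)
  expect_error(summarize_effects(empty), "empty")
})

test_that("summarize_effects handles a singleton table", {
  one <- make_effect_table("KDR", "C4S1878", 0.164993, 0.149975)
  s <- summarize_effects(one)
  expect_equal(s$n_snps, 1L)
  expect_equal(s$n_genes, 1L)
  expect_equal(s$maf_min, s$maf_max)
})
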