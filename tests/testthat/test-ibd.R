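test_that("IBD values are in {0, 0.5, 1} with exact structural identities", {
  ped <- generate_pedigree_set(1, 30, 10, 4, seed = 1)
  nf <- sum(is_founder(ped))
  map <- tiny_map(6)
  map$gene <- rep(c("GA", "GB"), each = 3)
  fp <- generate_founder_haplotypes(rep(0.3, 6), nf, map, seed = 2)
  drop <- gene_drop(ped, fp, seed = 3)
  ibd <- ibd_matrices(drop, gene_midpoints(map))
  for (m in ibd) {
    expect_true(all(as.vector(m) %in% c(0, 0.5, 1)))
    expect_true(isSymmetric(unclass(m)))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
  }
  # founder pairs share nothing; parent-offspring exactly one allele
  founders <- ped$person_id[is_founder(ped)]
  expect_true(all(ibd[[1]][founders, founders][upper.tri(diag(nf))] == 0))
  kids <- ped[!is_founder(ped), ]
  for (j in seq_len(nrow(kids))) {
    expect_equal(ibd[[1]][kids$person_id[j], kids$father_id[j]], 0.5)
    expect_equal(ibd[[2]][kids$person_id[j], kids$mother_id[j]], 0.5)
  }
})

test_that("mean IBD sharing over many meioses matches 2*kinship", {
  ped <- relative_ped()
  kin <- kinship(ped)
  map <- tiny_map(3)
  map$gene <- "GA"
  H <- matrix(0L, 3, 8)
  fp <- panel_from_matrix(H, map)
  loci <- gene_midpoints(map)
  pairs <- list(sibs = c("C", "D"), avuncular = c("D", "F"),
                cousins = c("F", "H"))
  n_seeds <- 500
  pihat <- matrix(NA_real_, n_seeds, length(pairs),
                  dimnames = list(NULL, names(pairs)))
  for (s in seq_len(n_seeds)) {
    ib <- ibd_matrices(gene_drop(ped, fp, seed = s), loci)[[1]]
    for (p in names(pairs))
      pihat[s, p] <- ib[pairs[[p]][1], pairs[[p]][2]]
  }
  for (p in names(pairs)) {
    expected <- 2 * kin[pairs[[p]][1], pairs[[p]][2]]
    se <- sd(pihat[, p]) / sqrt(n_seeds)
    expect_lt(abs(mean(pihat[, p]) - expected), 3 * se + 1e-9)
  }
})

test_that("loci outside the map's chromosomes are rejected", {
  ped <- relative_ped()
  map <- tiny_map(3)
  fp <- panel_from_matrix(matrix(0L, 3, 8), map)
  drop <- gene_drop(ped, fp, seed = 1)
  expect_error(ibd_matrices(drop, data.frame(gene = "X", chrom = 9L, pos = 10)),
               "outside")
})

test_that("IBD matrices and long format are written and consistent", {
  ped <- generate_pedigree_set(2, 20, 8, 3, seed = 4)
  nf <- sum(is_founder(ped))
  map <- tiny_map(4)
  map$gene <- rep(c("GA", "GB"), each = 2)
  fp <- generate_founder_haplotypes(rep(0.2, 4), nf, map, seed = 5)
  drop <- gene_drop(ped, fp, seed = 6)
  ibd <- ibd_matrices(drop, gene_midpoints(map))
  dir <- withr::local_tempdir()
  write_ibd_matrices(ibd, dir, ped)
  expect_true(all(file.exists(file.path(dir, c("GA.txt", "GB.txt",
                                               "index.tsv", "ibd_long.tsv")))))
  long <- read.table(file.path(dir, "ibd_long.tsv"), header = TRUE)
  # long table restricted to within-family pairs, values match the matrices
  fam <- setNames(ped$family_id, ped$person_id)
  expect_true(all(fam[long$id1] == fam[long$id2]))
  i <- sample(nrow(long), 5)
  expect_equal(long$pi_hat[i],
               mapply(function(a, b, g) ibd[[g]][a, b],
                      long$id1[i], long$id2[i], long$gene[i]),
               ignore_attr = TRUE)
})
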