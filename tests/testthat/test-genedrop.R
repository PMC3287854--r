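make_drop <- function(n_markers = 40, ped = generate_pedigree_set(1, 30, 10, 4, seed = 1),
                      maf = 0.3, seed_panel = 2, seed_drop = 3, exact = FALSE) {
  map <- tiny_map(n_markers)
  nf <- sum(is_founder(ped))
  fp <- generate_founder_haplotypes(rep(maf, n_markers), nf, map,
                                    seed = seed_panel, exact = exact)
  list(ped = ped, panel = fp, drop = gene_drop(ped, fp, seed = seed_drop))
}

test_that("gene drop is Mendelian-consistent at every marker", {
  x <- make_drop()
  ped <- x$ped; H <- x$drop$panel$alleles
  fa <- match(ped$father_id, ped$person_id)
  mo <- match(ped$mother_id, ped$person_id)
  for (i in which(!is_founder(ped))) {
    pat <- H[, 2 * i - 1]; mat <- H[, 2 * i]
    expect_true(all(pat == H[, 2 * fa[i] - 1] | pat == H[, 2 * fa[i]]))
    expect_true(all(mat == H[, 2 * mo[i] - 1] | mat == H[, 2 * mo[i]]))
  }
  expect_true(all(dosage_matrix(x$drop$panel)$dosage %in% 0:2))
})

test_that("founder genotypes are reproduced unchanged", {
  x <- make_drop()
  fidx <- which(is_founder(x$ped))
  for (k in seq_along(fidx)) {
    expect_identical(x$drop$panel$alleles[, 2 * fidx[k] - 1],
                     x$panel$alleles[, 2 * k - 1])
    expect_identical(x$drop$panel$alleles[, 2 * fidx[k]],
                     x$panel$alleles[, 2 * k])
  }
})

test_that("monomorphic founder markers stay monomorphic (no mutation)", {
  ped <- generate_pedigree_set(1, 30, 10, 4, seed = 5)
  map <- tiny_map(10)
  H <- matrix(0L, 10, 20)
  H[1:5, ] <- 1L   # first five markers fixed for the minor allele
  fp <- panel_from_matrix(H, map)
  drop <- gene_drop(ped, fp, seed = 6)
  expect_true(all(drop$panel$alleles[1:5, ] == 1L))
  expect_true(all(drop$panel$alleles[6:10, ] == 0L))
})

test_that("each meiosis switches haplotype source at most once per chromosome", {
  ped <- generate_pedigree_set(1, 14, 6, 3, seed = 7)
  map <- tiny_map(30)
  fp <- generate_founder_haplotypes(rep(0.4, 30), 6, map, seed = 8)
  drop <- gene_drop(ped, fp, seed = 9)
  loci <- data.frame(gene = sprintf("L%02d", 1:30), chrom = 1L,
                     pos = map$pos)
  labs <- exomesim:::trace_founder_labels(drop, loci)
  for (i in which(!is_founder(ped))) {
    for (lab in list(labs$paternal[i, ], labs$maternal[i, ])) {
      expect_lte(sum(diff(lab) != 0), 1L)
    }
  }
})

test_that("a private founder allele can reach many copies in descendants", {
  ped <- generate_pedigree_set(1, 40, 12, 4, seed = 10)
  map <- tiny_map(1)
  H <- matrix(0L, 1, 24)
  H[1, 1] <- 1L  # single copy carried by the top founder couple's father
  fp <- panel_from_matrix(H, map)
  copies <- vapply(1:50, function(s)
    sum(gene_drop(ped, fp, seed = s)$panel$alleles), numeric(1))
  expect_gte(max(copies), 5)       # branching can amplify a private allele
  expect_true(all(copies >= 0))    # and it can also be lost
})

test_that("gene drop is deterministic and size mismatches error", {
  x1 <- make_drop(seed_drop = 42)
  x2 <- make_drop(seed_drop = 42)
  expect_identical(x1$drop$panel$alleles, x2$drop$panel$alleles)
  expect_identical(x1$drop$vectors, x2$drop$vectors)

  ped <- generate_pedigree_set(1, 30, 10, 4, seed = 1)
  small <- generate_founder_haplotypes(rep(0.3, 5), 4, tiny_map(5), seed = 1)
  expect_error(gene_drop(ped, small), "founders")
})
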