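# Small in-code fixtures shared across tests.

# marker map with n evenly spaced markers on one chromosome
tiny_map <- function(n, chrom = 1L, spacing = 1000L, gene = NA_character_) {
  structure(
    data.frame(snp_id = sprintf("C%dS%d", chrom, seq_len(n)),
               chrom = chrom, pos = spacing * seq_len(n),
               gene = gene, stringsAsFactors = FALSE),
    chrom_lengths = rep(250e6, 22),
    class = c("marker_map", "data.frame"))
}

# panel built from an explicit markers x (2 * n) allele matrix
panel_from_matrix <- function(H, map, ids = NULL) {
  n <- ncol(H) / 2L
  structure(list(alleles = H, map = map, n_individuals = n,
                 sample_ids = ids %||% sprintf("IND%04d", seq_len(n))),
            class = "haplotype_panel")
}

genotype_from_matrix <- function(D, map, ids = NULL) {
  dimnames(D) <- list(ids %||% sprintf("IND%04d", seq_len(nrow(D))),
                      map$snp_id)
  structure(list(dosage = D, map = map), class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built 4-generation pedigree: A,B founders; their children C,D marry
# E,F; grandchildren G (of C+E) and H (of D+F) marry I,J; great-grandchildren
# K (of G+I) and L (of H+J) are second cousins.
second_cousin_ped <- function() {
  ped <- data.frame(
    person_id = c("A", "B", "E", "F", "I", "J", "C", "D", "G", "H", "K", "L"),
    family_id = "FAM1",
    father_id = c(NA, NA, NA, NA, NA, NA, "A", "A", "C", "D", "G", "H"),
    mother_id = c(NA, NA, NA, NA, NA, NA, "B", "B", "E", "F", "I", "J"),
    sex       = c("M", "F", "F", "F", "F", "F", "M", "M", "M", "M", "M", "F"),
    stringsAsFactors = FALSE)
  ped$generation <- c(1L, 1L, 2L, 2L, 3L, 3L, 2L, 2L, 3L, 3L, 4L, 4L)
  ped$founder <- is.na(ped$father_id)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# sibs / avuncular / first cousins: A+B -> C,D; C+E -> F; D+G -> H
relative_ped <- function() {
  ped <- data.frame(
    person_id = c("A", "B", "E", "G", "C", "D", "F", "H"),
    family_id = "FAM1",
    father_id = c(NA, NA, NA, NA, "A", "A", "C", "D"),
    mother_id = c(NA, NA, NA, NA, "B", "B", "E", "G"),
    sex       = c("M", "F", "F", "F", "M", "M", "M", "F"),
    stringsAsFactors = FALSE)
  ped$generation <- c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L)
  ped$founder <- is.na(ped$father_id)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# effect table built inline
make_effect_table <- function(gene, snp, maf, beta, trait = "Q1") {
  structure(data.frame(gene = gene, snp = snp, maf = maf, beta = beta,
                       stringsAsFactors = FALSE),
            trait = trait, class = c("effect_table", "data.frame"))
}
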