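#' Generate a phased founder haplotype panel
#'
#' Draws fully phased haplotypes (no missing data) at the target MAFs. A
#' marker whose target MAF equals `1/(2 n)` is treated as private: exactly one
#' minor-allele copy is placed on a randomly chosen haplotype. Other markers
#' get independent per-haplotype Bernoulli draws at the target MAF, unless
#' `exact = TRUE`, in which case `round(2 n maf)` copies are placed on
#' distinct random haplotypes so that observed frequencies match the targets
#' by construction (used for effect-table variants, whose MAFs the phenotype
#' model must honor).
#'
#' @param mafs Target MAFs, one per marker of `map`, each in `(0, 0.5]`.
#' @param n_individuals Number of diploid founders.
#' @param map A `marker_map` with one row per element of `mafs`.
#' @param seed Integer seed; a fixed seed reproduces the panel exactly.
#' @param exact Place exact minor-allele counts instead of Bernoulli draws;
#'   either a single flag or a logical vector with one element per marker.
#' @return A `haplotype_panel`: list with `alleles` (markers x 2n integer
#'   matrix of 0 = major / 1 = minor), `map`, `n_individuals`, `sample_ids`.
#' @examples
#' map <- functional_marker_map()
#' panel <- generate_founder_haplotypes(map$maf_ref, 697, map, seed = 1,
#'                                      exact = TRUE)
#' @export
generate_founder_haplotypes <- function(mafs, n_individuals, map, seed = 1L,
                                        exact = FALSE) {
  m <- nrow(map)
  if (length(mafs) != m)
    stop("length(mafs) must equal the number of markers in map")
  if (any(mafs <= 0 | mafs > 0.5))
    stop("target MAFs must lie in (0, 0.5]")
  two_n <- 2L * n_individuals
  exact <- rep_len(as.logical(exact), max(m, 1L))
  set.seed(seed)
  if (m == 0L) {
    H <- matrix(integer(0), nrow = 0L, ncol = two_n)
  } else {
    H <- matrix(stats::rbinom(m * two_n, 1L, mafs), nrow = m)
    # private markers (target MAF = one copy) and exact-count markers get
    # their implied copy number placed on random distinct haplotypes
    fixed <- exact | abs(mafs - 1 / two_n) < 1e-12
    counts <- pmax(1L, as.integer(round(mafs * two_n)))
    for (i in which(fixed)) {
      H[i, ] <- 0L
      H[i, sample.int(two_n, counts[i])] <- 1L
    }
  }
  structure(list(
    alleles = H, map = map, n_individuals = n_individuals,
    sample_ids = sprintf("IND%04d", seq_len(n_individuals))
  ), class = "haplotype_panel")
}

#' Subset a haplotype panel by individual
#'
#' @param panel A `haplotype_panel`.
#' @param individuals Integer indices of individuals to keep.
#' @param sample_ids Optional replacement sample ids.
#' @return A `haplotype_panel` over the selected individuals.
#' @export
subset_panel <- function(panel, individuals, sample_ids = NULL) {
  cols <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  structure(list(
    alleles = panel$alleles[, cols, drop = FALSE],
    map = panel$map,
    n_individuals = length(individuals),
    sample_ids = sample_ids %||% panel$sample_ids[individuals]
  ), class = "haplotype_panel")
}

#' Dosage matrix from a haplotype panel
#'
#' Sums each individual's two haplotypes, yielding minor-allele dosages in
#' \{0, 1, 2\}.
#'
#' @param panel A `haplotype_panel`.
#' @return A `genotype_matrix`: list with `dosage` (individuals x markers,
#'   dimnames from sample ids and snp ids) and `map`.
#' @export
dosage_matrix <- function(panel) {
  H <- panel$alleles
  n <- panel$n_individuals
  odd <- seq(1L, by = 2L, length.out = n)
  D <- t(H[, odd, drop = FALSE] + H[, odd + 1L, drop = FALSE])
  dimnames(D) <- list(panel$sample_ids, panel$map$snp_id)
  structure(list(dosage = D, map = panel$map), class = "genotype_matrix")
}

#' Write a panel or dosage matrix as VCF v4.2
#'
#' Haplotype panels are written phased (`0|1`); genotype matrices unphased
#' (`0/1`). Alleles are arbitrary fixed nucleotides (REF = major = A,
#' ALT = minor = G); the gene assignment travels in `INFO/GENE`. Paths ending
#' in `.gz` are gzip-compressed.
#'
#' @param x A `haplotype_panel` or `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  phased <- inherits(x, "haplotype_panel")
  map <- x$map
  if (phased) {
    H <- x$alleles
    n <- x$n_individuals
    odd <- seq(1L, by = 2L, length.out = n)
    gt <- matrix(paste0(H[, odd, drop = FALSE], "|", H[, odd + 1L, drop = FALSE]),
                 nrow = nrow(map))
    ids <- x$sample_ids
  } else {
    D <- t(x$dosage)
    gt <- matrix(c("0/0", "0/1", "1/1")[D + 1L], nrow = nrow(map))
    ids <- rownames(x$dosage)
  }
  info <- ifelse(is.na(map$gene) | map$gene == ".", ".",
                 paste0("GENE=", map$gene))
  body <- cbind(map$chrom, map$pos, map$snp_id, "A", "G", ".", "PASS",
                info, "GT", gt)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=exomesim",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Assigned gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' Uses \pkg{vcfR} for parsing. Phased files (`|` separators) are returned as
#' a `haplotype_panel`; unphased files as a `genotype_matrix`.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A `haplotype_panel` or `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  info <- v@fix[, "INFO"]
  gene <- ifelse(grepl("GENE=", info),
                 sub(".*GENE=([^;]+).*", "\\1", info), NA_character_)
  map <- structure(
    data.frame(snp_id = fix[, "ID"], chrom = as.integer(fix[, "CHROM"]),
               pos = as.integer(fix[, "POS"]), gene = gene,
               stringsAsFactors = FALSE),
    chrom_lengths = hg18_chrom_lengths,
    class = c("marker_map", "data.frame"))
  gt <- vcfR::extract.gt(v)
  ids <- colnames(gt)
  phased <- all(grepl("|", gt[1L, ], fixed = TRUE))
  if (phased) {
    a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
    a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
    H <- matrix(0L, nrow = nrow(gt), ncol = 2L * ncol(gt))
    H[, seq(1L, by = 2L, length.out = ncol(gt))] <- a1
    H[, seq(2L, by = 2L, length.out = ncol(gt))] <- a2
    structure(list(alleles = H, map = map, n_individuals = ncol(gt),
                   sample_ids = ids), class = "haplotype_panel")
  } else {
    d <- matrix(as.integer(substr(gt, 1L, 1L)) +
                  as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
    D <- t(d)
    dimnames(D) <- list(ids, map$snp_id)
    structure(list(dosage = D, map = map), class = "genotype_matrix")
  }
}
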