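#' Drop founder haplotypes through a pedigree with recombination
#'
#' Assigns the phased panel haplotypes to the pedigree founders (in pedigree
#' row order) and transmits haplotypes down each meiosis. Every meiosis
#' recombines with exactly one obligate crossover per chromosome: a starting
#' grandparental phase is drawn at random and switched once at a position
#' drawn uniformly over the chromosome's bp extent. No mutation is introduced,
#' so founder genotypes are reproduced unchanged, every child allele traces to
#' a parental allele, and markers monomorphic among the founders stay
#' monomorphic in all descendants.
#'
#' @param ped A `pedigree` (rows in parent-before-child order; founders are
#'   matched to panel individuals in order of appearance).
#' @param founders A `haplotype_panel` with one individual per pedigree
#'   founder; markers must be sorted by chromosome and position.
#' @param seed Integer seed; fixed seed gives identical inheritance vectors
#'   and genotypes.
#' @return A `gene_drop` list: `panel` (a `haplotype_panel` over all pedigree
#'   members, sample ids = person ids), `vectors` (an `inheritance_vectors`
#'   data frame: `person_id`, `parent` (`"father"`/`"mother"`), `chrom`,
#'   `phase` (1 or 2, grandparental haplotype transmitted first), `xover`
#'   (crossover bp position)), and `founder_ids`.
#' @examples
#' ped <- generate_pedigree_set(1, 14, 6, 3, seed = 1)
#' map <- functional_marker_map()
#' fp <- generate_founder_haplotypes(map$maf_ref, 6, map, seed = 2, exact = TRUE)
#' drop <- gene_drop(ped, fp, seed = 3)
#' @export
gene_drop <- function(ped, founders, seed = 1L) {
  validate_pedigree(ped)
  map <- founders$map
  if (is.unsorted(order(map$chrom, map$pos)))
    stop("markers must be sorted by chromosome and position")
  fidx <- which(is_founder(ped))
  if (length(fidx) != founders$n_individuals)
    stop("panel has ", founders$n_individuals, " individuals but pedigree has ",
         length(fidx), " founders")
  n <- nrow(ped)
  m <- nrow(map)
  chroms <- unique(map$chrom)
  chrom_rows <- lapply(chroms, function(ch) which(map$chrom == ch))
  names(chrom_rows) <- as.character(chroms)
  lens <- attr(map, "chrom_lengths")
  chrom_len <- function(ch) {
    if (!is.null(lens) && ch <= length(lens)) lens[ch]
    else max(map$pos[map$chrom == ch]) + 1
  }

  H <- matrix(0L, nrow = m, ncol = 2L * n)
  for (k in seq_along(fidx)) {
    H[, 2L * fidx[k] - 1L] <- founders$alleles[, 2L * k - 1L]
    H[, 2L * fidx[k]] <- founders$alleles[, 2L * k]
  }

  fa <- match(ped$father_id, ped$person_id)
  mo <- match(ped$mother_id, ped$person_id)
  nonf <- which(!is_founder(ped))
  set.seed(seed)
  nrec <- length(nonf) * 2L * length(chroms)
  vec <- data.frame(
    person_id = character(nrec), parent = character(nrec),
    chrom = integer(nrec), phase = integer(nrec), xover = numeric(nrec),
    stringsAsFactors = FALSE)
  r <- 0L
  for (i in nonf) {
    for (role in c("father", "mother")) {
      p <- if (role == "father") fa[i] else mo[i]
      target <- if (role == "father") 2L * i - 1L else 2L * i
      for (ci in seq_along(chroms)) {
        ch <- chroms[ci]
        rows <- chrom_rows[[ci]]
        phase <- sample.int(2L, 1L)
        x <- stats::runif(1L, 0, chrom_len(ch))
        before <- map$pos[rows] <= x
        c1 <- 2L * p - 2L + phase
        c2 <- 2L * p - 2L + (3L - phase)
        H[rows[before], target] <- H[rows[before], c1]
        H[rows[!before], target] <- H[rows[!before], c2]
        r <- r + 1L
        vec$person_id[r] <- ped$person_id[i]
        vec$parent[r] <- role
        vec$chrom[r] <- ch
        vec$phase[r] <- phase
        vec$xover[r] <- x
      }
    }
  }
  class(vec) <- c("inheritance_vectors", "data.frame")
  panel <- structure(list(
    alleles = H, map = map, n_individuals = n,
    sample_ids = ped$person_id
  ), class = "haplotype_panel")
  structure(list(panel = panel, vectors = vec,
                 founder_ids = ped$person_id[fidx], ped = ped),
            class = "gene_drop")
}

# Founder-haplotype labels carried by every individual at arbitrary loci.
# Founders carry labels (2k-1, 2k); a child's label at a locus is read from
# the transmitting parent's haplotype chosen by the meiosis record (phase
# before the crossover, the other haplotype after). Returns two
# n_individuals x n_loci integer matrices (paternal, maternal label).
trace_founder_labels <- function(drop, loci) {
  ped <- drop$ped
  map <- drop$panel$map
  lens <- attr(map, "chrom_lengths")
  known <- unique(map$chrom)
  bad <- !(loci$chrom %in% known)
  if (any(bad))
    stop("locus outside any chromosome in the map: chrom ",
         paste(unique(loci$chrom[bad]), collapse = ", "))
  n <- nrow(ped)
  nl <- nrow(loci)
  fa <- match(ped$father_id, ped$person_id)
  mo <- match(ped$mother_id, ped$person_id)
  L1 <- matrix(NA_integer_, n, nl)
  L2 <- matrix(NA_integer_, n, nl)
  fidx <- which(is_founder(ped))
  for (k in seq_along(fidx)) {
    L1[fidx[k], ] <- 2L * k - 1L
    L2[fidx[k], ] <- 2L * k
  }
  vsplit <- split(seq_len(nrow(drop$vectors)),
                  paste(drop$vectors$person_id, drop$vectors$parent))
  vec <- drop$vectors
  for (i in which(!is_founder(ped))) {
    for (role in c("father", "mother")) {
      rows <- vsplit[[paste(ped$person_id[i], role)]]
      mpos <- match(loci$chrom, vec$chrom[rows])
      phase <- vec$phase[rows][mpos]
      xover <- vec$xover[rows][mpos]
      take_first <- ifelse(loci$pos <= xover, phase == 1L, phase == 2L)
      p <- if (role == "father") fa[i] else mo[i]
      lab <- ifelse(take_first, L1[p, ], L2[p, ])
      if (role == "father") L1[i, ] <- lab else L2[i, ] <- lab
    }
  }
  list(paternal = L1, maternal = L2)
}

#' Per-gene IBD-sharing matrices from fully informative markers
#'
#' At each gene locus every individual's two founder-haplotype labels are read
#' from the inheritance vectors at the gene's position (genes inherit
#' atomically: recombination is not allowed within a gene, so one label per
#' gene per haplotype). The IBD proportion for a pair is the number of label
#' matches divided by 2, giving values in \{0, 0.5, 1\} for non-inbred
#' pedigrees, with parent-offspring pairs at exactly 0.5 and founder pairs at
#' 0.
#'
#' @param drop A `gene_drop` result.
#' @param gene_loci Data frame with columns `gene`, `chrom`, `pos` (typically
#'   the gene's bp midpoint); see [gene_midpoints()].
#' @return Named list of symmetric matrices (person ids as dimnames), one per
#'   gene, each of class `ibd_matrix`.
#' @export
ibd_matrices <- function(drop, gene_loci) {
  labs <- trace_founder_labels(drop, gene_loci)
  ids <- drop$ped$person_id
  out <- vector("list", nrow(gene_loci))
  names(out) <- gene_loci$gene
  for (g in seq_len(nrow(gene_loci))) {
    p1 <- labs$paternal[, g]
    p2 <- labs$maternal[, g]
    share1 <- outer(p1, p1, "==") | outer(p1, p2, "==")
    share2 <- outer(p2, p1, "==") | outer(p2, p2, "==")
    pihat <- (share1 + share2) / 2
    dimnames(pihat) <- list(ids, ids)
    out[[g]] <- structure(pihat, gene = gene_loci$gene[g], class = c("ibd_matrix", "matrix"))
  }
  out
}

#' Gene midpoint loci of a marker map
#'
#' One locus per gene: the midpoint between the gene's first and last marker.
#'
#' @param map A `marker_map` with a `gene` column.
#' @return Data frame with columns `gene`, `chrom`, `pos`.
#' @export
gene_midpoints <- function(map) {
  keep <- !is.na(map$gene)
  sp <- split(which(keep), map$gene[keep])
  genes <- names(sp)
  data.frame(
    gene = genes,
    chrom = vapply(sp, function(i) map$chrom[i[1L]], integer(1)),
    pos = vapply(sp, function(i)
      as.numeric(round((min(map$pos[i]) + max(map$pos[i])) / 2)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write per-gene IBD matrices
#'
#' One whitespace-delimited square matrix file per gene under `dir`, plus an
#' index file (`gene` to filename) and a long-format TSV
#' (`id1`, `id2`, `gene`, `pi_hat`) over within-family pairs.
#'
#' @param ibd Named list of `ibd_matrix` from [ibd_matrices()].
#' @param dir Output directory (created if needed).
#' @param ped Optional `pedigree`; if given, the long table is restricted to
#'   pairs within the same family (cross-family sharing is identically 0).
#' @return Invisible data frame: the index (gene, file).
#' @export
write_ibd_matrices <- function(ibd, dir, ped = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.txt", names(ibd))
  for (g in seq_along(ibd)) {
    utils::write.table(format(ibd[[g]], digits = 3), file.path(dir, files[g]),
                       quote = FALSE, col.names = FALSE, row.names = TRUE)
  }
  index <- data.frame(gene = names(ibd), file = files)
  utils::write.table(index, file.path(dir, "index.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  long <- do.call(rbind, lapply(names(ibd), function(g) {
    m <- ibd[[g]]
    ut <- which(upper.tri(m), arr.ind = TRUE)
    d <- data.frame(id1 = rownames(m)[ut[, 1L]], id2 = colnames(m)[ut[, 2L]],
                    gene = g, pi_hat = m[ut])
    if (!is.null(ped)) {
      fam <- stats::setNames(ped$family_id, ped$person_id)
      d <- d[fam[d$id1] == fam[d$id2], , drop = FALSE]
    }
    d
  }))
  utils::write.table(long, file.path(dir, "ibd_long.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(index)
}
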