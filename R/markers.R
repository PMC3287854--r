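# Approximate autosome lengths (bp) on the NCBI36/hg18 assembly, used to lay
# out synthetic marker maps and to draw crossover positions.
hg18_chrom_lengths <- c(
  247249719, 242951149, 199501827, 191273063, 180857866, 170899992,
  158821424, 146274826, 140273252, 135374737, 134452384, 132349534,
  114142980, 106368585, 100338915,  88827254,  78774742,  76117153,
   63811651,  62435964,  46944323,  49691432
)

#' Generate a synthetic exome-style marker map
#'
#' Lays out `n_snps` biallelic markers across the 22 autosomes, grouped into
#' `n_genes` genes. Genes are allocated to chromosomes proportionally to
#' chromosome length; gene sizes (SNPs per gene) are drawn from a truncated
#' negative binomial targeting a mean near 7.6, an SD near 14 and a maximum of
#' 231, so most genes carry a handful of variants while a few carry hundreds.
#' Markers are labeled `C#S#` where the S-index is the marker's rank on its
#' chromosome (`C1S254` is the 254th SNP on chromosome 1).
#'
#' @param n_snps Total marker count (default 24487).
#' @param n_genes Total gene count (default 3205).
#' @param seed Integer seed.
#' @param chrom_lengths Autosome lengths in bp (default hg18).
#' @param gene_size_max Upper truncation for SNPs per gene (default 231).
#' @return A `marker_map`: data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based), `gene`, sorted by chromosome and position, with the gene
#'   interval table in `attr(, "gene_table")` and `attr(, "chrom_lengths")`.
#' @examples
#' map <- generate_marker_map(n_snps = 500, n_genes = 60, seed = 1)
#' head(map)
#' @export
generate_marker_map <- function(n_snps = 24487L, n_genes = 3205L, seed = 1L,
                                chrom_lengths = hg18_chrom_lengths,
                                gene_size_max = 231L) {
  stopifnot(n_snps >= n_genes, n_genes >= 1L)
  set.seed(seed)
  n_chrom <- length(chrom_lengths)

  # genes per chromosome, proportional with largest-remainder rounding
  raw <- n_genes * chrom_lengths / sum(chrom_lengths)
  g_per_chrom <- floor(raw)
  rem <- n_genes - sum(g_per_chrom)
  if (rem > 0) {
    up <- order(raw - g_per_chrom, decreasing = TRUE)[seq_len(rem)]
    g_per_chrom[up] <- g_per_chrom[up] + 1L
  }
  g_per_chrom <- pmax(g_per_chrom, 1L)
  while (sum(g_per_chrom) > n_genes) {
    i <- which.max(g_per_chrom); g_per_chrom[i] <- g_per_chrom[i] - 1L
  }

  # SNPs per gene: zero-truncated negative binomial, clipped at gene_size_max,
  # then nudged so the sizes sum exactly to n_snps
  sizes <- integer(0)
  while (length(sizes) < n_genes) {
    draw <- stats::rnbinom(2L * n_genes, size = 0.31, mu = 4.4)
    draw <- draw[draw >= 1L & draw <= gene_size_max]
    sizes <- c(sizes, draw)
  }
  sizes <- sizes[seq_len(n_genes)]
  delta <- n_snps - sum(sizes)
  while (delta != 0L) {
    i <- sample.int(n_genes, 1L)
    step <- sign(delta)
    if (sizes[i] + step >= 1L && sizes[i] + step <= gene_size_max) {
      sizes[i] <- sizes[i] + step
      delta <- delta - step
    }
  }

  gene_idx <- 0L
  maps <- vector("list", n_chrom)
  gene_rows <- vector("list", n_chrom)
  for (ch in seq_len(n_chrom)) {
    ng <- g_per_chrom[ch]
    if (ng == 0L) next
    sz <- sizes[gene_idx + seq_len(ng)]
    k <- sum(sz)
    pos <- sort(sample.int(chrom_lengths[ch] - 1L, k))
    gene_names <- sprintf("SYNG%04d", gene_idx + seq_len(ng))
    gene_of <- rep(gene_names, times = sz)
    ends <- cumsum(sz)
    starts <- ends - sz + 1L
    maps[[ch]] <- data.frame(
      snp_id = sprintf("C%dS%d", ch, seq_len(k)),
      chrom = ch, pos = pos, gene = gene_of,
      stringsAsFactors = FALSE
    )
    gene_rows[[ch]] <- data.frame(
      gene = gene_names, chrom = ch,
      start = pos[starts], end = pos[ends],
      stringsAsFactors = FALSE
    )
    gene_idx <- gene_idx + ng
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  structure(map,
            gene_table = do.call(rbind, gene_rows),
            chrom_lengths = chrom_lengths,
            class = c("marker_map", "data.frame"))
}

#' Marker map holding only the functional variants of the effect tables
#'
#' Builds a compact map containing the union of variants appearing in the
#' supplied effect tables, placed on the chromosome encoded in their `C#S#`
#' label at positions proportional to their S-index (so the within-chromosome
#' order of the published labels is preserved). This is the map the phenotype
#' model needs: background markers carry no effects.
#'
#' @param tables List of `effect_table`s (default: the three packaged tables).
#' @param bp_per_index Base pairs per S-index unit (default 1000).
#' @return A `marker_map` with one row per distinct functional variant and a
#'   `maf_ref` column carrying the table MAF.
#' @export
functional_marker_map <- function(tables = load_packaged_effect_tables(),
                                  bp_per_index = 1000L) {
  all <- do.call(rbind, lapply(tables, function(t)
    data.frame(gene = t$gene, snp = t$snp, maf = t$maf,
               stringsAsFactors = FALSE)))
  all <- all[!duplicated(all$snp), , drop = FALSE]
  m <- regmatches(all$snp, regexec("^C([0-9]+)S([0-9]+)$", all$snp))
  chrom <- vapply(m, function(x) as.integer(x[2L]), integer(1))
  sidx <- vapply(m, function(x) as.integer(x[3L]), integer(1))
  map <- data.frame(snp_id = all$snp, chrom = chrom,
                    pos = sidx * as.integer(bp_per_index),
                    gene = all$gene, maf_ref = all$maf,
                    stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$pos), , drop = FALSE]
  rownames(map) <- NULL
  lens <- hg18_chrom_lengths
  structure(map, chrom_lengths = lens,
            class = c("marker_map", "data.frame"))
}

#' Inject functional variants into a synthetic marker map
#'
#' Adds the effect-table variants to a background map generated by
#' [generate_marker_map()], keeping their published `C#S#` labels and gene
#' symbols. Positions are placed on the labeled chromosome in S-index order
#' (scaled to the chromosome length), nudged past any collisions. Auto-named
#' background markers keep their original labels, so after injection the
#' S-index-equals-rank rule holds for the background markers only; the
#' published functional labels take priority over renumbering.
#'
#' @param map A `marker_map` from [generate_marker_map()].
#' @param tables List of `effect_table`s.
#' @return The augmented `marker_map`, re-sorted by chromosome and position,
#'   with a `maf_ref` column (NA for background markers).
#' @export
inject_functional_markers <- function(map, tables = load_packaged_effect_tables()) {
  fun <- functional_marker_map(tables, bp_per_index = 1L)
  if (any(fun$snp_id %in% map$snp_id))
    map <- map[!map$snp_id %in% fun$snp_id, , drop = FALSE]
  lens <- attr(map, "chrom_lengths") %||% hg18_chrom_lengths
  out <- map
  out$maf_ref <- NA_real_
  add <- fun
  for (ch in unique(add$chrom)) {
    sel <- add$chrom == ch
    sidx <- add$pos[sel]                       # bp_per_index = 1: pos == S-index
    smax <- max(sidx)
    cand <- round(lens[ch] * sidx / (smax * 1.1))
    taken <- out$pos[out$chrom == ch]
    for (i in seq_along(cand)) {
      while (cand[i] %in% taken || (i > 1L && cand[i] <= cand[i - 1L]))
        cand[i] <- cand[i] + 1L
    }
    add$pos[sel] <- cand
  }
  res <- rbind(out, add)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, gene_table = attr(map, "gene_table"),
            chrom_lengths = lens,
            class = c("marker_map", "data.frame"))
}

#' Assign markers to genes by first intersection
#'
#' Each marker is assigned to the first gene interval, in table order, whose
#' 1-based inclusive span contains the marker position; markers contained in
#' no interval get `NA`. Markers overlapping several genes are thus assigned
#' to exactly one.
#'
#' @param map A `marker_map` (or data frame with `chrom`, `pos`).
#' @param genes Data frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based, inclusive on both ends).
#' @return `map` with its `gene` column (re)filled.
#' @export
assign_snps_to_genes <- function(map, genes) {
  assigned <- rep(NA_character_, nrow(map))
  for (i in seq_len(nrow(genes))) {
    hit <- is.na(assigned) &
      map$chrom == genes$chrom[i] &
      map$pos >= genes$start[i] & map$pos <= genes$end[i]
    assigned[hit] <- genes$gene[i]
  }
  map$gene <- assigned
  map
}

#' Write a marker map as BED-like TSV
#'
#' Columns: `chrom`, `pos`, `snp_id`, `gene`.
#'
#' @param map A `marker_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(
    data.frame(chrom = map$chrom, pos = map$pos, snp_id = map$snp_id,
               gene = ifelse(is.na(map$gene), ".", map$gene)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker map written by [write_marker_map()]
#'
#' @param path Input path.
#' @return A `marker_map`.
#' @export
read_marker_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  map <- data.frame(snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
                    gene = ifelse(d$gene == ".", NA_character_, d$gene),
                    stringsAsFactors = FALSE)
  structure(map, chrom_lengths = hg18_chrom_lengths,
            class = c("marker_map", "data.frame"))
}
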