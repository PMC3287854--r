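#' Load a per-variant effect table
#'
#' Reads a table of functional variants: one row per SNP, with the gene it
#' belongs to, its marker label (`C#S#`), its reference minor allele frequency,
#' and `beta`, the displacement of the trait mean per copy of the minor allele
#' (in units of the trait's residual standard deviation). The minor allele
#' always raises the trait mean, so every `beta` must be strictly positive.
#'
#' The package ships three such tables covering the quantitative risk factors
#' Q1 and Q2 and the latent disease liability; see [effect_table_path()].
#'
#' @param path Path to a tab- or comma-separated file with header columns
#'   `gene`, `snp`, `maf`, `beta`.
#' @param trait Trait label the table applies to: `"Q1"`, `"Q2"` or
#'   `"LIABILITY"`.
#' @return An `effect_table`: a data frame with columns `gene`, `snp`, `maf`,
#'   `beta` in file order, with the trait label stored as an attribute.
#' @examples
#' q1 <- load_effect_table(effect_table_path("Q1"), "Q1")
#' nrow(q1)   # 39 functional variants
#' @seealso [summarize_effects()], [write_effect_table()]
#' @export
load_effect_table <- function(path, trait = c("Q1", "Q2", "LIABILITY")) {
  trait <- match.arg(trait)
  if (!file.exists(path)) stop("effect table file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("effect table file is empty: ", path)
  sep <- if (grepl(",", lines[[1L]], fixed = TRUE)) "," else "\t"
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  if (!identical(tolower(trimws(header)), c("gene", "snp", "maf", "beta"))) {
    stop("expected header 'gene,snp,maf,beta', got: ", lines[[1L]])
  }
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  rows <- strsplit(body, sep, fixed = TRUE)
  bad <- which(lengths(rows) != 4L)
  if (length(bad)) {
    stop("malformed effect-table row at line ", bad[[1L]] + 1L, ": ",
         body[[bad[[1L]]]])
  }
  tab <- data.frame(
    gene = vapply(rows, `[[`, "", 1L),
    snp  = vapply(rows, `[[`, "", 2L),
    maf  = as.numeric(vapply(rows, `[[`, "", 3L)),
    beta = as.numeric(vapply(rows, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  badnum <- which(is.na(tab$maf) | is.na(tab$beta))
  if (length(badnum)) {
    stop("non-numeric maf/beta at line ", badnum[[1L]] + 1L, ": ",
         body[[badnum[[1L]]]])
  }
  validate_effect_table(tab)
  structure(tab, trait = trait, class = c("effect_table", "data.frame"))
}

validate_effect_table <- function(tab) {
  if (anyDuplicated(tab$snp)) {
    stop("duplicate snp id(s) within effect table: ",
         paste(unique(tab$snp[duplicated(tab$snp)]), collapse = ", "))
  }
  if (nrow(tab)) {
    if (any(tab$beta <= 0)) {
      stop("all effect sizes must be > 0 (minor allele raises the mean); ",
           "offending snp(s): ", paste(tab$snp[tab$beta <= 0], collapse = ", "))
    }
    if (any(tab$maf <= 0 | tab$maf > 0.5)) {
      stop("maf must lie in (0, 0.5]; offending snp(s): ",
           paste(tab$snp[tab$maf <= 0 | tab$maf > 0.5], collapse = ", "))
    }
    if (!all(grepl("^C[0-9]+S[0-9]+$", tab$snp))) {
      stop("snp ids must match the C#S# pattern; offending: ",
           paste(tab$snp[!grepl("^C[0-9]+S[0-9]+$", tab$snp)], collapse = ", "))
    }
  }
  invisible(tab)
}

#' Path to a packaged effect-table fixture
#'
#' @param trait `"Q1"`, `"Q2"` or `"LIABILITY"`.
#' @return File path of the packaged TSV.
#' @export
effect_table_path <- function(trait = c("Q1", "Q2", "LIABILITY")) {
  trait <- match.arg(trait)
  fname <- switch(trait,
                  Q1 = "q1_effects.tsv",
                  Q2 = "q2_effects.tsv",
                  LIABILITY = "liability_effects.tsv")
  system.file("extdata", fname, package = "exomesim", mustWork = TRUE)
}

#' Load all three packaged effect tables
#'
#' @return Named list with elements `Q1`, `Q2`, `LIABILITY`, each an
#'   `effect_table`.
#' @export
load_packaged_effect_tables <- function() {
  list(Q1 = load_effect_table(effect_table_path("Q1"), "Q1"),
       Q2 = load_effect_table(effect_table_path("Q2"), "Q2"),
       LIABILITY = load_effect_table(effect_table_path("LIABILITY"), "LIABILITY"))
}

#' Write an effect table to TSV
#'
#' Inverse of [load_effect_table()]; a load/write/load round trip reproduces
#' the table exactly (values are written with full precision).
#'
#' @param table An `effect_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(table, path) {
  out <- data.frame(gene = table$gene, snp = table$snp,
                    maf = format(table$maf, trim = TRUE, scientific = FALSE, drop0trailing = TRUE),
                    beta = format(table$beta, trim = TRUE, scientific = FALSE, drop0trailing = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize an effect table
#'
#' @param table An `effect_table` with at least one row.
#' @return A list with `n_snps`, `n_genes`, `maf_min`, `maf_max`, `beta_min`,
#'   `beta_max`, and `snps_per_gene` (named integer vector, table order of
#'   first appearance).
#' @examples
#' summarize_effects(load_effect_table(effect_table_path("Q1"), "Q1"))$n_genes
#' @export
summarize_effects <- function(table) {
  if (nrow(table) == 0L) stop("cannot summarize an empty effect table")
  genes <- unique(table$gene)
  per_gene <- vapply(genes, function(g) sum(table$gene == g), integer(1))
  list(
    n_snps = nrow(table),
    n_genes = length(genes),
    maf_min = min(table$maf), maf_max = max(table$maf),
    beta_min = min(table$beta), beta_max = max(table$beta),
    snps_per_gene = per_gene
  )
}
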