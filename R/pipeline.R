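#' Run the full simulation pipeline and write all artifacts
#'
#' End-to-end driver: builds (or reuses) the synthetic marker map with the
#' effect-table variants injected, generates the unrelated founder panel,
#' derives the family design by sampling pedigree founders from the unrelated
#' panel without replacement and gene-dropping their haplotypes, simulates
#' replicate phenotypes for the requested design(s), and writes every
#' artifact under `out_dir`:
#'
#' \preformatted{
#' out_dir/<design>/genotypes.vcf.gz   called genotypes (unphased dosages)
#' out_dir/<design>/markers.tsv        marker map
#' out_dir/family/pedigree.fam         PED/FAM pedigree
#' out_dir/family/ibd/<gene>.txt       per-gene IBD matrices (+ index, long TSV)
#' out_dir/<design>/pheno/replicate_###.csv  one CSV per replicate
#' out_dir/manifest.json               seeds, digests, counts
#' }
#'
#' Identical configuration, seed and package version give byte-identical
#' outputs. Per-gene IBD matrices are emitted for `ibd_genes` only (default:
#' the genes carrying functional variants); a square 697 x 697 matrix per
#' gene for thousands of background genes is rarely wanted and can be
#' requested explicitly.
#'
#' @param cfg A `trait_model_config` (or path to a YAML config).
#' @param out_dir Output directory, created if needed.
#' @param design `"unrelated"`, `"family"` or `"both"`.
#' @param n_replicates,seed Overrides of the config values.
#' @param n_individuals Individuals per design (default 697).
#' @param ped_args Arguments for [generate_pedigree_set()].
#' @param n_snps,n_genes Background marker map scale (defaults 24487 / 3205);
#'   set `n_snps = 0` to simulate with the functional variants only.
#' @param ibd_genes Character vector of genes to emit IBD matrices for,
#'   `"functional"` (default) or `"none"`.
#' @param emit_latent Include latent liability in the phenotype CSVs.
#' @return The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(cfg = default_config(), out_dir,
                         design = c("both", "unrelated", "family"),
                         n_replicates = NULL, seed = NULL,
                         n_individuals = 697L,
                         ped_args = list(n_families = 8L, n_total = 697L,
                                         n_founders = 202L,
                                         n_generations = 4L),
                         n_snps = 24487L, n_genes = 3205L,
                         ibd_genes = "functional", emit_latent = FALSE) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  viol <- validate_config(cfg)
  if (length(viol))
    stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  design <- match.arg(design)
  designs <- if (design == "both") c("unrelated", "family") else design
  n_rep <- as.integer(n_replicates %||% cfg$n_replicates)
  seed <- as.integer(seed %||% cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  tables <- load_packaged_effect_tables()
  if (n_snps > 0L) {
    bg <- generate_marker_map(n_snps, n_genes,
                              seed = derive_substream(seed, "map"))
    map <- inject_functional_markers(bg, tables)
  } else {
    map <- functional_marker_map(tables)
  }
  functional <- !is.na(map$maf_ref)
  mafs <- map$maf_ref
  if (any(!functional))
    mafs[!functional] <- sample_maf_spectrum(
      sum(!functional), n_individuals,
      seed = derive_substream(seed, "mafs"))
  panel <- generate_founder_haplotypes(
    mafs, n_individuals, map,
    seed = derive_substream(seed, "haplotypes"), exact = functional)

  manifest <- list(
    master_seed = seed,
    software_version = as.character(utils::packageVersion("exomesim")),
    n_replicates = n_rep,
    n_markers = nrow(map),
    replicate_seeds = vapply(seq_len(n_rep), function(r)
      derive_substream(seed, "replicate", r), integer(1)),
    designs = list()
  )
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(cfg, cfg_path)
  manifest$config_digest <- unname(tools::md5sum(cfg_path))
  for (tr in names(tables))
    write_effect_table(tables[[tr]],
                       file.path(out_dir, sprintf("effects_%s.tsv", tolower(tr))))

  write_design <- function(dir, g, sim, extra = list()) {
    dir.create(file.path(dir, "pheno"), recursive = TRUE, showWarnings = FALSE)
    write_vcf(g, file.path(dir, "genotypes.vcf.gz"))
    write_marker_map(g$map, file.path(dir, "markers.tsv"))
    for (r in seq_along(sim$replicates)) {
      d <- sim$replicates[[r]]
      out <- data.frame(ID = d$id, FAMID = ifelse(is.na(d$family_id), ".",
                                                  d$family_id),
                        SEX = d$sex, AGE = d$age, SMOKE = d$smoker,
                        Q1 = d$Q1, Q2 = d$Q2, Q4 = d$Q4,
                        AFFECTED = d$affected)
      if (emit_latent) {
        out$LATENT <- d$latent
        out$LIABILITY <- d$liability
      }
      utils::write.csv(out,
                       file.path(dir, "pheno",
                                 sprintf("replicate_%03d.csv", r)),
                       row.names = FALSE, quote = FALSE)
    }
    c(list(genotype_digest = sim$genotype_digest,
           n_individuals = nrow(g$dosage),
           affected_per_replicate =
             vapply(sim$replicates, function(d) sum(d$affected), integer(1))[1L]),
      extra)
  }

  if ("unrelated" %in% designs) {
    g <- dosage_matrix(panel)
    sim <- run_replicates(g, tables, cfg, design = "unrelated",
                          n_replicates = n_rep, seed = seed,
                          emit_latent = emit_latent)
    manifest$designs$unrelated <-
      write_design(file.path(out_dir, "unrelated"), g, sim)
  }

  if ("family" %in% designs) {
    ped <- do.call(generate_pedigree_set,
                   c(ped_args, list(seed = derive_substream(seed, "pedigree"))))
    n_founders <- sum(is_founder(ped))
    if (n_founders > n_individuals)
      stop("pedigree founders exceed the unrelated panel size")
    set.seed(derive_substream(seed, "founder-draw"))
    founders <- subset_panel(panel, sample.int(n_individuals, n_founders))
    drop <- gene_drop(ped, founders,
                      seed = derive_substream(seed, "genedrop"))
    g <- dosage_matrix(drop$panel)
    sim <- run_replicates(g, tables, cfg, design = "family", ped = ped,
                          n_replicates = n_rep, seed = seed,
                          emit_latent = emit_latent)
    fam_dir <- file.path(out_dir, "family")
    dir.create(fam_dir, recursive = TRUE, showWarnings = FALSE)
    write_ped(ped, file.path(fam_dir, "pedigree.fam"))
    ibd_info <- list(ibd_genes = character(0))
    if (!identical(ibd_genes, "none")) {
      genes <- if (identical(ibd_genes, "functional"))
        unique(map$gene[functional]) else ibd_genes
      loci <- gene_midpoints(map)
      loci <- loci[loci$gene %in% genes, , drop = FALSE]
      ibd <- ibd_matrices(drop, loci)
      write_ibd_matrices(ibd, file.path(fam_dir, "ibd"), ped)
      ibd_info$ibd_genes <- loci$gene
    }
    manifest$designs$family <-
      write_design(fam_dir, g, sim,
                   c(list(n_founders = n_founders), ibd_info))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
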