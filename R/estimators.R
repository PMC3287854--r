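#' Haseman-Elston heritability estimate
#'
#' Standardizes the trait (optionally after residualizing on covariates),
#' forms the cross-product `z_i * z_j` for every pair of individuals with
#' nonzero kinship, and regresses it on expected allele sharing `2 * phi`.
#' Under a purely additive polygenic model `E[z_i z_j] = 2 phi h2`, so the
#' slope estimates the (narrow-sense) heritability. Unrelated pairs carry no
#' information and are excluded to avoid diluting the slope.
#'
#' @param trait Numeric vector of per-individual trait values.
#' @param kin Kinship matrix over the same individuals (as from [kinship()]).
#' @param covariates Optional data frame of fixed-effect regressors (age,
#'   sex, smoking, SNP genetic values, ...); the trait is replaced by its
#'   least-squares residual on them before standardization.
#' @return List with `h2_hat` (slope clamped to `[0, 1]`), `slope` (raw),
#'   `se`, `n_pairs`.
#' @examples
#' ped <- generate_pedigree_set(1, 14, 6, 3, seed = 1)
#' kin <- kinship(ped)
#' # pure noise has heritability ~ 0
#' haseman_elston_h2(rnorm(13), kin)$h2_hat
#' @export
haseman_elston_h2 <- function(trait, kin, covariates = NULL) {
  stopifnot(length(trait) == nrow(kin))
  if (!is.null(covariates)) {
    trait <- stats::resid(stats::lm(trait ~ ., data = as.data.frame(covariates)))
  }
  z <- as.vector(scale(trait))
  pairs <- which(upper.tri(kin) & kin > 0, arr.ind = TRUE)
  if (nrow(pairs) < 1L)
    stop("no related pairs: Haseman-Elston regression is undefined ",
         "in an unrelated design")
  y <- z[pairs[, 1L]] * z[pairs[, 2L]]
  x <- 2 * kin[pairs]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2L])
  list(h2_hat = min(max(slope, 0), 1), slope = slope, se = se,
       n_pairs = nrow(pairs))
}

#' Estimate the genotype-by-smoking effect uplift
#'
#' Fits `trait ~ dosage + smoker + dosage:smoker` by least squares and
#' returns the interaction coefficient divided by the main dosage
#' coefficient: the proportional uplift of the per-allele effect in smokers.
#' Data simulated with a multiplicative GxE factor `m` have expected uplift
#' `m - 1` (0.5 under the default multiplier of 1.5).
#'
#' @param trait Numeric vector (Q1 values).
#' @param dosage Minor-allele dosages of the interacting variant.
#' @param smoker 0/1 smoking indicators.
#' @return List with `uplift`, `se` (delta-method), `coef` (fitted
#'   coefficients), `fit` (the `lm` object).
#' @export
gxe_ratio <- function(trait, dosage, smoker) {
  carriers <- dosage > 0
  if (!any(carriers & smoker == 1L) || !any(carriers & smoker == 0L))
    stop("need variant carriers in both smoking strata")
  fit <- stats::lm(trait ~ dosage * smoker)
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  main <- b[["dosage"]]
  inter <- b[["dosage:smoker"]]
  uplift <- inter / main
  # delta method on the ratio
  gr <- c(-inter / main^2, 1 / main)
  idx <- c("dosage", "dosage:smoker")
  se <- sqrt(as.vector(t(gr) %*% V[idx, idx] %*% gr))
  list(uplift = uplift, se = se, coef = b, fit = fit)
}

#' Check prevalence and affected-set overlap across replicates
#'
#' @param reps A `trait_replicates` object (or list of per-replicate data
#'   frames with columns `id` and `affected`).
#' @return List with `fractions` (per-replicate affected fraction),
#'   `all_equal` (are all fractions identical), and `jaccard` (pairwise
#'   Jaccard overlap of the affected id sets; identically 1 only for a
#'   degenerate, noise-free configuration).
#' @export
prevalence_check <- function(reps) {
  if (inherits(reps, "trait_replicates")) reps <- reps$replicates
  if (length(reps) < 2L) stop("need at least 2 replicates")
  fractions <- vapply(reps, function(r) mean(r$affected), numeric(1))
  sets <- lapply(reps, function(r) r$id[r$affected == 1L])
  k <- length(sets)
  jac <- numeric(0)
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      u <- length(union(sets[[i]], sets[[j]]))
      jac <- c(jac, if (u == 0L) 1 else
        length(intersect(sets[[i]], sets[[j]])) / u)
    }
  }
  list(fractions = fractions,
       all_equal = length(unique(fractions)) == 1L,
       jaccard = jac)
}

#' Heritability-recovery suite on freshly simulated family data
#'
#' Closes the loop on the trait model: builds the default family design
#' (8 extended families, 697 members, 202 founders), drops founder haplotypes
#' carrying the packaged effect-table variants, simulates replicates, and
#' recovers each trait's residual heritability by Haseman-Elston regression.
#' Q4 is residualized on age, sex and smoking; Q1 on its SNP genetic values
#' (including the smoking interaction) plus age and smoking; Q2 on its SNP
#' genetic values. With the default configuration the mean estimates recover
#' the configured 0.70 / 0.44 / 0.29.
#'
#' @param cfg A `trait_model_config`.
#' @param n_replicates Number of replicates to average over (default 100).
#' @param seed Master seed.
#' @param tables Effect tables (default: packaged).
#' @param ped_args List of arguments for [generate_pedigree_set()].
#' @return Data frame with columns `parameter`, `configured`, `estimated`
#'   (mean Haseman-Elston estimate), `se` (Monte-Carlo standard error of the
#'   mean), `n_replicates`.
#' @export
he_recovery <- function(cfg = default_config(), n_replicates = 100L,
                        seed = cfg$seed,
                        tables = load_packaged_effect_tables(),
                        ped_args = list(n_families = 8L, n_total = 697L,
                                        n_founders = 202L,
                                        n_generations = 4L)) {
  fmap <- functional_marker_map(tables)
  ped <- do.call(generate_pedigree_set,
                 c(ped_args, list(seed = derive_substream(seed, "pedigree"))))
  n_unrel <- max(ped_args$n_total, 2L * ped_args$n_founders)
  panel <- generate_founder_haplotypes(
    fmap$maf_ref, n_unrel, fmap,
    seed = derive_substream(seed, "panel"), exact = TRUE)
  set.seed(derive_substream(seed, "founder-draw"))
  founders <- subset_panel(panel, sample.int(n_unrel, ped_args$n_founders))
  drop <- gene_drop(ped, founders, seed = derive_substream(seed, "genedrop"))
  g <- dosage_matrix(drop$panel)
  kin <- kinship(ped)
  sim <- run_replicates(g, tables, cfg, design = "family", ped = ped,
                        kin = kin, n_replicates = n_replicates, seed = seed)
  cov <- sim$covariates
  est <- matrix(NA_real_, n_replicates, 3L,
                dimnames = list(NULL, c("Q4", "Q1", "Q2")))
  for (r in seq_len(n_replicates)) {
    rep_r <- sim$replicates[[r]]
    cov_r <- cov
    cov_r$smoker <- rep_r$smoker
    base_cov <- data.frame(age = cov$age, female = as.numeric(cov$sex == "F"),
                           smoker = rep_r$smoker)
    gval_q1 <- genetic_value("Q1", g, tables$Q1, cov_r, cfg)
    gval_q2 <- genetic_value("Q2", g, tables$Q2, cov_r, cfg)
    est[r, "Q4"] <- haseman_elston_h2(rep_r$Q4, kin, base_cov)$h2_hat
    est[r, "Q1"] <- haseman_elston_h2(
      rep_r$Q1, kin, cbind(base_cov, gval = gval_q1))$h2_hat
    est[r, "Q2"] <- haseman_elston_h2(
      rep_r$Q2, kin, data.frame(gval = gval_q2))$h2_hat
  }
  data.frame(
    parameter = c("h2_Q4", "h2_Q1_residual", "h2_Q2_residual"),
    configured = unname(cfg$h2_residual[c("Q4", "Q1", "Q2")]),
    estimated = colMeans(est)[c("Q4", "Q1", "Q2")],
    se = apply(est, 2L, stats::sd)[c("Q4", "Q1", "Q2")] / sqrt(n_replicates),
    n_replicates = n_replicates,
    row.names = NULL)
}

#' Simulate a large unrelated sample for the GxE interaction check
#'
#' Builds an unrelated cohort carrying only the common interacting variant
#' (KDR C4S1878, MAF 0.164993 by default), simulates Q1 under the given
#' configuration, and estimates the smoker effect uplift with [gxe_ratio()].
#'
#' @param n Cohort size (default 50000).
#' @param cfg A `trait_model_config`.
#' @param seed Integer seed.
#' @param snp,gene,maf,beta The interacting variant (defaults: the common
#'   KDR variant from the Q1 table).
#' @return The [gxe_ratio()] result, with the true uplift
#'   (`cfg$gxe_smoking_multiplier - 1`) attached as `truth`.
#' @export
gxe_recovery <- function(n = 50000L, cfg = default_config(), seed = cfg$seed,
                         snp = "C4S1878", gene = "KDR", maf = 0.164993,
                         beta = 0.149975) {
  table <- structure(
    data.frame(gene = gene, snp = snp, maf = maf, beta = beta,
               stringsAsFactors = FALSE),
    trait = "Q1", class = c("effect_table", "data.frame"))
  chrom <- as.integer(sub("^C([0-9]+)S.*$", "\\1", snp))
  map <- structure(
    data.frame(snp_id = snp, chrom = chrom, pos = 1000L, gene = gene,
               maf_ref = maf, stringsAsFactors = FALSE),
    chrom_lengths = hg18_chrom_lengths,
    class = c("marker_map", "data.frame"))
  panel <- generate_founder_haplotypes(maf, n, map,
                                       seed = derive_substream(seed, "gxe-panel"))
  g <- dosage_matrix(panel)
  vm <- build_variance_model(cfg)
  cov <- simulate_covariates(n = n, cfg = cfg,
                             seed = derive_substream(seed, "gxe-cov"))
  set.seed(derive_substream(seed, "gxe-draws"))
  poly <- simulate_polygenic(vm, n = n)
  env <- simulate_environment(vm, n = n)
  gvals <- cbind(Q1 = genetic_value("Q1", g, table, cov, cfg),
                 Q2 = 0, LATENT = 0)
  traits <- compose_traits(gvals, poly, env, cov, cfg)
  res <- gxe_ratio(traits$Q1, as.vector(g$dosage[, 1L]), cov$smoker)
  res$truth <- cfg$gxe_smoking_multiplier - 1
  res
}
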