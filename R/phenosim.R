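#' Simulate covariates (age, sex, smoking)
#'
#' Ages are drawn from a normal distribution truncated to `cfg$age_range`
#' (default 16-91 years) with the truncation-corrected centre chosen so the
#' mean is `cfg$age_mean` (default 41.8). For a family design, ages are
#' reassigned within each family so earlier generations are older. Sexes come
#' from the pedigree when one is given, otherwise they are drawn 50/50.
#' Smoking is an independent Bernoulli draw per individual at
#' `cfg$smoking_prevalence`; in replicate runs it is the only covariate that
#' is redrawn per replicate (age and sex stay fixed).
#'
#' @param n Number of unrelated individuals (ignored when `ped` is given).
#' @param cfg A `trait_model_config`.
#' @param seed Integer seed.
#' @param ped Optional `pedigree` for the family design.
#' @return A `covariate_set` data frame: `id`, `family_id` (NA for
#'   unrelateds), `sex`, `age`, `smoker`.
#' @export
simulate_covariates <- function(n = NULL, cfg = default_config(), seed = 1L,
                                ped = NULL) {
  prev <- cfg$smoking_prevalence
  if (prev < 0 || prev > 1) stop("smoking prevalence must lie in [0, 1]")
  set.seed(seed)
  if (!is.null(ped)) {
    ids <- ped$person_id
    fam <- ped$family_id
    sex <- ped$sex
    n <- nrow(ped)
  } else {
    if (is.null(n) || n <= 0) stop("n must be a positive count")
    ids <- sprintf("IND%04d", seq_len(n))
    fam <- NA_character_
    sex <- c("M", "F")[stats::rbinom(n, 1L, 0.5) + 1L]
  }
  age <- rtrunc_ages(n, cfg)
  if (!is.null(ped)) {
    # older generations get higher ages within each family
    for (f in unique(fam)) {
      rows <- which(fam == f)
      age[rows[order(ped$generation[rows])]] <- sort(age[rows], decreasing = TRUE)
    }
  }
  smoker <- stats::rbinom(n, 1L, prev)
  structure(data.frame(id = ids, family_id = fam, sex = sex, age = age,
                       smoker = smoker, stringsAsFactors = FALSE),
            class = c("covariate_set", "data.frame"))
}

rtrunc_ages <- function(n, cfg) {
  lo <- cfg$age_range[1]; hi <- cfg$age_range[2]
  sd <- cfg$age_sd
  trunc_mean <- function(centre) {
    a <- (lo - centre) / sd; b <- (hi - centre) / sd
    centre + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  centre <- stats::uniroot(function(c) trunc_mean(c) - cfg$age_mean,
                           c(lo - 2 * sd, hi + 2 * sd))$root
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 10L, centre, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  round(out[seq_len(n)])
}

#' Additive genetic value of a trait from its effect table
#'
#' Sums `beta * dosage` over the trait's functional variants. All effects are
#' additive: each copy of the minor allele shifts the trait mean by `beta`.
#' For Q1, effects of variants in the genotype-by-smoking gene (KDR by
#' default) are multiplied by `cfg$gxe_smoking_multiplier` (default 1.5) in
#' smokers; the table betas are the non-smoker effects.
#'
#' @param trait `"Q1"`, `"Q2"` or `"LIABILITY"`.
#' @param g A `genotype_matrix` containing every table variant.
#' @param table The trait's `effect_table`.
#' @param cov A `covariate_set` (used for smoking status).
#' @param cfg A `trait_model_config`.
#' @return Numeric vector of per-individual genetic values.
#' @examples
#' # one copy of C4S4935 and nothing else gives Q1 value 1.40529
#' @export
genetic_value <- function(trait, g, table, cov, cfg = default_config()) {
  cols <- match(table$snp, g$map$snp_id)
  if (anyNA(cols))
    stop("markers absent from genotype matrix: ",
         paste(table$snp[is.na(cols)], collapse = ", "))
  D <- g$dosage[, cols, drop = FALSE]
  value <- as.vector(D %*% table$beta)
  if (trait == "Q1") {
    kdr <- table$gene == cfg$gxe_gene
    if (any(kdr)) {
      kdr_val <- as.vector(D[, kdr, drop = FALSE] %*% table$beta[kdr])
      value <- value + (cfg$gxe_smoking_multiplier - 1) * kdr_val * cov$smoker
    }
  }
  value
}

#' Simulate correlated residual polygenic deviations
#'
#' Draws zero-mean multivariate normal deviations for (Q1, Q2, LATENT) with
#' cross-trait covariance `sigma_g` and between-individual covariance `2 *
#' kinship` (identity for unrelateds), i.e. the Kronecker product of the two.
#' Q4's polygenic deviation is drawn with variance `q4_h2` and the same
#' between-individual structure but uncorrelated with the other traits (its
#' genetic component owes nothing to the sequenced variants or the shared
#' pathway background).
#'
#' @param vm A `variance_model` from [build_variance_model()].
#' @param n Number of individuals (unrelated design).
#' @param kin Optional kinship matrix (family design).
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @param kin_chol Optional precomputed upper Cholesky factor of `2 * kin`.
#' @return Numeric matrix `n x 4` with columns `Q1`, `Q2`, `LATENT`, `Q4`.
#' @export
simulate_polygenic <- function(vm, n = NULL, kin = NULL, seed = NULL,
                               kin_chol = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(kin_chol) && !is.null(kin)) kin_chol <- kinship_chol(kin)
  if (is.null(n)) n <- if (!is.null(kin_chol)) ncol(kin_chol) else
    stop("either n or kin must be given")
  Z <- matrix(stats::rnorm(n * 4L), n, 4L)
  X3 <- Z[, 1:3, drop = FALSE] %*% vm$sqrt_g
  x4 <- Z[, 4L] * sqrt(vm$q4_h2)
  if (!is.null(kin_chol)) {
    X3 <- crossprod(kin_chol, X3)
    x4 <- as.vector(crossprod(kin_chol, x4))
  }
  out <- cbind(X3, x4)
  colnames(out) <- c("Q1", "Q2", "LATENT", "Q4")
  out
}

kinship_chol <- function(kin) {
  A <- 2 * kin
  ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) stop("kinship matrix is not positive semidefinite")
  chol(A + diag(1e-9, nrow(A)))
}

#' Simulate residual environmental deviations
#'
#' Independent across individuals; weakly correlated across (Q1, Q2, LATENT)
#' with covariance `sigma_e` (per-trait variance `1 - h2`). Q4's
#' environmental deviation has variance `1 - q4_h2`, uncorrelated with the
#' rest.
#'
#' @inheritParams simulate_polygenic
#' @return Numeric matrix `n x 4` with columns `Q1`, `Q2`, `LATENT`, `Q4`.
#' @export
simulate_environment <- function(vm, n, seed = NULL) {
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(n * 4L), n, 4L)
  out <- cbind(Z[, 1:3, drop = FALSE] %*% vm$sqrt_e,
               Z[, 4L] * sqrt(1 - vm$q4_h2))
  colnames(out) <- c("Q1", "Q2", "LATENT", "Q4")
  out
}

#' Compose the quantitative traits from their components
#'
#' Q1 = SNP genetic value + age and smoking effects + polygenic +
#' environmental deviation; Q2 = SNP genetic value + polygenic +
#' environmental (no covariates); Q4 = age, sex and smoking effects +
#' polygenic + environmental (no sequenced-SNP term); latent liability = SNP
#' genetic value + age and smoking effects + polygenic + environmental. Ages
#' are centred at the sample mean so covariate effects do not shift trait
#' means.
#'
#' @param gvals Matrix `n x 3` of SNP genetic values, columns `Q1`, `Q2`,
#'   `LATENT` (as from [genetic_value()]).
#' @param poly,env Matrices `n x 4` from [simulate_polygenic()] /
#'   [simulate_environment()].
#' @param cov A `covariate_set`.
#' @param cfg A `trait_model_config`.
#' @return Data frame with columns `Q1`, `Q2`, `Q4`, `latent`.
#' @export
compose_traits <- function(gvals, poly, env, cov, cfg = default_config()) {
  n <- nrow(cov)
  if (nrow(gvals) != n || nrow(poly) != n || nrow(env) != n)
    stop("component lengths disagree with the covariate set")
  cb <- function(trait, name) {
    b <- cfg$covariate_betas[[trait]]
    if (is.null(b) || length(b) == 0L) return(0)
    v <- b[name]
    if (length(v) == 0L || is.na(v)) 0 else unname(v)
  }
  age_c <- cov$age - mean(cov$age)
  female <- as.numeric(cov$sex == "F")
  smoker <- cov$smoker
  Q1 <- gvals[, "Q1"] + cb("Q1", "age") * age_c + cb("Q1", "smoke") * smoker +
    poly[, "Q1"] + env[, "Q1"]
  Q2 <- gvals[, "Q2"] + poly[, "Q2"] + env[, "Q2"]
  Q4 <- cb("Q4", "age") * age_c + cb("Q4", "female") * female +
    cb("Q4", "smoke") * smoker + poly[, "Q4"] + env[, "Q4"]
  latent <- gvals[, "LATENT"] + cb("LATENT", "age") * age_c +
    cb("LATENT", "smoke") * smoker + poly[, "LATENT"] + env[, "LATENT"]
  data.frame(Q1 = Q1, Q2 = Q2, Q4 = Q4, latent = latent)
}

#' Liability score and affection status
#'
#' The liability score is `latent + Q1 + Q2 - Q4` (Q4 is protective: raising
#' an individual's Q4 strictly lowers their liability). The top
#' `round(prevalence * N)` individuals by liability are declared affected, so
#' every replicate has exactly the same number of affected individuals while
#' their identities vary. Ties are broken by stable individual order.
#'
#' @param traits Data frame from [compose_traits()] (columns `Q1`, `Q2`,
#'   `Q4`, `latent`).
#' @param cfg A `trait_model_config` (uses `disease_prevalence`).
#' @return List with `liability` (numeric) and `affected` (integer 0/1).
#' @examples
#' # N = 697 at 30% prevalence flags exactly round(0.3 * 697) = 209 affected
#' @export
assign_affection <- function(traits, cfg = default_config()) {
  liability <- traits$latent + traits$Q1 + traits$Q2 - traits$Q4
  n <- length(liability)
  n_aff <- round(cfg$disease_prevalence * n)
  affected <- integer(n)
  if (n_aff > 0L) {
    ord <- order(-liability)           # radix sort: stable within ties
    affected[ord[seq_len(n_aff)]] <- 1L
  }
  list(liability = liability, affected = affected)
}

#' Run replicate phenotype simulations on a fixed genotype scaffold
#'
#' Genotypes, age and sex are held constant across replicates (the genotype
#' digest is recorded to assert this); smoking, the polygenic deviations and
#' the environmental deviations are redrawn each replicate from a
#' deterministic per-replicate substream of the master seed, so any replicate
#' can be reproduced in isolation.
#'
#' @param g A `genotype_matrix` for all study individuals.
#' @param tables Named list of effect tables (`Q1`, `Q2`, `LIABILITY`), as
#'   from [load_packaged_effect_tables()].
#' @param cfg A `trait_model_config`.
#' @param design `"unrelated"` or `"family"`.
#' @param ped A `pedigree` (required for the family design).
#' @param kin Optional kinship matrix (computed from `ped` if missing).
#' @param cov Optional `covariate_set` (simulated if missing).
#' @param n_replicates,seed Overrides of the config values.
#' @param emit_latent Keep the latent liability and liability score in the
#'   output (withheld by default, as analysis data sets would not contain
#'   them).
#' @return A `trait_replicates` object: list with `replicates` (list of
#'   per-replicate data frames: `id`, `family_id`, `sex`, `age`, `smoker`,
#'   `Q1`, `Q2`, `Q4`, `affected`), `covariates`, `genotype_digest`, `design`,
#'   `seed`, `cfg`.
#' @export
run_replicates <- function(g, tables = load_packaged_effect_tables(),
                           cfg = default_config(),
                           design = c("unrelated", "family"),
                           ped = NULL, kin = NULL, cov = NULL,
                           n_replicates = NULL, seed = NULL,
                           emit_latent = FALSE) {
  design <- match.arg(design)
  viol <- validate_config(cfg)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  n_rep <- as.integer(n_replicates %||% cfg$n_replicates)
  seed <- as.integer(seed %||% cfg$seed)
  n <- nrow(g$dosage)
  if (design == "family") {
    if (is.null(ped)) stop("family design requires a pedigree")
    if (is.null(kin)) kin <- kinship(ped)
    kin_chol <- kinship_chol(kin)
  } else {
    kin_chol <- NULL
  }
  vm <- build_variance_model(cfg)
  if (is.null(cov))
    cov <- simulate_covariates(n = n, cfg = cfg, ped = ped,
                               seed = derive_substream(seed, "covariates"))
  digest <- object_digest(g$dosage)

  # SNP genetic values: smoking-independent part once; KDR part re-scaled
  # per replicate when smoking is resampled
  base <- list(
    Q1 = genetic_value("Q1", g, tables$Q1, transform_smoker(cov, 0L), cfg),
    Q2 = genetic_value("Q2", g, tables$Q2, cov, cfg),
    LATENT = genetic_value("LIABILITY", g, tables$LIABILITY, cov, cfg)
  )
  kdr <- tables$Q1$gene == cfg$gxe_gene
  kdr_val <- if (any(kdr)) {
    cols <- match(tables$Q1$snp[kdr], g$map$snp_id)
    as.vector(g$dosage[, cols, drop = FALSE] %*% tables$Q1$beta[kdr])
  } else rep(0, n)

  reps <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(derive_substream(seed, "replicate", r))
    smoker <- if (isTRUE(cfg$resample_smoking))
      stats::rbinom(n, 1L, cfg$smoking_prevalence) else cov$smoker
    cov_r <- cov
    cov_r$smoker <- smoker
    poly <- simulate_polygenic(vm, n = n, kin_chol = kin_chol)
    env <- simulate_environment(vm, n = n)
    gvals <- cbind(
      Q1 = base$Q1 + (cfg$gxe_smoking_multiplier - 1) * kdr_val * smoker,
      Q2 = base$Q2, LATENT = base$LATENT)
    traits <- compose_traits(gvals, poly, env, cov_r, cfg)
    aff <- assign_affection(traits, cfg)
    out <- data.frame(
      id = cov$id, family_id = cov$family_id, sex = cov$sex, age = cov$age,
      smoker = smoker, Q1 = traits$Q1, Q2 = traits$Q2, Q4 = traits$Q4,
      affected = aff$affected, stringsAsFactors = FALSE)
    if (emit_latent) {
      out$latent <- traits$latent
      out$liability <- aff$liability
    }
    reps[[r]] <- out
  }
  structure(list(replicates = reps, covariates = cov, genotype_digest = digest,
                 design = design, seed = seed, cfg = cfg),
            class = "trait_replicates")
}

transform_smoker <- function(cov, value) {
  cov$smoker <- rep(value, nrow(cov))
  cov
}
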