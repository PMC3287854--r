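#' Default trait-model configuration
#'
#' Returns the configuration that defines the simulated phenotype model:
#' residual heritabilities, disease and smoking prevalences, the
#' genotype-by-smoking multiplier applied to KDR variants on Q1, covariate
#' effects, and the genetic/environmental cross-trait correlation matrices
#' over (Q1, Q2, LATENT).
#'
#' Traits live on the residual scale: for each trait the residual
#' (polygenic + environmental) variance is 1, split as `h2` polygenic and
#' `1 - h2` environmental. Defaults: Q1 residual heritability 0.44, Q2 0.29,
#' Q4 0.70 (Q4 has no sequenced-SNP effects at all), latent liability 0.35.
#' Disease prevalence is 0.30 (rank-based threshold), smoking prevalence 0.25,
#' and KDR effects on Q1 are multiplied by 1.5 in smokers.
#'
#' Covariate effect magnitudes and the off-diagonal correlations (genetic 0.5,
#' environmental 0.2) are package defaults chosen to respect the stated signs
#' and the "correlated"/"weakly correlated" structure; all are configurable.
#'
#' @param ... Named fields overriding the defaults, e.g.
#'   `default_config(n_replicates = 10, seed = 7)`.
#' @return A `trait_model_config` list.
#' @examples
#' cfg <- default_config(n_replicates = 2)
#' validate_config(cfg)   # character(0): valid
#' @export
default_config <- function(...) {
  rho_g <- matrix(0.5, 3, 3, dimnames = list(c("Q1", "Q2", "LATENT"),
                                             c("Q1", "Q2", "LATENT")))
  diag(rho_g) <- 1
  rho_e <- matrix(0.2, 3, 3, dimnames = dimnames(rho_g))
  diag(rho_e) <- 1
  cfg <- list(
    h2_residual = c(Q1 = 0.44, Q2 = 0.29, Q4 = 0.70, LATENT = 0.35),
    disease_prevalence = 0.30,
    smoking_prevalence = 0.25,
    gxe_smoking_multiplier = 1.5,
    gxe_gene = "KDR",
    covariate_betas = list(
      Q1 = c(age = 0.01, smoke = 0.3),
      Q2 = c(),
      Q4 = c(age = -0.01, female = -0.5, smoke = -0.3),
      LATENT = c(age = 0.01, smoke = 0.3)
    ),
    rho_g = rho_g,
    rho_e = rho_e,
    age_range = c(16, 91),
    age_mean = 41.8,
    age_sd = 15,
    resample_smoking = TRUE,
    n_replicates = 200L,
    seed = 42L
  )
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(override)] <- override
  }
  structure(cfg, class = "trait_model_config")
}

#' Validate a trait-model configuration
#'
#' Violations are returned as data, not raised: each element names the field
#' and the rule it breaks. An empty character vector means the configuration
#' is valid.
#'
#' @param cfg A `trait_model_config`, as from [default_config()] or
#'   [read_config()].
#' @return Character vector of violations (possibly empty).
#' @export
validate_config <- function(cfg) {
  v <- character(0)
  chk_frac <- function(x, name) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
      sprintf("%s: must lie in [0, 1]", name)
    else character(0)
  }
  v <- c(v, chk_frac(cfg$h2_residual, "h2_residual"),
         chk_frac(cfg$disease_prevalence, "disease_prevalence"),
         chk_frac(cfg$smoking_prevalence, "smoking_prevalence"))
  if (!is.numeric(cfg$gxe_smoking_multiplier) || cfg$gxe_smoking_multiplier <= 0)
    v <- c(v, "gxe_smoking_multiplier: must be > 0")
  for (nm in c("rho_g", "rho_e")) {
    m <- cfg[[nm]]
    if (!is.matrix(m) || nrow(m) != ncol(m)) {
      v <- c(v, sprintf("%s: must be a square matrix", nm)); next
    }
    if (any(abs(diag(m) - 1) > 1e-12))
      v <- c(v, sprintf("%s: diagonal must be 1", nm))
    if (any(abs(m - t(m)) > 1e-12))
      v <- c(v, sprintf("%s: must be symmetric", nm))
    if (any(m < -1 | m > 1))
      v <- c(v, sprintf("%s: entries must be correlations in [-1, 1]", nm))
    ev <- tryCatch(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
                   error = function(e) NA_real_)
    if (is.na(ev) || ev < -1e-8)
      v <- c(v, sprintf("%s: must be positive semidefinite", nm))
  }
  if (!is.numeric(cfg$n_replicates) || cfg$n_replicates < 1)
    v <- c(v, "n_replicates: must be a positive count")
  if (length(cfg$age_range) != 2L || cfg$age_range[1] >= cfg$age_range[2])
    v <- c(v, "age_range: must be an increasing pair")
  v
}

#' Read a configuration from YAML
#'
#' Fields present in the file override the defaults from [default_config()];
#' everything else keeps its default. Correlation matrices may be given as
#' lists of rows.
#'
#' @param path Path to a YAML file.
#' @return A `trait_model_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  as_mat <- function(x, template) {
    if (is.matrix(x)) return(x)
    m <- do.call(rbind, lapply(x, as.numeric))
    dimnames(m) <- dimnames(template)
    m
  }
  for (nm in names(raw)) {
    if (!nm %in% names(cfg)) stop("unknown config field in ", path, ": ", nm)
    val <- raw[[nm]]
    if (nm %in% c("rho_g", "rho_e")) val <- as_mat(val, cfg[[nm]])
    if (nm == "h2_residual") val <- unlist(val)
    if (nm == "covariate_betas") val <- lapply(val, unlist)
    cfg[[nm]] <- val
  }
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg A `trait_model_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$rho_g <- apply(cfg$rho_g, 1, as.numeric, simplify = FALSE)
  out$rho_e <- apply(cfg$rho_e, 1, as.numeric, simplify = FALSE)
  out$h2_residual <- as.list(cfg$h2_residual)
  out$covariate_betas <- lapply(cfg$covariate_betas, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build the trait variance model from a configuration
#'
#' Constructs the 3x3 genetic and environmental covariance matrices over
#' (Q1, Q2, LATENT) as `D %*% rho %*% D` with `D = diag(sqrt(h2))` (genetic)
#' and `D = diag(sqrt(1 - h2))` (environmental), so each trait's residual
#' variance is exactly 1. Q4's polygenic/environmental variances (0.70 / 0.30
#' by default) are carried separately: its genetic component is uncorrelated
#' with the other traits.
#'
#' @param cfg A `trait_model_config`.
#' @return A `variance_model` list with `sigma_g`, `sigma_e` (3x3 matrices),
#'   `q4_h2`, and the Cholesky-like square roots used for simulation.
#' @export
build_variance_model <- function(cfg) {
  viol <- validate_config(cfg)
  if (length(viol)) stop("invalid config: ", paste(viol, collapse = "; "))
  h2 <- cfg$h2_residual[c("Q1", "Q2", "LATENT")]
  dg <- diag(sqrt(h2), 3)
  de <- diag(sqrt(1 - h2), 3)
  sigma_g <- dg %*% cfg$rho_g %*% dg
  sigma_e <- de %*% cfg$rho_e %*% de
  dimnames(sigma_g) <- dimnames(sigma_e) <- dimnames(cfg$rho_g)
  structure(list(
    sigma_g = sigma_g, sigma_e = sigma_e,
    q4_h2 = unname(cfg$h2_residual["Q4"]),
    sqrt_g = psd_sqrt(sigma_g), sqrt_e = psd_sqrt(sigma_e)
  ), class = "variance_model")
}

# symmetric square root tolerant of semidefinite input (zero heritabilities)
psd_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}
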