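cfg <- default_config()
tabs <- load_packaged_effect_tables()

test_that("covariates respect support, mean age, and smoking prevalence", {
  cov <- simulate_covariates(n = 5000, cfg = cfg, seed = 1)
  expect_true(all(cov$age >= 16 & cov$age <= 91))
  expect_lt(abs(mean(cov$age) - 41.8), 1)
  expect_lt(abs(mean(cov$smoker) - 0.25), 0.02)
  # zero prevalence: everyone a nonsmoker
  cfg0 <- default_config(smoking_prevalence = 0)
  expect_true(all(simulate_covariates(n = 100, cfg = cfg0, seed = 2)$smoker == 0))
  # determinism
  expect_identical(simulate_covariates(n = 50, cfg = cfg, seed = 3),
                   simulate_covariates(n = 50, cfg = cfg, seed = 3))
  expect_error(simulate_covariates(n = 10,
                                   cfg = default_config(smoking_prevalence = 2)))
})

test_that("family covariates follow the pedigree and age with generation", {
  ped <- generate_pedigree_set(1, 87, 25, 4, seed = 1)
  cov <- simulate_covariates(cfg = cfg, seed = 2, ped = ped)
  expect_equal(cov$id, ped$person_id)
  expect_equal(cov$sex, ped$sex)
  m_age <- tapply(cov$age, ped$generation, mean)
  expect_true(all(diff(m_age) < 0))  # later generations younger
})

test_that("genetic values follow the effect tables additively", {
  fmap <- functional_marker_map(tabs)
  n <- 4
  D <- matrix(0, n, nrow(fmap))
  g <- genotype_from_matrix(D, fmap)
  cov <- data.frame(id = sprintf("I%d", 1:n), smoker = c(0, 0, 1, 1))
  # null genotypes give value 0 for everyone
  expect_equal(genetic_value("Q1", g, tabs$Q1, cov, cfg), rep(0, n))
  # one copy of the large-effect VEGFC variant gives exactly its beta
  D2 <- D; D2[2, which(fmap$snp_id == "C4S4935")] <- 1
  g2 <- genotype_from_matrix(D2, fmap)
  v <- genetic_value("Q1", g2, tabs$Q1, cov, cfg)
  expect_equal(v[2], 1.40529)
  # KDR carrier: nonsmoker gets beta, smoker gets 1.5x
  D3 <- D; D3[c(2, 3), which(fmap$snp_id == "C4S1878")] <- 1
  g3 <- genotype_from_matrix(D3, fmap)
  v3 <- genetic_value("Q1", g3, tabs$Q1, cov, cfg)
  expect_equal(v3[2], 0.149975)
  expect_equal(v3[3], 0.149975 * 1.5)
  expect_equal(v3[3], 0.2249625)
  # no uplift outside Q1
  v3b <- genetic_value("LIABILITY", g3, tabs$Q1, cov, cfg)
  expect_equal(v3b[3], 0.149975)
  # linearity in dosage
  D4 <- D3; D4[3, which(fmap$snp_id == "C4S1878")] <- 2
  v4 <- genetic_value("Q1", genotype_from_matrix(D4, fmap), tabs$Q1, cov, cfg)
  expect_equal(v4[3], 2 * v3[3])
  # missing markers are named in the error
  gsmall <- genotype_from_matrix(matrix(0, n, 1), fmap[1, ])
  expect_error(genetic_value("Q1", gsmall, tabs$Q1, cov, cfg), "C4S1878")
})

test_that("polygenic deviations have the configured covariance structure", {
  vm <- build_variance_model(cfg)
  # unrelated design: cross-trait correlation approaches rho_g
  X <- simulate_polygenic(vm, n = 60000, seed = 1)
  expect_lt(abs(cor(X[, "Q1"], X[, "Q2"]) - 0.5), 0.02)
  expect_lt(abs(var(X[, "Q1"]) - 0.44), 0.02)
  expect_lt(abs(var(X[, "Q4"]) - 0.70), 0.02)
  expect_lt(abs(cor(X[, "Q4"], X[, "Q1"])), 0.02)
  # zero heritability: deviations identically zero
  cfg0 <- default_config()
  cfg0$h2_residual[] <- 0
  X0 <- simulate_polygenic(build_variance_model(cfg0), n = 100, seed = 2)
  expect_equal(unname(X0), matrix(0, 100, 4), tolerance = 1e-12)
  # parent-offspring covariance ~ 0.5 * sigma_g under the kinship structure
  ped <- second_cousin_ped()
  kin <- kinship(ped)
  po <- replicate(4000, {
    X <- simulate_polygenic(vm, kin = kin)
    X[match("A", ped$person_id), "Q1"] * X[match("C", ped$person_id), "Q1"]
  })
  expect_lt(abs(mean(po) - 0.5 * 0.44), 3 * sd(po) / sqrt(4000))
})

test_that("environmental deviations are weakly correlated with variance 1-h2", {
  vm <- build_variance_model(cfg)
  E <- simulate_environment(vm, n = 60000, seed = 3)
  expect_lt(abs(var(E[, "Q1"]) - 0.56), 0.02)
  expect_lt(abs(var(E[, "Q2"]) - 0.71), 0.02)
  expect_lt(abs(cor(E[, "Q1"], E[, "Q2"]) - 0.2), 0.02)
  cfg0 <- default_config()
  cfg0$rho_e[1, 2] <- cfg0$rho_e[2, 1] <- 0
  E0 <- simulate_environment(build_variance_model(cfg0), n = 60000, seed = 4)
  expect_lt(abs(cor(E0[, "Q1"], E0[, "Q2"])), 0.02)
  expect_identical(simulate_environment(vm, n = 10, seed = 5),
                   simulate_environment(vm, n = 10, seed = 5))
})

test_that("trait composition follows the stated covariate structure", {
  n <- 20000
  cov <- simulate_covariates(n = n, cfg = cfg, seed = 6)
  vm <- build_variance_model(cfg)
  set.seed(7)
  poly <- simulate_polygenic(vm, n = n)
  env <- simulate_environment(vm, n = n)
  gvals <- cbind(Q1 = 0, Q2 = 0, LATENT = 0)[rep(1, n), ]
  tr <- compose_traits(gvals, poly, env, cov, cfg)
  # Q2 unaffected by age, sex, smoking
  f2 <- lm(tr$Q2 ~ cov$age + I(cov$sex == "F") + cov$smoker)
  expect_true(all(abs(coef(f2)[-1]) < 0.03))
  # Q1 higher in smokers, increases with age; Q4 lower in smokers/females
  expect_gt(coef(lm(tr$Q1 ~ cov$smoker))[2], 0.2)
  expect_gt(coef(lm(tr$Q1 ~ cov$age))[2], 0.005)
  expect_lt(mean(tr$Q4[cov$smoker == 1]) - mean(tr$Q4[cov$smoker == 0]), 0)
  expect_lt(mean(tr$Q4[cov$sex == "F"]) - mean(tr$Q4[cov$sex == "M"]), 0)
  # deterministic path: no noise, one variant copy -> Q1 equals beta
  cfgz <- default_config()
  cfgz$h2_residual[] <- 0
  cfgz$covariate_betas <- list(Q1 = c(), Q2 = c(), Q4 = c(), LATENT = c())
  cfgz$rho_g[] <- diag(3); cfgz$rho_e[] <- diag(3)
  vmz <- build_variance_model(cfgz)
  covz <- data.frame(id = "I1", family_id = NA, sex = "M", age = 40, smoker = 0)
  trz <- compose_traits(cbind(Q1 = 0.59, Q2 = 0, LATENT = 0),
                        matrix(0, 1, 4, dimnames = list(NULL, c("Q1","Q2","LATENT","Q4"))),
                        matrix(0, 1, 4, dimnames = list(NULL, c("Q1","Q2","LATENT","Q4"))),
                        covz, cfgz)
  expect_equal(trz$Q1, 0.59)
  expect_error(compose_traits(gvals[1:5, ], poly, env, cov, cfg), "disagree")
})

test_that("affection assignment is a rank-based 30% rule", {
  tr <- data.frame(Q1 = rnorm(697), Q2 = rnorm(697), Q4 = rnorm(697),
                   latent = rnorm(697))
  aff <- assign_affection(tr, cfg)
  expect_equal(sum(aff$affected), 209L)  # round(0.30 * 697)
  expect_equal(aff$liability, tr$latent + tr$Q1 + tr$Q2 - tr$Q4)
  expect_true(min(aff$liability[aff$affected == 1]) >=
                max(aff$liability[aff$affected == 0]))
  # raising Q4 alone strictly lowers liability (protective)
  tr2 <- tr; tr2$Q4[5] <- tr2$Q4[5] + 1
  expect_lt(assign_affection(tr2, cfg)$liability[5], aff$liability[5])
  # all-tied liabilities: the first round(p*N) in stable order are flagged
  tied <- data.frame(Q1 = 0, Q2 = 0, Q4 = 0, latent = rep(1, 10))
  aff_t <- assign_affection(tied, cfg)
  expect_equal(aff_t$affected, c(1, 1, 1, rep(0, 7)))
})

test_that("replicates fix genotype/age/sex and vary the random components", {
  fmap <- functional_marker_map(tabs)
  panel <- generate_founder_haplotypes(fmap$maf_ref, 697, fmap, seed = 8,
                                       exact = TRUE)
  g <- dosage_matrix(panel)
  sim <- run_replicates(g, tabs, cfg, design = "unrelated",
                        n_replicates = 4, seed = 9, emit_latent = TRUE)
  expect_length(sim$replicates, 4L)
  # same affected count everywhere, identities vary
  counts <- vapply(sim$replicates, function(r) sum(r$affected), integer(1))
  expect_true(all(counts == 209L))
  pc <- prevalence_check(sim)
  expect_true(pc$all_equal)
  expect_true(all(pc$jaccard < 1))
  # age/sex identical across replicates; smoking redrawn
  expect_identical(sim$replicates[[1]]$age, sim$replicates[[2]]$age)
  expect_identical(sim$replicates[[1]]$sex, sim$replicates[[2]]$sex)
  expect_false(identical(sim$replicates[[1]]$smoker,
                         sim$replicates[[2]]$smoker))
  # full determinism under the master seed
  sim2 <- run_replicates(g, tabs, cfg, design = "unrelated",
                         n_replicates = 4, seed = 9, emit_latent = TRUE)
  expect_identical(sim$replicates, sim2$replicates)
  expect_identical(sim$genotype_digest, sim2$genotype_digest)
  # liability recomputed from emitted columns
  r1 <- sim$replicates[[1]]
  expect_equal(r1$liability, r1$latent + r1$Q1 + r1$Q2 - r1$Q4)
})
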