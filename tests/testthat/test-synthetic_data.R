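test_that("component calibration hits the requested pattern", {
  p <- paths_for_components(c(A = 0.51, S = 0.10, T = 0.16, E = 0.23),
                            spousal_r = 0.597)
  got <- attr(p, "achieved")
  expect_equal(unname(got[c("A", "S", "T", "E", "r_sp")]),
               c(0.51, 0.10, 0.16, 0.23, 0.597), tolerance = 1e-5)
  expect_equal(unname(got[c("N", "P", "rGE")]), c(0, 0, 0),
               tolerance = 1e-6)
  expect_error(paths_for_components(c(A = 0.5)), "E share")
})

test_that("seeded simulations are bit-reproducible", {
  cfg <- sim_config(n_mz_families = 60, n_dz_families = 60, seed = 17)
  t1 <- simulate_population(cfg)
  t2 <- simulate_population(cfg)
  expect_identical(t1$ph_raw, t2$ph_raw)
  expect_identical(t1$ea_years, t2$ea_years)
  t3 <- simulate_population(sim_config(n_mz_families = 60,
                                       n_dz_families = 60, seed = 18))
  expect_false(identical(t1$ph_raw, t3$ph_raw))
})

test_that("the population reaches a stationary state under assortment", {
  cfg <- sim_config(n_mz_families = 4000, n_dz_families = 4000, seed = 23,
                    missing_father = 0, missing_sibling = 0,
                    missing_mother = 0)
  tab <- simulate_population(cfg)
  pr <- attr(tab, "provenance")
  v <- pr$phenotypic_variance
  drift <- abs(v[length(v)] - v[length(v) - 1]) / v[length(v)]
  expect_lt(drift, 0.02)
  expect_lt(abs(tail(pr$realized_spousal_r, 1) - 0.597), 0.03)
})

test_that("assortment induces spousal genetic correlation only under PA", {
  base <- c(A = 0.4, S = 0.15, T = 0.15, E = 0.3)
  cfg_pa <- sim_config(n_mz_families = 4000, n_dz_families = 4000,
                       components = base, target_spousal_r = 0.5,
                       seed = 41, missing_father = 0, missing_sibling = 0,
                       missing_mother = 0)
  pr_pa <- attr(simulate_population(cfg_pa), "provenance")
  # PA: spousal additive correlation approx target x broad heritability
  expect_lt(abs(tail(pr_pa$realized_spousal_gen_r, 1) - 0.5 * 0.4), 0.05)
  # SH on the same shares: environmentally driven, no genetic correlation
  p_sh <- path_params(a = 0.63, s = 0.39, t = 0.39, e = 0.55, mu = 0.8)
  cfg_sh <- sim_config(n_mz_families = 4000, n_dz_families = 4000,
                       mating = "social_homogamy", paths = p_sh,
                       target_spousal_r = 0.35, seed = 42,
                       missing_father = 0, missing_sibling = 0,
                       missing_mother = 0)
  pr_sh <- attr(simulate_population(cfg_sh), "provenance")
  expect_lt(abs(tail(pr_sh$realized_spousal_gen_r, 1)), 0.05)
  # nothing heritable to match on: no genetic correlation even under PA
  cfg0 <- sim_config(n_mz_families = 3000, n_dz_families = 3000,
                     paths = path_params(a = 1e-5, s = 0.55, t = 0.45,
                                         e = 0.7, mu = 1.1),
                     target_spousal_r = 0.6, seed = 43,
                     missing_father = 0, missing_sibling = 0,
                     missing_mother = 0)
  pr0 <- attr(simulate_population(cfg0), "provenance")
  expect_lt(abs(tail(pr0$realized_spousal_gen_r, 1)), 0.05)
})

test_that("random mating leaves unit additive variance and no spousal r", {
  cfg <- sim_config(n_mz_families = 4000, n_dz_families = 4000,
                    mating = "random",
                    paths = path_params(a = 0.7, s = 0.3, t = 0.4, e = 0.5),
                    seed = 51, missing_father = 0, missing_sibling = 0,
                    missing_mother = 0)
  tab <- simulate_population(cfg)
  pr <- attr(tab, "provenance")
  expect_lt(abs(tail(pr$realized_spousal_r, 1)), 0.04)
  expect_lt(abs(tail(pr$additive_variance, 1) - 1), 0.05)
})

test_that("an unreachable spousal target is reported, not silently missed", {
  # social homogamy cannot push the phenotype correlation past the
  # squared phenotype/latent correlation
  expect_error(
    simulate_population(
      sim_config(n_mz_families = 500, n_dz_families = 500,
                 mating = "social_homogamy",
                 paths = path_params(a = 0.9, s = 0.2, t = 0.2, e = 0.3,
                                     mu = 0.5),
                 target_spousal_r = 0.9, seed = 3)),
    "unreachable")
})

test_that("default simulation reproduces the reference dyad pattern", {
  cfg <- sim_config(n_mz_families = 6000, n_dz_families = 6000, seed = 61,
                    missing_father = 0, missing_sibling = 0,
                    missing_mother = 0)
  tab <- simulate_population(cfg)
  w <- family_wide(tab, value = "ph_raw")
  mz <- w$zygosity == "MZ"
  r_mz <- cor(w$Y[mz, "twin1"], w$Y[mz, "twin2"])
  r_dz <- cor(w$Y[!mz, "twin1"], w$Y[!mz, "twin2"])
  r_sib <- cor(w$Y[, "twin1"], w$Y[, "sibling"])
  expect_lt(abs(r_mz - 0.77), 0.025)
  expect_lt(abs(r_dz - 0.593), 0.03)
  # twin-sibling resemblance sits below DZ by about the T share
  expect_lt(abs((r_dz - r_sib) - 0.16), 0.045)
})

test_that("emitted tables match the reference descriptive shape", {
  tab <- simulate_population(sim_config(seed = 71))
  s <- summarize_families(tab)
  tot <- s[s$role == "total", ]
  expect_equal(tot$mean_ea, 13.9, tolerance = 0.25)
  expect_equal(tot$sd_ea, 3.1, tolerance = 0.25)
  expect_equal(s$pairs[s$role == "mz_twin"], 498)
  expect_equal(s$pairs[s$role == "dz_twin"], 439)
  # bookkeeping: rows = twins + retained siblings/parents
  expect_equal(tot$n, nrow(tab))
  expect_true(all(tab$age[tab$role == "father"] >= 44))
  expect_error(summarize_families(tab[0, ]), "empty")
})

test_that("the MVN sampler matches its target correlations and missingness", {
  # identity: everything uncorrelated
  I5 <- diag(5)
  fam0 <- sample_families_mvn(I5, I5, n_mz = 800, n_dz = 800,
                              missing_father = 0, missing_sibling = 0,
                              missing_mother = 0, seed = 5)
  w0 <- family_wide(fam0, value = "ea_std")
  cc <- cor(w0$Y)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.09)
  # reference matrix at study sizes: dyads within 3 SEs of print
  fam <- study_sample(seed = 6)
  dy <- dyad_correlations(fam, seed = 2023)
  ref <- ea_dyad_reference()
  for (d in intersect(dy$dyad, ref$dyad)) {
    r_true <- ref$r[ref$dyad == d]
    n <- dy$n_pairs[dy$dyad == d]
    expect_lt(abs(dy$r[dy$dyad == d] - r_true),
              3 * (1 - r_true^2) / sqrt(n))
  }
  # a rank-one "all ones" matrix degenerates to identical members
  ones <- matrix(1, 5, 5)
  fam1 <- sample_families_mvn(ones, ones, n_mz = 5, n_dz = 5,
                              missing_father = 0, missing_sibling = 0,
                              missing_mother = 0, seed = 7)
  spread <- tapply(fam1$ea_std, fam1$family_id, function(x) diff(range(x)))
  expect_true(all(spread < 1e-6))
  # a genuinely non-PSD matrix is rejected with its eigenvalue
  bad <- diag(5); bad[1, 2] <- bad[2, 1] <- 0.9; bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  expect_error(sample_families_mvn(bad, diag(5)), "eigenvalue")
})

test_that("simulator covariances agree with the model algebra", {
  # a focused PA-with-transmission case; the full grid runs in the
  # acceptance suite
  p <- path_params(a = 0.6, s = 0.25, t = 0.3, e = 0.55, m = 0.15,
                   mu = 0.35)
  spec <- model_spec("NTFD_PA", c("a", "s", "t", "e", "m", "mu"))
  eq <- solve_equilibrium(spec, p)
  r_sp <- implied_covariance(spec, p, eq, "DZ")["mother", "father"] / eq$V
  cfg <- sim_config(n_mz_families = 10000, n_dz_families = 10000,
                    paths = p, target_spousal_r = r_sp, seed = 81,
                    missing_father = 0, missing_sibling = 0,
                    missing_mother = 0)
  tab <- simulate_population(cfg)
  w <- family_wide(tab, value = "ph_raw")
  for (z in c("MZ", "DZ")) {
    Y <- w$Y[w$zygosity == z, ]
    emp <- cov(Y)
    th <- implied_covariance(spec, p, eq, z)
    se <- sqrt((outer(diag(th), diag(th)) + th^2) / nrow(Y))
    expect_lt(max(abs((emp - th) / se)), 3.6)
  }
})
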