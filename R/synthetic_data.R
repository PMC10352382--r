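#' Published dyadic EA correlations from the German twin-family panel
#'
#' Reference Pearson correlations for years of education between family
#' members in the 1990-93 birth cohort of the German twin-family panel
#' (MZ/DZ twin pairs, their nearest sibling, and both parents), with pair
#' counts. These serve as calibration targets for the synthetic-data
#' generators.
#'
#' @return Data.frame with columns `dyad`, `r`, `n_pairs`.
#' @export
ea_dyad_reference <- function() {
  utils::read.csv(system.file("extdata", "ea_dyad_correlations.csv",
                              package = "twinfam", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Reference per-role descriptive statistics
#'
#' Counts, sex composition, age ranges and years-of-education means/SDs
#' per family role in the reference sample; used as the simulator's
#' default scaling targets.
#'
#' @return Data.frame with one row per role plus a `total` row.
#' @export
ea_role_reference <- function() {
  utils::read.csv(system.file("extdata", "ea_role_descriptives.csv",
                              package = "twinfam", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Assemble the 5x5 family correlation matrix from dyad correlations
#'
#' @param zygosity `"MZ"` or `"DZ"`: which twin-pair correlation fills the
#'   twin1-twin2 cell.
#' @param dyads Data.frame as [ea_dyad_reference()].
#' @return 5x5 correlation matrix over
#'   `c("twin1","twin2","sibling","mother","father")`.
#' @export
dyad_correlation_matrix <- function(zygosity = c("MZ", "DZ"),
                                    dyads = ea_dyad_reference()) {
  zygosity <- match.arg(zygosity)
  g <- function(d) dyads$r[match(d, dyads$dyad)]
  R <- diag(5)
  dimnames(R) <- list(FAMILY_ROLES, FAMILY_ROLES)
  R["twin1", "twin2"] <- if (zygosity == "MZ") g("mz_twins") else g("dz_twins")
  R["twin1", "sibling"] <- R["twin2", "sibling"] <- g("sibling_twin")
  R["twin1", "mother"] <- R["twin2", "mother"] <- g("mother_twin")
  R["sibling", "mother"] <- g("mother_sibling")
  R["twin1", "father"] <- R["twin2", "father"] <- g("father_twin")
  R["sibling", "father"] <- g("father_sibling")
  R["mother", "father"] <- g("parents")
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

#' Solve raw path coefficients for target standardized components
#'
#' Inverts the equilibrium standardization: finds raw paths (a, n, s, t,
#' e, m, mu) whose equilibrium standardized variance shares and spousal
#' phenotypic correlation match the requested targets. Used to calibrate
#' the simulator to a fitted model's component pattern.
#'
#' @param components Named vector with entries among `A`, `N`, `S`, `T`,
#'   `P`, `E` (proportions; omitted entries are taken as zero). Any
#'   passive-rGE share is implied, not targeted.
#' @param spousal_r Target spousal phenotypic correlation.
#' @param design `"NTFD_PA"` or `"NTFD_SH"`.
#' @param nonadditive `"dominance"` or `"epistasis"`.
#' @return A [path_params()] vector; attribute `"achieved"` holds the
#'   realized components and spousal correlation.
#' @examples
#' p <- paths_for_components(c(A = 0.51, S = 0.10, T = 0.16, E = 0.23),
#'                           spousal_r = 0.597)
#' @export
paths_for_components <- function(components, spousal_r = 0,
                                 design = c("NTFD_PA", "NTFD_SH"),
                                 nonadditive = "dominance") {
  design <- match.arg(design)
  full <- c(A = 0, N = 0, S = 0, T = 0, P = 0, E = 0)
  bad <- setdiff(names(components), names(full))
  if (length(bad)) stop("unknown components: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  full[names(components)] <- components
  if (full[["E"]] <= 0) stop("E share must be positive", call. = FALSE)
  use_m <- full[["P"]] > 0
  free <- c("a", "n", "s", "t", "e", "mu", if (use_m) "m")
  free <- free[c(full[c("A", "N", "S", "T")] > 0, TRUE, spousal_r > 0,
                 rep(use_m, use_m))]
  spec <- model_spec(design, free_paths = union(free, "e"),
                     nonadditive = nonadditive)

  unpack <- function(th) {
    v <- c(a = 0, n = 0, s = 0, t = 0, e = 1, m = 0, mu = 0)
    v[spec$free_paths] <- th
    do.call(path_params, as.list(v))
  }
  target <- c(full, r_sp = spousal_r)
  obj <- function(th) {
    p <- tryCatch(unpack(th), error = function(e) NULL)
    if (is.null(p)) return(1e6)
    eq <- tryCatch(solve_equilibrium(spec, p), error = function(e) NULL)
    if (is.null(eq)) return(1e6)
    sc <- standardize_components(spec, p, eq)
    S <- implied_covariance(spec, p, eq, "DZ")
    got <- c(sc[c("A", "N", "S", "T", "P", "E")],
             r_sp = unname(S["mother", "father"] / eq$V))
    sum((got - target)^2)
  }
  # mu is the copath on the raw-variance scale (spousal r = mu * V under
  # PA), so feasible starts scale the target down by a guess at V
  opt <- NULL
  for (mu_scale in c(0.7, 0.45, 0.25, 1)) {
    start <- c(a = sqrt(full[["A"]]), n = sqrt(full[["N"]]),
               s = sqrt(full[["S"]]), t = sqrt(full[["T"]]),
               e = sqrt(full[["E"]]), m = 0.1,
               mu = mu_scale * spousal_r)[spec$free_paths]
    o <- stats::optim(start, obj, control = list(maxit = 5000,
                                                 reltol = 1e-15))
    o <- tryCatch(stats::optim(o$par, obj, method = "BFGS",
                               control = list(maxit = 2000,
                                              reltol = 1e-15)),
                  error = function(e) o)
    if (is.null(opt) || o$value < opt$value) opt <- o
    if (opt$value < 1e-12) break
  }
  if (opt$value > 1e-10) {
    stop("could not match the requested component pattern (residual ",
         format(opt$value), "); the targets may be infeasible at equilibrium",
         call. = FALSE)
  }
  p <- unpack(abs_variance_paths(opt$par, spec))
  eq <- solve_equilibrium(spec, p)
  sc <- standardize_components(spec, p, eq)
  S <- implied_covariance(spec, p, eq, "DZ")
  attr(p, "achieved") <- c(sc, r_sp = unname(S["mother", "father"] / eq$V))
  attr(p, "spec") <- spec
  p
}

# variance-scale paths enter the algebra squared; flip signs to the
# positive branch for reporting
abs_variance_paths <- function(th, spec) {
  vs <- intersect(names(th), c("a", "n", "s", "t", "e"))
  th[vs] <- abs(th[vs])
  th
}

#' Simulation configuration for the forward-time family simulator
#'
#' Defaults emulate the reference German twin-family sample: 498 MZ and
#' 439 DZ twin families (birth cohort 1990-93) with at most one
#' near-in-age sibling and both parents; dyadic correlations calibrated
#' to the best-fitting phenotypic-assortment model of years of education
#' (standardized A = 0.51, S = 0.10, T = 0.16, E = 0.23, spousal r =
#' 0.597, no phenotypic transmission); fathers missing at 45%, siblings
#' at 78%, mothers at 8% (the observed absence rates); years of education
#' scaled to the per-role means/SDs and ages drawn from the per-role
#' ranges of the reference sample.
#'
#' @param n_mz_families,n_dz_families Numbers of MZ and DZ twin families.
#' @param generations Forward generations simulated before families are
#'   emitted (default 10, enough to reach the assortment equilibrium).
#' @param mating `"phenotypic_assortment"`, `"social_homogamy"`, or
#'   `"random"`.
#' @param target_spousal_r Spousal phenotypic correlation the mate
#'   matching is calibrated to.
#' @param components Standardized variance components (see
#'   [paths_for_components()]).
#' @param nonadditive `"dominance"` or `"epistasis"`.
#' @param paths Optional explicit [path_params()]; overrides
#'   `components`/`target_spousal_r` calibration.
#' @param missing_father,missing_sibling,missing_mother Missing-completely-
#'   at-random absence rates.
#' @param role_stats Data.frame as [ea_role_reference()].
#' @param discretize_ea Round emitted years of education to whole years
#'   (off by default; the analysis treats EA as continuous).
#' @param seed Integer seed; all randomness flows from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_mz_families = 498, n_dz_families = 439,
                       generations = 10,
                       mating = c("phenotypic_assortment", "social_homogamy",
                                  "random"),
                       target_spousal_r = 0.597,
                       components = c(A = 0.51, S = 0.10, T = 0.16, E = 0.23),
                       nonadditive = c("dominance", "epistasis"),
                       paths = NULL,
                       missing_father = 0.45, missing_sibling = 0.78,
                       missing_mother = 0.08,
                       role_stats = ea_role_reference(),
                       discretize_ea = FALSE,
                       seed = 1L) {
  mating <- match.arg(mating)
  nonadditive <- match.arg(nonadditive)
  rates <- c(missing_father, missing_sibling, missing_mother)
  if (any(rates < 0 | rates > 1)) stop("missing rates must lie in [0, 1]",
                                       call. = FALSE)
  if (is.null(paths)) {
    design <- if (mating == "social_homogamy") "NTFD_SH" else "NTFD_PA"
    paths <- paths_for_components(components,
                                  spousal_r = if (mating == "random") 0
                                              else target_spousal_r,
                                  design = design,
                                  nonadditive = nonadditive)
  }
  structure(list(n_mz_families = n_mz_families,
                 n_dz_families = n_dz_families,
                 generations = generations, mating = mating,
                 target_spousal_r = target_spousal_r,
                 paths = paths, nonadditive = nonadditive,
                 r_n_sib = if (nonadditive == "dominance") 0.25 else 0,
                 missing_father = missing_father,
                 missing_sibling = missing_sibling,
                 missing_mother = missing_mother,
                 role_stats = role_stats,
                 discretize_ea = discretize_ea,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw offspring latents for k children per couple given parent A and
# phenotype vectors; returns list of per-child latent data.frames
offspring_latents <- function(A_f, A_m, Ph_f, Ph_m, p, r_n_sib, n_children) {
  n_fam <- length(A_f)
  N_fam <- stats::rnorm(n_fam)
  S_fam <- stats::rnorm(n_fam)
  P_fam <- p[["m"]] * (Ph_f + Ph_m)
  mid_A <- 0.5 * (A_f + A_m)
  lapply(seq_len(n_children), function(i) {
    A <- mid_A + stats::rnorm(n_fam, sd = sqrt(0.5))
    N <- sqrt(r_n_sib) * N_fam + sqrt(1 - r_n_sib) * stats::rnorm(n_fam)
    list(A = A, N = N, S = S_fam, P = P_fam)
  })
}

phenotype_from <- function(lat, p, T_lat, E_lat) {
  p[["a"]] * lat$A + p[["n"]] * lat$N + p[["s"]] * lat$S + lat$P +
    p[["t"]] * T_lat + p[["e"]] * E_lat
}

# rank-match two pools on a key plus calibrated Gaussian noise so the
# realized spousal *phenotype* correlation hits the target
match_spouses <- function(key_f, key_m, ph_f, ph_m, target, tol = 0.005) {
  n <- length(key_f)
  ord_m <- order(key_m)
  Z <- stats::rnorm(n)   # one noise draw, rescaled during calibration, so
                         # the bisection target function is deterministic
  pair_at <- function(sigma) {
    ord_m[rank(key_f + sigma * Z, ties.method = "first")]
  }
  realized <- function(sigma) stats::cor(ph_f, ph_m[pair_at(sigma)])
  sd_key <- max(stats::sd(key_f), 1e-12)
  r_max <- realized(0)
  if (r_max < target - 0.02) {
    stop(sprintf(
      "target spousal correlation %.3f unreachable; maximum realized %.3f",
      target, r_max), call. = FALSE)
  }
  lo <- 0; hi <- 50 * sd_key
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- realized(mid)
    if (abs(r - target) < tol) return(pair_at(mid))
    if (r > target) lo <- mid else hi <- mid
  }
  pair_at((lo + hi) / 2)
}

#' Forward-in-time simulation of twin families under assortative mating
#'
#' Simulates a closed population forward through generations: founders
#' carry unit-variance latent factors; each generation, spouse pairs form
#' by rank-matching on the phenotype (phenotypic assortment), on its
#' non-genetic part (social homogamy), or at random, with matching noise
#' bisection-calibrated so the realized spousal correlation hits the
#' target; offspring receive mid-parent additive values plus segregation
#' noise (variance 1/2), non-additive values correlated between non-MZ
#' siblings at the dominance/epistasis value, a family-shared sibling
#' environment, and a familial-environment factor fed by both parental
#' phenotypes. After the configured number of generations the final
#' couples are emitted as MZ/DZ twin families with one near-in-age
#' sibling, role-scaled years of education, ages, sexes and
#' missing-at-random absent members.
#'
#' Because equilibrium is reached by simulation rather than imposed
#' analytically, the simulator is an independent Monte-Carlo check on
#' [solve_equilibrium()] and [implied_covariance()].
#'
#' @param config A [sim_config()].
#' @return A long-format family table (columns `family_id`, `role`,
#'   `zygosity`, `sex`, `age`, `ea_years`, `ea_std`, `ph_raw`), with a
#'   `provenance` attribute recording the seed, realized spousal
#'   correlation per generation, and per-generation phenotypic variance.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$paths
  r_n_sib <- config$r_n_sib
  n_fam <- config$n_mz_families + config$n_dz_families
  n_couples <- max(n_fam, 2000L)   # population floor keeps drift small
  mating <- config$mating

  # founders
  gen <- list(A = stats::rnorm(2 * n_couples),
              N = stats::rnorm(2 * n_couples),
              S = stats::rnorm(2 * n_couples),
              P = rep(0, 2 * n_couples))
  T_lat <- stats::rnorm(2 * n_couples)
  E_lat <- stats::rnorm(2 * n_couples)
  Ph <- phenotype_from(gen, p, T_lat, E_lat)
  nonGen <- Ph - p[["a"]] * gen$A - p[["n"]] * gen$N

  spousal_r <- numeric(0)
  spousal_gen_r <- numeric(0)
  var_A <- stats::var(gen$A)
  var_ph <- stats::var(Ph)

  couple <- NULL
  for (g in seq_len(config$generations)) {
    half <- seq_len(n_couples)
    perm <- sample(length(Ph))
    f_idx <- perm[half]
    m_idx <- perm[n_couples + half]
    key_f <- switch(mating,
                    phenotypic_assortment = Ph[f_idx],
                    social_homogamy = nonGen[f_idx],
                    random = stats::rnorm(n_couples))
    key_m <- switch(mating,
                    phenotypic_assortment = Ph[m_idx],
                    social_homogamy = nonGen[m_idx],
                    random = stats::rnorm(n_couples))
    if (mating == "random") {
      pair <- seq_len(n_couples)
    } else {
      pair <- match_spouses(key_f, key_m, Ph[f_idx], Ph[m_idx],
                            config$target_spousal_r)
    }
    m_idx <- m_idx[pair]
    spousal_r <- c(spousal_r, stats::cor(Ph[f_idx], Ph[m_idx]))
    spousal_gen_r <- c(spousal_gen_r, stats::cor(gen$A[f_idx], gen$A[m_idx]))
    couple <- list(A_f = gen$A[f_idx], A_m = gen$A[m_idx],
                   Ph_f = Ph[f_idx], Ph_m = Ph[m_idx])

    if (g < config$generations) {
      kids <- offspring_latents(couple$A_f, couple$A_m, couple$Ph_f,
                                couple$Ph_m, p, r_n_sib, 2L)
      gen <- list(A = c(kids[[1]]$A, kids[[2]]$A),
                  N = c(kids[[1]]$N, kids[[2]]$N),
                  S = c(kids[[1]]$S, kids[[2]]$S),
                  P = c(kids[[1]]$P, kids[[2]]$P))
      T_lat <- stats::rnorm(2 * n_couples)   # ordinary sibs: own T
      E_lat <- stats::rnorm(2 * n_couples)
      Ph <- phenotype_from(gen, p, T_lat, E_lat)
      nonGen <- Ph - p[["a"]] * gen$A - p[["n"]] * gen$N
      var_ph <- c(var_ph, stats::var(Ph))
      var_A <- c(var_A, stats::var(gen$A))
    }
  }

  # emit twin families from the final couples
  keep <- sample(n_couples, n_fam)
  cp <- lapply(couple, `[`, keep)
  zyg <- rep(c("MZ", "DZ"), c(config$n_mz_families, config$n_dz_families))

  N_fam <- stats::rnorm(n_fam)
  S_fam <- stats::rnorm(n_fam)
  P_fam <- p[["m"]] * (cp$Ph_f + cp$Ph_m)
  T_twin <- stats::rnorm(n_fam)             # shared by the twin pair only
  mid_A <- 0.5 * (cp$A_f + cp$A_m)
  draw_child_A <- function() mid_A + stats::rnorm(n_fam, sd = sqrt(0.5))
  draw_child_N <- function() sqrt(r_n_sib) * N_fam +
    sqrt(1 - r_n_sib) * stats::rnorm(n_fam)

  A1 <- draw_child_A(); A2 <- draw_child_A(); As <- draw_child_A()
  N1 <- draw_child_N(); N2 <- draw_child_N(); Ns <- draw_child_N()
  mz <- zyg == "MZ"
  A2[mz] <- A1[mz]                          # MZ co-twins: identical genomes
  N2[mz] <- N1[mz]

  child_ph <- function(A, N, T_c) {
    p[["a"]] * A + p[["n"]] * N + p[["s"]] * S_fam + P_fam +
      p[["t"]] * T_c + p[["e"]] * stats::rnorm(n_fam)
  }
  ph_t1 <- child_ph(A1, N1, T_twin)
  ph_t2 <- child_ph(A2, N2, T_twin)
  ph_sib <- child_ph(As, Ns, stats::rnorm(n_fam))

  twin_age <- sample(22:27, n_fam, replace = TRUE)
  gap <- sample(c(-4:-1, 1:4), n_fam, replace = TRUE)
  sib_age <- pmin(pmax(twin_age + gap, 21), 30)
  sex_t1 <- sample(c("female", "male"), n_fam, replace = TRUE)
  sex_t2 <- ifelse(mz, sex_t1, sample(c("female", "male"), n_fam,
                                      replace = TRUE))

  rows <- rbind(
    data.frame(family_id = seq_len(n_fam), role = "twin1", zygosity = zyg,
               sex = sex_t1, age = twin_age, ph_raw = ph_t1),
    data.frame(family_id = seq_len(n_fam), role = "twin2", zygosity = zyg,
               sex = sex_t2, age = twin_age, ph_raw = ph_t2),
    data.frame(family_id = seq_len(n_fam), role = "sibling", zygosity = zyg,
               sex = sample(c("female", "male"), n_fam, replace = TRUE),
               age = sib_age, ph_raw = ph_sib),
    data.frame(family_id = seq_len(n_fam), role = "mother", zygosity = zyg,
               sex = "female",
               age = sample(41:66, n_fam, replace = TRUE), ph_raw = cp$Ph_m),
    data.frame(family_id = seq_len(n_fam), role = "father", zygosity = zyg,
               sex = "male",
               age = sample(44:79, n_fam, replace = TRUE), ph_raw = cp$Ph_f)
  )

  drop_sib <- stats::runif(n_fam) < config$missing_sibling
  drop_mo <- stats::runif(n_fam) < config$missing_mother
  drop_fa <- stats::runif(n_fam) < config$missing_father
  drop <- (rows$role == "sibling" & drop_sib[rows$family_id]) |
    (rows$role == "mother" & drop_mo[rows$family_id]) |
    (rows$role == "father" & drop_fa[rows$family_id])
  rows <- rows[!drop, , drop = FALSE]

  rows$ea_std <- NA_real_
  rows$ea_years <- scale_to_roles(rows, config$role_stats,
                                  config$discretize_ea)
  rows <- rows[order(rows$family_id, match(rows$role, FAMILY_ROLES)), ]
  rownames(rows) <- NULL
  structure(rows,
            provenance = list(seed = config$seed,
                              mating = mating,
                              generations = config$generations,
                              realized_spousal_r = spousal_r,
                              realized_spousal_gen_r = spousal_gen_r,
                              additive_variance = var_A,
                              phenotypic_variance = var_ph,
                              paths = unclass(p),
                              config_hash = config_hash(config)))
}

scale_to_roles <- function(rows, role_stats, discretize) {
  key <- ifelse(rows$role %in% c("twin1", "twin2"),
                ifelse(rows$zygosity == "MZ", "mz_twin", "dz_twin"),
                rows$role)
  ea <- rep(NA_real_, nrow(rows))
  for (rk in unique(key)) {
    i <- key == rk
    st <- role_stats[role_stats$role == rk, ]
    if (nrow(st) == 0) st <- role_stats[role_stats$role == "total", ]
    z <- if (sum(i) > 1) scale(rows$ph_raw[i])[, 1] else 0
    ea[i] <- st$mean_ea + st$sd_ea * z
  }
  if (discretize) ea <- pmin(pmax(round(ea), 9), 18)
  ea
}

#' Direct multivariate-normal family sampler
#'
#' Samples standardized family member vectors (twin1, twin2, sibling,
#' mother, father) from multivariate normal distributions whose
#' correlations are given per zygosity, then applies
#' missing-completely-at-random absence of sibling, mother and father.
#' This bypasses the generative model: it calibrates directly to observed
#' dyadic correlations and is used for refits against published
#' estimates.
#'
#' @param R_mz,R_dz 5x5 member correlation matrices (see
#'   [dyad_correlation_matrix()]). Must be positive semi-definite.
#' @param n_mz,n_dz Numbers of MZ and DZ families.
#' @param missing_father,missing_sibling,missing_mother MCAR absence
#'   rates.
#' @param role_stats Per-role scaling targets for `ea_years`.
#' @param seed Integer seed.
#' @return A long-format family table; `ea_std` holds the standardized
#'   draws.
#' @export
sample_families_mvn <- function(R_mz = dyad_correlation_matrix("MZ"),
                                R_dz = dyad_correlation_matrix("DZ"),
                                n_mz = 498, n_dz = 439,
                                missing_father = 0.45,
                                missing_sibling = 0.78,
                                missing_mother = 0.08,
                                role_stats = ea_role_reference(),
                                seed = 1L) {
  for (R in list(R_mz, R_dz)) {
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10) {
      stop(sprintf("member correlation matrix is not PSD (min eigenvalue %.3g)",
                   ev), call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  n_fam <- n_mz + n_dz
  Y <- rbind(MASS::mvrnorm(n_mz, mu = rep(0, 5), Sigma = R_mz),
             MASS::mvrnorm(n_dz, mu = rep(0, 5), Sigma = R_dz))
  colnames(Y) <- FAMILY_ROLES
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  rows <- do.call(rbind, lapply(FAMILY_ROLES, function(rl) {
    data.frame(family_id = seq_len(n_fam), role = rl, zygosity = zyg,
               sex = switch(rl, mother = "female", father = "male",
                            sample(c("female", "male"), n_fam,
                                   replace = TRUE)),
               age = switch(rl,
                            mother = sample(41:66, n_fam, replace = TRUE),
                            father = sample(44:79, n_fam, replace = TRUE),
                            sibling = sample(21:30, n_fam, replace = TRUE),
                            sample(22:27, n_fam, replace = TRUE)),
               ph_raw = Y[, rl],
               ea_std = Y[, rl])
  }))
  drop_sib <- stats::runif(n_fam) < missing_sibling
  drop_mo <- stats::runif(n_fam) < missing_mother
  drop_fa <- stats::runif(n_fam) < missing_father
  drop <- (rows$role == "sibling" & drop_sib[rows$family_id]) |
    (rows$role == "mother" & drop_mo[rows$family_id]) |
    (rows$role == "father" & drop_fa[rows$family_id])
  rows <- rows[!drop, , drop = FALSE]
  rows$ea_years <- scale_to_roles(rows, role_stats, FALSE)
  rows <- rows[order(rows$family_id, match(rows$role, FAMILY_ROLES)), ]
  rownames(rows) <- NULL
  rows
}

#' Descriptive summary of a family table
#'
#' Per-role counts, sex counts, complete-twin-pair counts, age range and
#' years-of-education mean/SD, in the shape of the reference descriptive
#' table.
#'
#' @param table Long-format family table.
#' @return Data.frame with one row per (zygosity-split) role present plus
#'   a `total` row.
#' @export
summarize_families <- function(table) {
  if (nrow(table) == 0) stop("empty family table", call. = FALSE)
  key <- ifelse(table$role %in% c("twin1", "twin2"),
                ifelse(table$zygosity == "MZ", "mz_twin", "dz_twin"),
                table$role)
  one <- function(i, label) {
    sub <- table[i, ]
    pairs <- if (label %in% c("mz_twin", "dz_twin")) {
      sum(tapply(sub$role, sub$family_id,
                 function(r) all(c("twin1", "twin2") %in% r)))
    } else if (label == "total") {
      tw <- table[table$role %in% c("twin1", "twin2"), ]
      sum(tapply(tw$role, tw$family_id,
                 function(r) all(c("twin1", "twin2") %in% r)))
    } else 0L
    data.frame(role = label, n = nrow(sub),
               n_female = sum(sub$sex == "female"),
               n_male = sum(sub$sex == "male"),
               pairs = pairs,
               age_min = min(sub$age), age_max = max(sub$age),
               mean_ea = mean(sub$ea_years),
               sd_ea = stats::sd(sub$ea_years))
  }
  labels <- intersect(c("mz_twin", "dz_twin", "sibling", "mother", "father"),
                      unique(key))
  out <- do.call(rbind, lapply(labels, function(l) one(key == l, l)))
  rbind(out, one(rep(TRUE, nrow(table)), "total"))
}
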