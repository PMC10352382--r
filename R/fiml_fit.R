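#' Reshape a long family table to one row per family
#'
#' @param table Long-format family table.
#' @param value Column to spread (default `ea_std`, falling back to
#'   `ph_raw` if `ea_std` is all missing).
#' @return List with `Y` (families x 5 matrix, NA for absent members) and
#'   `zygosity` (per family).
#' @export
family_wide <- function(table, value = "ea_std") {
  if (value == "ea_std" && (is.null(table$ea_std) || all(is.na(table$ea_std)))
      && !is.null(table$ph_raw)) {
    value <- "ph_raw"
  }
  fams <- sort(unique(table$family_id))
  Y <- matrix(NA_real_, length(fams), 5,
              dimnames = list(NULL, FAMILY_ROLES))
  ri <- match(table$family_id, fams)
  ci <- match(table$role, FAMILY_ROLES)
  ok <- !is.na(ci)
  Y[cbind(ri[ok], ci[ok])] <- table[[value]][ok]
  zyg <- rep(NA_character_, length(fams))
  zyg[ri] <- table$zygosity
  list(Y = Y, zygosity = zyg, family_id = fams)
}

# group family rows by zygosity x missingness pattern for fast repeated
# likelihood evaluation
pattern_groups <- function(Y, zyg) {
  obs <- !is.na(Y)
  n_members <- rowSums(obs)
  skipped <- sum(n_members == 0)
  keep <- n_members > 0
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  zyg <- zyg[keep]
  key <- paste(zyg, apply(obs, 1, paste, collapse = ""))
  groups <- lapply(split(seq_along(key), key), function(i) {
    cols <- which(obs[i[1], ])
    list(zygosity = zyg[i[1]], cols = cols,
         Y = Y[i, cols, drop = FALSE])
  })
  structure(groups, skipped = skipped,
            n_obs = sum(obs), n_families = nrow(Y))
}

# -2 log likelihood over pattern groups given per-zygosity covariance
# matrices and a role-indexed mean vector (length 5)
m2ll_groups <- function(groups, S_mz, S_dz, mu) {
  total <- 0
  for (g in groups) {
    S <- if (g$zygosity == "MZ") S_mz else S_dz
    Ssub <- S[g$cols, g$cols, drop = FALSE]
    R <- tryCatch(chol(Ssub), error = function(e) NULL)
    if (is.null(R)) return(NA_real_)
    X <- sweep(g$Y, 2, mu[g$cols])
    quad <- sum(backsolve(R, t(X), transpose = TRUE)^2)
    total <- total + nrow(g$Y) *
      (length(g$cols) * log(2 * pi) + 2 * sum(log(diag(R)))) + quad
  }
  total
}

#' Full-information ML deviance of a family table under a model
#'
#' Computes -2 log likelihood of the observed family vectors under the
#' model-implied multivariate-normal structure, each family contributing
#' only its non-missing members. Families with no observed members are
#' skipped (their count is attached as attribute `n_skipped`).
#'
#' @param table Long-format family table with the phenotype filled
#'   (`ea_std`, or `ph_raw` as fallback).
#' @param spec A [model_spec()].
#' @param params A [path_params()] set.
#' @param mean Grand mean of the standardized phenotype (default 0).
#' @param per_family If `TRUE`, evaluate each family's density
#'   separately (slow reference path; equals the grouped computation).
#' @return The deviance (-2LL).
#' @export
fiml_loglik <- function(table, spec, params, mean = 0, per_family = FALSE) {
  wide <- family_wide(table)
  eq <- solve_equilibrium(spec, params)
  S_mz <- implied_covariance(spec, params, eq, "MZ")
  S_dz <- implied_covariance(spec, params, eq, "DZ")
  mu <- rep(mean, 5)
  if (per_family) {
    total <- 0
    for (i in seq_len(nrow(wide$Y))) {
      o <- which(!is.na(wide$Y[i, ]))
      if (!length(o)) next
      S <- if (wide$zygosity[i] == "MZ") S_mz else S_dz
      Ssub <- S[o, o, drop = FALSE]
      x <- wide$Y[i, o] - mu[o]
      total <- total - 2 * as.numeric(
        -0.5 * (length(o) * log(2 * pi) + determinant(Ssub)$modulus +
                  crossprod(x, solve(Ssub, x))))
    }
    return(total)
  }
  groups <- pattern_groups(wide$Y, wide$zygosity)
  val <- m2ll_groups(groups, S_mz, S_dz, mu)
  if (is.na(val)) {
    stop("implied covariance not positive definite at the supplied ",
         "parameters (", paste(sprintf("%s=%.4f", names(params),
                                       unclass(params)), collapse = ", "),
         ")", call. = FALSE)
  }
  structure(val, n_skipped = attr(groups, "skipped"))
}

#' Akaike and Bayesian information criteria
#'
#' AIC = -2LL + 2 k; BIC = -2LL + k log(n), with n the number of
#' non-missing observations.
#'
#' @param minus2LL Deviance.
#' @param n_params Number of free parameters k.
#' @param n_units Number of non-missing observations.
#' @return List with `AIC` and `BIC`.
#' @export
information_criteria <- function(minus2LL, n_params, n_units) {
  list(AIC = minus2LL + 2 * n_params,
       BIC = minus2LL + n_params * log(n_units))
}

# parameter vector <-> path params; variance-scale paths enter as |.|
theta_to_params <- function(theta, spec) {
  v <- c(a = 0, n = 0, s = 0, t = 0, e = 1, m = 0, mu = 0)
  th <- theta[names(theta) != "mean"]
  v[names(th)] <- th
  v[c("a", "n", "s", "t", "e")] <- abs(v[c("a", "n", "s", "t", "e")])
  v["e"] <- max(v[["e"]], 1e-6)
  do.call(path_params, as.list(v))
}

fit_objective <- function(groups, spec) {
  function(theta) {
    p <- theta_to_params(theta, spec)
    eq <- tryCatch(solve_equilibrium(spec, p), error = function(e) NULL)
    if (is.null(eq)) return(1e10)
    S_mz <- implied_covariance(spec, p, eq, "MZ")
    S_dz <- implied_covariance(spec, p, eq, "DZ")
    val <- m2ll_groups(groups, S_mz, S_dz, rep(theta[["mean"]], 5))
    if (is.na(val) || !is.finite(val)) return(1e10)
    val
  }
}

start_values <- function(spec, groups, seed) {
  set.seed(seed)
  base <- c(a = 0.6, n = 0.3, s = 0.3, t = 0.35, e = 0.5, m = 0.1, mu = 0.4)
  th <- base[spec$free_paths]
  jitter <- if (seed == 1) 0 else stats::rnorm(length(th), sd = 0.15)
  th <- pmax(th + jitter, 0.02)
  c(th, mean = 0)
}

#' Fit a twin-family model by full-information maximum likelihood
#'
#' Minimizes the FIML deviance over the model's free paths (the
#' equilibrium constraints are re-solved inside the objective) and a
#' grand mean, with multiple fixed-seed starts (Nelder-Mead exploration
#' refined by a bounded quasi-Newton pass). Standardized variance
#' components are reported with 95% confidence intervals, Wald by
#' default (delta method from the observed information) or profile
#' likelihood.
#'
#' @param table Long-format family table with the phenotype filled.
#' @param spec A [model_spec()].
#' @param n_starts Number of optimization starts (seeds 1..n_starts).
#' @param ci `"wald"`, `"profile"`, or `"none"`.
#' @param level Confidence level.
#' @return Object of class `twinfam_fit`: deviance, information
#'   criteria, path estimates with standard errors, standardized
#'   components with CIs, and convergence diagnostics.
#' @export
fit_model <- function(table, spec, n_starts = 5,
                      ci = c("wald", "profile", "none"), level = 0.95) {
  ci <- match.arg(ci)
  wide <- family_wide(table)
  groups <- pattern_groups(wide$Y, wide$zygosity)
  obj <- fit_objective(groups, spec)

  best <- NULL
  for (seed in seq_len(n_starts)) {
    th0 <- start_values(spec, groups, seed)
    o1 <- stats::optim(th0, obj, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-12))
    o2 <- tryCatch(
      stats::optim(o1$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) o1)
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("model fit failed to converge from any start", call. = FALSE)
  }
  theta <- best$par
  params <- theta_to_params(theta, spec)
  eq <- solve_equilibrium(spec, params)
  comp <- standardize_components(spec, params, eq)
  n_params <- length(theta)
  n_units <- attr(groups, "n_obs")
  icr <- information_criteria(best$value, n_params, n_units)

  H <- tryCatch(stats::optimHess(theta, obj), error = function(e) NULL)
  vc <- NULL
  if (!is.null(H)) {
    vc <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vc) && any(!is.finite(vc))) vc <- NULL
  }
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, n_params)
  names(se) <- names(theta)

  comp_ci <- NULL
  if (ci == "wald" && !is.null(vc)) {
    comp_ci <- wald_component_ci(theta, vc, spec, level)
  }
  boundary <- names(theta)[names(theta) %in% c("a", "n", "s", "t") &
                             abs(theta) < 1e-4]

  fit <- structure(list(
    minus2LL = best$value,
    n_params = n_params,
    n_units = n_units,
    n_families = attr(groups, "n_families"),
    df = n_units - n_params,
    AIC = icr$AIC, BIC = icr$BIC,
    params = params,
    theta = theta,
    se = se,
    vcov = vc,
    mean = theta[["mean"]],
    equilibrium = eq,
    components = comp,
    component_ci = comp_ci,
    boundary_paths = boundary,
    spec = spec,
    convergence = list(code = best$convergence, starts = n_starts),
    ci_method = ci, level = level), class = "twinfam_fit")
  if (ci == "profile") {
    fit$component_ci <- profile_component_ci(fit, groups, level)
  }
  fit
}

component_fun <- function(spec) {
  function(theta) {
    p <- theta_to_params(theta, spec)
    standardize_components(spec, p, solve_equilibrium(spec, p))
  }
}

wald_component_ci <- function(theta, vc, spec, level) {
  f <- component_fun(spec)
  est <- f(theta)
  J <- matrix(0, length(est), length(theta),
              dimnames = list(names(est), names(theta)))
  h <- 1e-5
  for (j in seq_along(theta)) {
    tp <- theta; tm <- theta
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    J[, j] <- (f(tp) - f(tm)) / (2 * h)
  }
  vse <- sqrt(pmax(diag(J %*% vc %*% t(J)), 0))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  lo <- est - zc * vse
  hi <- est + zc * vse
  nonneg <- names(est) != "rGE"
  lo[nonneg] <- pmax(lo[nonneg], 0)
  hi <- pmin(hi, 1)
  cbind(estimate = est, lower = lo, upper = hi, se = vse)
}

# profile-likelihood CI on each standardized component: for candidate
# value c, refit with a quadratic penalty pinning the component at c and
# find where the profiled deviance rises by the chi-square(1) quantile
profile_component_ci <- function(fit, groups, level) {
  spec <- fit$spec
  obj <- fit_objective(groups, spec)
  f <- component_fun(spec)
  est <- fit$components
  crit <- stats::qchisq(level, 1)
  base <- fit$minus2LL
  pen <- 1e7
  prof_dev <- function(k, c0) {
    po <- function(theta) obj(theta) + pen * (f(theta)[k] - c0)^2
    o <- stats::optim(fit$theta, po, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
    obj(o$par)
  }
  one_bound <- function(k, dir) {
    target <- function(c0) prof_dev(k, c0) - base - crit
    bound <- if (dir < 0) max(0, est[k] - 0.5) else min(1, est[k] + 0.5)
    lim <- if (dir < 0) 0 else 1
    f_at_bound <- tryCatch(target(bound), error = function(e) NA)
    if (is.na(f_at_bound) || f_at_bound < 0) return(lim)
    r <- tryCatch(
      stats::uniroot(target, sort(c(est[k], bound)), tol = 5e-4)$root,
      error = function(e) NA_real_)
    r
  }
  keep <- est > 1e-8 | names(est) %in% c("A", "E") # skip structurally-zero
  out <- cbind(estimate = est, lower = NA_real_, upper = NA_real_,
               se = NA_real_)
  for (k in which(keep)) {
    out[k, "lower"] <- one_bound(k, -1)
    out[k, "upper"] <- one_bound(k, +1)
  }
  out
}

#' @export
print.twinfam_fit <- function(x, ...) {
  cat(sprintf("%s fit by FIML: -2LL = %.2f, df = %d, AIC = %.2f, BIC = %.2f\n",
              x$spec$label, x$minus2LL, x$df, x$AIC, x$BIC))
  comp <- x$components
  shown <- comp[comp != 0 | names(comp) %in% c("A", "E")]
  cat("  components: ",
      paste(sprintf("%s = %d%%", names(shown), as_percent(shown)),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$component_ci)) {
    ci <- x$component_ci[names(shown), , drop = FALSE]
    cat("  95% CIs:    ",
        paste(sprintf("%s (%d-%d%%)", rownames(ci),
                      as_percent(ci[, "lower"]), as_percent(ci[, "upper"])),
              collapse = ", "), "\n", sep = "")
  }
  if (length(x$boundary_paths)) {
    cat("  note: paths at the zero boundary: ",
        paste(x$boundary_paths, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Fit the saturated model
#'
#' Estimates free means, variances and covariances per relative-class
#' pairing, constrained equal across families within each zygosity
#' configuration and exchangeable over the two twins, by FIML. Cells
#' with no jointly observed data are fixed at zero and excluded from the
#' parameter count (recorded in `dropped_cells`).
#'
#' @param table Long-format family table.
#' @return A `twinfam_fit`-like object of class `saturated_fit`.
#' @export
fit_saturated <- function(table) {
  wide <- family_wide(table)
  groups <- pattern_groups(wide$Y, wide$zygosity)

  cells <- list(tt = c("twin1", "twin2"), ts1 = c("twin1", "sibling"),
                ts2 = c("twin2", "sibling"),
                tm1 = c("twin1", "mother"), tm2 = c("twin2", "mother"),
                tf1 = c("twin1", "father"), tf2 = c("twin2", "father"),
                sm = c("sibling", "mother"), sf = c("sibling", "father"),
                mf = c("mother", "father"))
  # which roles/cells have data, per zygosity
  layout <- list()
  for (z in c("MZ", "DZ")) {
    Yz <- wide$Y[wide$zygosity == z, , drop = FALSE]
    if (!nrow(Yz)) next
    obs <- !is.na(Yz)
    roles_avail <- FAMILY_ROLES[colSums(obs) > 1]
    classes <- unique(ifelse(roles_avail %in% c("twin1", "twin2"), "twin",
                             roles_avail))
    pair_avail <- character(0)
    pair_classes <- list(tt = c("twin", "twin"), ts = c("twin", "sibling"),
                         tm = c("twin", "mother"), tf = c("twin", "father"),
                         sm = c("sibling", "mother"),
                         sf = c("sibling", "father"),
                         mf = c("mother", "father"))
    for (pc in names(pair_classes)) {
      members <- pair_classes[[pc]]
      cols1 <- if (members[1] == "twin") c("twin1", "twin2") else members[1]
      cols2 <- if (members[2] == "twin") c("twin1", "twin2") else members[2]
      n_joint <- 0
      for (c1 in cols1) for (c2 in cols2) {
        if (c1 != c2) n_joint <- n_joint + sum(obs[, c1] & obs[, c2])
      }
      if (n_joint >= 2) pair_avail <- c(pair_avail, pc)
    }
    layout[[z]] <- list(classes = classes, pairs = pair_avail)
  }

  par_names <- character(0)
  for (z in names(layout)) {
    lz <- layout[[z]]
    par_names <- c(par_names,
                   paste(z, "mean", lz$classes, sep = "."),
                   paste(z, "var", lz$classes, sep = "."),
                   paste(z, "cov", lz$pairs, sep = "."))
  }

  build_sigma <- function(theta, z) {
    lz <- layout[[z]]
    g <- function(kind, nm, default = 0) {
      key <- paste(z, kind, nm, sep = ".")
      if (key %in% names(theta)) theta[[key]] else default
    }
    role_class <- c(twin1 = "twin", twin2 = "twin", sibling = "sibling",
                    mother = "mother", father = "father")
    mu <- vapply(FAMILY_ROLES, function(r) g("mean", role_class[[r]]),
                 numeric(1))
    S <- diag(vapply(FAMILY_ROLES, function(r)
      g("var", role_class[[r]], default = 1), numeric(1)))
    dimnames(S) <- list(FAMILY_ROLES, FAMILY_ROLES)
    S["twin1", "twin2"] <- g("cov", "tt")
    S["twin1", "sibling"] <- S["twin2", "sibling"] <- g("cov", "ts")
    S["twin1", "mother"] <- S["twin2", "mother"] <- g("cov", "tm")
    S["twin1", "father"] <- S["twin2", "father"] <- g("cov", "tf")
    S["sibling", "mother"] <- g("cov", "sm")
    S["sibling", "father"] <- g("cov", "sf")
    S["mother", "father"] <- g("cov", "mf")
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    list(mu = mu, S = S)
  }

  obj <- function(theta) {
    names(theta) <- par_names
    mz <- build_sigma(theta, "MZ")
    dz <- build_sigma(theta, "DZ")
    # per-zygosity means require splitting groups by zygosity mean vecs
    total <- 0
    for (g in groups) {
      bz <- if (g$zygosity == "MZ") mz else dz
      Ssub <- bz$S[g$cols, g$cols, drop = FALSE]
      R <- tryCatch(chol(Ssub), error = function(e) NULL)
      if (is.null(R)) return(1e10)
      X <- sweep(g$Y, 2, bz$mu[g$cols])
      quad <- sum(backsolve(R, t(X), transpose = TRUE)^2)
      total <- total + nrow(g$Y) *
        (length(g$cols) * log(2 * pi) + 2 * sum(log(diag(R)))) + quad
    }
    total
  }

  # start from pairwise-complete sample moments
  start <- numeric(length(par_names))
  names(start) <- par_names
  for (z in names(layout)) {
    Yz <- wide$Y[wide$zygosity == z, , drop = FALSE]
    tw <- c(Yz[, "twin1"], Yz[, "twin2"])
    cls_val <- list(twin = tw, sibling = Yz[, "sibling"],
                    mother = Yz[, "mother"], father = Yz[, "father"])
    for (cl in layout[[z]]$classes) {
      v <- cls_val[[cl]]
      start[paste(z, "mean", cl, sep = ".")] <- mean(v, na.rm = TRUE)
      start[paste(z, "var", cl, sep = ".")] <- stats::var(v, na.rm = TRUE)
    }
    pc <- function(c1, c2) {
      ok <- stats::complete.cases(Yz[, c(c1, c2)])
      if (sum(ok) > 2) stats::cov(Yz[ok, c1], Yz[ok, c2]) else 0
    }
    pair_start <- c(tt = pc("twin1", "twin2"),
                    ts = mean(c(pc("twin1", "sibling"),
                                pc("twin2", "sibling"))),
                    tm = mean(c(pc("twin1", "mother"),
                                pc("twin2", "mother"))),
                    tf = mean(c(pc("twin1", "father"),
                                pc("twin2", "father"))),
                    sm = pc("sibling", "mother"), sf = pc("sibling", "father"),
                    mf = pc("mother", "father"))
    for (pr in layout[[z]]$pairs) {
      start[paste(z, "cov", pr, sep = ".")] <- pair_start[[pr]]
    }
  }

  o <- stats::nlminb(start, obj, control = list(iter.max = 2000,
                                                eval.max = 4000))
  o2 <- stats::optim(o$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-12))
  theta <- if (o2$value < o$objective) o2$par else o$par
  val <- min(o2$value, o$objective)
  names(theta) <- par_names
  n_units <- attr(groups, "n_obs")
  icr <- information_criteria(val, length(theta), n_units)
  all_cells <- unlist(lapply(names(layout), function(z)
    paste(z, "cov", c("tt", "ts", "tm", "tf", "sm", "sf", "mf"), sep = ".")))
  structure(list(minus2LL = val, n_params = length(theta),
                 n_units = n_units,
                 n_families = attr(groups, "n_families"),
                 df = n_units - length(theta),
                 AIC = icr$AIC, BIC = icr$BIC,
                 theta = theta,
                 dropped_cells = setdiff(all_cells, par_names),
                 spec = list(label = "saturated"),
                 convergence = list(code = o$convergence)),
            class = c("saturated_fit", "twinfam_fit"))
}

#' Likelihood-ratio test between nested fits
#'
#' @param restricted,general Fits of nested models on the same data
#'   (`general` has more free parameters).
#' @return List with `delta_m2ll`, `delta_df`, `p` (upper chi-square
#'   tail). Small negative deviance differences (optimizer noise, up to
#'   0.02) are clamped to zero; larger ones signal an optimizer failure.
#' @export
lrt <- function(restricted, general) {
  d <- restricted$minus2LL - general$minus2LL
  ddf <- general$n_params - restricted$n_params
  if (ddf < 1) stop("`restricted` must have fewer parameters", call. = FALSE)
  if (d < -0.02) {
    stop(sprintf(
      "restricted model fits better by %.3f units of deviance; optimizer failure",
      -d), call. = FALSE)
  }
  d <- max(d, 0)
  list(delta_m2ll = d, delta_df = ddf,
       p = stats::pchisq(d, ddf, lower.tail = FALSE))
}

#' Iteratively prune non-significant paths from a baseline model
#'
#' Starting from a fitted baseline, repeatedly drops all free paths
#' (other than `e`) whose 95% confidence interval covers zero, refits,
#' and tests the pruned model against the baseline by likelihood-ratio
#' test; pruning stops when no droppable path remains or the fit
#' degrades significantly (in which case the last acceptable model is
#' kept). Dropping the transmission path `m` forces the derived
#' quantities x and w to zero automatically.
#'
#' @param table Long-format family table.
#' @param baseline_spec Baseline [model_spec()].
#' @param alpha Significance level for the degradation test.
#' @param max_iter Iteration cap.
#' @param n_starts Optimization starts per refit.
#' @return Object of class `prune_report`: baseline and final fits, the
#'   drop history, and the LRT against the baseline.
#' @export
prune_paths <- function(table, baseline_spec, alpha = 0.05, max_iter = 10,
                        n_starts = 3) {
  baseline <- fit_model(table, baseline_spec, n_starts = n_starts)
  current <- baseline
  history <- list()
  for (i in seq_len(max_iter)) {
    th <- current$theta
    se <- current$se
    cand <- setdiff(current$spec$free_paths, "e")
    zc <- stats::qnorm(1 - (1 - current$level) / 2)
    crosses <- vapply(cand, function(pn) {
      est <- abs(th[[pn]])
      s <- se[[pn]]
      is.na(s) || est - zc * s <= 0
    }, logical(1))
    to_drop <- cand[crosses]
    if (!length(to_drop)) break
    new_free <- setdiff(current$spec$free_paths, to_drop)
    if (!"e" %in% new_free || length(new_free) < 2) break
    new_spec <- model_spec(current$spec$design, free_paths = new_free,
                           nonadditive = current$spec$nonadditive,
                           force_w_zero = current$spec$force_w_zero,
                           label = paste0(current$spec$label, " - ",
                                          paste(to_drop, collapse = ",")))
    new_fit <- fit_model(table, new_spec, n_starts = n_starts)
    test <- lrt(new_fit, baseline)
    history[[length(history) + 1]] <-
      list(dropped = to_drop, p_vs_baseline = test$p,
           minus2LL = new_fit$minus2LL)
    if (test$p < alpha) break   # degraded: keep the previous model
    current <- new_fit
  }
  final_test <- if (current$n_params < baseline$n_params) {
    lrt(current, baseline)
  } else NULL
  structure(list(baseline = baseline, final = current,
                 history = history, lrt_vs_baseline = final_test,
                 alpha = alpha),
            class = "prune_report")
}

#' @export
print.prune_report <- function(x, ...) {
  cat("path pruning from", x$baseline$spec$label, "\n")
  for (h in x$history) {
    cat(sprintf("  dropped %s (p vs baseline = %.3f)\n",
                paste(h$dropped, collapse = ", "), h$p_vs_baseline))
  }
  cat("final model:\n")
  print(x$final)
  invisible(x)
}

#' Fit and compare the six NTFD baseline models
#'
#' Fits the saturated model, then for each mating assumption
#' (phenotypic assortment and social homogamy) the three baseline models
#' fixing non-additive genetics, the sibling-shared environment, or
#' phenotypic transmission to zero, prunes each baseline, and assembles
#' the comparison ladder. The best model is the pruned model with the
#' lowest AIC among baselines not fitting significantly worse than the
#' saturated model.
#'
#' @param table Long-format family table.
#' @param designs Mating assumptions to include.
#' @param nonadditive `"dominance"` or `"epistasis"`.
#' @param alpha Significance level.
#' @param n_starts Optimization starts per fit.
#' @return Object of class `ladder_report` with the saturated fit, the
#'   per-baseline prune reports, a comparison table, and the selected
#'   best fit.
#' @export
model_ladder <- function(table, designs = c("PA", "SH"),
                         nonadditive = "dominance", alpha = 0.05,
                         n_starts = 3) {
  sat <- fit_saturated(table)
  base_names <- unlist(lapply(designs, function(d)
    paste0(d, c("-ASTPE", "-ANTPE", "-ANSTE"))))
  reports <- list()
  rows <- list()
  for (nm in base_names) {
    spec <- model_preset(nm, nonadditive)
    rep <- prune_paths(table, spec, alpha = alpha, n_starts = n_starts)
    reports[[nm]] <- rep
    t_base <- lrt(rep$baseline, sat)
    rows[[length(rows) + 1]] <- data.frame(
      model = nm, stage = "baseline",
      minus2LL = rep$baseline$minus2LL, df = rep$baseline$df,
      AIC = rep$baseline$AIC, BIC = rep$baseline$BIC,
      against = "saturated", delta_df = t_base$delta_df,
      delta_m2ll = t_base$delta_m2ll, p = t_base$p)
    if (!is.null(rep$lrt_vs_baseline)) {
      t_fin <- rep$lrt_vs_baseline
      rows[[length(rows) + 1]] <- data.frame(
        model = rep$final$spec$label, stage = "pruned",
        minus2LL = rep$final$minus2LL, df = rep$final$df,
        AIC = rep$final$AIC, BIC = rep$final$BIC,
        against = nm, delta_df = t_fin$delta_df,
        delta_m2ll = t_fin$delta_m2ll, p = t_fin$p)
    }
  }
  tab <- do.call(rbind, rows)
  admissible <- vapply(base_names, function(nm)
    lrt(reports[[nm]]$baseline, sat)$p >= alpha, logical(1))
  finals <- lapply(reports[base_names[admissible]], `[[`, "final")
  best <- if (length(finals)) finals[[which.min(vapply(finals, `[[`,
                                                       numeric(1), "AIC"))]]
          else NULL
  structure(list(saturated = sat, reports = reports, table = tab,
                 best = best), class = "ladder_report")
}

#' @export
print.ladder_report <- function(x, ...) {
  cat("model-comparison ladder (saturated -2LL =",
      sprintf("%.2f", x$saturated$minus2LL), ")\n")
  print(x$table, row.names = FALSE, digits = 5)
  if (!is.null(x$best)) {
    cat("best model by AIC:\n")
    print(x$best)
  }
  invisible(x)
}
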