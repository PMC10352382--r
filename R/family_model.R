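ALL_PATHS <- c("a", "n", "s", "t", "e", "m", "mu")
FAMILY_ROLES <- c("twin1", "twin2", "sibling", "mother", "father")

#' Specify a twin-family variance-component model
#'
#' Defines which design the model uses and which path coefficients are
#' free. Designs:
#' \describe{
#'   \item{CTD_ACE}{Classical Twin Design with additive genetics, shared
#'     environment (carried by the `s` path) and nonshared environment;
#'     twins only, random mating.}
#'   \item{CTD_ANE}{CTD with non-additive genetics instead of shared
#'     environment.}
#'   \item{NTFD_PA}{Nuclear Twin and Family Design under phenotypic
#'     assortment: the spousal copath `mu` connects the observed parental
#'     phenotypes, inducing a spousal genetic correlation.}
#'   \item{NTFD_SH}{NTFD under social homogamy: the copath connects latent
#'     parental phenotypes whose genetic loadings are zero, so spousal
#'     resemblance is environmentally driven and contributes no direct
#'     spousal genetic covariance.}
#' }
#' Path coefficients: `a` additive genetic, `n` non-additive genetic, `s`
#' sibling-shared environment, `t` twin-specific shared environment
#' (modelled as a variance component for every relative class), `e`
#' nonshared environment, `m` phenotypic transmission (each parent's
#' phenotype to the offspring familial-environment factor, whose loading
#' on the phenotype is fixed at 1), `mu` the spousal copath. Under
#' dominance the non-additive correlation between non-MZ siblings is
#' 0.25; under epistasis it is 0 (MZ twins always 1).
#'
#' At most two of `n`, `s`, `m` can be free simultaneously (they are not
#' jointly identified from twin, sibling and parent data).
#'
#' @param design One of `"CTD_ACE"`, `"CTD_ANE"`, `"NTFD_PA"`, `"NTFD_SH"`.
#' @param free_paths Character vector of free path names (subset of
#'   a, n, s, t, e, m, mu). Defaults to the design's standard free set.
#' @param nonadditive `"dominance"` or `"epistasis"`.
#' @param force_w_zero Logical; constrain the passive gene-environment
#'   covariance w to zero while keeping `m` free ("no rGE" variants).
#' @param label Optional display label.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("NTFD_PA", free_paths = c("a", "s", "t", "e", "mu"))
#' @export
model_spec <- function(design = c("NTFD_PA", "NTFD_SH", "CTD_ACE", "CTD_ANE"),
                       free_paths = NULL,
                       nonadditive = c("dominance", "epistasis"),
                       force_w_zero = FALSE,
                       label = NULL) {
  design <- match.arg(design)
  nonadditive <- match.arg(nonadditive)
  if (is.null(free_paths)) {
    free_paths <- switch(design,
      CTD_ACE = c("a", "s", "e"),
      CTD_ANE = c("a", "n", "e"),
      NTFD_PA = ,
      NTFD_SH = c("a", "s", "t", "e", "m", "mu"))
  }
  bad <- setdiff(free_paths, ALL_PATHS)
  if (length(bad)) stop("unknown paths: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (startsWith(design, "CTD") && any(c("m", "mu") %in% free_paths)) {
    stop("CTD designs assume random mating and no phenotypic transmission",
         call. = FALSE)
  }
  if (sum(c("n", "s", "m") %in% free_paths) > 2) {
    stop("at most two of n, s, m can be free simultaneously", call. = FALSE)
  }
  if (!"e" %in% free_paths) stop("`e` must always be free", call. = FALSE)
  structure(list(design = design,
                 free_paths = free_paths,
                 fixed_zero = setdiff(ALL_PATHS, free_paths),
                 nonadditive = nonadditive,
                 r_n_sib = if (nonadditive == "dominance") 0.25 else 0,
                 force_w_zero = force_w_zero,
                 label = label %||% design),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: %s (%s)\n  free: %s\n  fixed at zero: %s\n",
              x$label, x$design,
              paste(x$free_paths, collapse = ", "),
              paste(x$fixed_zero, collapse = ", ")))
  if (x$force_w_zero) cat("  passive rGE (w) constrained to zero\n")
  invisible(x)
}

#' Named model presets for the NTFD model-comparison ladder
#'
#' Returns the named baseline and pruned model configurations used in the
#' model-comparison ladder: for each mating assumption (PA, SH), three
#' baselines fixing non-additive genetics, sibling-shared environment, or
#' phenotypic transmission to zero, plus their standard submodels, and the
#' two CTD designs.
#'
#' @param nonadditive `"dominance"` or `"epistasis"` for the NTFD presets.
#' @return Named list of `model_spec` objects.
#' @examples
#' names(ntfd_presets())
#' model_preset("PA-ASTE")
#' @export
ntfd_presets <- function(nonadditive = "dominance") {
  mk <- function(design, free, label, w0 = FALSE) {
    model_spec(design, free_paths = free, nonadditive = nonadditive,
               force_w_zero = w0, label = label)
  }
  base <- c("e", "mu")
  out <- list()
  for (d in c("PA", "SH")) {
    design <- paste0("NTFD_", d)
    out[[paste0(d, "-ASTPE")]] <- mk(design, c("a", "s", "t", "m", base),
                                     paste0(d, "-ASTPE"))
    out[[paste0(d, "-ASTPE-norGE")]] <- mk(design, c("a", "s", "t", "m", base),
                                           paste0(d, "-ASTPE (no rGE)"), TRUE)
    out[[paste0(d, "-ASTE")]] <- mk(design, c("a", "s", "t", base),
                                    paste0(d, "-ASTE"))
    out[[paste0(d, "-ANTPE")]] <- mk(design, c("a", "n", "t", "m", base),
                                     paste0(d, "-ANTPE"))
    out[[paste0(d, "-ANTPE-norGE")]] <- mk(design, c("a", "n", "t", "m", base),
                                           paste0(d, "-ANTPE (no rGE)"), TRUE)
    out[[paste0(d, "-ATPE")]] <- mk(design, c("a", "t", "m", base),
                                    paste0(d, "-ATPE"))
    out[[paste0(d, "-ANTE")]] <- mk(design, c("a", "n", "t", base),
                                    paste0(d, "-ANTE"))
    out[[paste0(d, "-ATE")]] <- mk(design, c("a", "t", base),
                                   paste0(d, "-ATE"))
    out[[paste0(d, "-ANSTE")]] <- mk(design, c("a", "n", "s", "t", base),
                                     paste0(d, "-ANSTE"))
    out[[paste0(d, "-ANSE")]] <- mk(design, c("a", "n", "s", base),
                                    paste0(d, "-ANSE"))
    out[[paste0(d, "-ASE")]] <- mk(design, c("a", "s", base),
                                   paste0(d, "-ASE"))
  }
  out[["CTD-ACE"]] <- model_spec("CTD_ACE", label = "CTD-ACE")
  out[["CTD-ANE"]] <- model_spec("CTD_ANE", nonadditive = nonadditive,
                                 label = "CTD-ANE")
  out
}

#' @rdname ntfd_presets
#' @param name Preset name, e.g. `"PA-ASTE"`.
#' @export
model_preset <- function(name, nonadditive = "dominance") {
  presets <- ntfd_presets(nonadditive)
  if (!name %in% names(presets)) {
    stop("unknown preset `", name, "`; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  presets[[name]]
}

#' Construct a path-coefficient set
#'
#' @param a,n,s,t,e,m,mu Path coefficients (see [model_spec()]).
#' @return Named numeric vector of class `path_params`.
#' @export
path_params <- function(a = 0, n = 0, s = 0, t = 0, e = 1, m = 0, mu = 0) {
  p <- c(a = a, n = n, s = s, t = t, e = e, m = m, mu = mu)
  stopifnot_finite(params = p)
  if (e <= 0) stop("`e` must be strictly positive", call. = FALSE)
  structure(p, class = "path_params")
}

apply_spec <- function(params, spec) {
  p <- unclass(params)
  fixed <- setdiff(spec$fixed_zero, "e")
  p[fixed] <- 0
  p
}

#' Solve the intergenerational equilibrium of an assortment model
#'
#' Under sustained assortative mating and phenotypic transmission the
#' additive-genetic variance q, the familial-environment variance x, the
#' passive gene-environment covariance w, and the total phenotypic
#' variance V settle to a stationary fixed point. Founder additive
#' variance is normalized to 1 (segregation variance 1/2), so q >= 1
#' under phenotypic assortment. For the phenotypic-assortment design the
#' stationary system is
#' \deqn{q = 1 + \mu g^2, \quad w = m g (1 + \mu V), \quad
#'       x = 2 m^2 V (1 + \mu V), \quad
#'       V = a^2 q + n^2 + s^2 + t^2 + x + 2 a w + e^2,}
#' with g = a q + w. Under social homogamy the copath attaches to a
#' latent parental phenotype with zero genetic loadings, so the direct
#' spousal genetic covariance is zero; the analogue system replaces
#' \eqn{\mu g^2} with \eqn{\mu w^2} and propagates the copath through the
#' latent phenotype's covariance c' = s^2 + t^2 + x + a w + e^2.
#'
#' Solved by damped fixed-point iteration (tolerance 1e-10, cap 10000)
#' with a least-squares root-finder fallback.
#'
#' @param spec A [model_spec()].
#' @param params A [path_params()] set (paths fixed to zero by the spec
#'   are zeroed before solving).
#' @return Object of class `equilibrium_state` with elements `q`, `x`,
#'   `w`, `V`, `g`, `c_latent` (SH only; `NA` under PA), `converged`,
#'   `iterations`, `residual`.
#' @examples
#' eq <- solve_equilibrium(model_preset("PA-ASTE"),
#'                         path_params(a = 0.7, s = 0.3, t = 0.4, e = 0.5,
#'                                     mu = 0.4))
#' eq$q  # > 1: assortment inflates additive variance
#' @export
solve_equilibrium <- function(spec, params) {
  stopifnot(inherits(spec, "model_spec"))
  p <- apply_spec(params, spec)
  sh <- spec$design == "NTFD_SH"
  a <- p[["a"]]; n <- p[["n"]]; s <- p[["s"]]; t <- p[["t"]]
  e <- p[["e"]]; m <- p[["m"]]; mu <- p[["mu"]]
  w_zero <- isTRUE(spec$force_w_zero)

  step <- function(st) {
    q <- st[1]; w <- st[2]; x <- st[3]; V <- st[4]
    g <- a * q + w
    cp <- s^2 + t^2 + x + a * w + e^2
    if (sh) {
      q_new <- 1 + mu * w^2
      w_new <- if (w_zero) 0 else m * (g + mu * w * cp)
      x_new <- 2 * m^2 * (V + mu * cp^2)
    } else {
      q_new <- 1 + mu * g^2
      w_new <- if (w_zero) 0 else m * g * (1 + mu * V)
      x_new <- 2 * m^2 * V * (1 + mu * V)
    }
    V_new <- a^2 * q_new + n^2 + s^2 + t^2 + x_new + 2 * a * w_new + e^2
    c(q_new, w_new, x_new, V_new)
  }

  st <- c(1, 0, 0, a^2 + n^2 + s^2 + t^2 + e^2)
  damp <- 0.5
  tol <- 1e-10
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(10000L)) {
    new <- step(st)
    if (!all(is.finite(new))) break
    delta <- max(abs(new - st))
    st <- damp * st + (1 - damp) * new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    # fallback: minimize squared residuals of the stationarity conditions
    obj <- function(v) {
      r <- sum((step(v) - v)^2)
      if (!is.finite(r)) 1e30 else r
    }
    st0 <- c(1, 0, 0, a^2 + n^2 + s^2 + t^2 + e^2)
    opt <- tryCatch(
      stats::optim(st0, obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-16)),
      error = function(e) NULL)
    if (!is.null(opt) && all(is.finite(opt$par)) && obj(opt$par) < 1e-18) {
      st <- opt$par
      converged <- TRUE
    }
  }
  resid <- max(abs(step(st) - st))
  if (!converged || resid > 1e-8) {
    stop("equilibrium solver failed to converge (residual ",
         format(resid), ")", call. = FALSE)
  }
  q <- st[1]; w <- st[2]; x <- st[3]; V <- st[4]
  if (V <= 0) stop("parameter set yields non-positive phenotypic variance",
                   call. = FALSE)
  sp_r <- if (sh) mu * (s^2 + t^2 + x + a * w + e^2)^2 / V else mu * V
  if (abs(sp_r) > 1 + 1e-8) {
    stop(sprintf(
      "implied spousal correlation %.3f exceeds 1; assortment parameters inadmissible",
      sp_r), call. = FALSE)
  }
  g <- a * q + w
  structure(list(q = q, x = x, w = w, V = V, g = g,
                 c_latent = if (sh) s^2 + t^2 + x + a * w + e^2 else NA_real_,
                 converged = converged, iterations = iter, residual = resid,
                 params = p, design = spec$design,
                 r_n_sib = spec$r_n_sib),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "equilibrium (%s): q = %.4f, x = %.4f, w = %.4f, V = %.4f (%d iter)\n",
    x$design, x$q, x$x, x$w, x$V, x$iterations))
  invisible(x)
}

#' Model-implied family covariance matrix
#'
#' Expected covariance matrix of the standardized phenotype for an
#' ordered family member vector (twin1, twin2, sibling, mother, father)
#' under the model, at the solved intergenerational equilibrium. All
#' diagonal entries equal the total variance V (the twin-specific
#' component is modelled as a variance component in every relative
#' class). Key entries under phenotypic assortment:
#' \itemize{
#'   \item MZ twins: \eqn{a^2 q + n^2 + s^2 + t^2 + x + 2 a w}
#'   \item DZ twins: \eqn{a^2 (q - 1/2) + r_N n^2 + s^2 + t^2 + x + 2 a w}
#'   \item twin-sibling: the DZ entry minus \eqn{t^2}
#'   \item parent-offspring: \eqn{(1 + \mu V)(a g / 2 + m V)}
#'   \item spouses: \eqn{\mu V^2}
#' }
#' where \eqn{r_N} is 0.25 under dominance and 0 under epistasis. Under
#' social homogamy the spousal entry is \eqn{\mu c'^2} and the
#' parent-offspring entry \eqn{a (g + \mu w c')/2 + m (V + \mu c'^2)}.
#'
#' @param spec A [model_spec()].
#' @param params A [path_params()] set.
#' @param eq Optional pre-solved [solve_equilibrium()] state.
#' @param zygosity `"MZ"` or `"DZ"` (twin pair of the family).
#' @return 5x5 symmetric matrix with dimnames
#'   `c("twin1","twin2","sibling","mother","father")`.
#' @export
implied_covariance <- function(spec, params, eq = NULL,
                               zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  if (is.null(eq)) eq <- solve_equilibrium(spec, params)
  p <- eq$params
  a <- p[["a"]]; n <- p[["n"]]; s <- p[["s"]]; t <- p[["t"]]
  m <- p[["m"]]; mu <- p[["mu"]]
  q <- eq$q; w <- eq$w; x <- eq$x; V <- eq$V; g <- eq$g
  sh <- spec$design == "NTFD_SH"

  fam_env <- s^2 + t^2 + x + 2 * a * w           # shared by co-twins
  mz_tt <- a^2 * q + n^2 + fam_env
  dz_tt <- a^2 * (q - 0.5) + eq$r_n_sib * n^2 + fam_env
  tw_sib <- dz_tt - t^2
  if (sh) {
    cp <- eq$c_latent
    po <- 0.5 * a * (g + mu * w * cp) + m * (V + mu * cp^2)
    sp <- mu * cp^2
  } else {
    po <- (1 + mu * V) * (0.5 * a * g + m * V)
    sp <- mu * V^2
  }
  tt <- if (zygosity == "MZ") mz_tt else dz_tt
  S <- matrix(0, 5, 5, dimnames = list(FAMILY_ROLES, FAMILY_ROLES))
  diag(S) <- V
  S["twin1", "twin2"] <- tt
  S["twin1", "sibling"] <- S["twin2", "sibling"] <- tw_sib
  S["twin1", "mother"] <- S["twin2", "mother"] <- S["sibling", "mother"] <- po
  S["twin1", "father"] <- S["twin2", "father"] <- S["sibling", "father"] <- po
  S["mother", "father"] <- sp
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  S
}

#' Standardized variance components at equilibrium
#'
#' Expresses the solved model as proportions of total phenotypic
#' variance: A = a^2 q / V (additive, inflated by assortment), N = n^2/V
#' (non-additive), S = s^2/V (sibling-shared environment), T = t^2/V
#' (twin-specific environment), P = x/V (phenotypic transmission),
#' rGE = 2 a w / V (passive gene-environment covariance, possibly
#' negative), E = e^2/V. The components sum to 1.
#'
#' @inheritParams implied_covariance
#' @return Named numeric vector `c(A, N, S, T, P, rGE, E)`.
#' @export
standardize_components <- function(spec, params, eq = NULL) {
  if (is.null(eq)) eq <- solve_equilibrium(spec, params)
  p <- eq$params
  V <- eq$V
  if (V <= 0) stop("non-positive total variance", call. = FALSE)
  full <- c(A = p[["a"]]^2 * eq$q / V,
            N = p[["n"]]^2 / V,
            S = p[["s"]]^2 / V,
            T = p[["t"]]^2 / V,
            P = eq$x / V,
            rGE = 2 * p[["a"]] * eq$w / V,
            E = p[["e"]]^2 / V)
  # CTD designs pool the shared environment into a single C component
  if (spec$design == "CTD_ACE") {
    return(c(A = full[["A"]], C = full[["S"]] + full[["T"]],
             E = full[["E"]]))
  }
  if (spec$design == "CTD_ANE") {
    return(c(A = full[["A"]], N = full[["N"]], E = full[["E"]]))
  }
  full
}

#' Genetic vs environmental mediation of the parent-offspring covariance
#'
#' Splits the model-implied parent-offspring covariance into the share
#' flowing through the offspring's additive genotype versus the share
#' flowing through phenotypic transmission (the familial-environment
#' factor). Under phenotypic assortment these are
#' \eqn{(1+\mu V)\, a g / 2} and \eqn{(1+\mu V)\, m V}; under social
#' homogamy \eqn{a (g + \mu w c')/2} and \eqn{m (V + \mu c'^2)}.
#'
#' @inheritParams implied_covariance
#' @return List with `genetic_share`, `environmental_share` (summing to
#'   1) and the total `covariance`. Errors if the covariance is zero.
#' @export
decompose_parent_offspring <- function(spec, params, eq = NULL) {
  if (is.null(eq)) eq <- solve_equilibrium(spec, params)
  p <- eq$params
  a <- p[["a"]]; m <- p[["m"]]; mu <- p[["mu"]]
  if (spec$design == "NTFD_SH") {
    cp <- eq$c_latent
    gen <- 0.5 * a * (eq$g + mu * eq$w * cp)
    env <- m * (eq$V + mu * cp^2)
  } else {
    gen <- (1 + mu * eq$V) * 0.5 * a * eq$g
    env <- (1 + mu * eq$V) * m * eq$V
  }
  total <- gen + env
  if (abs(total) < 1e-12) {
    stop("parent-offspring covariance is zero; mediation shares undefined",
         call. = FALSE)
  }
  list(genetic_share = gen / total,
       environmental_share = env / total,
       covariance = total)
}
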