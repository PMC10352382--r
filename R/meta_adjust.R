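#' Falconer ACE decomposition from twin correlations
#'
#' Decomposes trait variance into additive genetic (A), shared
#' environmental (C) and nonshared environmental (E) proportions from the
#' monozygotic and dizygotic twin correlations, using Falconer's formulas
#' A = 2(rMZ - rDZ), C = rMZ - A, E = 1 - rMZ. Components falling outside
#' \[0, 1\] are clamped, with the `truncated` flag set (this happens when
#' rDZ > rMZ or rDZ < rMZ/2).
#'
#' @param r_mz Monozygotic twin correlation, in \[-1, 1\].
#' @param r_dz Dizygotic twin correlation, in \[-1, 1\].
#' @return An object of class `ace_estimate`: a list with elements `A`,
#'   `C`, `E` (proportions of variance), `adjusted` (FALSE here) and
#'   `truncated`.
#' @examples
#' falconer_decompose(0.82, 0.48)  # A = 0.68, C = 0.14, E = 0.18
#' @seealso [adjust_for_assortment()] for the assortative-mating correction.
#' @export
falconer_decompose <- function(r_mz, r_dz) {
  check_correlation(r_mz)
  check_correlation(r_dz)
  A <- 2 * (r_mz - r_dz)
  C <- r_mz - A
  E <- 1 - r_mz
  raw <- c(A = A, C = C, E = E)
  clamped <- pmin(pmax(raw, 0), 1)
  new_ace(clamped[["A"]], clamped[["C"]], clamped[["E"]],
          adjusted = FALSE, truncated = any(raw != clamped))
}

#' Adjust Falconer ACE estimates for assortative mating
#'
#' Under positive phenotypic assortment, spouses correlate genetically, so
#' DZ twins share more than half of the trait-relevant additive variance
#' and the Falconer estimator is biased (A downward, C upward). Given the
#' spousal correlation `mu`, the additive proportion solves the
#' phenotypic-assortment identity
#' \deqn{r_{MZ} - r_{DZ} = A (1 - \mu A) / 2,}
#' i.e. the quadratic \eqn{\mu A^2 - A + 2(r_{MZ} - r_{DZ}) = 0}, whose
#' relevant (smaller) root is
#' \eqn{A = [1 - \sqrt{1 - 8\mu(r_{MZ}-r_{DZ})}]/(2\mu)}. C and E follow
#' as in [falconer_decompose()]. When the discriminant is negative, or the
#' implied C would be negative, the estimate is truncated at the
#' no-shared-environment boundary: C = 0, A = rMZ, with the `truncated`
#' flag set. `mu = 0` reduces exactly to the unadjusted decomposition.
#'
#' @inheritParams falconer_decompose
#' @param mu Spousal (parental) phenotypic correlation, in \[0, 1\].
#' @return An `ace_estimate` with `adjusted = TRUE`.
#' @examples
#' adjust_for_assortment(0.89, 0.75, 0.86)  # A = 0.47, C = 0.42
#' adjust_for_assortment(0.82, 0.48, 0.72)  # truncated: A = 0.82, C = 0
#' @export
adjust_for_assortment <- function(r_mz, r_dz, mu) {
  check_correlation(r_mz)
  check_correlation(r_dz)
  stopifnot_finite(mu = mu)
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]", call. = FALSE)
  E <- 1 - r_mz
  if (mu == 0) {
    out <- falconer_decompose(r_mz, r_dz)
    out$adjusted <- TRUE
    return(out)
  }
  disc <- 1 - 8 * mu * (r_mz - r_dz)
  if (disc < 0) {
    return(new_ace(r_mz, 0, E, adjusted = TRUE, truncated = TRUE))
  }
  A <- (1 - sqrt(disc)) / (2 * mu)
  C <- r_mz - A
  if (C < 0) {
    return(new_ace(r_mz, 0, E, adjusted = TRUE, truncated = TRUE))
  }
  new_ace(A, C, E, adjusted = TRUE, truncated = FALSE)
}

new_ace <- function(A, C, E, adjusted, truncated) {
  structure(list(A = unname(A), C = unname(C), E = unname(E),
                 adjusted = adjusted, truncated = truncated),
            class = "ace_estimate")
}

#' @export
print.ace_estimate <- function(x, ...) {
  cat(sprintf("ACE estimate (%s)%s: A = %d%%, C = %d%%, E = %d%%\n",
              if (x$adjusted) "assortment-adjusted" else "unadjusted",
              if (x$truncated) " [truncated]" else "",
              as_percent(x$A), as_percent(x$C), as_percent(x$E)))
  invisible(x)
}

#' Published twin-study subgroups of educational attainment
#'
#' Loads the packaged table of 13 twin-study subgroups of educational
#' attainment for which spousal (or parental) correlations were published:
#' MZ/DZ pair counts, twin correlations, and the spousal correlation used
#' for the assortative-mating adjustment.
#'
#' @param path Optional path to a CSV with the same columns
#'   (`study,sex,cohort,n_mz,n_dz,r_mz,r_dz,r_parents`); defaults to the
#'   packaged fixture.
#' @return A data.frame with one row per study subgroup.
#' @export
ea_twin_studies <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ea_twin_studies.csv", package = "twinfam",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_twin_studies(df)
  df
}

validate_twin_studies <- function(df) {
  needed <- c("study", "sex", "cohort", "n_mz", "n_dz", "r_mz", "r_dz",
              "r_parents")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("study table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) < 1) stop("study table is empty", call. = FALSE)
  if (any(df$n_mz < 1) || any(df$n_dz < 1)) {
    stop("pair counts must be >= 1", call. = FALSE)
  }
  check_correlation(df$r_mz, "r_mz")
  check_correlation(df$r_dz, "r_dz")
  check_correlation(df$r_parents, "r_parents")
  invisible(df)
}

#' ACE decomposition of a table of study subgroups
#'
#' Applies [falconer_decompose()] (and optionally
#' [adjust_for_assortment()]) to every row of a study table.
#'
#' @param studies Data.frame as returned by [ea_twin_studies()].
#' @param adjust Logical; apply the assortative-mating adjustment using
#'   each row's `r_parents`.
#' @return The input with columns `A`, `C`, `E` (proportions) and
#'   `truncated` appended.
#' @export
decompose_studies <- function(studies, adjust = FALSE) {
  validate_twin_studies(studies)
  est <- lapply(seq_len(nrow(studies)), function(i) {
    if (adjust) {
      adjust_for_assortment(studies$r_mz[i], studies$r_dz[i],
                            studies$r_parents[i])
    } else {
      falconer_decompose(studies$r_mz[i], studies$r_dz[i])
    }
  })
  studies$A <- vapply(est, `[[`, numeric(1), "A")
  studies$C <- vapply(est, `[[`, numeric(1), "C")
  studies$E <- vapply(est, `[[`, numeric(1), "E")
  studies$truncated <- vapply(est, `[[`, logical(1), "truncated")
  studies
}

# Delta-method sampling variance of a correlation: Var(r) = (1 - r^2)^2 / n
var_r <- function(r, n) (1 - r^2)^2 / n

# Per-component sampling variances of the Falconer estimators, propagated
# from the correlation variances:
#   Var(A) = 4 [Var(rMZ) + Var(rDZ)]
#   Var(C) = Var(rMZ) + 4 Var(rDZ)
#   Var(E) = Var(rMZ)
component_variances <- function(studies) {
  vmz <- var_r(studies$r_mz, studies$n_mz)
  vdz <- var_r(studies$r_dz, studies$n_dz)
  cbind(A = 4 * (vmz + vdz), C = vmz + 4 * vdz, E = vmz)
}

#' Fixed-effects meta-analysis of twin-study ACE estimates
#'
#' Pools per-study A, C and E proportions with inverse-variance
#' fixed-effects weights, where each component's sampling variance is
#' propagated from the correlation variances Var(r) = (1 - r^2)^2 / n by
#' the delta method (so e.g. Var(A) = 4\[Var(rMZ) + Var(rDZ)\]). When
#' `adjust = TRUE` the per-study estimates are assortment-adjusted but the
#' weights remain those of the unadjusted estimators, whose sampling
#' variances are well defined.
#'
#' @inheritParams decompose_studies
#' @return An object of class `meta_result`: grand means per component,
#'   the per-study weight matrix, the per-study estimates, and `n_studies`.
#' @examples
#' m <- fixed_effects_meta(ea_twin_studies())
#' round(100 * m$grand_mean)  # A 38, C 39
#' @export
fixed_effects_meta <- function(studies, adjust = FALSE) {
  validate_twin_studies(studies)
  est <- decompose_studies(studies, adjust = adjust)
  v <- component_variances(studies)
  if (any(v <= 0)) stop("non-positive sampling variance; check counts",
                        call. = FALSE)
  w <- 1 / v
  comp <- as.matrix(est[, c("A", "C", "E")])
  gm <- colSums(comp * w) / colSums(w)
  structure(list(grand_mean = gm,
                 weights = w,
                 estimates = est,
                 adjusted = adjust,
                 n_studies = nrow(studies)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effects meta-analysis of %d study subgroups (%s)\n",
              x$n_studies,
              if (x$adjusted) "assortment-adjusted" else "unadjusted"))
  cat(sprintf("  grand means: A = %d%%, C = %d%%, E = %d%%\n",
              as_percent(x$grand_mean[["A"]]),
              as_percent(x$grand_mean[["C"]]),
              as_percent(x$grand_mean[["E"]])))
  invisible(x)
}

#' DZ correlation implied by ACE components
#'
#' Returns the dizygotic twin correlation implied by additive genetic and
#' shared environmental proportions: rDZ = 0.5 A + C.
#'
#' @param A,C Non-negative variance proportions with A + C <= 1.
#' @return The implied DZ correlation.
#' @export
derive_rdz_from_ace <- function(A, C) {
  stopifnot_finite(A = A, C = C)
  if (any(A < 0) || any(C < 0)) stop("A and C must be non-negative",
                                     call. = FALSE)
  if (any(A + C > 1 + 1e-9)) stop("A + C must not exceed 1", call. = FALSE)
  0.5 * A + C
}

#' Pool correlations across samples
#'
#' Pools correlations (e.g. male and female subsamples) two ways: the
#' simple arithmetic mean, and the inverse-variance weighted mean on the
#' Fisher-z scale (weights n - 3) transformed back. The two agree whenever
#' the inputs are equal.
#'
#' @param rs Correlations.
#' @param ns Sample sizes (pair counts), each >= 4.
#' @return A list with elements `arithmetic` and `fisher_z`.
#' @export
pool_correlations <- function(rs, ns) {
  if (length(rs) != length(ns)) stop("`rs` and `ns` differ in length",
                                     call. = FALSE)
  if (length(rs) == 0) stop("empty input", call. = FALSE)
  check_correlation(rs, "rs")
  if (any(ns < 4)) stop("each n must be >= 4", call. = FALSE)
  w <- ns - 3
  z <- atanh(rs)
  list(arithmetic = mean(rs), fisher_z = tanh(sum(w * z) / sum(w)))
}
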