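#' Default German qualification-to-years-of-education mapping
#'
#' Maps the highest completed (or currently enrolled) German educational
#' qualification to years of education, spanning 9 (Hauptschulabschluss)
#' to 18 (Promotion). The ladder follows the usual German schooling
#' track lengths.
#'
#' @return Data.frame with columns `qualification` and `years`.
#' @export
german_ea_map <- function() {
  data.frame(
    qualification = c("hauptschule", "realschule", "berufsausbildung",
                      "fachhochschulreife", "abitur", "meister_techniker",
                      "fachhochschul_diplom", "bachelor", "master_diplom",
                      "promotion"),
    years = c(9, 10, 12, 12, 13, 14, 15, 15, 17, 18),
    stringsAsFactors = FALSE)
}

#' Assign years of education from qualification codes
#'
#' Fills `ea_years` from each record's qualification code via the
#' mapping. Records enrolled in an ongoing course (non-missing
#' `enrolled_in`) are assigned the years of that course's completed
#' qualification, on the rationale that German students who leave a
#' course typically attain an alternative qualification of the same type
#' rather than dropping out.
#'
#' @param records Data.frame with a `qualification` column and optional
#'   `enrolled_in` column.
#' @param map Data.frame with `qualification` and `years` columns; see
#'   [german_ea_map()].
#' @return `records` with `ea_years` filled.
#' @export
map_qualifications <- function(records, map = german_ea_map()) {
  if (nrow(map) == 0 && nrow(records) > 0) {
    stop("empty qualification map; unmapped codes: ",
         paste(sort(unique(records$qualification)), collapse = ", "),
         call. = FALSE)
  }
  code <- records$qualification
  if (!is.null(records$enrolled_in)) {
    enrolled <- !is.na(records$enrolled_in) & nzchar(records$enrolled_in)
    code[enrolled] <- records$enrolled_in[enrolled]
  }
  idx <- match(code, map$qualification)
  if (anyNA(idx)) {
    stop("unmapped qualification codes: ",
         paste(sort(unique(code[is.na(idx)])), collapse = ", "),
         call. = FALSE)
  }
  records$ea_years <- map$years[idx]
  records
}

#' Drop siblings born too far from the twins
#'
#' Removes sibling records whose absolute age gap to the family's twins
#' is `max_gap` years or more ("born less than `max_gap` apart" is
#' strict). Siblings with missing ages are retained and flagged.
#'
#' @param table Long-format family table.
#' @param max_gap Maximum allowed gap in years (exclusive); default 5.
#' @return Filtered table with attributes `n_removed` and
#'   `n_missing_age`.
#' @export
filter_siblings <- function(table, max_gap = 5) {
  sib <- table$role == "sibling"
  twin_age <- tapply(table$age[table$role %in% c("twin1", "twin2")],
                     table$family_id[table$role %in% c("twin1", "twin2")],
                     function(a) mean(a, na.rm = TRUE))
  gap <- abs(table$age - twin_age[as.character(table$family_id)])
  unknown <- sib & is.na(gap)
  drop <- sib & !is.na(gap) & gap >= max_gap
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  attr(out, "n_missing_age") <- sum(unknown)
  out
}

#' Residualize years of education on age and sex
#'
#' Regresses `ea_years` on age, sex, age squared and the age-by-sex
#' interaction by least squares, separately within generation (offspring:
#' twins and siblings; parents: mother and father), and stores the
#' z-standardized residuals in `ea_std` (mean 0, SD 1 within each
#' stratum). Strata with fewer than 10 complete records fall back to
#' centering and scaling only, with a warning.
#'
#' @param table Long-format family table with `age`, `sex`, `ea_years`.
#' @param quadratic Include the quadratic age term and interaction
#'   (default); `FALSE` gives a plain linear age + sex correction.
#' @return The table with `ea_std` filled.
#' @export
residualize <- function(table, quadratic = TRUE) {
  table$ea_std <- NA_real_
  gen <- ifelse(table$role %in% c("mother", "father"), "parent", "offspring")
  for (gname in unique(gen)) {
    i <- which(gen == gname & !is.na(table$ea_years))
    if (length(i) < 10) {
      warning("stratum `", gname, "` has < 10 records; centering only")
      z <- scale(table$ea_years[i])[, 1]
    } else {
      d <- data.frame(ea = table$ea_years[i], age = table$age[i],
                      sex = factor(table$sex[i]))
      form <- if (quadratic && nlevels(d$sex) > 1) {
        ea ~ age + I(age^2) + sex + age:sex
      } else if (quadratic) {
        ea ~ age + I(age^2)
      } else if (nlevels(d$sex) > 1) {
        ea ~ age + sex
      } else {
        ea ~ age
      }
      res <- stats::residuals(stats::lm(form, data = d))
      z <- scale(res)[, 1]
    }
    table$ea_std[i] <- z
  }
  table
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' @param r Correlation estimate.
#' @param n Number of pairs.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`:
#'   tanh(atanh(r) +/- z / sqrt(n - 3)).
#' @examples
#' fisher_ci(0.769, 498)
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  check_correlation(r)
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(atanh(r) + c(-1, 1) * half)
}

#' Dyadic correlations between family members
#'
#' Pearson correlations of the standardized phenotype for the standard
#' dyads: MZ twin pairs, DZ twin pairs, sibling and a random twin,
#' mother/father and a random twin, mother/father and sibling, and the
#' two parents. "Random twin" dyads use one seeded random twin per family
#' (so each family contributes a single pair). Confidence intervals are
#' Fisher-z based.
#'
#' @param table Long-format family table with `ea_std` filled.
#' @param seed Seed for the random-twin choice (default 2023).
#' @param min_pairs Dyads with fewer complete pairs are omitted with a
#'   warning (default 4).
#' @return Data.frame with columns `dyad`, `r`, `ci_low`, `ci_high`,
#'   `n_pairs`.
#' @export
dyad_correlations <- function(table, seed = 2023, min_pairs = 4) {
  if (all(is.na(table$ea_std))) {
    stop("`ea_std` is empty; run residualize() first", call. = FALSE)
  }
  wide <- family_wide(table, value = "ea_std")
  Y <- wide$Y
  set.seed(as.integer(seed))
  pick <- sample(c("twin1", "twin2"), nrow(Y), replace = TRUE)
  rnd_twin <- ifelse(pick == "twin1", Y[, "twin1"], Y[, "twin2"])
  # fall back to the co-twin when the picked twin is missing
  rnd_twin[is.na(rnd_twin)] <-
    ifelse(pick == "twin1", Y[, "twin2"], Y[, "twin1"])[is.na(rnd_twin)]
  pairs <- list(
    mz_twins = cbind(Y[wide$zygosity == "MZ", "twin1"],
                     Y[wide$zygosity == "MZ", "twin2"]),
    dz_twins = cbind(Y[wide$zygosity == "DZ", "twin1"],
                     Y[wide$zygosity == "DZ", "twin2"]),
    sibling_twin = cbind(Y[, "sibling"], rnd_twin),
    mother_twin = cbind(Y[, "mother"], rnd_twin),
    mother_sibling = cbind(Y[, "mother"], Y[, "sibling"]),
    father_twin = cbind(Y[, "father"], rnd_twin),
    father_sibling = cbind(Y[, "father"], Y[, "sibling"]),
    parents = cbind(Y[, "mother"], Y[, "father"]))
  out <- lapply(names(pairs), function(nm) {
    xy <- pairs[[nm]][stats::complete.cases(pairs[[nm]]), , drop = FALSE]
    n <- nrow(xy)
    if (n < min_pairs) {
      warning("dyad `", nm, "` has fewer than ", min_pairs,
              " complete pairs; omitted")
      return(NULL)
    }
    r <- stats::cor(xy[, 1], xy[, 2])
    ci <- fisher_ci(r, n)
    data.frame(dyad = nm, r = r, ci_low = ci[1], ci_high = ci[2],
               n_pairs = n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full preprocessing pipeline
#'
#' Qualification mapping (when `ea_years` is absent), sibling age
#' filtering, and age/sex residualization, in order. Applying the
#' pipeline twice equals applying it once.
#'
#' @param table Long-format family table.
#' @param map Qualification map (used only when `ea_years` is missing).
#' @param max_gap Sibling age-gap limit.
#' @param quadratic Passed to [residualize()].
#' @return Preprocessed table with `ea_std` filled.
#' @export
preprocess_families <- function(table, map = german_ea_map(), max_gap = 5,
                                quadratic = TRUE) {
  if (is.null(table$ea_years) || all(is.na(table$ea_years))) {
    table <- map_qualifications(table, map)
  }
  table <- filter_siblings(table, max_gap = max_gap)
  residualize(table, quadratic = quadratic)
}
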