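# internal helpers shared across modules

# round half away from zero (display convention for percentage tables;
# base round() uses banker's rounding which disagrees at .5 cells)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

as_percent <- function(x) round_half_up(100 * x)

stopifnot_finite <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    if (!all(is.finite(args[[i]]))) {
      stop(sprintf("`%s` must be finite, got %s", nm[i],
                   paste(format(args[[i]]), collapse = ", ")), call. = FALSE)
    }
  }
  invisible(TRUE)
}

check_correlation <- function(r, name = deparse(substitute(r))) {
  stopifnot_finite(r = r)
  if (any(r < -1 | r > 1)) {
    stop(sprintf("`%s` must lie in [-1, 1]", name), call. = FALSE)
  }
  invisible(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of an R object via its serialized form (provenance stamps)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
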