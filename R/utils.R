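# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All user-facing randomness funnels
# through this so that a single integer seed reproduces a whole run.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a root seed; keeps results < 2^31.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 1000003 * k) %% 2147483587)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

assert_vitals <- function(vitals, channels = NULL) {
  if (!is.data.frame(vitals)) abort("`vitals` must be a data frame")
  need <- c("case_id", "time_min", channels)
  missing_cols <- setdiff(need, names(vitals))
  if (length(missing_cols)) {
    abort(paste0("`vitals` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  invisible(vitals)
}

channel_cols <- function(vitals) {
  setdiff(names(vitals), c("case_id", "patient_id", "time_min"))
}

# type-7 (linear interpolation) percentile, the R default, used everywhere
pctl <- function(x, p) unname(quantile(x, probs = p / 100, na.rm = TRUE, type = 7))
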