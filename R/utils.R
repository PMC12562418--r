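# shared internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched so seeded operations compose deterministically.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# round half away from zero, matching how results tables are formatted; the
# 1e-9 guard keeps decimal halves (stored slightly below .5 in binary) from
# rounding down
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

one_hot <- function(labels, n_classes = NULL) {
  labels <- as.integer(labels)
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  if (any(labels < 0L | labels >= n_classes))
    abort("labels must lie in 0..n_classes-1", class = "spectraseed_config_error")
  out <- matrix(0, length(labels), n_classes)
  out[cbind(seq_along(labels), labels + 1L)] <- 1
  out
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    abort(sprintf("`%s` must be an integer >= %s", name, min),
          class = "spectraseed_config_error")
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    abort(sprintf("`%s` must be a non-negative scalar", name),
          class = "spectraseed_config_error")
  as.numeric(x)
}
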