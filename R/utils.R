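# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state
# afterwards so package functions are pure in their `seed` argument.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Feature matrix (numeric, no id column) from a feature tibble.
feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("id", "label"))
  mat <- as.matrix(features[, cols, drop = FALSE])
  if (!is.numeric(mat) || any(!is.finite(mat))) {
    abort("feature matrix must be finite numeric")
  }
  mat
}
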