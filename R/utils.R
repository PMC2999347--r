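`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so seeded package functions do not perturb
# user-level randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic substream seeds: `n` integers drawn under the master seed.
# Used to give each forest, tree and permutation its own reproducible
# stream (R integers are 32-bit, hence the bound).
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Internal canonical class coding: factor with levels negative < positive.
as_label_factor <- function(x) {
  lv <- c("negative", "positive")
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- ifelse(x, "positive", "negative")
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      stop("numeric labels must be 0 (negative) or 1 (positive)")
    }
    x <- ifelse(x == 1, "positive", "negative")
  }
  if (!all(x %in% lv)) {
    stop("labels must be 'positive'/'negative' (or logical/0-1)")
  }
  factor(x, levels = lv)
}
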