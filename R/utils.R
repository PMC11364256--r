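# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# simulations.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seeds: mixes a master seed with stream offsets,
# staying inside the 31-bit signed-integer range R requires.
derive_seed <- function(seed, ...) {
  ks <- c(as.numeric(seed), as.numeric(c(...)))
  h <- 0
  for (k in ks) h <- (h * 69069 + k + 1) %% 2147483629
  as.integer(h)
}

clamp01 <- function(x) { # preserves dim attributes, unlike pmin/pmax
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Trapezoidal area under y(x); x need not be sorted.
trapz <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unknown_labels <- c("novel_category", "poor_quality", "multiple_views")

is_unknown_label <- function(label) label %in% unknown_labels
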