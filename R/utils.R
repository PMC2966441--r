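# Internal helpers shared across the package.

# Evaluate `code` under a given RNG seed without disturbing the caller's
# RNG state. All stochastic functions in the package route through this so
# that a seed argument fully determines the output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a master seed and a stream index; kept within
# 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k)) %% 2147483647)
}

stopif_not_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

# Condition label helpers: conditions are tokens like "L_low".
condition_label <- function(eye, sf) paste(eye, sf, sep = "_")

parse_condition <- function(label) {
  parts <- strsplit(label, "_", fixed = TRUE)
  eye <- vapply(parts, `[`, "", 1L)
  sf <- vapply(parts, `[`, "", 2L)
  bad <- !(eye %in% c("L", "R")) | !(sf %in% c("low", "high"))
  if (any(bad)) {
    stop("unknown condition label(s): ", paste(unique(label[bad]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(eye = eye, sf = sf, stringsAsFactors = FALSE)
}
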