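# internal helpers: seeded RNG streams, classed errors, argument checks

# Derived per-stage seeds from one root seed. Streams are consumed in a fixed,
# documented order (see the methods vignette): genotypes = 1, ascertainment
# batches = 100 + batch, serology = 2, pcs = 3, haplotypes = 4.
derive_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root))
  as.integer((as.double(root) * 48271 + stage * 10007) %% 2147483647)
}

# Evaluate `code` under a fixed seed without clobbering the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

mn_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mnarch_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

config_error <- function(message, ...) mn_error("mnarch_config_error", message, ...)
data_error <- function(message, ...) mn_error("mnarch_data_error", message, ...)
numeric_error <- function(message, ...) mn_error("mnarch_numeric_error", message, ...)

check_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) config_error(sprintf("`%s` must be in %s", name,
                                if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
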