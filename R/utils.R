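# Internal helpers shared across modules.

# Run `expr` under a temporarily-seeded RNG, restoring the caller's RNG state.
# All stochastic package code funnels through this so that user-level seeds
# are honoured without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

# Deterministic sub-seed derivation; keeps results below 2^31 - 1.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p)) %% 2147483629
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_caspnet <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop_caspnet(sprintf("'%s' must be a probability in [0, 1], got %s",
                         name, format(x)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != round(x)) {
    stop_caspnet(sprintf("'%s' must be an integer >= %d, got %s",
                         name, min, format(x)))
  }
  invisible(as.integer(x))
}

is_finite_all <- function(x) all(is.finite(x))

# Flatten a nested list of numeric arrays into a flat named list, names
# joined with "." -- used by the optimizer, parameter counting and
# checkpointing.
flatten_params <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    el <- x[[nm]]
    if (is.list(el)) {
      out <- c(out, flatten_params(el, key))
    } else if (!is.null(el)) {
      out[[key]] <- el
    }
  }
  out
}

# Inverse of flatten_params given a template with the target nesting.
unflatten_params <- function(flat, template) {
  relist_one <- function(tmpl, prefix) {
    if (!is.list(tmpl)) {
      return(flat[[prefix]])
    }
    out <- vector("list", length(tmpl))
    names(out) <- names(tmpl)
    for (nm in names(tmpl)) {
      key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
      out[[nm]] <- relist_one(tmpl[[nm]], key)
    }
    out
  }
  relist_one(template, NULL)
}
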