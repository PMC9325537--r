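#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Typed conditions so callers (and the CLI) can distinguish user-input problems
# from programming errors.
grn_stop <- function(msg, class = "grn_validation_error", call. = FALSE) {
  cnd <- structure(
    class = c(class, "grn_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cnd)
}

grn_warn <- function(msg, class = "grn_warning") {
  cnd <- structure(
    class = c(class, "grn_warning_base", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cnd)
}

# One top-level seed deterministically derives per-stage seeds, all < 2^31.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- sum(utf8ToInt(stage)) %% 1000L
  as.integer((abs(seed) * 7919 + offs * 104729 + 12345) %% 2147483647)
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

sign_chr <- function(x, tol = 1e-12) {
  ifelse(abs(x) <= tol, "none", ifelse(x > 0, "+", "-"))
}
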