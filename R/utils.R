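# Internal helpers shared across modules.

plex_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "plexscreen_error")))
}

#' Toggle pipeline stage logging
#'
#' When `options(plexscreen.verbose = TRUE)` each pipeline stage reports its
#' input/output entity counts via [message()], mirroring the per-stage
#' retention bookkeeping screens require.
#'
#' @param stage Character scalar naming the stage.
#' @param msg `sprintf` format string.
#' @param ... Values interpolated into `msg`.
#' @return Invisibly `NULL`.
#' @keywords internal
plex_log <- function(stage, msg, ...) {
  if (isTRUE(getOption("plexscreen.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
  }
  invisible(NULL)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic 31-bit string hash (polynomial rolling hash), used to derive
# independent RNG substreams per (model, treatment) group.
string_hash31 <- function(x) {
  codes <- utf8ToInt(paste(x, collapse = "\r"))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
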