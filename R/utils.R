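# Small internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.  All randomness in the package flows through this so that
# runs are bitwise reproducible and never disturb the user's RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Content hash of an arbitrary R object (used for determinism and leakage
# sentinels).  Serializes without version/header ambiguity and md5s the bytes.
hash_of <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(raw, f)
  unname(tools::md5sum(f))
}

# Gated diagnostic messages; enable with options(voxelsurv.verbose = TRUE).
vx_note <- function(...) {
  if (isTRUE(getOption("voxelsurv.verbose", FALSE)))
    message("voxelsurv: ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize an outcome to the package's internal representation
#'
#' Outcomes are survival (right-censored time-to-event), gaussian, or
#' binomial.  Survival outcomes may be supplied as a [survival::Surv] object
#' or as a list/data.frame with `time` and `event` components.
#'
#' @param y outcome: a `Surv` object, a list with `time` and `event`, or a
#'   numeric (gaussian) / 0-1 (binomial) vector.
#' @param family one of `"survival"` (alias `"cox"`), `"gaussian"`,
#'   `"binomial"`; inferred from `y` when possible.
#' @return a list with elements `family`, and `time`/`event` or `y`.
#' @export
as_vx_outcome <- function(y, family = NULL) {
  if (inherits(y, "vx_outcome")) return(y)
  if (survival::is.Surv(y)) {
    out <- list(family = "survival", time = as.numeric(y[, "time"]),
                event = as.numeric(y[, "status"]))
  } else if (is.list(y) && !is.null(y$time)) {
    out <- list(family = "survival", time = as.numeric(y$time),
                event = as.numeric(y$event))
  } else {
    if (is.null(family)) {
      family <- if (all(y %in% c(0, 1))) "binomial" else "gaussian"
    }
    out <- list(family = family, y = as.numeric(y))
  }
  if (!is.null(family)) {
    family <- match.arg(family, c("survival", "cox", "gaussian", "binomial"))
    if (family == "cox") family <- "survival"
    if (xor(out$family == "survival", family == "survival"))
      stop("outcome shape does not match family = ", family)
    out$family <- family
  }
  if (out$family == "survival") {
    stopifnot(all(out$time > 0), all(out$event %in% c(0, 1)))
  }
  class(out) <- "vx_outcome"
  out
}

vx_outcome_n <- function(o) length(o$time %||% o$y)
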