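# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a condition class prefixed
#' `sphingoem_` so callers (and tests) can match on failure mode rather than
#' message text.
#'
#' @param class short error class, e.g. "validation"
#' @param ... message parts passed to [sprintf()]-free [paste0()]
#' @noRd
sphingo_abort <- function(class, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(paste0("sphingoem_", class), "sphingoem_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
sphingo_warn <- function(class, ...) {
  msg <- paste0(...)
  warning(structure(
    class = c(paste0("sphingoem_", class), "sphingoem_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Derive a child RNG seed from a base seed and a label
#'
#' Keeps every stochastic stage of the pipeline reproducible from one user
#' seed while decorrelating stages. Result is kept below 2^31 - 1.
#' @noRd
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 2654435.0) %% 2147483629) + 1L
}

#' Evaluate an expression with a locally-set RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Gas constant, kJ/(mol K)
.R_GAS <- 0.0083144626

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
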