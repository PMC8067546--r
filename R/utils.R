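# internal helpers: condition constructors, seed derivation, numerics

nwStop <- function(msg, class) {
  stop(structure(
    class = c(class, "nwError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

nwWarn <- function(msg, class) {
  warning(structure(
    class = c(class, "nwWarning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assertPositiveScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    nwStop(sprintf("'%s' must be a positive finite scalar", name),
           "nwInvalidParameterError")
  invisible(x)
}

assertNonNegativeScalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    nwStop(sprintf("'%s' must be a non-negative finite scalar", name),
           "nwInvalidParameterError")
  invisible(x)
}

## Gas constant, kcal/(mol K).  Entropies are reported in cal/(mol K),
## so the cal-scale constant is also kept.
.RGasKcal <- 1.987e-3
.RGasCal <- 1.987

#' Gas constant used throughout the package
#'
#' @return The gas constant in kcal/(mol K), 1.987e-3.
#' @export
gasConstantKcal <- function() .RGasKcal

## Deterministic 31-bit seed from a base seed and a character label, so
## that each spot gets its own named stream and fixture sets are
## order-independent.  Plain polynomial string hash; not cryptographic.
deriveSeed <- function(baseSeed, label) {
  stopifnot(is.numeric(baseSeed), length(baseSeed) == 1L)
  h <- as.double(baseSeed %% 2147483647)
  for (k in utf8ToInt(as.character(label))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

## Evaluate an expression with a locally seeded RNG, restoring (or
## removing) the global .Random.seed afterwards.
withLocalSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## md5 of a character scalar via a temp file (no digest package available)
md5Hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
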