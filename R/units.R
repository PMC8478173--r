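#' Unit conversion helpers
#'
#' Raw biaxial data are kept in lab units (mmHg, micrometres, millinewtons);
#' all mechanics is computed internally in SI. 1 mmHg = 133.322 Pa.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / 133.322

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
mN_to_N <- function(x) x * 1e-3

# Seed handling: generators are pure functions of (spec, seed).  Setting a
# seed inside a function must not disturb the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
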