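## internal helpers shared across modules

# element symbol <-> nuclear charge lookup (organic subset + common others)
.ZTABLE <- c(H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L,
             O = 8L, F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L,
             Si = 14L, P = 15L, S = 16L, Cl = 17L, Ar = 18L, K = 19L,
             Ca = 20L, Br = 35L, I = 53L)

#' Map element symbols to nuclear charges
#'
#' @param symbols character vector of element symbols (e.g. "C", "Cl").
#' @return integer vector of nuclear charges, named by symbol.
#' @examples
#' elementToZ(c("H", "C", "O"))
#' @export
elementToZ <- function(symbols) {
  z <- .ZTABLE[symbols]
  if (anyNA(z))
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(z)]), collapse = ", "))
  z
}

#' Map nuclear charges to element symbols
#'
#' @param z integer vector of nuclear charges.
#' @return character vector of element symbols.
#' @export
zToElement <- function(z) {
  idx <- match(as.integer(z), .ZTABLE)
  if (anyNA(idx))
    stop("unknown nuclear charge(s): ", paste(unique(z[is.na(idx)]), collapse = ", "))
  names(.ZTABLE)[idx]
}

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic 31-bit string hash (scaffold -> template seed)
.stableHash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

.classLevels <- c("I_saturated", "II_single_unsaturated", "III_aromatic_carbonyl")
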