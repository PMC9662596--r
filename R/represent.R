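#' Build the representation basis of a dataset
#'
#' Collects the element types over all molecules and expands them into the
#' canonical channel layout: elements ascending by nuclear charge, all
#' unordered element pairs (lexicographic), and all (pair, centre element)
#' triples (lexicographic in pair, then centre). The basis is a function of
#' the element set only, so shuffling molecules cannot change it, and every
#' molecule of the dataset maps to a vector of one shared length.
#'
#' @param x a [MoleculeSet-class] (non-empty).
#' @return a [RepresentationBasis-class].
#' @examples
#' ms <- MoleculeSet(ids = "ch4", elements = list(c("C", "H", "H", "H", "H")),
#'                   coords = list(matrix(rnorm(15), 5, 3)))
#' buildBasis(ms)  # elements {1, 6}; pairs (1,1), (1,6), (6,6)
#' @export
buildBasis <- function(x) {
  if (!nMol(x)) stop("empty dataset: cannot build a basis")
  els <- sort(unique(unlist(x@charges)))
  pr <- expand.grid(a = els, b = els)
  pr <- as.matrix(pr[pr$a <= pr$b, c("a", "b")])
  pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE]
  tr <- expand.grid(p = seq_len(nrow(pr)), c = els)
  tr <- cbind(pr[tr$p, , drop = FALSE], center = tr$c)
  tr <- tr[order(tr[, 1], tr[, 2], tr[, 3]), , drop = FALSE]
  dimnames(pr) <- dimnames(tr) <- NULL
  new("RepresentationBasis", elements = as.integer(els),
      pairs = matrix(as.integer(pr), ncol = 2),
      triples = matrix(as.integer(tr), ncol = 3))
}

#' @export
setMethod("show", "RepresentationBasis", function(object) {
  cat(sprintf("RepresentationBasis: %d elements (%s), %d pairs, %d triples\n",
              length(object@elements),
              paste(zToElement(object@elements), collapse = ", "),
              nrow(object@pairs), nrow(object@triples)))
})

#' Representation configuration
#'
#' Grids and Gaussian widths of the spectral representation. The defaults
#' (radial grid 0.2-8.0 A at 0.05 A with 0.05 A width; 40 angular bins over
#' 0..pi with 0.05 rad width; 4.8 A three-body cutoff) are conventional
#' for this family of spectra and are fully exposed.
#'
#' @param rMin,rMax,dr radial grid start, end and step (Angstrom).
#' @param sigmaR radial Gaussian width (Angstrom).
#' @param thetaBins angular bins over 0..pi.
#' @param sigmaTheta angular Gaussian width (radians).
#' @param rCut three-body neighbour cutoff (Angstrom).
#' @return a [RepresentationConfig-class].
#' @export
repConfig <- function(rMin = 0.2, rMax = 8.0, dr = 0.05, sigmaR = 0.05,
                      thetaBins = 40L, sigmaTheta = 0.05, rCut = 4.8) {
  new("RepresentationConfig", rMin = rMin, rMax = rMax, dr = dr,
      sigmaR = sigmaR, thetaBins = as.integer(thetaBins),
      sigmaTheta = sigmaTheta, rCut = rCut)
}

#' @export
setMethod("show", "RepresentationConfig", function(object) {
  cat(sprintf(
    "RepresentationConfig: r in [%.2f, %.2f] A by %.3f (sigma %.3f), %d theta bins (sigma %.3f rad), rCut %.2f A\n",
    object@rMin, object@rMax, object@dr, object@sigmaR, object@thetaBins,
    object@sigmaTheta, object@rCut))
})

.radialGrid <- function(config) seq(config@rMin, config@rMax, by = config@dr)
.angularGrid <- function(config) seq(0, pi, length.out = config@thetaBins)

#' Length of a representation vector under a basis and configuration
#' @param basis a [RepresentationBasis-class].
#' @param config a [RepresentationConfig-class].
#' @export
repLength <- function(basis, config) {
  length(basis@elements) +
    nrow(basis@pairs) * length(.radialGrid(config)) +
    nrow(basis@triples) * config@thetaBins
}

#' SLATM-style spectral representation of one molecule
#'
#' Concatenates, in basis order: a one-body block (atom count per element
#' times nuclear charge), a two-body block per element pair (sum over
#' matching atom pairs of normalised Gaussians centred at the interatomic
#' distance on the radial grid, each scaled by the London-dispersion-style
#' weight 0.5 * Z_i * Z_j / r^6 * dr), and a three-body block per (pair,
#' centre) triple (sum over centre atoms and neighbour pairs within `rCut`
#' of Gaussians in the central angle, scaled by Z_i * Z_j * Z_k / 3 * dtheta).
#' Built from internal distances and angles only, the vector is invariant
#' under rigid rotation, translation, reflection and atom reindexing.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param charges integer nuclear charges (length N).
#' @param basis a [RepresentationBasis-class]; every element of the
#'   molecule must be present.
#' @param config a [RepresentationConfig-class].
#' @return numeric vector of length [repLength()].
#' @export
slatmVector <- function(coords, charges, basis, config = repConfig()) {
  coords <- as.matrix(coords); storage.mode(coords) <- "double"
  rg <- .radialGrid(config); tg <- .angularGrid(config)
  dt <- pi / (config@thetaBins - 1L)
  cpp_slatm(as.integer(charges), coords, basis@elements, basis@pairs,
            basis@triples, rg, config@sigmaR, config@dr, tg,
            config@sigmaTheta, dt, config@rCut)
}

#' SLATM-style representation matrix of a MoleculeSet
#'
#' @param x a [MoleculeSet-class].
#' @param basis a [RepresentationBasis-class] (default: built from `x`).
#' @param config a [RepresentationConfig-class].
#' @return numeric matrix, one row per molecule, rownames = molecule ids.
#' @export
slatmMatrix <- function(x, basis = buildBasis(x), config = repConfig()) {
  n <- nMol(x)
  out <- matrix(0, n, repLength(basis, config))
  for (i in seq_len(n))
    out[i, ] <- slatmVector(x@coords[[i]], x@charges[[i]], basis, config)
  rownames(out) <- x@ids
  out
}

#' Coulomb-matrix eigenvalue spectrum
#'
#' The heuristic fallback representation: the matrix with diagonal
#' 0.5 * Z_i^2.4 and off-diagonal Z_i * Z_j / r_ij (r in Angstrom), reduced
#' to its eigenvalues sorted by descending absolute value and zero-padded
#' to `nMax`. Permutation-invariant by construction.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param charges integer nuclear charges.
#' @param nMax padded length, at least the atom count.
#' @return numeric vector of length `nMax`.
#' @examples
#' coulombEigs(matrix(0, 1, 3), 1L, nMax = 3)        # (0.5, 0, 0)
#' @export
coulombEigs <- function(coords, charges, nMax) {
  coords <- as.matrix(coords)
  n <- length(charges)
  if (n < 1) stop("molecule must have at least one atom")
  if (nMax < n) stop("nMax must be at least the atom count (", n, ")")
  d <- as.matrix(stats::dist(coords))
  if (n > 1 && any(d[upper.tri(d)] == 0))
    stop("geometry error: coincident atoms (zero interatomic distance)")
  M <- outer(charges, charges) / pmax(d, .Machine$double.eps)
  diag(M) <- 0.5 * charges^2.4
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[order(abs(ev), decreasing = TRUE)]
  c(ev, rep(0, nMax - n))
}
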