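#' @useDynLib selml, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.emptyRecords <- function() {
  data.frame(id = character(), level = character(), homo = numeric(),
             lumo = numeric(), gap = numeric(), stringsAsFactors = FALSE)
}

#' MoleculeSet: molecules plus property records
#'
#' Central container of the package: a set of molecules (identity, optional
#' SMILES, element symbols, Cartesian coordinates in Angstrom, nuclear
#' charges) together with a table of property records (HOMO, LUMO and gap in
#' eV at one or more named levels of theory).
#'
#' Validity enforces: unique ids; per-molecule agreement of element,
#' coordinate and charge lengths; finite coordinates; charges consistent with
#' element symbols; every record id resolving to a molecule; at most one
#' record per (id, level); and the gap identity |gap - (lumo - homo)| <=
#' 1e-6 eV whenever all three energies are present.
#'
#' @slot ids character vector of unique molecule identifiers.
#' @slot smiles character vector, `NA` where only a geometry is known.
#' @slot elements list of character vectors of element symbols.
#' @slot coords list of numeric N x 3 matrices (Angstrom).
#' @slot charges list of integer vectors of nuclear charges.
#' @slot records data.frame with columns id, level, homo, lumo, gap (eV).
#' @aliases MoleculeSet-class
#' @exportClass MoleculeSet
setClass("MoleculeSet",
  representation(ids = "character", smiles = "character",
                 elements = "list", coords = "list", charges = "list",
                 records = "data.frame"),
  prototype(ids = character(), smiles = character(), elements = list(),
            coords = list(), charges = list(), records = .emptyRecords()))

setValidity("MoleculeSet", function(object) {
  n <- length(object@ids)
  msg <- character()
  if (anyDuplicated(object@ids))
    msg <- c(msg, paste("duplicate molecule ids:",
      paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
  if (length(object@smiles) != n || length(object@elements) != n ||
      length(object@coords) != n || length(object@charges) != n)
    msg <- c(msg, "slot lengths differ from number of ids")
  else for (i in seq_len(n)) {
    el <- object@elements[[i]]; xyz <- object@coords[[i]]; ch <- object@charges[[i]]
    if (!is.matrix(xyz) || ncol(xyz) != 3 || nrow(xyz) != length(el) ||
        length(ch) != length(el)) {
      msg <- c(msg, sprintf("molecule '%s': elements/coords/charges lengths disagree",
                            object@ids[i]))
      next
    }
    if (!all(is.finite(xyz)))
      msg <- c(msg, sprintf("molecule '%s': non-finite coordinates", object@ids[i]))
    expect <- unname(elementToZ(el))
    if (!identical(as.integer(ch), as.integer(expect)))
      msg <- c(msg, sprintf("molecule '%s': charges inconsistent with elements",
                            object@ids[i]))
  }
  rec <- object@records
  need <- c("id", "level", "homo", "lumo", "gap")
  if (!all(need %in% names(rec)))
    msg <- c(msg, "records must have columns id, level, homo, lumo, gap")
  else if (nrow(rec)) {
    bad <- setdiff(rec$id, object@ids)
    if (length(bad))
      msg <- c(msg, paste("records reference unknown ids:",
                          paste(utils::head(bad, 5), collapse = ", ")))
    key <- paste(rec$id, rec$level, sep = "\r")
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (id, level) property records")
    full <- !is.na(rec$homo) & !is.na(rec$lumo) & !is.na(rec$gap)
    if (any(full) &&
        any(abs(rec$gap[full] - (rec$lumo[full] - rec$homo[full])) > 1e-6))
      msg <- c(msg, "gap differs from lumo - homo by more than 1e-6 eV")
  }
  if (length(msg)) msg else TRUE
})

#' DensityCurve: one tag's share of the gap distribution
#'
#' A Gaussian-kernel density estimate of the HOMO-LUMO gaps of the molecules
#' matching one structural tag, scaled so that its integral equals the
#' fraction of the whole dataset carrying the tag.
#'
#' @slot grid gap values (eV) at which the density is evaluated.
#' @slot density non-negative density values.
#' @slot weight fraction of the dataset carrying the tag.
#' @aliases DensityCurve-class
#' @exportClass DensityCurve
setClass("DensityCurve",
  representation(grid = "numeric", density = "numeric", weight = "numeric"))

setValidity("DensityCurve", function(object) {
  msg <- character()
  if (any(object@density < 0)) msg <- c(msg, "negative density values")
  if (length(object@density) != length(object@grid))
    msg <- c(msg, "grid/density length mismatch")
  if (length(object@grid) > 1) {
    integ <- sum(diff(object@grid) *
                 (utils::head(object@density, -1) + utils::tail(object@density, -1)) / 2)
    if (abs(integ - object@weight) > 1e-3)
      msg <- c(msg, sprintf("density integrates to %.5f, weight is %.5f",
                            integ, object@weight))
  }
  if (length(msg)) msg else TRUE
})

#' RepresentationBasis: element, pair and triple channels
#'
#' The canonical, dataset-wide channel layout for spectral representations:
#' elements in ascending nuclear charge, unordered element pairs in
#' lexicographic order, and (pair, centre element) triples in lexicographic
#' order. Identical for every molecule of one dataset, so all vectors share
#' one length.
#'
#' @slot elements integer vector of nuclear charges, ascending.
#' @slot pairs integer matrix, one row (z_a, z_b) per unordered pair, z_a <= z_b.
#' @slot triples integer matrix, one row (z_a, z_b, z_centre) per triple.
#' @aliases RepresentationBasis-class
#' @exportClass RepresentationBasis
setClass("RepresentationBasis",
  representation(elements = "integer", pairs = "matrix", triples = "matrix"))

setValidity("RepresentationBasis", function(object) {
  msg <- character()
  if (is.unsorted(object@elements, strictly = TRUE))
    msg <- c(msg, "elements must be strictly ascending nuclear charges")
  if (ncol(object@pairs) != 2) msg <- c(msg, "pairs must have two columns")
  if (ncol(object@triples) != 3) msg <- c(msg, "triples must have three columns")
  if (nrow(object@pairs) && any(object@pairs[, 1] > object@pairs[, 2]))
    msg <- c(msg, "pair rows must satisfy z_a <= z_b")
  if (length(msg)) msg else TRUE
})

#' RepresentationConfig: grids and widths of the spectral representation
#'
#' @slot rMin,rMax radial grid bounds (Angstrom).
#' @slot dr radial grid step (Angstrom).
#' @slot sigmaR radial Gaussian width (Angstrom).
#' @slot thetaBins number of angular bins over 0..pi.
#' @slot sigmaTheta angular Gaussian width (radians).
#' @slot rCut neighbour cutoff for three-body terms (Angstrom).
#' @aliases RepresentationConfig-class
#' @exportClass RepresentationConfig
setClass("RepresentationConfig",
  representation(rMin = "numeric", rMax = "numeric", dr = "numeric",
                 sigmaR = "numeric", thetaBins = "integer",
                 sigmaTheta = "numeric", rCut = "numeric"))

setValidity("RepresentationConfig", function(object) {
  msg <- character()
  if (object@rMin >= object@rMax) msg <- c(msg, "rMin must be < rMax")
  if (object@dr <= 0) msg <- c(msg, "dr must be > 0")
  if (object@sigmaR <= 0 || object@sigmaTheta <= 0)
    msg <- c(msg, "Gaussian widths must be > 0")
  if (object@thetaBins < 2) msg <- c(msg, "thetaBins must be >= 2")
  if (object@rCut <= 0) msg <- c(msg, "rCut must be > 0")
  if (length(msg)) msg else TRUE
})

#' KernelModel: a trained Laplacian-kernel ridge regressor
#'
#' Stores everything needed for prediction: the training representations,
#' the regression coefficients alpha solving (K + lambda I) alpha = y, the
#' kernel width sigma and the regularisation lambda, plus a free-text label
#' naming property and level of theory.
#'
#' @slot Xtrain numeric matrix, one training representation per row.
#' @slot alpha regression coefficients, one per training molecule.
#' @slot sigma kernel width (units of the L1 distance).
#' @slot lam ridge regularisation, >= 0.
#' @slot label property/level tag, e.g. "gap@target".
#' @aliases KernelModel-class
#' @exportClass KernelModel
setClass("KernelModel",
  representation(Xtrain = "matrix", alpha = "numeric", sigma = "numeric",
                 lam = "numeric", label = "character"))

setValidity("KernelModel", function(object) {
  msg <- character()
  if (length(object@alpha) != nrow(object@Xtrain))
    msg <- c(msg, "one alpha coefficient per training row required")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@lam < 0) msg <- c(msg, "lam must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SplitSpec: sizes, repetitions and seed of a learning-curve experiment
#'
#' @slot trainSizes strictly increasing training-set sizes.
#' @slot testSizePerClass held-out molecules per class.
#' @slot repetitions number of independent draws averaged over (default 10).
#' @slot seed base seed; repetition r uses seed + r.
#' @aliases SplitSpec-class
#' @exportClass SplitSpec
setClass("SplitSpec",
  representation(trainSizes = "integer", testSizePerClass = "integer",
                 repetitions = "integer", seed = "integer"))

setValidity("SplitSpec", function(object) {
  msg <- character()
  if (length(object@trainSizes) < 1 ||
      is.unsorted(object@trainSizes, strictly = TRUE))
    msg <- c(msg, "trainSizes must be non-empty and strictly increasing")
  if (object@repetitions < 1) msg <- c(msg, "repetitions must be >= 1")
  if (object@testSizePerClass < 1) msg <- c(msg, "testSizePerClass must be >= 1")
  if (length(msg)) msg else TRUE
})

#' LearningCurve: MAE versus training-set size
#'
#' Mean and standard deviation of the test MAE over repetitions, per
#' training-set size, for one property and one selection mode ("generic" =
#' training molecules drawn from the whole pool, "selected" = drawn within
#' the evaluated class).
#'
#' @slot sizes training-set sizes.
#' @slot maeMean,maeSd mean / sd of MAE (eV) over repetitions, per size.
#' @slot maeReps repetitions x sizes matrix of raw MAEs.
#' @slot label property/level tag.
#' @slot selection "generic" or "selected".
#' @slot classId class evaluated ("all" for a pooled test set).
#' @aliases LearningCurve-class
#' @exportClass LearningCurve
setClass("LearningCurve",
  representation(sizes = "integer", maeMean = "numeric", maeSd = "numeric",
                 maeReps = "matrix", label = "character",
                 selection = "character", classId = "character"))

setValidity("LearningCurve", function(object) {
  msg <- character()
  if (length(object@maeMean) != length(object@sizes) ||
      length(object@maeSd) != length(object@sizes))
    msg <- c(msg, "maeMean/maeSd must match sizes in length")
  if (any(object@maeMean < 0)) msg <- c(msg, "MAE must be >= 0")
  if (!object@selection %in% c("generic", "selected"))
    msg <- c(msg, "selection must be 'generic' or 'selected'")
  if (length(msg)) msg else TRUE
})

#' GeneratorParams: study conditions of the synthetic fixture
#'
#' Parameters of the synthetic molecule/label generator. Class gap means are
#' strictly decreasing from class I (saturated, highest gap) to class III
#' (aromatic/carbonyl, lowest gap), mirroring the empirical ordering of the
#' gap sub-distributions.
#'
#' @slot nPerClass molecule counts for classes I/II/III.
#' @slot classGapMeans gap means (eV), strictly decreasing.
#' @slot classGapSds gap spreads (eV), all > 0.
#' @slot smoothWeight fraction of the within-class spread tied to the
#'   representation through a smooth map (learnable signal).
#' @slot noiseSd residual label noise (eV).
#' @slot baselineOffset,baselineSlope,baselineNoiseSd parameters of the
#'   correlated second level of theory: baseline = slope * target + offset
#'   + N(0, noise).
#' @slot seed integer seed; the generator is bit-reproducible given it.
#' @aliases GeneratorParams-class
#' @exportClass GeneratorParams
setClass("GeneratorParams",
  representation(nPerClass = "integer", classGapMeans = "numeric",
                 classGapSds = "numeric", smoothWeight = "numeric",
                 noiseSd = "numeric", baselineOffset = "numeric",
                 baselineSlope = "numeric", baselineNoiseSd = "numeric",
                 seed = "integer"))

setValidity("GeneratorParams", function(object) {
  msg <- character()
  if (length(object@nPerClass) != 3 || any(object@nPerClass < 1))
    msg <- c(msg, "nPerClass must be three counts >= 1")
  if (length(object@classGapMeans) != 3 ||
      is.unsorted(rev(object@classGapMeans), strictly = TRUE))
    msg <- c(msg, "classGapMeans must be strictly decreasing from class I to III")
  if (length(object@classGapSds) != 3 || any(object@classGapSds <= 0))
    msg <- c(msg, "classGapSds must be three positive values")
  if (object@noiseSd < 0 || object@baselineNoiseSd < 0)
    msg <- c(msg, "noise standard deviations must be >= 0")
  if (length(msg)) msg else TRUE
})
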