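#' Construct a SplitSpec
#'
#' @param trainSizes strictly increasing training-set sizes (e.g. powers of
#'   two).
#' @param testSizePerClass held-out molecules per class (default 200, a
#'   QM7b-scale choice).
#' @param repetitions independent draws averaged over (default 10).
#' @param seed base seed; repetition r derives its stream from seed + r.
#' @return a [SplitSpec-class].
#' @export
splitSpec <- function(trainSizes, testSizePerClass = 200L,
                      repetitions = 10L, seed = 1L) {
  new("SplitSpec", trainSizes = as.integer(trainSizes),
      testSizePerClass = as.integer(testSizePerClass),
      repetitions = as.integer(repetitions), seed = as.integer(seed))
}

#' @export
setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec: sizes %s, %d test/class, %d repetitions, seed %d\n",
              paste(object@trainSizes, collapse = "/"),
              object@testSizePerClass, object@repetitions, object@seed))
})

# bounded derived seed for a (repetition, size, machine) cell
.cellSeed <- function(base, rep, size = 0L, machine = 0L)
  as.integer((as.numeric(base) + 7907 * rep + 131 * size + 17 * machine) %%
             2147483647)

#' Draw train/test splits for the paired SML protocol
#'
#' Per repetition: one fixed test set per class, disjoint from every
#' training draw of that repetition; a generic training draw sampled
#' uniformly from the whole remaining pool (all classes, all test molecules
#' excluded); and a selected training draw per class sampled uniformly from
#' that class's remainder. Draws are nested by size - the training set of a
#' smaller size is a prefix of the larger one - so learning-curve points of
#' one repetition are comparable.
#'
#' @param ids molecule ids of the pool.
#' @param spec a [SplitSpec-class].
#' @param classMap factor/character of class labels named by (or aligned
#'   with) `ids`.
#' @return list with elements `classes` and `reps`; each repetition holds
#'   `test` (named list class -> ids), `generic` (nested training draw, use
#'   the first n) and `selected` (named list class -> nested draw).
#' @export
makeSplits <- function(ids, spec, classMap) {
  if (is.null(names(classMap))) names(classMap) <- ids
  classMap <- classMap[ids]
  cls <- if (is.factor(classMap)) levels(droplevels(classMap))
         else sort(unique(as.character(classMap)))
  maxTr <- max(spec@trainSizes)
  ts <- spec@testSizePerClass
  for (cc in cls) {
    ncc <- sum(classMap == cc)
    if (ncc < maxTr + ts)
      stop(sprintf(
        "capacity error: class %s has %d molecules but %d (train) + %d (test) requested",
        cc, ncc, maxTr, ts))
  }
  if (length(ids) - length(cls) * ts < maxTr)
    stop("capacity error: pool too small for the generic training draw")
  reps <- lapply(seq_len(spec@repetitions), function(r) {
    .withSeed(.cellSeed(spec@seed, r), {
      test <- lapply(cls, function(cc) sample(ids[classMap == cc], ts))
      names(test) <- cls
      excluded <- unlist(test, use.names = FALSE)
      pool <- setdiff(ids, excluded)
      generic <- sample(pool)[seq_len(maxTr)]
      selected <- lapply(cls, function(cc)
        sample(setdiff(ids[classMap == cc], test[[cc]]))[seq_len(maxTr)])
      names(selected) <- cls
      list(test = test, generic = generic, selected = selected)
    })
  })
  list(classes = cls, spec = spec, reps = reps)
}

# shared engine: MAE per (repetition, size) for given train/test id draws.
# D is the full symmetric L1 distance matrix with id dimnames; y is named.
.curveEngine <- function(D, y, spec, trainDraw, testIds, sigmas, lam, folds,
                         machine) {
  ns <- length(spec@trainSizes)
  maes <- matrix(NA_real_, spec@repetitions, ns)
  sigsel <- matrix(NA_real_, spec@repetitions, ns)
  for (r in seq_len(spec@repetitions)) {
    tr_all <- trainDraw(r)
    te <- testIds(r)
    for (si in seq_len(ns)) {
      tr <- tr_all[seq_len(spec@trainSizes[si])]
      sg <- .selectSigmaFromD(D[tr, tr, drop = FALSE], y[tr], sigmas, folds,
                              .cellSeed(spec@seed, r, si, machine), lam)
      a <- .solveKrr(exp(-D[tr, tr, drop = FALSE] / sg), y[tr], lam)
      pred <- drop(exp(-D[te, tr, drop = FALSE] / sg) %*% a)
      maes[r, si] <- mae(pred, y[te])
      sigsel[r, si] <- sg
    }
  }
  list(maes = maes, sigmas = sigsel)
}

.asCurve <- function(maes, spec, label, selection, classId) {
  new("LearningCurve", sizes = spec@trainSizes,
      maeMean = colMeans(maes),
      maeSd = apply(maes, 2, stats::sd),
      maeReps = maes, label = label, selection = selection,
      classId = classId)
}

#' Run one learning curve
#'
#' For each training size and repetition: select sigma by cross validation
#' inside the training set, train, predict on the held-out test set, record
#' the MAE; then average over repetitions.
#'
#' @param reps representation matrix with molecule ids as rownames.
#' @param labels named numeric property vector (eV).
#' @param splits output of [makeSplits()].
#' @param selection `"generic"` (training molecules drawn from the whole
#'   pool) or `"selected"` (drawn within `classId`).
#' @param classId class whose test set is evaluated, or `"all"` for the
#'   union of all class test sets (generic selection only).
#' @param sigmas,folds,lam hyperparameter search settings.
#' @param label free-text property tag.
#' @return a [LearningCurve-class].
#' @export
runLearningCurve <- function(reps, labels, splits,
                             selection = c("generic", "selected"),
                             classId = "all", sigmas = defaultSigmaGrid(),
                             folds = 5L, lam = 1e-12, label = "gap") {
  selection <- match.arg(selection)
  spec <- splits$spec
  if (selection == "selected" && classId == "all")
    stop("selected training requires a specific classId")
  if (classId != "all" && !classId %in% splits$classes)
    stop("unknown classId: ", classId)
  ids <- rownames(reps)
  y <- labels[ids]
  if (anyNA(y)) stop("labels missing for some molecules")
  D <- cpp_l1_cross(reps, reps)
  dimnames(D) <- list(ids, ids)
  trainDraw <- if (selection == "generic")
    function(r) splits$reps[[r]]$generic
  else function(r) splits$reps[[r]]$selected[[classId]]
  testIds <- if (classId == "all")
    function(r) unlist(splits$reps[[r]]$test, use.names = FALSE)
  else function(r) splits$reps[[r]]$test[[classId]]
  machine <- if (selection == "generic") 0L else match(classId, splits$classes)
  eng <- .curveEngine(D, y, spec, trainDraw, testIds, sigmas, lam, folds,
                      machine)
  .asCurve(eng$maes, spec, label, selection, classId)
}

#' Paired comparison of generic and selected training
#'
#' The core experiment: per repetition, one generic machine (trained on
#' molecules drawn from the whole pool) and one selected machine per class
#' (trained within the class) are evaluated on the same fixed class test
#' sets, so the two predictions for a class are computed on identical
#' molecules and differ only in training selection.
#'
#' @param reps representation matrix with molecule ids as rownames.
#' @param labels named numeric property vector (eV).
#' @param classMap factor of class labels named by molecule id.
#' @param spec a [SplitSpec-class].
#' @param sigmas,folds,lam hyperparameter search settings.
#' @param label free-text property tag.
#' @param collectScatter also return a per-molecule prediction table at the
#'   largest training size of the first repetition, with outliers flagged
#'   at |error| > 3 x class MAE.
#' @return list with `curves` (per class: list(generic, selected), each a
#'   [LearningCurve-class]), `splits`, `selectedSigmas`, and optionally
#'   `scatter`.
#' @export
runSmlComparison <- function(reps, labels, classMap, spec,
                             sigmas = defaultSigmaGrid(), folds = 5L,
                             lam = 1e-12, label = "gap",
                             collectScatter = FALSE) {
  ids <- rownames(reps)
  y <- labels[ids]
  if (anyNA(y)) stop("labels missing for some molecules")
  splits <- makeSplits(ids, spec, classMap)
  cls <- splits$classes
  D <- cpp_l1_cross(reps, reps)
  dimnames(D) <- list(ids, ids)
  ns <- length(spec@trainSizes)
  gen <- lapply(cls, function(cc) matrix(NA_real_, spec@repetitions, ns))
  sel <- lapply(cls, function(cc) matrix(NA_real_, spec@repetitions, ns))
  names(gen) <- names(sel) <- cls
  sigLog <- list()
  scatter <- NULL
  for (r in seq_len(spec@repetitions)) {
    rp <- splits$reps[[r]]
    for (si in seq_len(ns)) {
      n <- spec@trainSizes[si]
      # one generic machine per (repetition, size), evaluated on every class
      tr <- rp$generic[seq_len(n)]
      sg <- .selectSigmaFromD(D[tr, tr, drop = FALSE], y[tr], sigmas, folds,
                              .cellSeed(spec@seed, r, si, 0L), lam)
      ag <- .solveKrr(exp(-D[tr, tr, drop = FALSE] / sg), y[tr], lam)
      sigLog[[length(sigLog) + 1L]] <-
        data.frame(repetition = r, size = n, machine = "generic",
                   class = "all", sigma = sg)
      for (ci in seq_along(cls)) {
        cc <- cls[ci]
        te <- rp$test[[cc]]
        predG <- drop(exp(-D[te, tr, drop = FALSE] / sg) %*% ag)
        gen[[cc]][r, si] <- mae(predG, y[te])
        trS <- rp$selected[[cc]][seq_len(n)]
        sgS <- .selectSigmaFromD(D[trS, trS, drop = FALSE], y[trS], sigmas,
                                 folds, .cellSeed(spec@seed, r, si, ci), lam)
        aS <- .solveKrr(exp(-D[trS, trS, drop = FALSE] / sgS), y[trS], lam)
        predS <- drop(exp(-D[te, trS, drop = FALSE] / sgS) %*% aS)
        sel[[cc]][r, si] <- mae(predS, y[te])
        sigLog[[length(sigLog) + 1L]] <-
          data.frame(repetition = r, size = n, machine = "selected",
                     class = cc, sigma = sgS)
        if (collectScatter && r == 1L && si == ns) {
          sc <- rbind(
            data.frame(id = te, y_ref = unname(y[te]), y_pred = predG,
                       class = cc, selection = "generic"),
            data.frame(id = te, y_ref = unname(y[te]), y_pred = predS,
                       class = cc, selection = "selected"))
          scatter <- rbind(scatter, sc)
        }
      }
    }
  }
  if (!is.null(scatter)) {
    err <- abs(scatter$y_pred - scatter$y_ref)
    thr <- stats::ave(err, paste(scatter$class, scatter$selection),
                      FUN = function(e) 3 * mean(e))
    scatter$outlier <- err > thr
  }
  curves <- lapply(cls, function(cc) list(
    generic = .asCurve(gen[[cc]], spec, label, "generic", cc),
    selected = .asCurve(sel[[cc]], spec, label, "selected", cc)))
  names(curves) <- cls
  out <- list(curves = curves, splits = splits,
              selectedSigmas = do.call(rbind, sigLog))
  if (collectScatter) out$scatter <- scatter
  out
}

#' @export
setMethod("show", "LearningCurve", function(object) {
  cat(sprintf("LearningCurve '%s' (%s, class %s):\n", object@label,
              object@selection, object@classId))
  print(data.frame(size = object@sizes, maeMean = object@maeMean,
                   maeSd = object@maeSd))
})

#' Flatten learning curves to a table
#'
#' @param curves a [LearningCurve-class] or list of them (possibly nested).
#' @return data.frame with columns size, mae_mean, mae_sd, label,
#'   selection, class.
#' @export
learningCurveTable <- function(curves) {
  if (is(curves, "LearningCurve")) curves <- list(curves)
  flat <- list()
  rec <- function(x) {
    if (is(x, "LearningCurve")) flat[[length(flat) + 1L]] <<- x
    else lapply(x, rec)
  }
  rec(curves)
  do.call(rbind, lapply(flat, function(cv)
    data.frame(size = cv@sizes, mae_mean = cv@maeMean, mae_sd = cv@maeSd,
               label = cv@label, selection = cv@selection,
               class = cv@classId)))
}

#' Train a delta-learning correction model
#'
#' Learns the difference between two levels of theory: the model is trained
#' on y_target - y_baseline, so that adding its predicted correction to a
#' cheap baseline estimates the expensive target level. The better the two
#' levels correlate, the smaller and smoother the learned difference.
#'
#' @param X training representation matrix.
#' @param yBaseline,yTarget baseline- and target-level labels (eV), no
#'   missing values.
#' @param sigma fixed kernel width, or `NULL` to select by cross validation
#'   on the differences.
#' @param sigmas,folds,seed CV settings used when `sigma` is `NULL`.
#' @param lam ridge regularisation.
#' @param label free-text tag.
#' @return a [KernelModel-class] trained on the level differences.
#' @export
deltaTrain <- function(X, yBaseline, yTarget, sigma = NULL,
                       sigmas = defaultSigmaGrid(), folds = 5L, seed = 1L,
                       lam = 1e-12, label = "delta") {
  if (anyNA(yBaseline) || anyNA(yTarget))
    stop("data error: baseline or target level missing for a training molecule")
  d <- yTarget - yBaseline
  if (is.null(sigma))
    sigma <- selectSigma(X, d, sigmas = sigmas, folds = folds, seed = seed,
                         lam = lam)
  krrTrain(X, d, sigma = sigma, lam = lam, label = label)
}

#' Predict target-level values from baseline plus learned correction
#'
#' @param model a correction model from [deltaTrain()].
#' @param Xtest test representation matrix.
#' @param baseline baseline-level values for the test molecules (eV), no
#'   missing values.
#' @return estimated target-level values: baseline + predicted correction.
#' @export
deltaPredict <- function(model, Xtest, baseline) {
  if (anyNA(baseline)) stop("data error: missing baseline value")
  if (length(baseline) != nrow(as.matrix(Xtest)))
    stop("one baseline value per test molecule required")
  baseline + krrPredict(model, Xtest)
}

#' Fit a learning curve on log-log axes
#'
#' Least-squares line log10(MAE) = offset + slope * log10(N_train). Parallel
#' curves with different offsets - the signature of selection improving the
#' prefactor but not the exponent - show up as equal slopes and an offset
#' drop.
#'
#' @param x a [LearningCurve-class], or a numeric vector of training sizes.
#' @param maeValues MAE per size (required when `x` is numeric), all > 0.
#' @return named numeric `c(offset, slope)` with the residual sum of
#'   squares in `attr(, "rss")`.
#' @examples
#' fitLogLog(c(10, 100, 1000), 2 * c(10, 100, 1000)^-0.3)
#' @export
fitLogLog <- function(x, maeValues = NULL) {
  if (is(x, "LearningCurve")) {
    sizes <- x@sizes; m <- x@maeMean
  } else {
    sizes <- x; m <- maeValues
  }
  if (length(sizes) < 2) stop("need at least two sizes")
  if (any(m <= 0)) stop("domain error: nonpositive MAE")
  fit <- stats::lm(log10(m) ~ log10(sizes))
  out <- c(offset = unname(stats::coef(fit)[1]),
           slope = unname(stats::coef(fit)[2]))
  attr(out, "rss") <- sum(stats::residuals(fit)^2)
  out
}
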