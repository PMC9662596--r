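smallSplitSetup <- function() {
  syn <- synthFixture("small")
  list(syn = syn,
       spec = splitSpec(c(8L, 16L), testSizePerClass = 20L,
                        repetitions = 3L, seed = 42L),
       splits = makeSplits(rownames(syn$reps),
                           splitSpec(c(8L, 16L), testSizePerClass = 20L,
                                     repetitions = 3L, seed = 42L),
                           syn$classes))
}

test_that("splits keep training and test sets disjoint in every cell", {
  st <- smallSplitSetup()
  for (rp in st$splits$reps) {
    testAll <- unlist(rp$test, use.names = FALSE)
    expect_false(anyDuplicated(testAll) > 0)
    expect_length(intersect(rp$generic, testAll), 0)
    for (cc in st$splits$classes) {
      expect_length(intersect(rp$selected[[cc]], testAll), 0)
      # selected draws stay inside their class
      expect_true(all(st$syn$classes[rp$selected[[cc]]] == cc))
      expect_true(all(st$syn$classes[rp$test[[cc]]] == cc))
    }
  }
})

test_that("splits are seeded-deterministic and nested by size", {
  st <- smallSplitSetup()
  again <- makeSplits(rownames(st$syn$reps), st$spec, st$syn$classes)
  expect_identical(st$splits, again)
  rp <- st$splits$reps[[1]]
  expect_identical(rp$generic[1:8], rp$generic[seq_len(8)])
  expect_false(anyDuplicated(rp$generic) > 0)
})

test_that("capacity shortfalls name the offending class", {
  syn <- synthFixture("small")
  expect_error(
    makeSplits(rownames(syn$reps),
               splitSpec(c(1000L), testSizePerClass = 20L,
                         repetitions = 2L, seed = 1L), syn$classes),
    "capacity error: class I_saturated")
})

test_that("learning curves are deterministic and shrink with training size", {
  syn <- synthFixture("small")
  spec <- splitSpec(c(16L, 64L), testSizePerClass = 15L, repetitions = 3L,
                    seed = 42L)
  splits <- makeSplits(rownames(syn$reps), spec, syn$classes)
  y <- gaps(syn$molecules, "target")
  cv1 <- runLearningCurve(syn$reps, y, splits, selection = "generic",
                          classId = "all")
  cv2 <- runLearningCurve(syn$reps, y, splits, selection = "generic",
                          classId = "all")
  expect_equal(cv1@maeMean, cv2@maeMean, tolerance = 1e-10)
  # consistency on smooth synthetic labels: within one sd
  expect_lte(cv1@maeMean[2], cv1@maeMean[1] + cv1@maeSd[1])

  one <- runLearningCurve(syn$reps, y,
                          makeSplits(rownames(syn$reps),
                                     splitSpec(16L, testSizePerClass = 15L,
                                               repetitions = 2L, seed = 1L),
                                     syn$classes),
                          selection = "generic", classId = "all")
  expect_length(one@maeMean, 1L)
})

test_that("selected training within one class beats generic on its test set", {
  syn <- synthFixture("small")
  spec <- splitSpec(c(16L, 32L), testSizePerClass = 15L, repetitions = 4L,
                    seed = 42L)
  cmp <- runSmlComparison(syn$reps, gaps(syn$molecules, "target"),
                          syn$classes, spec)
  for (cc in names(cmp$curves)) {
    expect_identical(cmp$curves[[cc]]$generic@sizes,
                     cmp$curves[[cc]]$selected@sizes)
    expect_true(all(cmp$curves[[cc]]$selected@maeMean <
                    cmp$curves[[cc]]$generic@maeMean))
  }
  # sigma log covers every (repetition, size, machine) cell
  expect_equal(nrow(cmp$selectedSigmas), 4 * 2 * (1 + 3))
})

test_that("scatter export pairs both machines on identical molecules", {
  syn <- synthFixture("small")
  spec <- splitSpec(16L, testSizePerClass = 10L, repetitions = 2L, seed = 5L)
  cmp <- runSmlComparison(syn$reps, gaps(syn$molecules, "target"),
                          syn$classes, spec, collectScatter = TRUE)
  sc <- cmp$scatter
  expect_true(!is.null(sc))
  for (cc in unique(sc$class)) {
    g <- sc$id[sc$class == cc & sc$selection == "generic"]
    s <- sc$id[sc$class == cc & sc$selection == "selected"]
    expect_identical(g, s)
  }
  expect_true(is.logical(sc$outlier))
})

test_that("a single-class pool makes generic and selected indistinguishable", {
  syn <- synthFixture("small")
  ids <- names(syn$classes)[syn$classes == "I_saturated"]
  oneClass <- factor(rep("I_saturated", length(ids)),
                     levels = levels(syn$classes))
  names(oneClass) <- ids
  spec <- splitSpec(c(16L, 32L), testSizePerClass = 15L, repetitions = 6L,
                    seed = 42L)
  cmp <- runSmlComparison(syn$reps[ids, ], gaps(syn$molecules, "target")[ids],
                          droplevels(oneClass), spec)
  cv <- cmp$curves[[1]]
  d <- cv$generic@maeReps - cv$selected@maeReps
  expect_lt(abs(mean(d)), 2 * stats::sd(d))
})

test_that("delta learning reproduces shifts and beats direct learning", {
  syn <- synthFixture("small")
  reps <- syn$reps
  yt <- gaps(syn$molecules, "target")
  ids <- selml:::.withSeed(13L, sample(rownames(reps)))
  tr <- ids[1:32]; te <- ids[33:132]

  # identical levels: zero correction, predictions equal baseline exactly
  m0 <- deltaTrain(reps[tr, ], yt[tr], yt[tr], sigma = 64)
  expect_equal(m0@alpha, rep(0, 32))
  expect_equal(deltaPredict(m0, reps[te, ], yt[te]), yt[te])

  # constant shift: correction learned to high accuracy
  yb <- yt + 0.5
  mC <- suppressWarnings(deltaTrain(reps[tr, ], yb[tr], yt[tr], seed = 13L))
  expect_lt(mae(deltaPredict(mC, reps[te, ], yb[te]), yt[te]), 1e-4)

  # correlated noisy baseline: delta beats direct at matched sizes
  yb2 <- gaps(syn$molecules, "baseline")
  expect_gt(stats::cor(yb2, yt), 0.99)
  for (n in c(16L, 64L)) {
    trn <- ids[seq_len(n)]
    md <- suppressWarnings(deltaTrain(reps[trn, ], yb2[trn], yt[trn],
                                      seed = 13L))
    deltaMae <- mae(deltaPredict(md, reps[te, ], yb2[te]), yt[te])
    sg <- selectSigma(reps[trn, ], yt[trn], seed = 13L)
    directMae <- mae(krrPredict(krrTrain(reps[trn, ], yt[trn], sg),
                                reps[te, ]), yt[te])
    expect_lt(deltaMae, directMae)
  }
})

test_that("delta predictions equal baseline plus the kernel-sum correction", {
  set.seed(3)
  Xtr <- matrix(runif(9), 3, 3)
  yb <- c(1, 2, 3); yt <- c(1.5, 2.2, 3.9)
  m <- deltaTrain(Xtr, yb, yt, sigma = 2, lam = 1e-12)
  Xte <- matrix(runif(9), 3, 3)
  base <- c(0.5, 1.5, 2.5)
  # hand-summed kernel prediction
  byHand <- vapply(1:3, function(i)
    base[i] + sum(exp(-colSums(abs(t(Xtr) - Xte[i, ])) / 2) * m@alpha),
    numeric(1))
  expect_equal(deltaPredict(m, Xte, base), byHand, tolerance = 1e-10)
  expect_error(deltaTrain(Xtr, c(1, NA, 3), yt), "data error")
  expect_error(deltaPredict(m, Xte, c(1, NA, 2)), "missing baseline")
})

test_that("log-log fits recover exact and noisy power laws", {
  N <- c(10, 100, 1000)
  fit <- fitLogLog(N, 2 * N^-0.3)
  expect_equal(unname(fit["slope"]), -0.3, tolerance = 1e-12)
  expect_equal(unname(fit["offset"]), log10(2), tolerance = 1e-12)
  expect_lt(attr(fit, "rss"), 1e-12)

  two <- fitLogLog(c(16, 256), c(1.0, 0.25))
  expect_equal(unname(two["slope"]), log10(0.25) / log10(16), tolerance = 1e-12)

  set.seed(20)
  slopes <- replicate(20, {
    m <- 1.5 * N^-0.4 * 10^rnorm(3, 0, 0.01)
    unname(fitLogLog(N, m)["slope"])
  })
  expect_lt(max(abs(slopes + 0.4)), 0.05)

  expect_error(fitLogLog(c(10, 100), c(0.5, 0)), "nonpositive MAE")
  expect_error(fitLogLog(10, 0.5), "at least two sizes")
})
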