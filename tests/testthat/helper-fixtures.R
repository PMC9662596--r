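# Shared fixtures, generated once per test run and cached in-session.
# All fixture seeds are fixed here and nowhere else.

.fixtureEnv <- new.env(parent = emptyenv())

synthFixture <- function(key = c("small", "large")) {
  key <- match.arg(key)
  if (!is.null(.fixtureEnv[[key]])) return(.fixtureEnv[[key]])
  val <- switch(key,
    small = syntheticDataset(generatorParams(nPerClass = c(80L, 80L, 80L),
                                             seed = 42L)),
    large = syntheticDataset(generatorParams(seed = 42L)))
  .fixtureEnv[[key]] <- val
  val
}

classifierFixture <- function() {
  utils::read.csv(system.file("extdata", "classifier_fixture.csv",
                              package = "selml"),
                  stringsAsFactors = FALSE)
}

# random rigid transform: rotation from QR of a Gaussian matrix + translation
randomRigid <- function(coords) {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qrd)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords %*% R, 2, stats::rnorm(3, sd = 5), `+`)
}
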