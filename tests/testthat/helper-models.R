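# Shared heavy fixtures: the benchmark pair and the trained toy classifiers
# are built once per test run and cached, since several test files probe the
# same study conditions (300 training scenes, 50 held-out scenes, toy pair
# trained on the regular views plus triple-weighted focus views).

.fixtureCache <- new.env(parent = emptyenv())

trainBenchmark <- function() {
  if (is.null(.fixtureCache$bench))
    .fixtureCache$bench <- makeFixtureBenchmark(300, seed = 11)
  .fixtureCache$bench
}

heldOutBenchmark <- function() {
  if (is.null(.fixtureCache$test))
    .fixtureCache$test <- makeFixtureBenchmark(50, seed = 321)
  .fixtureCache$test
}

# the toy training recipe used throughout: regular views once, focus views
# three times (the localization study leans on object-centered training, as
# does fine-tuning on bounding-box crops), plus the background class
toyPair <- function(seed) {
  key <- paste0("pair", seed)
  if (is.null(.fixtureCache[[key]])) {
    bench <- trainBenchmark()
    dat <- list(bench$regular, bench$focus, bench$focus, bench$focus)
    .fixtureCache[[key]] <- list(
      cartesian = trainToyClassifier(dat, "cartesian", seed = seed),
      retinotopic = trainToyClassifier(dat, "retinotopic", seed = seed))
  }
  .fixtureCache[[key]]
}

# an untrained (random-weight) toy classifier, cheap to build
untrainedToy <- function(mode, seed = 1, nScenes = 8) {
  small <- makeFixtureBenchmark(nScenes, seed = 5)$regular
  trainToyClassifier(small, mode, epochs = 1, lr = 0, seed = seed,
                     restarts = 0, restartThreshold = 0,
                     backgroundClass = FALSE)
}

# grid-cell (Chebyshev) distance between a map's peak fixation and a point
peakCellDistance <- function(map, point) {
  pk <- FoveatedVision:::.peakCell(mapValues(map))
  fix <- map@fixations[pk[1], pk[2], ]
  G <- nrow(mapValues(map))
  max(abs(fix - point)) / (2 / (G - 1))
}
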