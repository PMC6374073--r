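# Shared fixtures, built once per test run. The "small" session uses one
# stimulus and one blank trial to keep unit tests fast; acceptance tests
# build full default sessions themselves.

.fixtures <- new.env(parent = emptyenv())

smallConfig <- function() generatorConfig(seed = 101L, nTrials = 1L,
                                          nBlankTrials = 1L)

smallProtocol <- function() {
  if (is.null(.fixtures$protocol))
    .fixtures$protocol <- makeProtocol(smallConfig())
  .fixtures$protocol
}

smallBehavior <- function() {
  if (is.null(.fixtures$behavior))
    .fixtures$behavior <- simulateBehavior(smallProtocol(), smallConfig())
  .fixtures$behavior
}

# homogeneous Poisson spike train helper (for constructed statistics)
poissonTrain <- function(rate, duration, seed = 1,
                         label = "simple") {
  set.seed(seed)
  t <- cumsum(stats::rexp(ceiling(rate * duration * 1.5 + 20), rate))
  SpikeTrain(t[t < duration], label, duration = duration)
}
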