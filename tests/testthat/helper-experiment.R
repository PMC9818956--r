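# The synthetic two-stage study is expensive (several minutes of CPU
# training), so it runs once per test session and is shared by the
# acceptance blocks that assert on different aspects of it.
experimentCache <- new.env(parent = emptyenv())

getRecoveryExperiment <- function() {
  if (is.null(experimentCache$result))
    experimentCache$result <- runRecoveryExperiment(seed = 1L)
  experimentCache$result
}
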