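# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture_pair <- function(size = 64L) {
  key <- paste0("pair", size)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_phantom_pair(
      phantom_spec(size = c(size, size), seed = 7L))
  }
  .fixture_env[[key]]
}

fixture_pair_default <- function() {
  if (is.null(.fixture_env$pair_default)) {
    .fixture_env$pair_default <- generate_phantom_pair(phantom_spec())
  }
  .fixture_env$pair_default
}
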