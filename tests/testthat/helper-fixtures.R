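# Shared fixtures and small assertion helpers.

reg <- default_registry()
kc <- phys_constants()

expect_within <- function(object, expected, band) {
  expect_lt(abs(object - expected), band)
}

expect_rel <- function(object, expected, rel) {
  expect_lt(abs(object / expected - 1), rel)
}
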