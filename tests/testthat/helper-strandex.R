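# Draw a random positive rate set inside the default fitting box,
# log-uniformly, reproducible from `seed`.
random_rates <- function(seed, scheme = "three_step") {
  sc <- reaction_scheme(scheme)
  lo <- ifelse(sc$bimolecular, 1e-6, 1e-5)
  hi <- ifelse(sc$bimolecular, 1e-3, 1e-1)
  set.seed(seed)
  k <- 10^runif(length(lo), log10(lo), log10(hi))
  do.call(rate_constants, c(as.list(k), list(scheme = scheme)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) / abs(expected)), tol))
}
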