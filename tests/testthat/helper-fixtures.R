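# Deterministic battery of random rating matrices shared between the tests
# and the frozen reference-implementation fixture
# (fixtures/icc_reference_oracle.csv, computed once with the established
# Python reliability implementation of ICC(A,1) and its exact F interval).
gen_icc_matrices <- function(n_mats = 100L, seed = 20260910L) {
  set.seed(seed)
  lapply(seq_len(n_mats), function(i) {
    n <- sample(5:30, 1)
    mu <- runif(1, 0, 10)
    sigma_b <- runif(1, 0.1, 3)     # between-subject spread
    sigma_e <- runif(1, 0.05, 2)    # within-subject noise
    bias <- rnorm(1, 0, 0.3)        # systematic test/retest shift
    b <- rnorm(n, mu, sigma_b)
    cbind(b + rnorm(n, 0, sigma_e), b + bias + rnorm(n, 0, sigma_e))
  })
}

# Small test-retest phantom pair shared across tests (64^3 grid, ~2 s).
make_test_pair <- function(seed = 101L, shape = c(64, 64, 64),
                           tumor_radius = 15, texture_amplitude = 0.25,
                           exposure = 400) {
  ps <- phantom_spec(shape = shape, tumor_radius = tumor_radius,
                     texture_amplitude = texture_amplitude,
                     exposure = exposure)
  ph <- make_phantom(ps, seed = seed)
  cnt <- simulate_counts(ph, exposure = exposure, seed = seed + 1L)
  h <- split_events(cnt, seed = seed + 2L)
  pair <- trt_pair(reconstruct_image(h$a), reconstruct_image(h$b), "T001")
  list(pair = pair, spec = ps, phantom = ph)
}
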