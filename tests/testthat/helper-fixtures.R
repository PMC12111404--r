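# Fixtures are built in code; nothing is read from disk except the
# packaged amino-acid CSVs.

default_noiseless_table <- function(seed = 7, n = 33) {
  spec <- make_default_spec(noise_sd = 0)
  design <- generate_design(process_bounds(), n = n, seed = seed)
  simulate_experiments(spec, design, seed = seed)
}

default_noisy_table <- function(seed = 7, n = 33) {
  spec <- make_default_spec()
  design <- generate_design(process_bounds(), n = n, seed = seed)
  simulate_experiments(spec, design, seed = seed)
}

# small random network with reproducible weights
random_mlp <- function(n_hidden, n_in = 3, seed = 1, scale = 1) {
  set.seed(seed)
  mlp_params(
    w_ih = matrix(runif(n_hidden * n_in, -scale, scale), n_hidden, n_in),
    b_h = runif(n_hidden, -scale, scale),
    w_ho = runif(n_hidden, -scale, scale),
    b_o = runif(1, -scale, scale)
  )
}

# Brute-force double-loop evaluation of the connection-weight importance,
# independent of the vectorized implementation.
yoon_bruteforce <- function(params) {
  m <- params$n_in
  num <- numeric(m)
  for (i in seq_len(m)) {
    s <- 0
    for (k in seq_len(params$n_hidden)) {
      s <- s + params$w_ih[k, i] * params$w_ho[k]
    }
    num[i] <- s
  }
  den <- sum(abs(num))
  100 * num / den
}

aa_fixture_path <- function() {
  system.file("extdata", "rapeseed_isolate_amino_acids.csv",
              package = "dephenolize")
}

aa_printed_path <- function() {
  system.file("extdata", "rapeseed_isolate_aa_printed_summaries.csv",
              package = "dephenolize")
}
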