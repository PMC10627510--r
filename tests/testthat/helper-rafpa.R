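# Shared fixtures: the representative parameter set used for descriptive
# plots (K_A = 10, K_d = K_dim = 0.1 uM, [RAF] = 0.04 uM), and a log-uniform
# sampler over the fitting bounds for property-style tests.

default_ca_params <- function() {
  model_params(K_A = 10, K_dim = 0.1, K_d = 0.1, raf_total = 0.04,
               variant = "CA")
}

default_unified_params <- function(f = 1, g = 1) {
  model_params(K_A = 10, K_dim = 0.1, K_d = 0.1, f = f, g = g,
               raf_total = 0.04, variant = "unified")
}

# n random parameter sets for a variant, drawn log-uniformly within the
# fitting bounds; returns a list of raf_params
sample_params <- function(n, variant = "unified", seed = 1) {
  b <- default_bounds()
  lu <- function(rg, n) 10^stats::runif(n, log10(rg[1]), log10(rg[2]))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  KA <- lu(b$K_A, n); Kdim <- lu(b$K_dim, n); Kd <- lu(b$K_d, n)
  raf <- lu(b$raf_total, n); f <- lu(b$f, n); g <- lu(b$g, n)
  lapply(seq_len(n), function(i)
    model_params(
      K_A = if (variant %in% c("CA", "unified")) KA[i] else 0,
      K_dim = Kdim[i], K_d = Kd[i],
      f = if (variant %in% c("DP", "unified")) f[i] else 1,
      g = if (variant %in% c("NC", "unified")) g[i] else 1,
      raf_total = raf[i], variant = variant))
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-300)
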