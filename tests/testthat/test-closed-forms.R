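test_that("dimensionless groups reduce correctly at zero drug", {
  p <- default_ca_params()
  E <- dimensionless_groups(p, 0)
  expect_identical(E$d_rel, 0)
  expect_equal(E$RAF_rel, 0.4)
  expect_equal(E$E1, 1 + 10)
  expect_equal(E$E1n, 1)
  expect_equal(E$E2c, 8 * 0.4)
  expect_equal(E$E3, 3.2 / 121)   # 8 * 0.4 / (1 + 10)^2, forced arithmetic
})

test_that("E3 coincides with the K_A-free baseline argument when K_A = 0", {
  p <- model_params(K_A = 0, K_dim = 0.1, K_d = 0.1, raf_total = 0.04,
                    variant = "CA")
  E <- dimensionless_groups(p, 0)
  expect_equal(E$E3, 8 * E$RAF_rel)
})

test_that("negative dose and degenerate constants are rejected", {
  p <- default_ca_params()
  expect_error(dimensionless_groups(p, -1), "drug_free")
  expect_error(model_params(K_dim = 0), "> 0")
  expect_error(model_params(K_d = -1), "> 0")
  expect_error(model_params(K_A = -0.1), "K_A")
  expect_error(model_params(f = 2, variant = "CA"), "CA")
  expect_error(model_params(K_A = 5, variant = "DP"), "DP")
  expect_error(model_params(f = 2, variant = "NC"), "NC")
})

test_that("active fraction at zero drug equals the baseline for all variants", {
  for (v in c("CA", "DP", "NC", "unified")) {
    for (p in sample_params(25, v, seed = 7)) {
      expect_equal(active_raf_fraction(p, 0), baseline_active_fraction(p),
                   tolerance = 1e-10)
    }
  }
})

test_that("strong autoinhibition abolishes active RAF", {
  p <- model_params(K_A = 1e9, K_dim = 0.1, K_d = 0.1, raf_total = 0.04,
                    variant = "CA")
  expect_lt(baseline_active_fraction(p), 1e-8)
  expect_lt(active_raf_fraction(p, 1), 2e-4)
})

test_that("baseline saturates with abundance and vanishes in dilution", {
  # DP baseline -> 1 as RAF_rel -> Inf and -> 0 as RAF_rel -> 0
  hi <- model_params(K_dim = 1e-4, raf_total = 1e3, variant = "DP")
  lo <- model_params(K_dim = 1e4, raf_total = 1e-4, variant = "DP")
  expect_gt(baseline_active_fraction(hi), 0.999)
  expect_lt(baseline_active_fraction(lo), 1e-6)
})

test_that("baseline is increasing in RAF_rel and decreasing in K_A", {
  rafs <- 10^seq(-3, 2, length.out = 30)
  b <- vapply(rafs, function(r)
    baseline_active_fraction(model_params(K_A = 10, K_dim = 0.1,
                                          raf_total = r, variant = "CA")),
    numeric(1))
  expect_true(all(diff(b) > 0))
  kas <- 10^seq(-2, 2, length.out = 30)
  b2 <- vapply(kas, function(k)
    baseline_active_fraction(model_params(K_A = k, K_dim = 0.1,
                                          raf_total = 0.04,
                                          variant = "CA")),
    numeric(1))
  expect_true(all(diff(b2) < 0))
})

test_that("CA with K_A = 0 coincides with DP with f = 1 at all doses", {
  doses <- c(0, 10^seq(-3, 2, length.out = 20))
  ca <- model_params(K_A = 0, K_dim = 0.2, K_d = 0.05, raf_total = 0.1,
                     variant = "CA")
  dp <- model_params(K_dim = 0.2, K_d = 0.05, f = 1, raf_total = 0.1,
                     variant = "DP")
  expect_equal(active_raf_fraction(ca, doses),
               active_raf_fraction(dp, doses), tolerance = 1e-12)
})

test_that("the unified model collapses exactly onto CA, DP and NC", {
  doses <- c(0, 10^seq(-4, 3, length.out = 30))
  for (p in sample_params(40, "unified", seed = 3)) {
    cases <- list(
      CA = list(model_params(K_A = p$K_A, K_dim = p$K_dim, K_d = p$K_d,
                             raf_total = p$raf_total, variant = "CA"),
                model_params(K_A = p$K_A, K_dim = p$K_dim, K_d = p$K_d,
                             f = 1, g = 1, raf_total = p$raf_total,
                             variant = "unified")),
      DP = list(model_params(K_dim = p$K_dim, K_d = p$K_d, f = p$f,
                             raf_total = p$raf_total, variant = "DP"),
                model_params(K_A = 0, K_dim = p$K_dim, K_d = p$K_d,
                             f = p$f, g = 1, raf_total = p$raf_total,
                             variant = "unified")),
      NC = list(model_params(K_dim = p$K_dim, K_d = p$K_d, g = p$g,
                             raf_total = p$raf_total, variant = "NC"),
                model_params(K_A = 0, K_dim = p$K_dim, K_d = p$K_d, f = 1,
                             g = p$g, raf_total = p$raf_total,
                             variant = "unified")))
    for (nm in names(cases)) {
      restricted <- cases[[nm]][[1]]; unified <- cases[[nm]][[2]]
      expect_equal(active_raf_fraction(unified, doses),
                   active_raf_fraction(restricted, doses),
                   tolerance = 1e-12, label = paste("active", nm))
      expect_equal(baseline_active_fraction(unified),
                   baseline_active_fraction(restricted),
                   tolerance = 1e-12, label = paste("baseline", nm))
      expect_equal(total_dimer_ratio(unified, doses),
                   total_dimer_ratio(restricted, doses),
                   tolerance = 1e-12, label = paste("dimer ratio", nm))
    }
  }
})

test_that("fractions stay in [0, 1] and vanish at saturating drug", {
  for (v in c("CA", "DP", "NC", "unified")) {
    for (p in sample_params(30, v, seed = 11)) {
      a <- active_raf_fraction(p, c(0, 10^seq(-4, 2, length.out = 15)))
      expect_true(all(a >= 0 & a <= 1))
      # fully drugged dimers carry no active protomer
      expect_lt(active_raf_fraction(p, 1e9 * p$K_d * max(1, p$f, p$g)),
                1e-4)
    }
  }
})

test_that("dimer/active ratio is 1/2 at zero drug for every variant", {
  for (v in c("CA", "DP", "NC", "unified")) {
    for (p in sample_params(20, v, seed = 5)) {
      expect_equal(total_dimer_ratio(p, 0), 0.5, tolerance = 1e-12)
    }
  }
})

test_that("dimer/active ratio grows without bound at saturating drug", {
  # dimers persist in the doubly drugged inactive form, so the ratio of
  # total dimers to active protomers diverges rather than decaying
  p <- default_ca_params()
  d <- c(1, 10, 100)
  r <- total_dimer_ratio(p, d)
  expect_equal(r, (1 + d / p$K_d) / 2, tolerance = 1e-12)
  expect_true(all(diff(r) > 0))
})

test_that("species distribution has no drug-bound species at zero dose", {
  for (v in c("CA", "unified")) {
    p <- if (v == "CA") default_ca_params() else
      default_unified_params(f = 0.1, g = 10)
    sp <- species_distribution(p, 0)
    expect_identical(sp$RD, 0)
    expect_identical(sp$R2D, 0)
    expect_identical(sp$R2D2, 0)
  }
})

test_that("autoinhibited pool dominates at large K_A and zero dose", {
  p <- model_params(K_A = 1e6, K_dim = 0.1, K_d = 0.1, raf_total = 0.04,
                    variant = "CA")
  sp <- species_distribution(p, 0)
  expect_gt(sp$A / p$raf_total, 0.999)
})

test_that("species satisfy protomer conservation and match active fraction", {
  doses <- c(0, 10^seq(-3, 2, length.out = 12))
  for (p in sample_params(40, "unified", seed = 13)) {
    sp <- species_distribution(p, doses)
    total <- sp$A + sp$R + sp$RD + 2 * (sp$R2 + sp$R2D + sp$R2D2)
    expect_equal(total, rep(p$raf_total, length(doses)),
                 tolerance = 1e-10)
    expect_true(all(sp[, c("A", "R", "RD", "R2", "R2D", "R2D2")] >= 0))
    expect_equal((2 * sp$R2 + sp$R2D) / p$raf_total,
                 active_raf_fraction(p, doses), tolerance = 1e-12)
  }
})

test_that("species progression along a dose sweep shows the PA anatomy", {
  # autoinhibited pool declines monotonically; singly bound dimers rise then
  # fall; doubly bound dimers saturate
  p <- default_unified_params()
  doses <- dose_grid(1e-4, 1e2, points_per_decade = 10)
  sp <- species_distribution(p, doses)
  expect_true(all(diff(sp$A) <= 1e-15))
  i_pk <- which.max(sp$R2D)
  expect_gt(i_pk, 1)
  expect_lt(i_pk, nrow(sp))
  expect_true(all(diff(sp$R2D[1:i_pk]) >= 0))
  expect_true(all(diff(sp$R2D[i_pk:nrow(sp)]) <= 0))
  expect_true(all(diff(sp$R2D2) >= 0))
})

test_that("parameter serialization round-trips and rejects unknown keys", {
  p <- default_unified_params(f = 0.3, g = 50)
  q <- params_from_list(params_to_list(p))
  expect_equal(q, p)
  expect_error(params_from_list(list(K_A = 1, bogus = 2)), "unknown")
})
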