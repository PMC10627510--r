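test_that("NC dose-response is monotone non-increasing (no PA possible)", {
  for (p in sample_params(25, "NC", seed = 31)) {
    dr <- dose_response(p, dose_grid(1e-4, 1e2, points_per_decade = 8))
    expect_true(all(diff(dr$active_fraction) <= 1e-15))
    m <- pa_metrics(dr)
    expect_false(m$has_pa)
    expect_equal(m$pa_fold_change, 1, tolerance = 1e-9)
  }
})

test_that("a single-point grid normalizes to one", {
  p <- default_ca_params()
  dr <- dose_response(p, 0)
  expect_equal(nrow(dr), 1L)
  expect_equal(dr$active_normalized, 1)
})

test_that("the representative CA curve is non-monotone with finite PA range", {
  # K_A = 10, K_d = K_dim = 0.1 uM, [RAF] = 0.04 uM
  p <- default_ca_params()
  dr <- dose_response(p, dose_grid())
  m <- pa_metrics(dr)
  expect_true(m$has_pa)
  expect_gt(m$pa_fold_change, 1)
  d <- diff(dr$active_fraction)
  expect_true(any(d > 0) && any(d < 0))       # rises then falls
  # the upper range endpoint is a genuine baseline re-crossing
  expect_true(is.finite(m$pa_range_hi_uM))
  expect_lt(m$pa_range_hi_uM, max(dr$dose_uM))
  expect_equal(active_raf_fraction(p, m$pa_range_hi_uM), m$baseline,
               tolerance = 1e-3)
  # beyond the range the curve sits below baseline
  expect_lt(active_raf_fraction(p, 10 * m$pa_range_hi_uM), m$baseline)
})

test_that("an effectively flat curve yields fold change 1 and empty range", {
  # doses orders of magnitude below K_d leave the system unperturbed
  p <- model_params(K_A = 10, K_dim = 0.1, K_d = 1e10, raf_total = 0.04,
                    variant = "CA")
  dr <- dose_response(p, dose_grid(1e-4, 1e2, points_per_decade = 5))
  m <- pa_metrics(dr)
  expect_false(m$has_pa)
  expect_equal(m$pa_fold_change, 1, tolerance = 1e-7)
  expect_equal(m$pa_range_width_uM, 0)
})

test_that("pa_metrics demands a baseline dose", {
  p <- default_ca_params()
  dr <- dose_response(p, dose_grid(include_zero = FALSE))
  expect_error(pa_metrics(dr), "dose 0")
})

test_that("PA condition predicates carry the right epistemic strength", {
  nc <- pa_condition(model_params(g = 50, variant = "NC"))
  expect_false(nc$pa_predicted)
  expect_identical(nc$condition_kind, "impossible")

  # the CA threshold vanishes at K_A = 1: autoinhibition must be favored
  ca1 <- pa_condition(model_params(K_A = 1, K_dim = 0.1, raf_total = 1e-3,
                                   variant = "CA"))
  expect_false(ca1$pa_predicted)
  expect_identical(ca1$condition_kind, "necessary_and_sufficient")

  ca <- pa_condition(default_ca_params())   # RAF_rel 0.4 < 31*9/8
  expect_true(ca$pa_predicted)

  dp <- pa_condition(model_params(K_dim = 0.1, K_d = 0.1, f = 0.1,
                                  raf_total = 0.001, variant = "DP"))
  expect_true(dp$pa_predicted)
  expect_identical(dp$condition_kind, "sufficient")
  dp2 <- pa_condition(model_params(K_dim = 0.1, K_d = 0.1, f = 0.9,
                                   raf_total = 0.001, variant = "DP"))
  expect_true(is.na(dp2$pa_predicted))      # sufficient-only: indeterminate

  un <- pa_condition(default_unified_params())
  expect_true(un$pa_predicted)
})

test_that("no PA is ever detected for CA with K_A <= 1", {
  for (KA in c(0, 0.3, 0.7, 1)) {
    for (rr in 10^seq(-3, 3, length.out = 7)) {
      p <- model_params(K_A = KA, K_dim = 0.1, raf_total = 0.1 * rr,
                        variant = "CA")
      dr <- dose_response(p, dose_grid(1e-4, 1e2, points_per_decade = 8))
      expect_false(pa_metrics(dr)$has_pa)
    }
  }
})

test_that("CA predicate agrees with numerical detection off the boundary", {
  # coarse version of the full phase-grid check in the acceptance suite
  KAs <- 10^seq(-1, 2, length.out = 12)
  rrs <- 10^seq(-3, 3, length.out = 12)
  doses <- dose_grid(1e-4, 1e2, points_per_decade = 10)
  for (KA in KAs) for (rr in rrs) {
    thr <- (1 + 3 * KA) * (KA - 1) / 8
    if (thr > 0 && abs(rr - thr) <= 0.02 * thr) next  # boundary band
    p <- model_params(K_A = KA, K_dim = 0.1, raf_total = 0.1 * rr,
                      variant = "CA")
    m <- pa_metrics(dose_response(p, doses))
    expect_identical(m$has_pa, rr < thr,
                     label = sprintf("K_A=%.3g RAF_rel=%.3g", KA, rr))
  }
})

test_that("phase scan shows no PA without autoinhibition and decaying fold", {
  sc <- phase_scan(K_A_grid = c(0, 10),
                   raf_total_grid = 10^seq(-3, 0.5, length.out = 8),
                   doses = dose_grid(1e-4, 1e2, points_per_decade = 8))
  row0 <- sc[sc$K_A == 0, ]
  expect_true(all(abs(row0$fold_change - 1) < 1e-9))
  expect_true(all(!row0$has_pa))
  # at K_A = 10, fold change decays as abundance approaches the threshold
  row10 <- sc[sc$K_A == 10, ]
  expect_true(all(diff(row10$fold_change) < 0))
  thr_raf <- (1 + 30) * 9 / 8 * 0.1           # RAF_rel threshold * K_dim
  expect_true(all(row10$has_pa == (row10$raf_total_uM < thr_raf)))
})

test_that("PA range endpoints are invariant under monotone readout maps", {
  p <- default_ca_params()
  doses <- dose_grid()
  act <- active_raf_fraction(p, doses)
  fun <- function(d) active_raf_fraction(p, d)
  m0 <- rafpa:::.pa_metrics_core(doses, act, fun)
  for (tr in list(function(x) x^0.7, function(x) log1p(50 * x),
                  function(x) 2 * x / (1 + x))) {
    mt <- rafpa:::.pa_metrics_core(doses, tr(act), function(d) tr(fun(d)))
    expect_equal(mt$pa_range_lo_uM, m0$pa_range_lo_uM, tolerance = 1e-3)
    expect_equal(mt$pa_range_hi_uM, m0$pa_range_hi_uM, tolerance = 1e-3)
  }
})

test_that("dose-response CSV export keeps the normalized curve", {
  p <- default_ca_params()
  dr <- dose_response(p, dose_grid(1e-3, 10, points_per_decade = 3))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_dose_response(dr, tf)
  back <- utils::read.csv(tf)
  expect_equal(back$active_normalized, dr$active_normalized,
               tolerance = 1e-12)
})
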