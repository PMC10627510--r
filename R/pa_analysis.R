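#' Simulate a dose-response curve
#'
#' Evaluates the closed-form active-RAF fraction of a model over a dose grid
#' and returns the curve in absolute and max-normalized form, together with
#' total dimer concentrations.
#'
#' @param params a [model_params()] object.
#' @param doses dose grid, uM (see [dose_grid()]); must be strictly
#'   increasing and nonnegative.
#' @return An object of class `raf_dose_response`: a data frame with columns
#'   `dose_uM`, `active_fraction`, `active_normalized` (divided by the curve
#'   maximum) and `total_dimers_uM`, carrying `params` as an attribute.
#' @export
dose_response <- function(params, doses = dose_grid()) {
  assert_doses(doses)
  act <- active_raf_fraction(params, doses)
  sp <- species_distribution(params, doses)
  out <- data.frame(
    dose_uM = doses,
    active_fraction = act,
    active_normalized = act / max(act),
    total_dimers_uM = sp$R2 + sp$R2D + sp$R2D2)
  attr(out, "params") <- params
  class(out) <- c("raf_dose_response", "data.frame")
  out
}

# Golden-section maximization of fun on [lo, hi] (dose axis, searched in log
# space when lo > 0), to relative tolerance rtol on the argument.
.golden_max <- function(fun, lo, hi, rtol = 1e-4) {
  phi <- (sqrt(5) - 1) / 2
  logspace <- lo > 0
  tf <- if (logspace) log else identity
  itf <- if (logspace) exp else identity
  a <- tf(lo); b <- tf(hi)
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- fun(itf(x1)); f2 <- fun(itf(x2))
  while ((b - a) > rtol * max(abs(b), 1e-12)) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- fun(itf(x2))
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- fun(itf(x1))
    }
  }
  x <- (a + b) / 2
  list(dose = itf(x), value = fun(itf(x)))
}

# Shared engine behind pa_metrics() and phase_scan(): works on a raw
# activity vector plus an evaluator for refinement.
.pa_metrics_core <- function(doses, activity, fun, refine = TRUE,
                             dose_rtol = 1e-4, activity_tol = 1e-9) {
  baseline <- activity[1]
  i_max <- which.max(activity)
  peak <- activity[i_max]
  peak_dose <- doses[i_max]
  if (refine && i_max > 1 && i_max < length(doses)) {
    gm <- .golden_max(fun, doses[i_max - 1], doses[i_max + 1],
                      rtol = dose_rtol)
    if (gm$value > peak) { peak <- gm$value; peak_dose <- gm$dose }
  }
  has_pa <- peak > baseline + activity_tol
  range_lo <- NA_real_; range_hi <- NA_real_
  if (has_pa) {
    above <- activity > baseline + activity_tol
    # contiguous super-baseline region containing the grid peak
    lo_i <- i_max; while (lo_i > 1 && above[lo_i - 1]) lo_i <- lo_i - 1
    hi_i <- i_max; while (hi_i < length(doses) && above[hi_i + 1])
      hi_i <- hi_i + 1
    excess <- function(d) fun(d) - baseline
    # bisect for the baseline crossing between a super- and sub-baseline
    # grid point; if the outer point is within tolerance of the baseline
    # the crossing is below resolution and the grid point itself is used
    cross <- function(inner, outer) {
      if (excess(outer) >= 0) return(outer)
      stats::uniroot(excess, sort(c(inner, outer)),
                     tol = dose_rtol * max(inner, outer))$root
    }
    range_lo <- if (lo_i == 1 || (lo_i == 2 && doses[1] == 0)) {
      # activity exceeds baseline from the smallest positive dose on
      doses[1]
    } else cross(doses[lo_i], doses[lo_i - 1])
    range_hi <- if (hi_i == length(doses)) doses[hi_i] else
      cross(doses[hi_i], doses[hi_i + 1])
  }
  list(baseline = baseline, peak = peak, peak_dose_uM = peak_dose,
       pa_fold_change = peak / baseline, has_pa = has_pa,
       pa_range_lo_uM = range_lo, pa_range_hi_uM = range_hi,
       pa_range_width_uM = if (has_pa) range_hi - range_lo else 0)
}

#' Paradoxical-activation metrics of a dose-response curve
#'
#' Computes the drug-free baseline, the peak activity (grid maximum refined
#' by golden-section search between the bracketing grid points), the PA fold
#' change (peak/baseline), and the PA range: the dose interval over which
#' activity exceeds the baseline, with endpoints located by bisection on the
#' activity-minus-baseline excess. Because the range endpoints are defined by
#' baseline crossings, they are invariant under any monotone increasing
#' transformation of the activity readout.
#'
#' @param dr a [dose_response()] object whose grid contains dose 0.
#' @param activity_tol absolute activity tolerance used to call a curve
#'   point "above baseline" (default 1e-9, far below biological scales and
#'   far above solver noise).
#' @param dose_rtol relative tolerance on refined dose locations
#'   (default 1e-4).
#' @return An object of class `raf_pa_metrics`: list with `baseline`, `peak`,
#'   `peak_dose_uM`, `pa_fold_change`, `has_pa`, `pa_range_lo_uM`,
#'   `pa_range_hi_uM`, `pa_range_width_uM`.
#' @export
pa_metrics <- function(dr, activity_tol = 1e-9, dose_rtol = 1e-4) {
  stopifnot(inherits(dr, "raf_dose_response"))
  if (dr$dose_uM[1] != 0)
    stop("dose grid must contain dose 0 (baseline)", call. = FALSE)
  params <- attr(dr, "params")
  fun <- function(d) active_raf_fraction(params, d)
  out <- .pa_metrics_core(dr$dose_uM, dr$active_fraction, fun,
                          dose_rtol = dose_rtol,
                          activity_tol = activity_tol)
  class(out) <- "raf_pa_metrics"
  out
}

#' @export
print.raf_pa_metrics <- function(x, ...) {
  cat(sprintf("PA metrics: baseline %.4g, peak %.4g (at %.4g uM)\n",
              x$baseline, x$peak, x$peak_dose_uM))
  cat(sprintf("  fold change %.4g; PA %s", x$pa_fold_change,
              if (x$has_pa) "detected" else "absent"))
  if (x$has_pa)
    cat(sprintf("; range [%.4g, %.4g] uM", x$pa_range_lo_uM,
                x$pa_range_hi_uM))
  cat("\n")
  invisible(x)
}

#' Algebraic paradoxical-activation conditions
#'
#' Evaluates the closed-form PA conditions of the analytic solution table.
#' The strength of the statement differs by variant and is part of the
#' return value:
#' \describe{
#'   \item{CA}{`RAF_rel < (1 + 3 K_A)(K_A - 1) / 8` is *necessary and
#'     sufficient*; in particular autoinhibition must be favored at
#'     equilibrium (`K_A > 1`) for any PA.}
#'   \item{DP}{`f < 1/2` together with `8 RAF_rel < 3 - 8 f + 4 f^2` is
#'     *sufficient only*; when it fails, PA is `NA` (indeterminate) rather
#'     than excluded.}
#'   \item{NC}{PA is impossible: always `FALSE`.}
#'   \item{unified}{`g >= 1`, `2 f < 1 + K_A` and
#'     `8 RAF_rel < 4 f^2 - 8 f (1 + K_A) + 3 (1 + K_A)^2` is *sufficient
#'     only*. This inequality collapses exactly to the CA condition at
#'     `f = g = 1` and to the DP condition at `K_A = 0`.}
#' }
#'
#' @param params a [model_params()] object.
#' @return List with `pa_predicted` (`TRUE`, `FALSE`, or `NA` for
#'   indeterminate) and `condition_kind` (one of
#'   `"necessary_and_sufficient"`, `"sufficient"`, `"impossible"`).
#' @export
pa_condition <- function(params) {
  stopifnot(inherits(params, "raf_params"))
  rr <- params$raf_total / params$K_dim
  KA <- params$K_A; f <- params$f; g <- params$g
  switch(params$variant,
    CA = list(
      pa_predicted = rr < (1 + 3 * KA) * (KA - 1) / 8,
      condition_kind = "necessary_and_sufficient"),
    NC = list(pa_predicted = FALSE, condition_kind = "impossible"),
    DP = list(
      pa_predicted = if (f < 0.5 && 8 * rr < 3 - 8 * f + 4 * f^2) TRUE
                     else NA,
      condition_kind = "sufficient"),
    unified = list(
      pa_predicted = if (g >= 1 && 2 * f < 1 + KA &&
                         8 * rr < 4 * f^2 - 8 * f * (1 + KA) +
                           3 * (1 + KA)^2) TRUE else NA,
      condition_kind = "sufficient"))
}

#' Phase map of PA over autoinhibition strength and RAF abundance
#'
#' Scans PA fold change and PA range width over a grid of `K_A` and total
#' RAF values, holding the remaining parameters fixed — the two key control
#' parameters of the autoinhibition mechanism. The activity over the dose
#' axis is evaluated fully vectorized over the whole (cell, dose) product
#' grid, then each cell's metrics are refined as in [pa_metrics()].
#'
#' @param variant model variant for the scan (default `"CA"`).
#' @param K_A_grid,raf_total_grid numeric vectors of grid values
#'   (dimensionless; uM).
#' @param fixed named list of the fixed parameters `K_dim`, `K_d`, `f`, `g`.
#' @param doses dose axis, uM, containing 0.
#' @param refine refine peaks/range endpoints per cell (default `TRUE`;
#'   disable for very large scans where grid resolution suffices).
#' @return Long-format data frame: `K_A`, `raf_total_uM`, `baseline`,
#'   `fold_change`, `has_pa`, `range_lo_uM`, `range_hi_uM`, `range_width_uM`.
#' @export
phase_scan <- function(variant = "CA", K_A_grid, raf_total_grid,
                       fixed = list(K_dim = 0.1, K_d = 0.1, f = 1, g = 1),
                       doses = dose_grid(), refine = TRUE) {
  assert_doses(doses, require_zero = TRUE)
  stopifnot(all(K_A_grid >= 0), all(raf_total_grid > 0))
  cells <- expand.grid(K_A = K_A_grid, raf_total = raf_total_grid,
                       KEEP.OUT.ATTRS = FALSE)
  n <- nrow(cells); nd <- length(doses)
  # vectorized activity over the full product grid
  dvec <- rep(doses, times = n) / fixed$K_d
  KAv <- rep(cells$K_A, each = nd)
  rrv <- rep(cells$raf_total, each = nd) / fixed$K_dim
  f <- fixed$f; g <- fixed$g
  W <- 1 + 2 * dvec / f + dvec^2 / (f * g)
  E1 <- 1 + KAv + dvec
  E2 <- 8 * rrv * W
  S <- .safe_root_gap(E1, E2)
  act <- matrix(S^2 * (1 + dvec / f) / (E2 * W), nrow = nd)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    p <- model_params(K_A = cells$K_A[i], K_dim = fixed$K_dim,
                      K_d = fixed$K_d, f = f, g = g,
                      raf_total = cells$raf_total[i], variant = variant)
    fun <- function(d) active_raf_fraction(p, d)
    m <- .pa_metrics_core(doses, act[, i], fun, refine = refine)
    res[[i]] <- c(m$baseline, m$pa_fold_change, m$has_pa,
                  if (m$has_pa) m$pa_range_lo_uM else NA_real_,
                  if (m$has_pa) m$pa_range_hi_uM else NA_real_,
                  m$pa_range_width_uM)
  }
  res <- do.call(rbind, res)
  data.frame(K_A = cells$K_A, raf_total_uM = cells$raf_total,
             baseline = res[, 1], fold_change = res[, 2],
             has_pa = as.logical(res[, 3]), range_lo_uM = res[, 4],
             range_hi_uM = res[, 5], range_width_uM = res[, 6])
}

#' Write a dose-response curve as CSV
#'
#' @param dr a [dose_response()] object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_dose_response <- function(dr, file) {
  stopifnot(inherits(dr, "raf_dose_response"))
  utils::write.csv(
    dr[, c("dose_uM", "active_fraction", "active_normalized")],
    file, row.names = FALSE)
  invisible(file)
}
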