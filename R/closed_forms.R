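#' Dimensionless groups of the equilibrium solutions
#'
#' Computes the reduced variables and abbreviated expressions in which the
#' closed-form steady-state solutions are written: the relative dose
#' `d_rel = drug_free / K_d`, the relative RAF abundance
#' `RAF_rel = raf_total / K_dim`, and the E-symbols
#'
#' \preformatted{
#'   E1  = 1 + K_A + d_rel                      E1d = (1 + d_rel) f
#'   E1n = 1 + d_rel                            E3  = 8 RAF_rel / (1 + K_A)^2
#'   E2c = 8 RAF_rel (1 + 2 d_rel + d_rel^2)
#'   E2d = 8 f RAF_rel (f + 2 d_rel + d_rel^2)
#'   E2n = 8 RAF_rel (g + 2 g d_rel + d_rel^2)
#'   E2u = 8 RAF_rel (f g + 2 g d_rel + d_rel^2) / (f g)
#' }
#'
#' All are nonnegative for admissible parameters and nonnegative dose.
#'
#' @param params a [model_params()] object.
#' @param drug_free free drug concentration(s), uM (vectorized, `>= 0`).
#' @return A list of numeric vectors: `d_rel`, `RAF_rel`, `E1`, `E1d`, `E1n`,
#'   `E2c`, `E2d`, `E2n`, `E2u`, `E3`.
#' @export
dimensionless_groups <- function(params, drug_free) {
  stopifnot(inherits(params, "raf_params"))
  if (any(!is.finite(drug_free)) || any(drug_free < 0))
    stop("drug_free must be finite and >= 0", call. = FALSE)
  if (params$K_d <= 0 || params$K_dim <= 0)
    stop("K_d and K_dim must be positive", call. = FALSE)
  d <- drug_free / params$K_d
  rr <- params$raf_total / params$K_dim
  f <- params$f; g <- params$g; KA <- params$K_A
  list(
    d_rel = d, RAF_rel = rr,
    E1  = 1 + KA + d,
    E1d = (1 + d) * f,
    E1n = 1 + d,
    E2c = 8 * rr * (1 + 2 * d + d^2),
    E2d = 8 * f * rr * (f + 2 * d + d^2),
    E2n = 8 * rr * (g + 2 * g * d + d^2),
    E2u = 8 * rr * (f * g + 2 * g * d + d^2) / (f * g),
    E3  = 8 * rr / (1 + KA)^2)
}

# sqrt(E1^2 + E2) - E1 without catastrophic cancellation; E2 >= 0 is the
# discriminant condition -- a negative value signals a transcription bug and
# must raise, never be clamped.
.safe_root_gap <- function(E1, E2) {
  disc <- E1^2 + E2
  if (any(disc < -1e-12 * pmax(E1^2, 1)))
    stop("negative discriminant in closed-form solution; ",
         "invalid parameterization or transcription error", call. = FALSE)
  E2 / (sqrt(pmax(disc, 0)) + E1)
}

#' Drug-free baseline active-RAF fraction
#'
#' Fraction of RAF protomers that are active (in a dimer, not drug-bound) in
#' the absence of drug. For the autoinhibition-containing variants (CA and
#' unified) this is
#' \deqn{(-1 + \sqrt{1 + E3})^2 / E3,\quad E3 = 8\,RAF_{rel}/(1+K_A)^2,}
#' and for DP/NC the same expression with \eqn{K_A = 0}. It increases
#' monotonically with `RAF_rel` (more dimers at higher abundance) and
#' decreases with `K_A` (more protein locked in the autoinhibited state).
#'
#' @inheritParams dimensionless_groups
#' @return Baseline active fraction in `[0, 1]`.
#' @export
baseline_active_fraction <- function(params) {
  stopifnot(inherits(params, "raf_params"))
  rr <- params$raf_total / params$K_dim
  KA <- if (params$variant %in% c("CA", "unified")) params$K_A else 0
  E3 <- 8 * rr / (1 + KA)^2
  S <- .safe_root_gap(1, E3)       # sqrt(1 + E3) - 1
  S^2 / E3
}

#' Active-RAF fraction at a given free-drug concentration
#'
#' Evaluates the variant-specific closed-form steady-state solution for the
#' fraction of RAF protomers that are active, i.e. part of a dimer and not
#' bound to drug. Each variant is coded in the abbreviated symbols of its own
#' column of the analytic solution table, so the reduction identities between
#' variants are nontrivial checks of the transcriptions:
#'
#' * CA: \eqn{(E1 - \sqrt{E1^2 + E2c})^2 / (E2c (1 + d_{rel}))}
#' * DP: \eqn{(E1d - \sqrt{E1d^2 + E2d})^2 \, f\,(E1d + (f-1)f) /
#'        (E2d\,(E1d^2 + (f-1)f^2))}
#' * NC: \eqn{(E1n - \sqrt{E1n^2 + E2n/g})^2 \, g^2 (1 + d_{rel}) /
#'        (E2n\,(g + 2 g d_{rel} + d_{rel}^2))}.
#'   (In the NC column the radical takes `E2n/g`, the occupancy polynomial
#'   divided by its leading coefficient; writing the radical with a bare
#'   `E2n` is inconsistent with detailed balance and fails the equilibrium
#'   oracle.)
#' * unified: \eqn{(E1 - \sqrt{E1^2 + E2u})^2 \, g (f + d_{rel}) /
#'        (E2u\,(f g + 2 g d_{rel} + d_{rel}^2))}.
#'   The grouping is resolved so that `E2u` (which already carries the
#'   `1/(fg)` factor) appears once under the radical and once linearly in the
#'   denominator, with the bare occupancy polynomial
#'   `fg + 2g d_rel + d_rel^2` alongside; this is the unique grouping that
#'   agrees with the detailed-balance oracle.
#'
#' @inheritParams dimensionless_groups
#' @return Active fraction(s) in `[0, 1]`, same length as `drug_free`.
#' @seealso [baseline_active_fraction()], [species_distribution()],
#'   [solve_equilibrium()] for the independent numerical ground truth.
#' @export
active_raf_fraction <- function(params, drug_free) {
  E <- dimensionless_groups(params, drug_free)
  d <- E$d_rel; f <- params$f; g <- params$g
  switch(params$variant,
    CA = {
      S <- .safe_root_gap(E$E1, E$E2c)
      S^2 / (E$E2c * (1 + d))
    },
    DP = {
      S <- .safe_root_gap(E$E1d, E$E2d)
      # printed factors evaluated in factored form: E1d + (f-1)f = f(d+f)
      # and E1d^2 + (f-1)f^2 = f^2(f + 2d + d^2), avoiding the cancellation
      # the literal grouping incurs at small d and f
      S^2 * f * (f * (d + f)) / (E$E2d * (f^2 * (f + 2 * d + d^2)))
    },
    NC = {
      S <- .safe_root_gap(E$E1n, E$E2n / g)
      S^2 * g^2 * (1 + d) / (E$E2n * (g + 2 * g * d + d^2))
    },
    unified = {
      S <- .safe_root_gap(E$E1, E$E2u)
      S^2 * g * (f + d) / (E$E2u * (f * g + 2 * g * d + d^2))
    })
}

#' Total RAF dimers relative to active RAF
#'
#' Ratio of total dimer concentration (drug-free, singly and doubly bound) to
#' active-RAF protomer concentration. At zero drug every dimer carries two
#' active protomers, so the ratio is exactly 1/2 for all variants; at high
#' dose dimers persist in the doubly drugged, inactive form and the ratio
#' grows without bound. The closed forms per variant:
#'
#' * CA: \eqn{(1 + d_{rel})/2}
#' * DP: \eqn{(f + d_{rel}(2 + d_{rel})) / (2 (f + d_{rel}))}
#' * NC: \eqn{(g + d_{rel}(2g + d_{rel})) / (2 g (1 + d_{rel}))}
#' * unified: \eqn{(fg + d_{rel}(2g + d_{rel})) / (2 g (f + d_{rel}))}
#'
#' @inheritParams dimensionless_groups
#' @return Dimensionless ratio(s), `>= 1/2`.
#' @export
total_dimer_ratio <- function(params, drug_free) {
  E <- dimensionless_groups(params, drug_free)
  d <- E$d_rel; f <- params$f; g <- params$g
  act <- active_raf_fraction(params, drug_free)
  if (any(act <= 0))
    stop("active RAF is zero; dimer/active ratio undefined", call. = FALSE)
  switch(params$variant,
    CA      = (1 + d) / 2,
    DP      = (f + d * (2 + d)) / (2 * (f + d)),
    NC      = (g + d * (2 * g + d)) / (2 * g * (1 + d)),
    unified = (f * g + d * (2 * g + d)) / (2 * g * (f + d)))
}

#' Equilibrium concentrations of the six RAF species
#'
#' Decomposes total RAF into the six states of the model at the given free
#' drug concentration: autoinhibited monomer `A`, non-autoinhibited drug-free
#' monomer `R`, drug-bound monomer `RD`, and dimers with zero (`R2`), one
#' (`R2D`) or two (`R2D2`) drugs bound. Computed from the closed-form free
#' monomer concentration; consistent with [active_raf_fraction()] through
#' `2 R2 + R2D = active fraction x raf_total` and with protomer conservation
#' `A + R + RD + 2 (R2 + R2D + R2D2) = raf_total`.
#'
#' @inheritParams dimensionless_groups
#' @return A data frame with one row per dose and columns `dose_uM`, `A`,
#'   `R`, `RD`, `R2`, `R2D`, `R2D2`, `D_free` (all uM) and `active_fraction`.
#' @export
species_distribution <- function(params, drug_free) {
  E <- dimensionless_groups(params, drug_free)
  d <- E$d_rel; f <- params$f; g <- params$g
  KA <- params$K_A; Kdim <- params$K_dim
  # occupancy polynomial of a dimer over its drug states, relative to R2
  W <- 1 + 2 * d / f + d^2 / (f * g)
  E2 <- 8 * E$RAF_rel * W
  S <- .safe_root_gap(E$E1, E2)
  R <- Kdim * S / (4 * W)          # free non-autoinhibited monomer
  R2 <- R^2 / Kdim
  R2D <- 2 * d * R2 / f
  # active protomers: both of a drug-free dimer, one of a singly bound dimer
  data.frame(
    dose_uM = drug_free,
    A = KA * R,
    R = R,
    RD = d * R,
    R2 = R2,
    R2D = R2D,
    R2D2 = d^2 * R2 / (f * g),
    D_free = drug_free,
    active_fraction = (2 * R2 + R2D) / params$raf_total)
}
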