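#' Model parameters for one RAF/inhibitor equilibrium system
#'
#' Bundles the equilibrium constants and thermodynamic factors that define one
#' instance of the RAF paradoxical-activation model (one drug in one cellular
#' context), together with the model variant in force.
#'
#' The four variants are nested restrictions of a single unified equilibrium
#' scheme:
#' \describe{
#'   \item{`"CA"`}{conformational autoinhibition only: `f = 1`, `g = 1`.}
#'   \item{`"DP"`}{dimer potentiation only: `K_A = 0`, `g = 1`.}
#'   \item{`"NC"`}{negative cooperativity only: `K_A = 0`, `f = 1`.}
#'   \item{`"unified"`}{all three mechanisms free.}
#' }
#' The variant is explicit and never inferred from parameter values: `f = 1`
#' inside a unified-model fit is a legal outcome, not a variant switch.
#'
#' @param K_A dimensionless autoinhibition equilibrium constant, the
#'   concentration ratio of autoinhibited to non-autoinhibited monomer
#'   (`K_A >= 0`; `K_A = 0` disables autoinhibition).
#' @param K_dim RAF dimer dissociation constant, uM (`> 0`).
#' @param K_d drug dissociation constant for the non-autoinhibited monomer,
#'   uM (`> 0`).
#' @param f dimensionless dimer-potentiation factor. The drug binds a dimer
#'   site with per-site dissociation constant `f * K_d`, and (by detailed
#'   balance) a drug-bound monomer dimerizes with dissociation constant scaled
#'   by `f`; `f < 1` means the drug stabilizes dimers.
#' @param g dimensionless negative-cooperativity factor: the second drug
#'   binding event within a dimer is weakened so that the doubly bound dimer
#'   carries statistical weight `d_rel^2 / (f*g)` relative to the drug-free
#'   dimer; `g > 1` disfavours double occupancy.
#' @param raf_total total RAF protomer concentration, uM (`> 0`).
#' @param variant one of `"CA"`, `"DP"`, `"NC"`, `"unified"`.
#'
#' @return An object of class `raf_params`: a named list with the validated
#'   fields above.
#' @examples
#' p <- model_params(K_A = 10, K_dim = 0.1, K_d = 0.1, raf_total = 0.04,
#'                   variant = "CA")
#' baseline_active_fraction(p)
#' @export
model_params <- function(K_A = 0, K_dim = 0.1, K_d = 0.1, f = 1, g = 1,
                         raf_total = 0.04,
                         variant = c("unified", "CA", "DP", "NC")) {
  variant <- match.arg(variant)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    as.numeric(x)
  }
  K_A <- num1(K_A, "K_A"); K_dim <- num1(K_dim, "K_dim")
  K_d <- num1(K_d, "K_d"); f <- num1(f, "f"); g <- num1(g, "g")
  raf_total <- num1(raf_total, "raf_total")
  if (K_A < 0) stop("K_A must be >= 0", call. = FALSE)
  if (K_dim <= 0 || K_d <= 0 || raf_total <= 0 || f <= 0 || g <= 0)
    stop("K_dim, K_d, raf_total, f and g must all be > 0", call. = FALSE)
  tolv <- 1e-12
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  switch(variant,
    CA = {
      chk(abs(f - 1) <= tolv && abs(g - 1) <= tolv,
          "variant 'CA' requires f = 1 and g = 1")
      f <- 1; g <- 1
    },
    DP = {
      chk(K_A <= tolv && abs(g - 1) <= tolv,
          "variant 'DP' requires K_A = 0 and g = 1")
      K_A <- 0; g <- 1
    },
    NC = {
      chk(K_A <= tolv && abs(f - 1) <= tolv,
          "variant 'NC' requires K_A = 0 and f = 1")
      K_A <- 0; f <- 1
    },
    unified = NULL)
  structure(
    list(K_A = K_A, K_dim = K_dim, K_d = K_d, f = f, g = g,
         raf_total = raf_total, variant = variant),
    class = "raf_params")
}

#' @export
print.raf_params <- function(x, ...) {
  cat(sprintf("RAF equilibrium model parameters [%s]\n", x$variant))
  cat(sprintf("  K_A   = %g        (autoinhibition, dimensionless)\n", x$K_A))
  cat(sprintf("  K_dim = %g uM     (dimer dissociation)\n", x$K_dim))
  cat(sprintf("  K_d   = %g uM     (drug-monomer dissociation)\n", x$K_d))
  cat(sprintf("  f     = %g        (dimer potentiation)\n", x$f))
  cat(sprintf("  g     = %g        (negative cooperativity)\n", x$g))
  cat(sprintf("  [RAF] = %g uM     (total protomer)\n", x$raf_total))
  invisible(x)
}

#' Serialize / deserialize model parameters
#'
#' `params_to_list()` flattens a `raf_params` object to the key-value schema
#' used in config files (`K_A`, `K_dim_uM`, `K_d_uM`, `f`, `g`,
#' `raf_total_uM`, `variant`); `params_from_list()` inverts it. Unknown keys
#' are rejected so that typos in hand-written configs fail loudly.
#'
#' @param params a `raf_params` object.
#' @param x a named list (e.g. parsed from YAML or JSON).
#' @return A plain named list, or a `raf_params` object respectively.
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "raf_params"))
  list(K_A = params$K_A, K_dim_uM = params$K_dim, K_d_uM = params$K_d,
       f = params$f, g = params$g, raf_total_uM = params$raf_total,
       variant = params$variant)
}

#' @rdname params_to_list
#' @export
params_from_list <- function(x) {
  allowed <- c("K_A", "K_dim_uM", "K_d_uM", "f", "g", "raf_total_uM",
               "variant")
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown parameter keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  get1 <- function(k, default) if (!is.null(x[[k]])) x[[k]] else default
  model_params(K_A = get1("K_A", 0), K_dim = get1("K_dim_uM", 0.1),
               K_d = get1("K_d_uM", 0.1), f = get1("f", 1), g = get1("g", 1),
               raf_total = get1("raf_total_uM", 0.04),
               variant = get1("variant", "unified"))
}

#' Logarithmic dose grid
#'
#' Builds the default dose axis used throughout: decade-spaced free-drug
#' concentrations with a leading zero dose so the drug-free baseline is always
#' represented. Drug is treated as buffered, so grid values are free drug.
#'
#' @param from,to span of the positive doses, uM.
#' @param points_per_decade grid density (default 25).
#' @param include_zero prepend a zero dose (default `TRUE`).
#' @return Numeric vector of doses (uM), strictly increasing.
#' @export
dose_grid <- function(from = 1e-4, to = 1e2, points_per_decade = 25,
                      include_zero = TRUE) {
  stopifnot(from > 0, to > from, points_per_decade >= 1)
  d <- 10^seq(log10(from), log10(to), by = 1 / points_per_decade)
  if (d[length(d)] < to) d <- c(d, to)
  if (include_zero) d <- c(0, d)
  d
}

assert_doses <- function(doses, require_zero = FALSE) {
  if (!is.numeric(doses) || length(doses) == 0L || any(!is.finite(doses)))
    stop("doses must be a non-empty finite numeric vector", call. = FALSE)
  if (any(doses < 0)) stop("doses must be nonnegative", call. = FALSE)
  if (is.unsorted(doses, strictly = TRUE))
    stop("doses must be strictly increasing", call. = FALSE)
  if (require_zero && doses[1] != 0)
    stop("dose grid must contain 0 (baseline)", call. = FALSE)
  invisible(doses)
}
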