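#' Inhibitor archetypes for synthetic panels
#'
#' Generating ranges for the drug-specific parameters of three RAF-inhibitor
#' archetypes, mirroring the qualitative signatures by which type I, I.5 and
#' II inhibitors separate in the (f, K_d) plane: type I inhibitors are strong
#' dimer potentiators (f well below 1) with high potency; type I.5
#' inhibitors potentiate dimers more weakly and bind with larger K_d; type
#' II inhibitors have f near 1. The f ranges are non-overlapping and ordered
#' `type_I < type_I5 < type_II`. All ranges lie inside the fitting bounds of
#' [default_bounds()]. The specific intervals are documented synthetic
#' choices of this package, not measured values.
#'
#' @return Data frame with one row per archetype: `label`, `f_lo`, `f_hi`,
#'   `K_d_lo`, `K_d_hi` (uM), `g_lo`, `g_hi`; parameters are drawn
#'   log-uniformly within these intervals.
#' @export
drug_archetypes <- function() {
  data.frame(
    label = c("type_I", "type_I5", "type_II"),
    f_lo = c(0.010, 0.15, 0.80), f_hi = c(0.040, 0.50, 1.40),
    K_d_lo = c(0.003, 0.08, 0.02), K_d_hi = c(0.012, 0.40, 0.08),
    g_lo = c(20, 100, 10), g_hi = c(200, 1000, 100))
}

#' Generate the ground truth of a synthetic dose-response panel
#'
#' Draws per-drug parameters from the archetype ranges, emulating the design
#' of a nine-inhibitor, seven-dose panel of max-normalized active-RAF
#' readouts: shared cell-intrinsic parameters (`K_A = 10`, `K_dim = 0.1` uM,
#' `raf_total = 0.04` uM by default) and drug-specific `(K_d, f, g)`.
#'
#' @param n_drugs number of drugs (default 9).
#' @param archetype_mix named integer vector giving how many drugs of each
#'   archetype (must sum to `n_drugs`); default 3/3/3 across
#'   `type_I`, `type_I5`, `type_II`.
#' @param shared named list of shared parameters `K_A`, `K_dim`,
#'   `raf_total`.
#' @param doses dose axis, uM: 7 log-spaced inhibitor concentrations by
#'   default (1e-4 to 10 uM), spanning from below the most potent drug's
#'   K_d (so the normalized baseline plateau is sampled) to past the PA
#'   peak into the inhibitory regime.
#' @param seed integer seed; the panel is fully reproducible from it.
#' @return An object of class `raf_panel`: list with `drugs` (data frame of
#'   per-drug ground-truth parameters and archetype labels), `shared`,
#'   `doses`, `seed`; response matrices are added by
#'   [simulate_responses()].
#' @export
make_panel <- function(n_drugs = 9,
                       archetype_mix = c(type_I = 3, type_I5 = 3,
                                         type_II = 3),
                       shared = list(K_A = 10, K_dim = 0.1,
                                     raf_total = 0.04),
                       doses = 10^seq(-4, 1, length.out = 7),
                       seed = 1) {
  stopifnot(n_drugs >= 1, sum(archetype_mix) == n_drugs)
  if (length(archetype_mix) == 0L) stop("empty archetype mix", call. = FALSE)
  arch <- drug_archetypes()
  stopifnot(all(names(archetype_mix) %in% arch$label))
  assert_doses(doses)
  labels <- rep(names(archetype_mix), archetype_mix)
  drugs <- .with_seed(seed, {
    runif_log <- function(lo, hi) 10^stats::runif(length(lo), log10(lo),
                                                  log10(hi))
    a <- arch[match(labels, arch$label), ]
    data.frame(
      drug = sprintf("%s_%d", labels, stats::ave(seq_along(labels), labels,
                                                 FUN = seq_along)),
      archetype = labels,
      K_d = runif_log(a$K_d_lo, a$K_d_hi),
      f = runif_log(a$f_lo, a$f_hi),
      g = runif_log(a$g_lo, a$g_hi))
  })
  structure(list(drugs = drugs, shared = shared, doses = doses,
                 seed = seed),
            class = "raf_panel")
}

#' Simulate noisy normalized responses for a panel
#'
#' Evaluates the unified model at every drug's ground-truth parameters over
#' the dose grid, applies multiplicative log-normal noise with the given
#' coefficient of variation (readouts are positive band-intensity-like
#' quantities), and max-normalizes each drug's noisy curve — normalization
#' after noise, as real normalized blots are produced.
#'
#' @param panel a [make_panel()] object.
#' @param noise_cv relative standard deviation of the multiplicative noise
#'   (default 0.05; 0 gives noise-free data). The log-normal is mean-1 with
#'   `sdlog = sqrt(log(1 + noise_cv^2))`.
#' @param seed integer seed for the noise draw.
#' @return The panel with matrices added: `noiseless` (absolute active
#'   fraction), `noiseless_normalized`, `noisy_raw` (noise applied, not yet
#'   normalized), `Y` (noisy, max-normalized, the fitting input), and
#'   fields `noise_cv`, `noise_seed`.
#' @export
simulate_responses <- function(panel, noise_cv = 0.05, seed = 1) {
  stopifnot(inherits(panel, "raf_panel"), noise_cv >= 0)
  nd <- length(panel$doses)
  noiseless <- t(vapply(seq_len(nrow(panel$drugs)), function(i) {
    p <- model_params(K_A = panel$shared$K_A, K_dim = panel$shared$K_dim,
                      K_d = panel$drugs$K_d[i], f = panel$drugs$f[i],
                      g = panel$drugs$g[i],
                      raf_total = panel$shared$raf_total,
                      variant = "unified")
    active_raf_fraction(p, panel$doses)
  }, numeric(nd)))
  rownames(noiseless) <- panel$drugs$drug
  colnames(noiseless) <- signif(panel$doses, 6)
  noisy <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    eps <- .with_seed(seed, {
      matrix(stats::rlnorm(length(noiseless), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog), nrow = nrow(noiseless))
    })
    noiseless * eps
  } else noiseless
  panel$noiseless <- noiseless
  panel$noiseless_normalized <- noiseless / apply(noiseless, 1, max)
  panel$noisy_raw <- noisy
  panel$Y <- noisy / apply(noisy, 1, max)
  panel$noise_cv <- noise_cv
  panel$noise_seed <- seed
  panel
}

#' @export
print.raf_panel <- function(x, ...) {
  cat(sprintf("Synthetic dose-response panel: %d drugs x %d doses (seed %d)\n",
              nrow(x$drugs), length(x$doses), x$seed))
  cat("  archetypes:", paste(sprintf("%s x%d", names(table(x$drugs$archetype)),
                                     table(x$drugs$archetype)),
                             collapse = ", "), "\n")
  if (!is.null(x$Y))
    cat(sprintf("  responses simulated at noise CV %.3g\n", x$noise_cv))
  invisible(x)
}

#' Write / read a panel (CSV + JSON sidecar)
#'
#' `write_panel()` writes the noisy normalized responses as long-format CSV
#' (`drug, dose_uM, response_normalized`) and, alongside it, a JSON sidecar
#' (`<path>.json`) holding the ground truth (per-drug parameters, shared
#' parameters, noise model, seeds) so recovery experiments can round-trip.
#' `read_panel()` inverts this; without a sidecar it returns just the
#' observed panel (no ground truth), which [as_fit_problem()] accepts.
#' Numeric round-trip is exact to 1e-12 (values serialized at full
#' precision).
#'
#' @param panel a simulated [make_panel()] object (after
#'   [simulate_responses()]).
#' @param file CSV path; the sidecar is written at `paste0(file, ".json")`.
#' @param sidecar write the ground-truth sidecar (default `TRUE`).
#' @return `write_panel()`: `file`, invisibly. `read_panel()`: a `raf_panel`
#'   (with ground truth if the sidecar is present).
#' @export
write_panel <- function(panel, file, sidecar = TRUE) {
  stopifnot(inherits(panel, "raf_panel"), !is.null(panel$Y))
  long <- data.frame(
    drug = rep(rownames(panel$Y), each = ncol(panel$Y)),
    dose_uM = sprintf("%.17g", rep(panel$doses, times = nrow(panel$Y))),
    response_normalized = sprintf("%.17g", as.vector(t(panel$Y))))
  utils::write.csv(long, file, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    side <- list(drugs = panel$drugs, shared = panel$shared,
                 doses = panel$doses, seed = panel$seed,
                 noise_cv = panel$noise_cv, noise_seed = panel$noise_seed)
    jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(file)
}

#' @rdname write_panel
#' @export
read_panel <- function(file) {
  long <- tryCatch(
    utils::read.csv(file, stringsAsFactors = FALSE),
    error = function(e) stop("malformed panel CSV '", file, "': ",
                             conditionMessage(e), call. = FALSE))
  need <- c("drug", "dose_uM", "response_normalized")
  if (!all(need %in% names(long)))
    stop("panel CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  drugs <- unique(long$drug)
  doses <- sort(unique(long$dose_uM))
  Y <- matrix(NA_real_, length(drugs), length(doses),
              dimnames = list(drugs, signif(doses, 6)))
  for (k in seq_len(nrow(long))) {
    i <- match(long$drug[k], drugs); j <- match(long$dose_uM[k], doses)
    Y[i, j] <- long$response_normalized[k]
  }
  if (any(is.na(Y)))
    stop("panel CSV is not a complete drugs x doses grid", call. = FALSE)
  panel <- structure(list(doses = doses, Y = Y), class = "raf_panel")
  sidecar <- paste0(file, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    panel$drugs <- side$drugs[match(drugs, side$drugs$drug), ]
    panel$shared <- as.list(side$shared)
    panel$seed <- side$seed
    panel$noise_cv <- side$noise_cv
    panel$noise_seed <- side$noise_seed
  }
  panel
}

#' Turn a panel into a fitting problem
#'
#' @param panel a `raf_panel` with simulated or loaded responses.
#' @param ... passed to [fit_problem()] (e.g. `free_global`, `exclude`).
#' @return A [fit_problem()] object over the panel's noisy normalized
#'   matrix and dose grid.
#' @export
as_fit_problem <- function(panel, ...) {
  stopifnot(inherits(panel, "raf_panel"), !is.null(panel$Y))
  fit_problem(panel$Y, panel$doses, ...)
}
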