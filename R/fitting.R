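#' Default box bounds for fitting, per parameter
#'
#' Log-uniform multi-start sampling and the bounded local optimization both
#' operate inside these decade-spanning boxes (concentrations in uM):
#' `f` in \[1e-5, 1e2\], `g` in \[1, 1e4\], `K_A` in \[1e-3, 1e2\],
#' `K_d` in \[1e-4, 1e4\], `K_dim` in \[1e-4, 1e4\], `raf_total` in
#' \[1e-4, 1e3\].
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function() {
  list(K_A = c(1e-3, 1e2), K_d = c(1e-4, 1e4), K_dim = c(1e-4, 1e4),
       raf_total = c(1e-4, 1e3), f = c(1e-5, 1e2), g = c(1, 1e4))
}

#' Define a dose-response fitting problem
#'
#' Sets up the inverse problem: given a drugs x doses matrix of
#' max-normalized active-RAF readouts, fit the unified equilibrium model
#' with cell-intrinsic parameters shared across drugs (the autoinhibition
#' constant `K_A`, and optionally `K_dim` and `raf_total`) and drug-specific
#' parameters (`K_d`, `f`, `g`) per drug. With 9 drugs and `K_A` the only
#' global free parameter this is the 28-parameter layout (1 global + 27
#' drug-specific).
#'
#' Mechanisms can be excluded for sub-model comparison: excluding `"CA"`
#' pins `K_A = 0`, excluding `"DP"` pins `f = 1`, excluding `"NC"` pins
#' `g = 1`.
#'
#' Predictions are max-normalized per drug before metric evaluation, exactly
#' as the observations are, so absolute activity levels are never compared
#' to normalized data.
#'
#' @param Y numeric matrix (`n_drugs x n_doses`) of observed max-normalized
#'   responses; must be finite and strictly positive (both fit metrics
#'   divide by the observation). Row names identify drugs.
#' @param doses dose axis, uM: a vector shared by all drugs, or a matrix /
#'   list of per-drug dose vectors matching `Y`'s rows.
#' @param fixed named list of pinned global parameters (default
#'   `raf_total = 0.04`, `K_dim = 0.1`, the representative literature-range
#'   values used when these are not fitted).
#' @param free_global character vector of globally shared free parameters,
#'   subset of `c("K_A", "K_dim", "raf_total")` (default `"K_A"`).
#' @param exclude character vector of excluded mechanisms, subset of
#'   `c("CA", "DP", "NC")`.
#' @param bounds named list of per-parameter bounds (see
#'   [default_bounds()]).
#' @return An object of class `raf_fit_problem`.
#' @export
fit_problem <- function(Y, doses,
                        fixed = list(raf_total = 0.04, K_dim = 0.1),
                        free_global = "K_A", exclude = character(),
                        bounds = default_bounds()) {
  Y <- as.matrix(Y)
  if (!all(is.finite(Y)) || any(Y <= 0))
    stop("Y must be finite and > 0 (metrics divide by the observations)",
         call. = FALSE)
  n_drugs <- nrow(Y)
  if (is.null(rownames(Y))) rownames(Y) <- paste0("drug_", seq_len(n_drugs))
  if (is.list(doses)) {
    stopifnot(length(doses) == n_drugs)
    dose_mat <- do.call(rbind, doses)
  } else if (is.matrix(doses)) {
    dose_mat <- doses
  } else {
    dose_mat <- matrix(doses, n_drugs, length(doses), byrow = TRUE)
  }
  if (!identical(dim(dose_mat), dim(Y)))
    stop("dose layout does not match Y", call. = FALSE)
  if (any(dose_mat < 0)) stop("doses must be >= 0", call. = FALSE)
  stopifnot(all(free_global %in% c("K_A", "K_dim", "raf_total")),
            all(exclude %in% c("CA", "DP", "NC")))
  if ("CA" %in% exclude) free_global <- setdiff(free_global, "K_A")
  # layout: global rows first, then (K_d, f, g) per drug
  rows <- list()
  for (p in free_global)
    rows[[length(rows) + 1L]] <- data.frame(param = p, drug = NA_integer_)
  per_drug <- c("K_d", if (!"DP" %in% exclude) "f",
                if (!"NC" %in% exclude) "g")
  for (i in seq_len(n_drugs))
    for (p in per_drug)
      rows[[length(rows) + 1L]] <- data.frame(param = p, drug = i)
  layout <- do.call(rbind, rows)
  layout$name <- ifelse(is.na(layout$drug), layout$param,
                        paste0(layout$param, "[", rownames(Y)[layout$drug],
                               "]"))
  layout$lb <- vapply(layout$param, function(p) bounds[[p]][1], numeric(1))
  layout$ub <- vapply(layout$param, function(p) bounds[[p]][2], numeric(1))
  # integer maps from the theta vector into model parameters (hot path)
  idx <- list()
  for (p in c("K_A", "K_dim", "raf_total")) {
    i <- which(layout$param == p & is.na(layout$drug))
    if (length(i)) idx[[p]] <- i
  }
  for (p in c("K_d", "f", "g")) {
    i <- which(layout$param == p & !is.na(layout$drug))
    if (length(i)) idx[[p]] <- i[order(layout$drug[i])]
  }
  structure(
    list(Y = Y, dose_mat = dose_mat, fixed = fixed,
         free_global = free_global, exclude = exclude, layout = layout,
         idx = idx, tdose = as.vector(t(dose_mat)), bounds = bounds,
         n_drugs = n_drugs, n_doses = ncol(Y)),
    class = "raf_fit_problem")
}

#' @export
print.raf_fit_problem <- function(x, ...) {
  cat(sprintf(
    "RAF dose-response fit problem: %d drugs x %d doses, %d free parameters\n",
    x$n_drugs, x$n_doses, nrow(x$layout)))
  if (length(x$exclude))
    cat("  mechanisms excluded:", paste(x$exclude, collapse = ", "), "\n")
  invisible(x)
}

# Expand a free-parameter vector (natural scale, layout order) to full model
# parameters: scalars K_A, K_dim, raf_total and per-drug vectors K_d, f, g.
.unpack_theta <- function(theta, problem) {
  idx <- problem$idx
  K_A <- if (!is.null(idx$K_A)) theta[idx$K_A]
         else if ("CA" %in% problem$exclude) 0
         else if (!is.null(problem$fixed$K_A)) problem$fixed$K_A
         else stop("K_A neither free nor fixed", call. = FALSE)
  list(
    K_A = K_A,
    K_dim = if (!is.null(idx$K_dim)) theta[idx$K_dim]
            else problem$fixed$K_dim,
    raf_total = if (!is.null(idx$raf_total)) theta[idx$raf_total]
                else problem$fixed$raf_total,
    K_d = theta[idx$K_d],
    f = if (!is.null(idx$f)) theta[idx$f] else rep(1, problem$n_drugs),
    g = if (!is.null(idx$g)) theta[idx$g] else rep(1, problem$n_drugs))
}

# Vectorized unified-model prediction over the whole panel, max-normalized
# per drug. th: output of .unpack_theta().
.predict_core <- function(th, problem) {
  nd <- problem$n_doses
  Kd <- rep(th$K_d, each = nd)
  f <- rep(th$f, each = nd)
  g <- rep(th$g, each = nd)
  d <- problem$tdose / Kd
  rr <- th$raf_total / th$K_dim
  W <- 1 + 2 * d / f + d^2 / (f * g)
  E1 <- 1 + th$K_A + d
  E2 <- 8 * rr * W
  S <- E2 / (sqrt(E1^2 + E2) + E1)
  act <- matrix(S^2 * (1 + d / f) / (E2 * W), ncol = nd, byrow = TRUE)
  act / apply(act, 1, max)
}

#' Predict the normalized response matrix for a parameter vector
#'
#' @param theta free-parameter vector in natural scale, in the order of
#'   `problem$layout` (see [fit_problem()]).
#' @param problem a [fit_problem()] object.
#' @return Matrix matching `problem$Y`: per-drug max-normalized predicted
#'   activity.
#' @export
predict_matrix <- function(theta, problem) {
  stopifnot(inherits(problem, "raf_fit_problem"),
            length(theta) == nrow(problem$layout))
  out <- .predict_core(.unpack_theta(theta, problem), problem)
  dimnames(out) <- dimnames(problem$Y)
  out
}

#' Fit metrics: mean squared and mean absolute relative deviation
#'
#' `fit_metric_chisq()` is the chi-square-like objective minimized during
#' fitting: the mean over all drugs and doses of
#' `((pred - obs) / obs)^2`. `fit_metric_absolute()` is the average
#' proportionate deviation `|pred - obs| / obs`, used for sub-model
#' comparison; multiplied by 100 it is the mean percentage error per data
#' point.
#'
#' @param pred,obs numeric matrices of identical shape; `obs` must be
#'   strictly positive.
#' @return Nonnegative scalar; zero iff `pred == obs`.
#' @export
fit_metric_chisq <- function(pred, obs) {
  .check_metric_args(pred, obs)
  mean(((pred - obs) / obs)^2)
}

#' @rdname fit_metric_chisq
#' @export
fit_metric_absolute <- function(pred, obs) {
  .check_metric_args(pred, obs)
  mean(abs(pred - obs) / obs)
}

.check_metric_args <- function(pred, obs) {
  if (!identical(dim(as.matrix(pred)), dim(as.matrix(obs))))
    stop("pred and obs must have identical shape", call. = FALSE)
  if (any(obs <= 0)) stop("observations must be > 0", call. = FALSE)
  invisible(TRUE)
}

# Run code with a local RNG state derived from `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Multi-start bounded fit of the equilibrium model
#'
#' Fits the model to the problem's normalized response matrix by repeated
#' bounded local optimization from random starting points. Optimization is
#' over log10-transformed parameters (bounds mapped accordingly): the search
#' domain spans many decades and the starts are drawn log-uniformly within
#' the boxes, mirroring how such multi-start protocols are run. Each start
#' is refined with `stats::optim(method = "L-BFGS-B")`, a gradient-based
#' local optimizer honoring the box bounds; starts that fail to converge are
#' recorded and skipped. The best-fit ensemble collects every converged
#' start whose metric is within 10% of the lowest metric found.
#'
#' The local stage is staged to cope with the objective's large plateaus
#' (a `K_d` far outside the dose range yields a flat normalized curve with
#' vanishing gradients): each start first runs blockwise descent — a coarse
#' deterministic probe over `(K_d, f)` per drug to escape plateaus, bounded
#' quasi-Newton refinement of each drug's `(K_d, f, g)` triple, and a
#' one-dimensional (or low-dimensional) search over the shared global
#' parameters — iterated to stagnation, followed by a joint bounded
#' quasi-Newton polish ([stats::nlminb]) over the full parameter vector.
#' The blockwise stage exploits that, for fixed globals, the objective is a
#' mean of independent per-drug terms.
#'
#' @param problem a [fit_problem()] object.
#' @param n_starts number of random starts (>= 1). 1500 reproduces the
#'   full published-style protocol; 100 is a practical default for
#'   synthetic-panel studies.
#' @param seed integer seed; the full result is reproducible from it.
#' @param metric `"chisq"` (default, used for fitting) or `"absolute"`
#'   (used for sub-model comparison).
#' @param maxit maximum iterations of the joint polish.
#' @param n_sweeps maximum blockwise sweeps per start (default 8; sweeps
#'   stop early at relative stagnation 1e-12).
#' @param init optional matrix (rows = starts) or vector of natural-scale
#'   starting parameter vectors in layout order, replacing the random
#'   log-uniform draws (e.g. to polish a known solution).
#' @return An object of class `raf_fit`: list with `best` (named natural-
#'   scale vector), `best_metric`, `ensemble` (matrix, natural scale, one
#'   row per member within 10% of the minimum), `ensemble_metrics`,
#'   `predicted` (best-fit normalized curves), `predicted_mean`/
#'   `predicted_sd` (over the ensemble), `n_starts`, `n_converged`, `seed`,
#'   `metric`, and the `problem`.
#' @export
multistart_fit <- function(problem, n_starts = 100, seed = 1,
                           metric = c("chisq", "absolute"), maxit = 400,
                           n_sweeps = 8, init = NULL) {
  stopifnot(inherits(problem, "raf_fit_problem"), n_starts >= 1)
  metric <- match.arg(metric)
  mfun <- if (metric == "chisq") fit_metric_chisq else fit_metric_absolute
  cellmean <- if (metric == "chisq") {
    function(p, o) mean(((p - o) / o)^2)
  } else {
    function(p, o) mean(abs(p - o) / o)
  }
  lay <- problem$layout; idx <- problem$idx
  llb <- log10(lay$lb); lub <- log10(lay$ub)
  obj <- function(ltheta) {
    v <- tryCatch(
      mfun(.predict_core(.unpack_theta(10^ltheta, problem), problem),
           problem$Y),
      error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  # per-drug contribution for the blockwise stage (globals passed in)
  drug_obj <- function(i, Kd, f, g, KA, rr) {
    d <- problem$dose_mat[i, ] / Kd
    W <- 1 + 2 * d / f + d^2 / (f * g)
    E1 <- 1 + KA + d
    E2 <- 8 * rr * W
    S <- E2 / (sqrt(E1^2 + E2) + E1)
    a <- S^2 * (1 + d / f) / (E2 * W)
    v <- cellmean(a / max(a), problem$Y[i, ])
    if (is.finite(v)) v else 1e10
  }
  gl_idx <- unlist(idx[c("K_A", "K_dim", "raf_total")])
  f_free <- !is.null(idx$f); g_free <- !is.null(idx$g)
  probe <- expand.grid(
    lKd = seq(llb[idx$K_d[1]], lub[idx$K_d[1]], by = 0.5),
    lf = if (f_free) seq(llb[idx$f[1]], lub[idx$f[1]], by = 0.5) else 0)
  localfit <- function(lt) {
    prev <- Inf
    for (sweep in seq_len(n_sweeps)) {
      th <- .unpack_theta(10^lt, problem)
      KA <- th$K_A; rr <- th$raf_total / th$K_dim
      for (i in seq_len(problem$n_drugs)) {
        di <- c(idx$K_d[i], if (f_free) idx$f[i], if (g_free) idx$g[i])
        l3 <- lt[di]
        gi <- if (g_free) 10^l3[length(l3)] else 1
        if (sweep == 1L) {
          # coarse probe escapes the flat-curve plateaus
          vals <- mapply(function(k, lf)
            drug_obj(i, 10^k, if (f_free) 10^lf else 1, gi, KA, rr),
            probe$lKd, probe$lf)
          b <- which.min(vals)
          cur <- drug_obj(i, 10^l3[1], if (f_free) 10^l3[2] else 1, gi,
                          KA, rr)
          if (vals[b] < cur) {
            l3[1] <- probe$lKd[b]
            if (f_free) l3[2] <- probe$lf[b]
          }
        }
        oi <- function(lx) {
          Kd <- 10^lx[1]
          f <- if (f_free) 10^lx[2] else 1
          g <- if (g_free) 10^lx[length(lx)] else 1
          drug_obj(i, Kd, f, g, KA, rr)
        }
        r <- tryCatch(
          stats::nlminb(l3, oi, lower = llb[di], upper = lub[di],
                        control = list(rel.tol = 1e-13)),
          error = function(e) NULL)
        if (!is.null(r)) lt[di] <- r$par
      }
      if (length(gl_idx) == 1L) {
        og <- function(lg) { l <- lt; l[gl_idx] <- lg; obj(l) }
        rg <- stats::optimize(og, c(llb[gl_idx], lub[gl_idx]), tol = 1e-7)
        if (rg$objective < obj(lt)) lt[gl_idx] <- rg$minimum
      } else if (length(gl_idx) > 1L) {
        og <- function(lg) { l <- lt; l[gl_idx] <- lg; obj(l) }
        rg <- tryCatch(
          stats::nlminb(lt[gl_idx], og, lower = llb[gl_idx],
                        upper = lub[gl_idx],
                        control = list(rel.tol = 1e-13)),
          error = function(e) NULL)
        if (!is.null(rg) && rg$objective < obj(lt)) lt[gl_idx] <- rg$par
      }
      cur <- obj(lt)
      if (prev - cur < 1e-12 * max(cur, 1e-12)) { prev <- cur; break }
      prev <- cur
    }
    pol <- tryCatch(
      stats::nlminb(lt, obj, lower = llb, upper = lub,
                    control = list(rel.tol = 1e-13, iter.max = maxit,
                                   eval.max = 4L * maxit)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$objective <= prev)
      list(par = pol$par, value = pol$objective)
    else list(par = lt, value = prev)
  }
  starts <- if (!is.null(init)) {
    m <- log10(if (is.matrix(init)) init else matrix(init, nrow = 1))
    stopifnot(ncol(m) == nrow(lay))
    n_starts <- nrow(m)
    m
  } else .with_seed(seed, {
    matrix(stats::runif(n_starts * nrow(lay), rep(llb, each = n_starts),
                        rep(lub, each = n_starts)),
           nrow = n_starts)
  })
  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fits[[s]] <- tryCatch(localfit(starts[s, ]), error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("no start converged; check the problem scaling and bounds",
         call. = FALSE)
  vals <- vapply(fits[ok], `[[`, numeric(1), "value")
  pars <- do.call(rbind, lapply(fits[ok], `[[`, "par"))
  best_i <- which.min(vals)
  in_ens <- vals <= 1.1 * vals[best_i]
  ens <- 10^pars[in_ens, , drop = FALSE]
  colnames(ens) <- lay$name
  best <- stats::setNames(10^pars[best_i, ], lay$name)
  pred_ens <- lapply(seq_len(nrow(ens)), function(i)
    predict_matrix(ens[i, ], problem))
  pred_arr <- simplify2array(pred_ens)
  out <- list(
    best = best, best_metric = vals[best_i],
    ensemble = ens, ensemble_metrics = vals[in_ens],
    predicted = predict_matrix(best, problem),
    predicted_mean = apply(pred_arr, c(1, 2), mean),
    predicted_sd = apply(pred_arr, c(1, 2), stats::sd),
    n_starts = n_starts, n_converged = sum(ok), seed = seed,
    metric = metric, problem = problem)
  class(out) <- "raf_fit"
  out
}

#' @export
print.raf_fit <- function(x, ...) {
  cat(sprintf(
    "Multi-start fit: %d/%d starts converged; best %s metric %.4g\n",
    x$n_converged, x$n_starts, x$metric, x$best_metric))
  cat(sprintf("  best-fit ensemble (within 10%% of minimum): %d members\n",
              nrow(x$ensemble)))
  if ("K_A" %in% names(x$best))
    cat(sprintf("  global K_A = %.4g\n", x$best[["K_A"]]))
  invisible(x)
}

#' Compare sub-models by mechanism exclusion
#'
#' Refits the same panel under the same multi-start protocol with one or two
#' of the PA mechanisms switched off, and reports each sub-model's best mean
#' percentage error per data point (the average proportionate deviation
#' x 100). The fits minimize [fit_metric_absolute()] directly so the
#' comparison metric is also the optimization target.
#'
#' @param problem a [fit_problem()] object (built with `exclude = NULL`;
#'   exclusions are applied per sub-model here).
#' @param variants character vector of sub-models among `"unified"`,
#'   `"no_NC"`, `"no_DP"`, `"no_CA"`, `"CA_only"`, `"DP_only"`, `"NC_only"`.
#' @param n_starts,seed protocol settings per sub-model (each sub-model
#'   gets a distinct seed derived from `seed`).
#' @return Data frame: `variant`, `n_free_params`, `mean_pct_error`,
#'   ordered as given; attribute `"fits"` holds the full `raf_fit` objects.
#' @export
compare_submodels <- function(problem,
                              variants = c("unified", "no_NC", "no_DP",
                                           "no_CA", "CA_only", "DP_only",
                                           "NC_only"),
                              n_starts = 40, seed = 1) {
  excl_map <- list(unified = character(), no_NC = "NC", no_DP = "DP",
                   no_CA = "CA", CA_only = c("DP", "NC"),
                   DP_only = c("CA", "NC"), NC_only = c("CA", "DP"))
  stopifnot(all(variants %in% names(excl_map)))
  fits <- list()
  rows <- lapply(seq_along(variants), function(k) {
    v <- variants[k]
    pk <- fit_problem(problem$Y, problem$dose_mat, fixed = problem$fixed,
                      free_global = union(problem$free_global, "K_A"),
                      exclude = excl_map[[v]], bounds = problem$bounds)
    fit <- multistart_fit(pk, n_starts = n_starts, seed = seed + k,
                          metric = "absolute")
    fits[[v]] <<- fit
    data.frame(variant = v, n_free_params = nrow(pk$layout),
               mean_pct_error = 100 * fit$best_metric)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Identifiability diagnostics of a best-fit ensemble
#'
#' Summarizes how well each parameter is constrained by the data: the
#' min-max span and coefficient of variation of every free parameter across
#' the best-fit ensemble, plus all pairwise Pearson correlations between
#' log10 parameters, flagging strongly coupled pairs (`|r| > 0.9`) — the
#' signature of a structurally non-identifiable parameter combination, such
#' as a jointly free dimer affinity and autoinhibition constant.
#'
#' @param fit a [multistart_fit()] result with ensemble size >= 2 (a
#'   single-member ensemble yields zero spreads and no correlations).
#' @param cor_threshold flag threshold on `|r|` (default 0.9).
#' @return List with `parameters` (data frame: `name`, `min`, `max`, `cv`),
#'   `correlations` (matrix on log10 scale), `flagged_pairs` (data frame:
#'   `param1`, `param2`, `r`).
#' @export
identifiability_report <- function(fit, cor_threshold = 0.9) {
  stopifnot(inherits(fit, "raf_fit"))
  ens <- fit$ensemble
  pars <- data.frame(
    name = colnames(ens),
    min = apply(ens, 2, min),
    max = apply(ens, 2, max),
    cv = apply(ens, 2, function(x)
      if (mean(x) > 0) stats::sd(x) / mean(x) else 0),
    row.names = NULL)
  pars$cv[is.na(pars$cv)] <- 0
  flagged <- data.frame(param1 = character(), param2 = character(),
                        r = numeric())
  cors <- NULL
  if (nrow(ens) >= 2) {
    lg <- log10(ens)
    keep <- apply(lg, 2, function(x) stats::sd(x) > 0)
    if (sum(keep) >= 2) {
      cors <- stats::cor(lg[, keep, drop = FALSE])
      iu <- which(upper.tri(cors) & abs(cors) > cor_threshold,
                  arr.ind = TRUE)
      if (nrow(iu))
        flagged <- data.frame(param1 = rownames(cors)[iu[, 1]],
                              param2 = colnames(cors)[iu[, 2]],
                              r = cors[iu])
    }
  }
  list(parameters = pars, correlations = cors, flagged_pairs = flagged)
}
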