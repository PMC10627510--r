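#' Build the RAF/drug equilibrium reaction network
#'
#' Constructs the pairwise-equilibrium network underlying the model, built
#' only from elementary binding steps, statistical site multiplicities and
#' detailed balance — no closed-form algebra. It is the independent ground
#' truth against which every analytic solution is validated.
#'
#' Each edge states `[product] = w * prod([reactants])` at equilibrium, with
#' `w` the association weight (site multiplicity / dissociation constant):
#' \describe{
#'   \item{`A <-> R`}{autoinhibition, `[A] = K_A [R]`. The autoinhibited
#'     monomer can neither dimerize nor bind drug.}
#'   \item{`R + R <-> R2`}{dimerization, dissociation constant `K_dim`.}
#'   \item{`R + D <-> RD`}{monomer drug binding, dissociation constant `K_d`.}
#'   \item{`R2 + D <-> R2D`}{first dimer site: 2 equivalent sites, per-site
#'     dissociation `f * K_d` (dimer potentiation).}
#'   \item{`R2D + D <-> R2D2`}{second dimer site: 1 site, dissociation
#'     `2 g K_d` (statistical factor plus negative cooperativity).}
#' }
#' Two redundant edges — dimerization of drug-bound monomers,
#' `RD + R <-> R2D` (`f K_dim / 2`) and `RD + RD <-> R2D2` (`f g K_dim`) —
#' close the thermodynamic cycles; their consistency with the spanning edges
#' is asserted to relative tolerance 1e-10 and any violation is a hard error
#' naming the offending loop.
#'
#' @param params a [model_params()] object.
#' @return An object of class `raf_network`: species table (with protomer
#'   counts and drug counts) and edge list, cycle-checked.
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "raf_params"))
  KA <- params$K_A; Kdim <- params$K_dim; Kd <- params$K_d
  f <- params$f; g <- params$g
  edge <- function(reactants, product, sites_on, sites_off, Kdiss, spanning) {
    list(reactants = reactants, product = product,
         w = sites_on / (sites_off * Kdiss), sites_on = sites_on,
         sites_off = sites_off, Kdiss = Kdiss, spanning = spanning)
  }
  edges <- list(
    autoinhibition = list(reactants = "R", product = "A", w = KA,
                          spanning = TRUE),
    dimerization   = edge(c("R", "R"), "R2", 1, 1, Kdim, TRUE),
    monomer_drug   = edge(c("R", "D"), "RD", 1, 1, Kd, TRUE),
    dimer_drug_1   = edge(c("R2", "D"), "R2D", 2, 1, f * Kd, TRUE),
    dimer_drug_2   = edge(c("R2D", "D"), "R2D2", 1, 2, g * Kd, TRUE),
    bound_dimerization_1 = edge(c("RD", "R"), "R2D", 2, 1, f * Kdim, FALSE),
    bound_dimerization_2 = edge(c("RD", "RD"), "R2D2", 1, 1, f * g * Kdim,
                                FALSE))
  species <- data.frame(
    name = c("A", "R", "RD", "R2", "R2D", "R2D2", "D"),
    protomers = c(1, 1, 1, 2, 2, 2, 0),
    drugs = c(0, 0, 1, 0, 1, 2, 1))
  net <- structure(list(species = species, edges = edges, params = params),
                   class = "raf_network")
  .check_cycles(net)
  # cache the equilibrium monomials as vectors for fast state evaluation
  mono <- .species_monomials(net)
  ord <- species$name
  net$coef <- vapply(ord, function(nm) mono[[nm]][["coef"]], numeric(1))
  net$pow_R <- vapply(ord, function(nm) mono[[nm]][["a"]], numeric(1))
  net$pow_D <- vapply(ord, function(nm) mono[[nm]][["b"]], numeric(1))
  net
}

#' @export
print.raf_network <- function(x, ...) {
  cat("RAF equilibrium reaction network:",
      nrow(x$species), "species,", length(x$edges), "edges",
      "(cycle-closure verified)\n")
  invisible(x)
}

# Assign each species an equilibrium monomial c * R^a * D^b from the spanning
# edges, then require every redundant edge to be satisfied: this is exactly
# the statement that every closed reaction cycle has equilibrium-constant
# product 1 (detailed balance).
.species_monomials <- function(net) {
  mono <- list(R = c(coef = 1, a = 1, b = 0), D = c(coef = 1, a = 0, b = 1))
  for (pass in 1:3) {
    for (e in net$edges) {
      if (!isTRUE(e$spanning)) next
      if (!is.null(mono[[e$product]])) next
      if (!all(e$reactants %in% names(mono))) next
      m <- c(coef = e$w, a = 0, b = 0)
      for (r in e$reactants) {
        m["coef"] <- m[["coef"]] * mono[[r]][["coef"]]
        m["a"] <- m[["a"]] + mono[[r]][["a"]]
        m["b"] <- m[["b"]] + mono[[r]][["b"]]
      }
      mono[[e$product]] <- m
    }
  }
  mono
}

.check_cycles <- function(net, tol = 1e-10) {
  mono <- .species_monomials(net)
  for (nm in names(net$edges)) {
    e <- net$edges[[nm]]
    lhs <- c(coef = e$w, a = 0, b = 0)
    for (r in e$reactants) {
      lhs["coef"] <- lhs[["coef"]] * mono[[r]][["coef"]]
      lhs["a"] <- lhs[["a"]] + mono[[r]][["a"]]
      lhs["b"] <- lhs[["b"]] + mono[[r]][["b"]]
    }
    rhs <- mono[[e$product]]
    if (lhs[["a"]] != rhs[["a"]] || lhs[["b"]] != rhs[["b"]])
      stop("stoichiometry mismatch on edge ", nm, call. = FALSE)
    # a zero coefficient (K_A = 0 disabling autoinhibition) carries no cycle
    ratio <- lhs[["coef"]] / rhs[["coef"]]
    if (is.finite(ratio) && abs(ratio - 1) > tol)
      stop(sprintf(
        "detailed-balance violation on cycle closed by edge '%s': ",
        nm), sprintf("equilibrium-constant product %.6g != 1", ratio),
        call. = FALSE)
  }
  invisible(TRUE)
}

# All species concentrations given free monomer R and free drug D
# (vectorized over the species axis using the cached monomials; note R's
# convention 0^0 = 1 handles the zero-dose and zero-K_A cases).
.network_state <- function(net, R, D) {
  st <- net$coef * R^net$pow_R * D^net$pow_D
  st[length(st)] <- D              # species "D" is the free drug itself
  names(st) <- net$species$name
  st
}

#' Solve the equilibrium network by safeguarded bracketing
#'
#' Independent numerical solution of the reaction network: every species is
#' expressed in terms of the free non-autoinhibited monomer `R` (and free
#' drug `D`) via the network edges, the protomer conservation law is reduced
#' to a scalar root problem in `log R`, and solved by Brent bracketing
#' ([stats::uniroot]) to relative tolerance 1e-13. In `"conserved"` drug mode
#' the free-drug level is found by an outer bracketing on `log D` against the
#' drug conservation law (total drug = free + bound).
#'
#' @param network a [build_network()] object.
#' @param raf_total total RAF protomer concentration, uM.
#' @param drug drug concentration, uM: free drug if `drug_mode = "buffered"`
#'   (the model's standard reading, where the dose axis is free drug), total
#'   drug if `"conserved"`.
#' @param drug_mode `"buffered"` (default) or `"conserved"`.
#' @param tol root-solver tolerance on the log-concentration scale
#'   (default 1e-13; the solution is insensitive to it well below 1e-9,
#'   which is part of the test suite's stability checks).
#' @return One-row data frame with columns `A`, `R`, `RD`, `R2`, `R2D`,
#'   `R2D2`, `D_free` (uM) and `active_fraction`.
#' @export
solve_equilibrium <- function(network, raf_total, drug,
                              drug_mode = c("buffered", "conserved"),
                              tol = 1e-13) {
  stopifnot(inherits(network, "raf_network"))
  drug_mode <- match.arg(drug_mode)
  if (!is.numeric(raf_total) || raf_total <= 0)
    stop("raf_total must be > 0", call. = FALSE)
  if (!is.numeric(drug) || drug < 0) stop("drug must be >= 0", call. = FALSE)
  prot <- stats::setNames(network$species$protomers, network$species$name)
  drg <- stats::setNames(network$species$drugs, network$species$name)
  solve_R <- function(D) {
    h <- function(lR) {
      st <- .network_state(network, exp(lR), D)
      sum(prot * st) - raf_total
    }
    lo <- log(raf_total) - 90; hi <- log(raf_total)
    if (h(lo) > 0 || h(hi) < 0)
      stop("protomer conservation root not bracketable", call. = FALSE)
    r <- stats::uniroot(h, c(lo, hi), tol = tol, maxiter = 1000L)
    exp(r$root)
  }
  if (drug_mode == "buffered" || drug == 0) {
    D <- drug
    R <- solve_R(D)
  } else {
    hd <- function(lD) {
      D <- exp(lD)
      st <- .network_state(network, solve_R(D), D)
      st[["D"]] <- 0              # count bound drug only, add free explicitly
      sum(drg * st) + D - drug
    }
    lo <- log(drug) - 70; hi <- log(drug)
    rD <- stats::uniroot(hd, c(lo, hi), tol = tol, maxiter = 1000L)
    D <- exp(rD$root)
    R <- solve_R(D)
  }
  st <- .network_state(network, R, D)
  out <- data.frame(A = st[["A"]], R = st[["R"]], RD = st[["RD"]],
                    R2 = st[["R2"]], R2D = st[["R2D"]], R2D2 = st[["R2D2"]],
                    D_free = D)
  out$active_fraction <- (2 * out$R2 + out$R2D) / raf_total
  out
}

#' Tabulate oracle equilibria over a dose grid
#'
#' Convenience wrapper running [solve_equilibrium()] across doses; the format
#' matches the fixture CSVs used by the test suite
#' (`dose_uM, A, R, RD, R2, R2D, R2D2, active_fraction`).
#'
#' @param params a [model_params()] object.
#' @param doses numeric vector of doses, uM.
#' @param drug_mode passed to [solve_equilibrium()].
#' @param file optional path; if given the table is also written as CSV.
#' @return Data frame, one row per dose.
#' @export
oracle_species_table <- function(params, doses, drug_mode = "buffered",
                                 file = NULL) {
  net <- build_network(params)
  rows <- lapply(doses, function(d)
    solve_equilibrium(net, params$raf_total, d, drug_mode))
  out <- cbind(dose_uM = doses, do.call(rbind, rows))
  out$D_free <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
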