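# From a reaction network to the polynomial mass-action ODE system, its
# stoichiometric matrix, and the exact linear conservation laws.

#' Build the mass-action ODE system of a reaction network
#'
#' The flux of reaction `j` is `k_j * prod_i X_i^{alpha_ij}` with `alpha` the
#' reactant stoichiometries; the rate of change of species `i` is row `i` of
#' the stoichiometric matrix `Gamma = beta - alpha` times the flux vector.
#' Constant species are excluded from the state: their (fixed) concentrations
#' are folded into the per-reaction rate factors, so they neither get an
#' equation nor generate spurious conservation laws.
#'
#' @param network a `reaction_network`.
#' @param constant_values optional named numeric giving concentrations of the
#'   constant species (defaults to the network's stored initial values; a
#'   constant species without a value is a configuration error).
#' @return an object of class `ode_system` with fields `state_species`,
#'   `stoich` (integer matrix, species x reactions), `flux_k`, `kfac`
#'   (numeric rate factors including constant-species contributions),
#'   `expo_state` / `expo_const` (integer exponent matrices), `rhs(x)`,
#'   `jac(x)`, `initial`, plus the sparse structure used by the C kernel.
#' @export
build_odes <- function(network, constant_values = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  const_sp <- network$constant_species
  state_sp <- setdiff(network$species, const_sp)
  cv <- setNames(rep(NA_real_, length(const_sp)), const_sp)
  if (length(const_sp)) cv[const_sp] <- network$initial[const_sp]
  if (!is.null(constant_values)) cv[names(constant_values)] <- constant_values
  if (anyNA(cv)) stop("constant species without a concentration: ",
                      paste(names(cv)[is.na(cv)], collapse = ", "))

  R <- length(network$reactions)
  S <- length(state_sp); C <- length(const_sp)
  alpha <- matrix(0L, S, R, dimnames = list(state_sp, NULL))
  gamma_c <- matrix(0L, max(C, 0), R,
                    dimnames = if (C) list(const_sp, NULL) else NULL)
  stoich <- matrix(0L, S, R, dimnames = list(state_sp, NULL))
  k <- numeric(R)
  for (j in seq_len(R)) {
    r <- network$reactions[[j]]
    k[j] <- r$rate_value
    for (sp in names(r$reactants)) {
      n <- r$reactants[[sp]]
      if (sp %in% const_sp) gamma_c[sp, j] <- gamma_c[sp, j] + n
      else { alpha[sp, j] <- alpha[sp, j] + n; stoich[sp, j] <- stoich[sp, j] - n }
    }
    for (sp in names(r$products)) {
      n <- r$products[[sp]]
      if (!(sp %in% const_sp)) stoich[sp, j] <- stoich[sp, j] + n
    }
  }
  colnames(stoich) <- vapply(network$reactions, `[[`, "", "rate_name")

  kfac <- k
  if (C) for (m in seq_len(C)) kfac <- kfac * cv[m]^gamma_c[m, ]

  # sparse flux-term and stoichiometry structure for the C kernel
  tw <- which(alpha != 0, arr.ind = TRUE)
  term_s <- as.integer(tw[, 1]); term_r <- as.integer(tw[, 2])
  term_p <- as.integer(alpha[tw])
  gw <- which(stoich != 0, arr.ind = TRUE)
  g_i <- as.integer(gw[, 1]); g_j <- as.integer(gw[, 2])
  g_v <- as.numeric(stoich[gw])

  sys <- list(state_species = state_sp, constant_species = const_sp,
              constant_values = cv[const_sp],
              stoich = stoich, flux_k = k, kfac = kfac,
              expo_state = alpha, expo_const = gamma_c,
              term_r = term_r, term_s = term_s, term_p = term_p,
              g_i = g_i, g_j = g_j, g_v = g_v,
              initial = network$initial[state_sp],
              network = network)
  sys$rhs <- function(x) {
    dx <- ma_rhs_field(matrix(as.numeric(x[state_sp]), ncol = 1),
                       term_r, term_s, term_p,
                       matrix(kfac, ncol = 1), g_i, g_j, g_v)
    setNames(as.vector(dx), state_sp)
  }
  sys$rhs_field <- function(xmat, kfac_mat) {
    ma_rhs_field(xmat, term_r, term_s, term_p, kfac_mat, g_i, g_j, g_v)
  }
  sys$jac <- function(x) ma_jacobian(sys, x)
  class(sys) <- "ode_system"
  sys
}

#' Analytic Jacobian of a mass-action system
#'
#' `d(flux_j)/d(x_l) = kfac_j * alpha_lj * x_l^(alpha_lj - 1) *
#' prod_{m != l} x_m^(alpha_mj)`; the Jacobian is `Gamma %*% dflux`.
#'
#' @param sys an `ode_system`.
#' @param x state vector (named or in `state_species` order).
#' @return dense Jacobian matrix (species x species).
#' @export
ma_jacobian <- function(sys, x) {
  sp <- sys$state_species
  x <- if (!is.null(names(x))) as.numeric(x[sp]) else as.numeric(x)
  x <- pmax(x, 0)
  S <- length(sp); R <- ncol(sys$stoich)
  alpha <- sys$expo_state
  dflux <- matrix(0, R, S)
  for (j in seq_len(R)) {
    nz <- which(alpha[, j] != 0)
    base <- sys$kfac[j]
    for (l in nz) {
      a <- alpha[l, j]
      d <- base * a * if (a > 1) x[l]^(a - 1) else 1
      for (m in setdiff(nz, l)) d <- d * x[m]^alpha[m, j]
      dflux[j, l] <- d
    }
  }
  J <- sys$stoich %*% dflux
  dimnames(J) <- list(sp, sp)
  J
}

#' @export
print.ode_system <- function(x, ...) {
  cat(sprintf("mass-action ODE system: %d state variables, %d reactions\n",
              length(x$state_species), ncol(x$stoich)))
  eqs <- ode_equations(x)
  for (i in seq_along(eqs))
    cat(sprintf("  d%s/dt = %s\n", x$state_species[i], eqs[i]))
  if (length(x$constant_species))
    cat("  constant:", paste(sprintf("%s = %g", x$constant_species,
                                     x$constant_values), collapse = ", "), "\n")
  invisible(x)
}

#' Symbolic right-hand sides as character strings
#'
#' One polynomial per state species, written with rate-constant names and
#' species symbols (constant species appear by name).
#'
#' @param sys an `ode_system`.
#' @return character vector, one equation per state species.
#' @export
ode_equations <- function(sys) {
  sp <- sys$state_species; cs <- sys$constant_species
  R <- ncol(sys$stoich)
  mono <- vapply(seq_len(R), function(j) {
    f <- colnames(sys$stoich)[j]
    for (i in seq_along(sp)) {
      a <- sys$expo_state[i, j]
      if (a == 1) f <- paste0(f, "*", sp[i])
      else if (a > 1) f <- paste0(f, "*", sp[i], "^", a)
    }
    if (length(cs)) for (m in seq_along(cs)) {
      a <- sys$expo_const[m, j]
      if (a == 1) f <- paste0(f, "*", cs[m])
      else if (a > 1) f <- paste0(f, "*", cs[m], "^", a)
    }
    f
  }, "")
  vapply(seq_along(sp), function(i) {
    terms <- character(0)
    for (j in seq_len(R)) {
      g <- sys$stoich[i, j]
      if (g == 0) next
      coef <- if (abs(g) == 1) "" else paste0(abs(g), "*")
      terms <- c(terms, paste0(if (g < 0) "- " else
                                 if (length(terms)) "+ " else "",
                               coef, mono[j]))
    }
    if (!length(terms)) "0" else paste(terms, collapse = " ")
  }, "")
}

#' Linear conservation laws of a mass-action system
#'
#' Computes a canonical basis of the left null space of the stoichiometric
#' matrix in exact rational arithmetic: every returned coefficient vector `w`
#' satisfies `t(w) %*% Gamma == 0` exactly, is scaled to coprime integers with
#' positive leading coefficient, and is deterministically ordered. The
#' conserved constant of each law is evaluated from the initial conditions,
#' so `sum(w * x(t))` stays at that constant along every trajectory.
#'
#' @param sys an `ode_system` (or a `reaction_network`, compiled on the fly).
#' @param initial optional named numeric initial state (defaults to the
#'   system's stored initial concentrations).
#' @return list of `conservation_law` objects, each with `coefficients`
#'   (named integer vector over the state species) and `constant`. Empty list
#'   if `Gamma` has full row rank.
#' @export
conservation_laws <- function(sys, initial = NULL) {
  if (inherits(sys, "reaction_network")) sys <- build_odes(sys)
  stopifnot(inherits(sys, "ode_system"))
  x0 <- sys$initial
  if (!is.null(initial)) x0[names(initial)] <- initial
  B <- integer_kernel(t(sys$stoich))
  laws <- list()
  if (ncol(B) == 0) return(laws)
  for (j in seq_len(ncol(B))) {
    w <- setNames(B[, j], sys$state_species)
    laws[[j]] <- structure(list(coefficients = w,
                                constant = sum(w * x0)),
                           class = "conservation_law")
  }
  laws
}

#' @export
print.conservation_law <- function(x, ...) {
  w <- x$coefficients[x$coefficients != 0]
  terms <- paste(ifelse(abs(w) == 1, names(w), paste0(abs(w), "*", names(w))),
                 collapse = " + ")
  terms <- gsub("\\+ -", "- ", terms)
  cat(sprintf("%s = %g\n", terms, x$constant))
  invisible(x)
}

#' Eliminate species using conservation laws
#'
#' Substitutes, for each law, one chosen species by the affine expression the
#' law implies: the remaining equations form a reduced system of dimension
#' `length(state) - length(laws)`. The reduced system exposes `rhs`, `jac`
#' (via the chain rule through the affine lift), and `lift(x_red)`
#' reconstructing the full state.
#'
#' @param sys an `ode_system`.
#' @param laws list of `conservation_law` (default: computed from `sys`).
#' @param eliminate character vector of species to eliminate, one per law
#'   (default: the first species with nonzero coefficient in each law, chosen
#'   so the elimination is solvable). A species with zero coefficient in its
#'   law is an error.
#' @return an object of class `reduced_ode_system`.
#' @export
reduce_by_conservation <- function(sys, laws = NULL, eliminate = NULL) {
  stopifnot(inherits(sys, "ode_system"))
  if (is.null(laws)) laws <- conservation_laws(sys)
  if (!length(laws)) stop("system has no conservation laws to reduce by")
  sp <- sys$state_species
  L <- length(laws)
  W <- t(vapply(laws, function(l) l$coefficients[sp], numeric(length(sp))))
  consts <- vapply(laws, `[[`, 0, "constant")
  if (is.null(eliminate)) {
    eliminate <- character(0)
    for (i in seq_len(L)) {
      cand <- sp[W[i, ] != 0]
      cand <- setdiff(cand, eliminate)
      if (!length(cand)) stop("cannot choose independent species to eliminate")
      eliminate <- c(eliminate, cand[1])
    }
  }
  stopifnot(length(eliminate) == L, all(eliminate %in% sp))
  for (i in seq_len(L))
    if (W[i, match(eliminate[i], sp)] == 0)
      stop("species '", eliminate[i],
           "' has zero coefficient in its conservation law")
  keep <- setdiff(sp, eliminate)
  We <- W[, match(eliminate, sp), drop = FALSE]
  if (abs(det(We)) < 1e-12)
    stop("chosen species give a singular elimination; pick others")
  Wk <- W[, match(keep, sp), drop = FALSE]
  # x_e = We^{-1} (consts - Wk x_k);  x_full = c0 + Lmat %*% x_k
  We_inv <- solve(We)
  c0 <- setNames(numeric(length(sp)), sp)
  c0[eliminate] <- as.vector(We_inv %*% consts)
  Lmat <- matrix(0, length(sp), length(keep), dimnames = list(sp, keep))
  Lmat[keep, keep] <- diag(length(keep))
  Lmat[eliminate, ] <- -We_inv %*% Wk
  lift <- function(xk) {
    xk <- if (!is.null(names(xk))) as.numeric(xk[keep]) else as.numeric(xk)
    setNames(c0 + as.vector(Lmat %*% xk), sp)
  }
  red <- list(state_species = keep, full = sys, laws = laws,
              eliminated = eliminate, lift = lift, lift_matrix = Lmat,
              lift_offset = c0, initial = sys$initial[keep])
  red$rhs <- function(xk) sys$rhs(lift(xk))[keep]
  red$jac <- function(xk) (sys$jac(lift(xk)) %*% Lmat)[keep, , drop = FALSE]
  class(red) <- "reduced_ode_system"
  red
}

#' @export
print.reduced_ode_system <- function(x, ...) {
  cat(sprintf("reduced ODE system: %d variables (%d eliminated by conservation)\n",
              length(x$state_species), length(x$eliminated)))
  cat("  state:", paste(x$state_species, collapse = ", "), "\n")
  cat("  eliminated:", paste(x$eliminated, collapse = ", "), "\n")
  invisible(x)
}

#' Export the stoichiometric matrix and flux monomials as JSON
#'
#' @param sys an `ode_system`.
#' @param path output file.
#' @export
write_odes_json <- function(sys, path) {
  stopifnot(inherits(sys, "ode_system"))
  obj <- list(
    state_species = sys$state_species,
    constant_species = sys$constant_species,
    stoichiometric_matrix = unname(apply(sys$stoich, 1, as.list,
                                         simplify = FALSE)),
    rate_names = colnames(sys$stoich),
    rate_values = unname(as.list(sys$flux_k)),
    reactant_exponents = unname(apply(sys$expo_state, 1, as.list,
                                      simplify = FALSE)),
    equations = ode_equations(sys))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
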