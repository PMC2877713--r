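# Numerical dynamics: trajectory integration, steady-state location and
# classification, and the conserved-gene-total scan exhibiting the
# transcritical concentration threshold.

.sys_rhs <- function(sys) {
  if (inherits(sys, c("ode_system", "reduced_ode_system"))) return(sys$rhs)
  stop("expected an ode_system or reduced_ode_system")
}

#' Integrate a mass-action ODE system
#'
#' Stiff-capable integration with `deSolve` (lsoda by default). The
#' right-hand side clamps small negative excursions at zero, which together
#' with the tight default tolerances keeps trajectories non-negative and the
#' conservation laws constant to high accuracy.
#'
#' @param sys an `ode_system` or `reduced_ode_system`.
#' @param init named numeric initial state (defaults to the system's stored
#'   initial concentrations); must be non-negative.
#' @param times numeric vector of output times, or a single final time
#'   `t_final > 0` (expanded to 201 points from 0).
#' @param method `deSolve` method (default `"lsoda"`).
#' @param rtol,atol integrator tolerances.
#' @param ... passed to [deSolve::ode()].
#' @return matrix with a `time` column and one column per state species.
#' @export
integrate_odes <- function(sys, init = NULL, times, method = "lsoda",
                           rtol = 1e-8, atol = 1e-10, ...) {
  rhs <- .sys_rhs(sys)
  sp <- sys$state_species
  y0 <- sys$initial
  if (!is.null(init)) y0[names(init)] <- init
  if (any(y0 < 0)) stop("initial conditions must be non-negative")
  if (length(times) == 1) {
    stopifnot(times > 0)
    times <- seq(0, times, length.out = 201)
  }
  if (inherits(sys, "ode_system")) {
    out <- .integrate_field_raw(sys, matrix(as.numeric(y0[sp]), ncol = 1),
                                times, matrix(sys$kfac, ncol = 1),
                                method = method, rtol = rtol, atol = atol, ...)
    colnames(out) <- c("time", sp)
  } else {
    f <- function(t, y, parms) list(unname(rhs(setNames(y, sp))))
    out <- deSolve::ode(y = setNames(as.numeric(y0[sp]), sp), times = times,
                        func = f, parms = NULL, method = method,
                        rtol = rtol, atol = atol, ...)
  }
  attr_diag <- attributes(out)$istate
  if (!is.null(attr_diag) && attr_diag[1] < 0)
    warning("integration stopped early at t = ", max(out[, "time"]))
  class(out) <- "matrix"
  out
}

#' Locate and classify the steady states of a system
#'
#' Multistart damped Newton iteration on the (reduced) vector field with the
#' analytic Jacobian. Starting points are the origin, scaled coordinate
#' vertices, and log-uniform random points; steps leaving the non-negative
#' orthant are shortened. Converged roots are deduplicated and classified by
#' the eigenvalues of the Jacobian (`stable` if the leading real part is
#' below `-margin`, `unstable` above `+margin`, otherwise `marginal`).
#'
#' @param sys an `ode_system` or `reduced_ode_system` (typically reduced, so
#'   conservation constraints are built in).
#' @param n_starts number of random multistart points (default 50).
#' @param scale characteristic concentration scale for start generation
#'   (default: max of initial state and 1).
#' @param tol residual infinity-norm tolerance for a root (default 1e-8).
#' @param dedup_tol distance below which two roots are the same point.
#' @param margin stability margin on the leading eigenvalue real part.
#' @param seed RNG seed for the multistart cloud (restored on exit).
#' @return list of `steady_state` objects, each with `coordinates`,
#'   `eigenvalues`, `stability`; empty (with a warning) if no root is found.
#' @export
find_steady_states <- function(sys, n_starts = 50, scale = NULL, tol = 1e-8,
                               dedup_tol = 1e-6, margin = 1e-9, seed = 1L) {
  rhs <- .sys_rhs(sys)
  jac <- sys$jac
  sp <- sys$state_species
  n <- length(sp)
  if (is.null(scale)) scale <- max(c(sys$initial, 1), na.rm = TRUE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  starts <- list(setNames(numeric(n), sp))
  for (i in seq_len(n)) {
    v <- setNames(numeric(n), sp); v[i] <- scale
    starts[[length(starts) + 1]] <- v
  }
  for (k in seq_len(n_starts)) {
    v <- setNames(10^runif(n, log10(scale) - 3, log10(scale) + 1), sp)
    starts[[length(starts) + 1]] <- v
  }

  newton <- function(x) {
    for (it in 1:200) {
      fx <- rhs(x)
      if (max(abs(fx)) < tol) return(x)
      J <- jac(x)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        xn <- x + lam * step
        xn[xn > -1e-12 & xn < 0] <- 0
        if (all(xn >= 0)) {
          fn <- rhs(xn)
          if (max(abs(fn)) < max(abs(fx)) || max(abs(fn)) < tol) break
        }
        lam <- lam / 2
        if (lam < 1e-10) return(NULL)
      }
      x <- xn
    }
    if (max(abs(rhs(x))) < tol) x else NULL
  }

  polish <- function(x) {
    # a few undamped Newton steps: quadratic convergence takes a root that
    # just met `tol` down to machine precision, so duplicates collapse
    for (it in 1:4) {
      fx <- rhs(x)
      step <- tryCatch(solve(jac(x), -fx), error = function(e) NULL)
      if (is.null(step)) break
      xn <- x + step
      xn[xn > -1e-12 & xn < 0] <- 0
      if (any(xn < 0) || max(abs(rhs(xn))) > max(abs(fx))) break
      x <- xn
    }
    x
  }

  roots <- list()
  for (x0 in starts) {
    r <- newton(x0)
    if (is.null(r)) next
    r <- polish(r)
    dup <- any(vapply(roots, function(z)
      max(abs(z - r)) < dedup_tol * max(1, max(abs(r))), TRUE))
    if (!dup) roots[[length(roots) + 1]] <- r
  }
  if (!length(roots)) {
    warning("no steady state found from any start")
    return(list())
  }
  # deterministic order: by first coordinate, then second, ...
  ord <- do.call(order, as.data.frame(do.call(rbind, roots)))
  roots <- roots[ord]
  lapply(roots, function(r) {
    ev <- eigen(jac(r), only.values = TRUE)$values
    lead <- max(Re(ev))
    stab <- if (lead < -margin) "stable" else if (lead > margin) "unstable" else "marginal"
    structure(list(coordinates = r, eigenvalues = ev, stability = stab),
              class = "steady_state")
  })
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state (%s): %s | leading Re(eigenvalue) = %.3g\n",
              x$stability,
              paste(sprintf("%s = %.6g", names(x$coordinates), x$coordinates),
                    collapse = ", "),
              max(Re(x$eigenvalues))))
  invisible(x)
}

# leading eigenvalue of the Jacobian at the trivial (protein-zero) branch,
# found by Newton from the origin
.trivial_leading_eig <- function(sys, tol = 1e-12) {
  n <- length(sys$state_species)
  x <- setNames(numeric(n), sys$state_species)
  fx <- sys$rhs(x)
  if (max(abs(fx)) > 1e-10) {
    # damped Newton towards the branch near the origin
    for (it in 1:100) {
      J <- sys$jac(x)
      x <- x - as.vector(solve(J, fx))
      x[abs(x) < 1e-15] <- 0
      fx <- sys$rhs(x)
      if (max(abs(fx)) < tol) break
    }
  }
  max(Re(eigen(sys$jac(x), only.values = TRUE)$values))
}

#' Scan a conserved gene total for the transcritical threshold
#'
#' Sweeps the conservation-law constant `C` (total gene/operon concentration)
#' over a grid; at each value the steady states of the reduced system are
#' located and classified. The critical total `C*` is then refined by
#' bisection on the sign change of the leading eigenvalue of the trivial
#' (protein-zero) branch, to relative tolerance `tol`. Below `C*` the trivial
#' branch is stable (the protein stays at zero); above it the positive branch
#' is stable — the mechanistic concentration threshold.
#'
#' @param builder function `C -> reduced_ode_system` building the reduced
#'   model at gene total `C`.
#' @param range length-2 positive numeric, the scanned interval of `C`.
#' @param n_grid number of grid points (>= 3).
#' @param protein name of the protein coordinate in the reduced state.
#' @param tol relative bisection tolerance for `C*`.
#' @param ... passed to [find_steady_states()].
#' @return object of class `bifurcation_scan`: `grid`, `states` (list of
#'   steady-state lists per grid value), `protein`, and `C_star` (`NA` if no
#'   stability exchange occurs in the range).
#' @export
threshold_scan <- function(builder, range, n_grid = 25, protein, tol = 1e-6,
                           ...) {
  stopifnot(length(range) == 2, all(range > 0), n_grid >= 3)
  grid <- seq(range[1], range[2], length.out = n_grid)
  states <- lapply(grid, function(C) find_steady_states(builder(C), ...))
  g <- function(C) .trivial_leading_eig(builder(C))
  gs <- vapply(grid, g, 0)
  C_star <- NA_real_
  idx <- which(gs[-1] * gs[-n_grid] < 0)
  if (length(idx)) {
    lo <- grid[idx[1]]; hi <- grid[idx[1] + 1]
    glo <- gs[idx[1]]
    while ((hi - lo) > tol * max(abs(hi), 1)) {
      mid <- (lo + hi) / 2
      gm <- g(mid)
      if (gm == 0) { lo <- hi <- mid; break }
      if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    C_star <- (lo + hi) / 2
  }
  structure(list(parameter = "gene total C", grid = grid, states = states,
                 protein = protein, C_star = C_star, leading_eigs = gs),
            class = "bifurcation_scan")
}

#' @export
print.bifurcation_scan <- function(x, ...) {
  cat(sprintf("bifurcation scan over %s in [%g, %g] (%d points)\n",
              x$parameter, min(x$grid), max(x$grid), length(x$grid)))
  if (is.na(x$C_star)) cat("  no stability exchange located in range\n")
  else cat(sprintf("  transcritical threshold C* = %.8g\n", x$C_star))
  invisible(x)
}

#' Stable protein level on each branch of a scan
#'
#' Convenience extractor: for every grid value returns the protein coordinate
#' of the stable steady state (the biologically realized level).
#'
#' @param scan a `bifurcation_scan`.
#' @return data frame with columns `C` and `protein`.
#' @export
scan_stable_protein <- function(scan) {
  p <- vapply(scan$states, function(ss) {
    st <- Filter(function(s) s$stability == "stable", ss)
    if (!length(st)) return(NA_real_)
    max(vapply(st, function(s) s$coordinates[[scan$protein]], 0))
  }, 0)
  data.frame(C = scan$grid, protein = p)
}

#' The self-activating gene model
#'
#' Builds the simplest autoregulatory network — a single gene whose protein
#' activates its own transcription — compiles it under per-site semantics,
#' and reduces it by the operon-total conservation law. The reduced
#' two-variable system (bound operon state, free protein) undergoes a
#' transcritical bifurcation at the critical gene total
#' `C* = ku * kd / (kb * kp)`.
#'
#' @param kb,ku binding/unbinding rates of the protein at its own operon.
#' @param kp production rate from the bound state.
#' @param kd protein degradation rate.
#' @param total total gene (operon) concentration `C`.
#' @param reduce return the reduced system (default) or the full 3-variable
#'   one.
#' @return a `reduced_ode_system` (or `ode_system` if `reduce = FALSE`) with
#'   attribute `"protein" = "A"`.
#' @export
self_activation_system <- function(kb = 1, ku = 1, kp = 1, kd = 0.1,
                                   total = 1, reduce = TRUE) {
  g <- double_graph(activations = list(c("A", "A")))
  net <- compile_reactions(g, "per_site",
                           rate_defaults = list(kb_A_A = kb, ku_A_A = ku,
                                                kp_A_a1 = kp, kd_A = kd),
                           gene_totals = c(A = total))
  sys <- build_odes(net)
  if (reduce) sys <- reduce_by_conservation(sys, eliminate = "A_a0")
  attr(sys, "protein") <- "A"
  sys
}
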