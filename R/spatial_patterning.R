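# Spatial patterning along a scaled 1D axis: every position carries an
# independent copy of the compiled kinetics (no diffusion, no advection);
# spatial structure enters only through position-dependent, time-constant
# regulator profiles and per-position initial conditions.

#' Sampled spatial concentration profile
#'
#' A profile samples a non-negative concentration on strictly increasing
#' positions in `[0, 1]` (embryo length scaled to the unit interval), with
#' optional per-point standard deviations.
#'
#' @param positions strictly increasing numeric in `[0, 1]`.
#' @param values non-negative concentrations, same length.
#' @param sd optional positive standard deviations, same length.
#' @return object of class `spatial_profile`.
#' @export
spatial_profile <- function(positions, values, sd = NULL) {
  positions <- as.numeric(positions); values <- as.numeric(values)
  if (length(positions) != length(values))
    stop("positions and values must have the same length")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(positions < 0) || any(positions > 1))
    stop("positions must lie in [0, 1] (scaled embryo length)")
  if (any(values < 0)) stop("profile values must be non-negative")
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    stopifnot(length(sd) == length(values))
    if (any(sd < 0)) stop("profile sd must be non-negative")
  }
  structure(list(positions = positions, values = values, sd = sd),
            class = "spatial_profile")
}

#' Bundle of profiles on a shared position grid
#'
#' @param positions shared grid.
#' @param ... named numeric vectors or `spatial_profile`s (positions must
#'   match the shared grid).
#' @param sd optional named list of sd vectors.
#' @return object of class `spatial_field`: `positions`, `values` (named list
#'   of numeric vectors), `sd` (named list or empty).
#' @export
spatial_field <- function(positions, ..., sd = list()) {
  profs <- list(...)
  if (length(profs) == 1 && is.null(names(profs)) && is.list(profs[[1]]) &&
      !inherits(profs[[1]], "spatial_profile"))
    profs <- profs[[1]]
  values <- list(); sds <- sd
  for (nm in names(profs)) {
    p <- profs[[nm]]
    if (inherits(p, "spatial_profile")) {
      if (length(p$positions) != length(positions) ||
          max(abs(p$positions - positions)) > 1e-12)
        stop("profile '", nm, "' is not on the shared grid")
      values[[nm]] <- p$values
      if (!is.null(p$sd)) sds[[nm]] <- p$sd
    } else {
      stopifnot(length(p) == length(positions))
      values[[nm]] <- as.numeric(p)
    }
  }
  structure(list(positions = as.numeric(positions), values = values, sd = sds),
            class = "spatial_field")
}

#' @export
print.spatial_field <- function(x, ...) {
  cat(sprintf("spatial field: %d positions in [%g, %g], species: %s\n",
              length(x$positions), min(x$positions), max(x$positions),
              paste(names(x$values), collapse = ", ")))
  invisible(x)
}

#' Extract one species from a field as a profile
#' @param field a `spatial_field`.
#' @param species species name.
#' @return a `spatial_profile`.
#' @export
field_profile <- function(field, species) {
  stopifnot(species %in% names(field$values))
  spatial_profile(field$positions, pmax(field$values[[species]], 0),
                  sd = field$sd[[species]])
}

# per-position rate factors: k_j * prod(const^gamma) with constants taken
# from the input field
.kfac_matrix <- function(sys, inputs) {
  cs <- sys$constant_species
  P <- length(inputs$positions)
  missing <- setdiff(cs, names(inputs$values))
  if (length(missing))
    stop("missing input profile for constant species: ",
         paste(missing, collapse = ", "))
  kf <- matrix(sys$flux_k, nrow = ncol(sys$stoich), ncol = P)
  for (m in seq_along(cs)) {
    g <- sys$expo_const[m, ]
    nz <- which(g != 0)
    if (!length(nz)) next
    vals <- inputs$values[[cs[m]]]
    for (j in nz) kf[j, ] <- kf[j, ] * vals^g[j]
  }
  kf
}

#' Simulate a network over a spatial axis
#'
#' Integrates the compiled kinetics independently at every position of the
#' shared grid: constant regulators take their profile value at that
#' position, and there is no coupling or transport between positions. The
#' stacked system is integrated in one call (banded Jacobian, block size =
#' number of state species), which is exactly equivalent to position-by-
#' position integration.
#'
#' @param network a `reaction_network` (or a prebuilt `ode_system`).
#' @param inputs `spatial_field` providing a profile for every constant
#'   species.
#' @param t_final final time (or vector of output times; the last is
#'   reported).
#' @param initial optional `spatial_field` of per-position initial values for
#'   state species (species not given start from the network's defaults,
#'   e.g. gene totals in the free operon state).
#' @param gene_totals optional named numeric of spatially uniform gene totals
#'   (overrides the free-state initial value per gene).
#' @param rtol,atol integrator tolerances.
#' @param method `deSolve` method.
#' @return `spatial_field` with one profile per state species at the final
#'   time.
#' @export
simulate_field <- function(network, inputs, t_final, initial = NULL,
                           gene_totals = NULL, rtol = 1e-8, atol = 1e-10,
                           method = "lsoda") {
  sys <- if (inherits(network, "ode_system")) network
         else build_odes(network, constant_values = setNames(
           rep(1, length(network$constant_species)), network$constant_species))
  sp <- sys$state_species
  S <- length(sp); P <- length(inputs$positions)
  kf <- .kfac_matrix(sys, inputs)

  y0 <- matrix(sys$initial, nrow = S, ncol = P, dimnames = list(sp, NULL))
  if (!is.null(gene_totals)) {
    net <- sys$network
    for (g in names(gene_totals)) {
      free <- net$genes[[g]]$states$name[1]
      y0[free, ] <- gene_totals[[g]]
    }
  }
  if (!is.null(initial)) {
    if (max(abs(initial$positions - inputs$positions)) > 1e-12)
      stop("initial field is not on the input grid")
    for (nm in names(initial$values)) {
      if (!nm %in% sp) stop("initial profile for non-state species: ", nm)
      y0[nm, ] <- initial$values[[nm]]
    }
  }
  if (any(y0 < 0)) stop("initial conditions must be non-negative")

  times <- if (length(t_final) == 1) c(0, t_final) else t_final
  out <- .integrate_field_raw(sys, y0, times, kf, method = method,
                              rtol = rtol, atol = atol)
  yT <- matrix(out[nrow(out), -1], nrow = S, dimnames = list(sp, NULL))
  vals <- lapply(sp, function(s) pmax(as.numeric(yT[s, ]), 0))
  names(vals) <- sp
  spatial_field(inputs$positions, vals)
}

#' Closed-form steady state of an affine (competitive-site) spatial model
#'
#' When every regulator is a constant input the compiled kinetics are affine
#' in the state variables (each flux involves at most one state species
#' linearly). Per position, the steady state is then the unique solution of a
#' linear system: the conservation constraints (gene totals) are substituted
#' first, and the reduced affine system `J x + b = 0` is solved exactly. A
#' state-variable product in any flux raises a not-applicable error.
#'
#' @param network a `reaction_network` whose regulators are all constant.
#' @param inputs `spatial_field` of regulator profiles.
#' @param gene_totals optional named numeric (default: free-state initials).
#' @return `spatial_field` of steady-state profiles for all state species.
#' @export
linear_steady_state <- function(network, inputs, gene_totals = NULL) {
  sys <- build_odes(network, constant_values = setNames(
    rep(1, length(network$constant_species)), network$constant_species))
  # linearity check: no flux may involve two (or a squared) state species
  if (any(colSums(sys$expo_state) > 1))
    stop("system is nonlinear in its state variables; ",
         "linear_steady_state is not applicable")
  sp <- sys$state_species
  P <- length(inputs$positions)
  kf <- .kfac_matrix(sys, inputs)
  laws <- conservation_laws(sys)
  x0 <- sys$initial
  if (!is.null(gene_totals)) {
    for (g in names(gene_totals)) {
      free <- network$genes[[g]]$states$name[1]
      x0[free] <- gene_totals[[g]]
    }
  }
  out <- matrix(0, length(sp), P, dimnames = list(sp, NULL))
  for (p in seq_len(P)) {
    sysp <- sys
    sysp$kfac <- kf[, p]
    sysp$rhs <- function(x) {
      dx <- ma_rhs_field(matrix(as.numeric(x[sp]), ncol = 1),
                         sys$term_r, sys$term_s, sys$term_p,
                         matrix(kf[, p], ncol = 1),
                         sys$g_i, sys$g_j, sys$g_v)
      setNames(as.vector(dx), sp)
    }
    sysp$jac <- function(x) ma_jacobian(sysp, x)
    if (length(laws)) {
      lws <- lapply(laws, function(l) {
        l$constant <- sum(l$coefficients * x0)
        l
      })
      red <- reduce_by_conservation(sysp, laws = lws)
      A <- red$jac(setNames(numeric(length(red$state_species)),
                            red$state_species))
      b <- red$rhs(setNames(numeric(length(red$state_species)),
                            red$state_species))
      xr <- solve(A, -b)
      out[, p] <- red$lift(setNames(xr, red$state_species))
    } else {
      A <- sysp$jac(setNames(numeric(length(sp)), sp))
      b <- sysp$rhs(setNames(numeric(length(sp)), sp))
      out[, p] <- solve(A, -b)
    }
  }
  vals <- lapply(sp, function(s) pmax(as.numeric(out[s, ]), 0))
  names(vals) <- sp
  spatial_field(inputs$positions, vals)
}

#' Count interior local maxima of a sampled profile
#'
#' Runs of equal values (within `tol` relative to the profile range) are
#' merged, so symmetric plateaus count as one peak; maxima touching the
#' domain boundary are not interior and are excluded.
#'
#' @param values numeric vector of sampled values.
#' @param tol relative tolerance for treating adjacent samples as equal.
#' @return integer count of interior local maxima.
#' @export
interior_maxima <- function(values, tol = 1e-9) {
  v <- as.numeric(values)
  if (length(v) < 3) return(0L)
  scale <- max(abs(v), 1e-300)
  r <- rle(round(v / (scale * tol)))
  m <- r$values * (scale * tol)
  n <- length(m)
  if (n < 3) return(0L)
  sum(m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] > m[3:n])
}

#' Read/write spatial profiles as CSV
#'
#' Profile CSVs have columns `position,value[,sd]`; field CSVs are wide, with
#' a `position` column, one column per species, and optional `<species>_sd`
#' columns.
#'
#' @param profile a `spatial_profile`.
#' @param path file path.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(position = profile$positions, value = profile$values)
  if (!is.null(profile$sd)) df$sd <- profile$sd
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path)
  spatial_profile(df$position, df$value, sd = df$sd)
}

#' @rdname write_profile_csv
#' @param field a `spatial_field`.
#' @export
write_field_csv <- function(field, path) {
  df <- data.frame(position = field$positions)
  for (nm in names(field$values)) df[[nm]] <- field$values[[nm]]
  for (nm in names(field$sd)) df[[paste0(nm, "_sd")]] <- field$sd[[nm]]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_field_csv <- function(path) {
  df <- read.csv(path)
  cols <- setdiff(names(df), "position")
  sdcols <- grep("_sd$", cols, value = TRUE)
  vcols <- setdiff(cols, sdcols)
  vals <- lapply(vcols, function(c) df[[c]])
  names(vals) <- vcols
  sds <- lapply(sdcols, function(c) df[[c]])
  names(sds) <- sub("_sd$", "", sdcols)
  spatial_field(df$position, vals, sd = sds)
}
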