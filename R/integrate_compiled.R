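# Compiled-model integration path: the mass-action structure is packed into
# the deSolve parms vector and evaluated by the C routine operonet_derivs,
# avoiding any R callback during time stepping. Used for single systems and
# for stacked per-position spatial fields alike.

.OPERONET_MAXPAR <- 40000L

.pack_field_parms <- function(sys, kfac_mat) {
  S <- length(sys$state_species)
  P <- ncol(kfac_mat)
  R <- nrow(kfac_mat)
  nt <- length(sys$term_r)
  ng <- length(sys$g_i)
  head <- c(S, P, R, nt, ng)
  terms <- as.vector(rbind(sys$term_r, sys$term_s, sys$term_p))
  gam <- as.vector(rbind(sys$g_i, sys$g_j, sys$g_v))
  body <- c(head, terms, gam, as.vector(kfac_mat))
  if (length(body) > .OPERONET_MAXPAR) return(NULL)   # caller falls back
  c(body, numeric(.OPERONET_MAXPAR - length(body)))
}

# integrate a stacked field (y0 is an S x P matrix, kfac_mat R x P);
# returns the deSolve output matrix
.integrate_field_raw <- function(sys, y0mat, times, kfac_mat,
                                 method = "lsoda", rtol = 1e-8, atol = 1e-10,
                                 ...) {
  S <- nrow(y0mat)
  parms <- .pack_field_parms(sys, kfac_mat)
  if (!is.null(parms)) {
    deSolve::ode(y = as.vector(y0mat), times = times,
                 func = "operonet_derivs", dllname = "operonet",
                 initfunc = "operonet_initmod", parms = parms,
                 method = method, rtol = rtol, atol = atol,
                 jactype = "bandint", bandup = S - 1L, banddown = S - 1L, ...)
  } else {
    f <- function(t, y, p) list(as.vector(sys$rhs_field(matrix(y, nrow = S),
                                                        kfac_mat)))
    deSolve::ode(y = as.vector(y0mat), times = times, func = f, parms = NULL,
                 method = method, rtol = rtol, atol = atol,
                 jactype = "bandint", bandup = S - 1L, banddown = S - 1L, ...)
  }
}
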