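# Exact rational linear algebra for small integer matrices.
#
# Stoichiometric matrices have small integer entries (|v| <= 2 here), so exact
# arithmetic with numerator/denominator pairs held in doubles is safe: every
# intermediate is a ratio of small determinants, and fractions are reduced at
# each step. Used to compute left null spaces (conservation laws) bit-stably.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.gcd_vec <- function(v) Reduce(.gcd2, abs(v), accumulate = FALSE)

.lcm2 <- function(a, b) if (a == 0 || b == 0) 0 else abs(a / .gcd2(a, b) * b)

# Reduced-row-echelon form of an integer matrix in exact rational arithmetic.
# Returns list(num, den, pivots): num/den give the RREF entrywise.
rational_rref <- function(M) {
  M <- as.matrix(M)
  storage.mode(M) <- "double"
  stopifnot(all(M == round(M)))
  n <- nrow(M); m <- ncol(M)
  num <- M
  den <- matrix(1, n, m)
  reduce <- function(i, j) {
    if (num[i, j] == 0) { den[i, j] <<- 1; return(invisible()) }
    g <- .gcd2(num[i, j], den[i, j])
    num[i, j] <<- num[i, j] / g
    den[i, j] <<- den[i, j] / g
    if (den[i, j] < 0) { num[i, j] <<- -num[i, j]; den[i, j] <<- -den[i, j] }
    invisible()
  }
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(m)) {
    if (row > n) break
    pr <- which(num[row:n, col] != 0)
    if (length(pr) == 0) next
    pr <- pr[1] + row - 1L
    if (pr != row) {
      tmp <- num[row, ]; num[row, ] <- num[pr, ]; num[pr, ] <- tmp
      tmp <- den[row, ]; den[row, ] <- den[pr, ]; den[pr, ] <- tmp
    }
    # scale pivot row to 1
    pn <- num[row, col]; pd <- den[row, col]
    for (j in seq_len(m)) {
      num[row, j] <- num[row, j] * pd
      den[row, j] <- den[row, j] * pn
      reduce(row, j)
    }
    # clear other rows
    for (i in seq_len(n)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      for (j in seq_len(m)) {
        # entry(i,j) <- entry(i,j) - (fn/fd) * entry(row,j)
        a <- num[i, j] * fd * den[row, j] - fn * num[row, j] * den[i, j]
        b <- den[i, j] * fd * den[row, j]
        num[i, j] <- a; den[i, j] <- b
        reduce(i, j)
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots)
}

#' Exact integer kernel of an integer matrix
#'
#' Computes a canonical basis of \{x : A x = 0\} for an integer matrix `A` in
#' exact rational arithmetic, returning integer basis vectors with content 1
#' and positive first nonzero entry, ordered by free column. The left null
#' space of a stoichiometric matrix `G` is `integer_kernel(t(G))`.
#'
#' @param A integer matrix.
#' @return integer matrix whose columns are the basis vectors (0 columns if
#'   the kernel is trivial).
#' @export
integer_kernel <- function(A) {
  A <- as.matrix(A)
  m <- ncol(A)
  if (nrow(A) == 0) {
    # every vector is in the kernel: identity basis
    return(diag(1, m))
  }
  rr <- rational_rref(A)
  piv <- rr$pivots
  free <- setdiff(seq_len(m), piv)
  basis <- matrix(0, nrow = m, ncol = length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    # rational solution: x[f] = 1, x[piv[i]] = -R[i, f]
    numv <- numeric(m); denv <- rep(1, m)
    numv[f] <- 1
    if (length(piv)) {
      numv[piv] <- -rr$num[seq_along(piv), f]
      denv[piv] <- rr$den[seq_along(piv), f]
    }
    l <- Reduce(.lcm2, denv)
    v <- numv * (l / denv)
    g <- .gcd_vec(v[v != 0])
    if (length(g) && g > 0) v <- v / g
    fz <- v[v != 0][1]
    if (!is.na(fz) && fz < 0) v <- -v
    basis[, k] <- v
  }
  basis
}

# rank of an integer matrix, exact
integer_rank <- function(A) length(rational_rref(A)$pivots)
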