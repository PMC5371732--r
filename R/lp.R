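#' Solve a bounded linear program over steady-state constraints
#'
#' Minimizes (or maximizes) a linear objective subject to equality constraints
#' \code{A v = b} and finite box bounds \code{lb <= v <= ub}. This is the LP
#' core used by every flux-balance computation in the package. It is a dense
#' two-phase primal simplex: upper bounds are handled through explicit slack
#' rows, phase I uses artificial variables on the equality rows, and the
#' pivoting rule is Dantzig with an automatic switch to Bland's rule after a
#' run of degenerate pivots, which guarantees termination.
#'
#' Status is always reported explicitly; infeasible or unbounded problems
#' never come back as silent zero vectors.
#'
#' @param obj numeric objective coefficients, one per variable.
#' @param A dense or sparse equality constraint matrix (rows = constraints).
#' @param b right-hand side of the equality constraints.
#' @param lb,ub finite lower/upper bounds per variable.
#' @param maximize if \code{TRUE}, maximize \code{obj} instead of minimizing.
#' @param tol numerical tolerance for pivoting and feasibility tests.
#' @param maxit maximum number of simplex pivots across both phases.
#' @return list with elements \code{status} (\code{"optimal"},
#'   \code{"infeasible"} or \code{"unbounded"}), \code{x} (solution vector, or
#'   \code{NULL} when not optimal) and \code{objval}.
#' @export
solve_lp <- function(obj, A, b = NULL, lb, ub, maximize = FALSE,
                     tol = 1e-9, maxit = 20000L) {
  A <- as.matrix(A)
  n <- ncol(A)
  m1 <- nrow(A)
  if (is.null(b)) b <- rep(0, m1)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n, length(b) == m1)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp() requires finite bounds; apply a finite default bound first")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))

  cost <- if (maximize) -obj else obj

  ## shift to x = v - lb >= 0; drop variables fixed by lb == ub
  u <- ub - lb
  free <- which(u > tol)
  nf <- length(free)
  b1 <- b - A %*% lb
  Af <- A[, free, drop = FALSE]
  cf <- cost[free]
  ubrow <- which(u[free] < 1e30)              # finite shifted upper bounds

  m2 <- length(ubrow)
  m <- m1 + m2
  ncols <- nf + m2 + m1                        # vars, ub slacks, artificials
  Tm <- matrix(0, m, ncols + 1L)
  Tm[seq_len(m1), seq_len(nf)] <- Af
  Tm[seq_len(m1), ncols + 1L] <- as.numeric(b1)
  if (m2 > 0L) {
    for (k in seq_len(m2)) {
      i <- m1 + k
      Tm[i, ubrow[k]] <- 1
      Tm[i, nf + k] <- 1
      Tm[i, ncols + 1L] <- u[free[ubrow[k]]]
    }
  }
  ## make rhs of equality rows nonnegative (artificials need b >= 0)
  negr <- which(Tm[seq_len(m1), ncols + 1L] < 0)
  if (length(negr)) Tm[negr, ] <- -Tm[negr, , drop = FALSE]
  art <- nf + m2 + seq_len(m1)
  for (i in seq_len(m1)) Tm[i, art[i]] <- 1

  ## basis[i] is the basic column of row i
  basis <- integer(m)
  basis[seq_len(m1)] <- art
  if (m2 > 0L) basis[m1 + seq_len(m2)] <- nf + seq_len(m2)

  ## phase I objective row: minimize sum of artificials
  zrow <- numeric(ncols + 1L)
  zrow[art] <- 1
  for (i in seq_len(m1)) zrow <- zrow - Tm[i, ]   # reduce by artificial-basic rows

  piv <- .simplex_iterate(Tm, zrow, basis, forbid = integer(0), tol = tol,
                          maxit = maxit)
  Tm <- piv$Tm; zrow <- piv$zrow; basis <- piv$basis
  if (piv$status == "maxit")
    stop("solve_lp(): iteration limit reached in phase I")
  if (-zrow[ncols + 1L] > 1e-7)
    return(list(status = "infeasible", x = NULL, objval = NA_real_))

  ## drive any residual artificials out of the basis
  for (i in which(basis %in% art)) {
    cand <- which(abs(Tm[i, seq_len(nf + m2)]) > tol)
    if (length(cand)) {
      Tm_z <- .pivot(Tm, zrow, basis, i, cand[1L])
      Tm <- Tm_z$Tm; zrow <- Tm_z$zrow; basis <- Tm_z$basis
    }
    ## else: redundant row, harmless — artificial stays basic at zero
  }

  ## phase II objective row
  zrow <- numeric(ncols + 1L)
  zrow[seq_len(nf)] <- cf
  for (i in seq_len(m)) {
    bj <- basis[i]
    if (bj <= nf && cf[bj] != 0) zrow <- zrow - cf[bj] * Tm[i, ]
  }
  zrow[art] <- Inf                              # artificials may never re-enter

  piv <- .simplex_iterate(Tm, zrow, basis, forbid = art, tol = tol,
                          maxit = maxit)
  Tm <- piv$Tm; zrow <- piv$zrow; basis <- piv$basis
  if (piv$status == "maxit")
    stop("solve_lp(): iteration limit reached in phase II")
  if (piv$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objval = NA_real_))

  xf <- numeric(nf)
  inb <- which(basis <= nf)
  xf[basis[inb]] <- Tm[inb, ncols + 1L]
  x <- lb
  x[free] <- x[free] + xf
  objval <- sum(obj * x)
  list(status = "optimal", x = as.numeric(x), objval = objval)
}

## One simplex phase: pivot until optimal/unbounded/maxit.
## Dantzig rule, switching to Bland's rule after 50 consecutive degenerate
## pivots (anti-cycling). `forbid` columns are never entered.
.simplex_iterate <- function(Tm, zrow, basis, forbid, tol, maxit) {
  m <- nrow(Tm); ncols <- ncol(Tm) - 1L
  rhs_col <- ncols + 1L
  degen <- 0L
  allowed <- setdiff(seq_len(ncols), forbid)
  for (it in seq_len(maxit)) {
    zr <- zrow[allowed]
    neg <- which(zr < -tol)
    if (!length(neg)) {
      return(list(status = "optimal", Tm = Tm, zrow = zrow, basis = basis))
    }
    if (degen > 50L) {
      jcol <- allowed[neg[1L]]                  # Bland: smallest index
    } else {
      jcol <- allowed[neg[which.min(zr[neg])]]  # Dantzig
    }
    col <- Tm[, jcol]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", Tm = Tm, zrow = zrow, basis = basis))
    }
    ratios <- Tm[pos, rhs_col] / col[pos]
    rmin <- min(ratios)
    tie <- pos[ratios <= rmin + tol]
    irow <- tie[which.min(basis[tie])]          # Bland-style tie break
    degen <- if (rmin < tol) degen + 1L else 0L
    st <- .pivot(Tm, zrow, basis, irow, jcol)
    Tm <- st$Tm; zrow <- st$zrow; basis <- st$basis
  }
  list(status = "maxit", Tm = Tm, zrow = zrow, basis = basis)
}

.pivot <- function(Tm, zrow, basis, irow, jcol) {
  prow <- Tm[irow, ] / Tm[irow, jcol]
  Tm <- Tm - outer(Tm[, jcol], prow)
  Tm[irow, ] <- prow
  fin <- is.finite(zrow)
  zrow[fin] <- zrow[fin] - zrow[jcol] * prow[fin]
  basis[irow] <- jcol
  list(Tm = Tm, zrow = zrow, basis = basis)
}

#' Enumerate the vertices of a steady-state flux polytope
#'
#' Brute-force vertex enumeration for tiny networks: every subset of
#' \code{n - rank(A)} variables is fixed at a lower or upper bound, the
#' equality system is solved for the rest, and points violating bounds are
#' discarded. Intended as an independent optimality oracle for networks with
#' at most ~8 reactions; cost grows combinatorially.
#'
#' @inheritParams solve_lp
#' @param tol feasibility tolerance for accepting a candidate vertex.
#' @return matrix with one vertex per row (possibly zero rows when the
#'   polytope is empty).
#' @export
enumerate_vertices <- function(A, b = NULL, lb, ub, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (is.null(b)) b <- rep(0, nrow(A))
  qa <- qr(A)
  r <- qa$rank
  k <- n - r                                   # degrees of freedom
  if (k < 0) k <- 0
  verts <- list()
  combos <- utils::combn(n, k, simplify = FALSE)
  if (k == 0) combos <- list(integer(0))
  for (fix in combos) {
    freev <- setdiff(seq_len(n), fix)
    Af <- A[, freev, drop = FALSE]
    if (qr(Af)$rank < length(freev)) next
    grids <- if (length(fix)) {
      expand.grid(lapply(fix, function(j) unique(c(lb[j], ub[j]))))
    } else data.frame(row.names = 1)
    for (g in seq_len(nrow(grids))) {
      x <- numeric(n)
      if (length(fix)) x[fix] <- as.numeric(grids[g, ])
      rhs <- b - if (length(fix)) A[, fix, drop = FALSE] %*% x[fix] else 0
      sol <- tryCatch(qr.solve(Af, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      x[freev] <- sol
      if (max(abs(A %*% x - b)) > 1e-6) next
      if (all(x >= lb - tol) && all(x <= ub + tol)) {
        verts[[length(verts) + 1L]] <- pmin(pmax(x, lb), ub)
      }
    }
  }
  if (!length(verts)) return(matrix(numeric(0), 0, n))
  V <- do.call(rbind, verts)
  unique(round(V, 9))
}
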