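#' Apply personalized exchange bounds to a network
#'
#' Overwrites the bounds of the boundary reactions matched by metabolite name
#' and direction; interior reaction bounds are untouched. A bound entry whose
#' (metabolite, direction) pair has no boundary reaction in the network is an
#' error, never a silent skip. Applying the same bounds twice is idempotent.
#'
#' @param network a \code{metabolic_network}.
#' @param bounds an \code{exchange_bounds} table.
#' @return the network with updated boundary bounds.
#' @export
apply_bounds <- function(network, bounds) {
  if (nrow(bounds) == 0) return(network)
  key_net <- paste(network$reactions$bnd_metabolite,
                   network$reactions$bnd_direction)
  for (i in seq_len(nrow(bounds))) {
    j <- which(key_net == paste(bounds$metabolite[i], bounds$direction[i]))
    if (length(j) != 1)
      stop("no boundary reaction for metabolite '", bounds$metabolite[i],
           "' (", bounds$direction[i], ")")
    network$reactions$lower[j] <- bounds$lower[i]
    network$reactions$upper[j] <- bounds$upper[i]
  }
  network
}

## network -> LP ingredients
.lp_form <- function(network) {
  list(A = as.matrix(network$S),
       lb = network$reactions$lower,
       ub = network$reactions$upper)
}

.flux_solution <- function(status, fluxes, objective, tol = 1e-9) {
  structure(list(status = status, fluxes = fluxes, objective = objective,
                 feas_tol = tol, opt_tol = 1e-6),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status,
      if (x$status == "optimal") paste0("(objective ",
                                        format(x$objective, digits = 6), ")"),
      "\n")
  invisible(x)
}

#' Maximize a reaction flux (flux balance analysis)
#'
#' Solves \code{max v[objective]} subject to \code{S v = 0} and the current
#' reaction bounds. Infeasibility or unboundedness is surfaced in the
#' \code{status} field, never as silent zeros.
#'
#' @param network a \code{metabolic_network} with bounds applied.
#' @param objective_id reaction id; defaults to the network objective.
#' @return a \code{flux_solution}.
#' @export
maximize_objective <- function(network, objective_id = network$objective) {
  j <- match(objective_id, network$reactions$id)
  if (is.na(j)) stop("objective reaction '", objective_id, "' not in network")
  lu <- .lp_form(network)
  obj <- rep(0, ncol(lu$A)); obj[j] <- 1
  res <- solve_lp(obj, lu$A, lb = lu$lb, ub = lu$ub, maximize = TRUE)
  fl <- if (res$status == "optimal")
    stats::setNames(res$x, network$reactions$id) else NULL
  .flux_solution(res$status, fl,
                 if (res$status == "optimal") res$objval else NA_real_)
}

#' Minimize the total flux at fixed exchange constraints
#'
#' Parsimonious solve: minimizes the flux sum \code{sum(|v_i|)} subject to
#' \code{S v = 0}, the current bounds, and any additional pinned reaction
#' fluxes, under the assumption that cells reduce pathway usage to the
#' minimum required. Reversible reactions are split into nonnegative forward
#' and backward parts internally and recombined in the reported fluxes.
#'
#' @param network a \code{metabolic_network} with bounds applied.
#' @param fixed_constraints optional named numeric vector of reaction fluxes
#'   to pin (lower = upper = value), e.g. the measured VLDL secretion.
#' @return a \code{flux_solution}; \code{objective} is the minimal flux sum.
#' @export
minimize_flux_sum <- function(network, fixed_constraints = NULL) {
  lu <- .lp_form(network)
  n <- ncol(lu$A)
  if (!is.null(fixed_constraints)) {
    j <- match(names(fixed_constraints), network$reactions$id)
    if (anyNA(j))
      stop("fixed constraint references unknown reaction(s): ",
           paste(names(fixed_constraints)[is.na(j)], collapse = ", "))
    lu$lb[j] <- lu$ub[j] <- as.numeric(fixed_constraints)
  }
  twoside <- which(lu$lb < 0)
  A <- cbind(lu$A, -lu$A[, twoside, drop = FALSE])
  lb <- c(pmax(lu$lb, 0), rep(0, length(twoside)))
  ub <- c(pmax(lu$ub, 0), pmax(-lu$lb[twoside], 0))
  obj <- rep(1, ncol(A))
  res <- solve_lp(obj, A, lb = lb, ub = ub)
  if (res$status != "optimal") {
    sol <- .flux_solution(res$status, NULL, NA_real_)
    sol$pinned <- names(fixed_constraints)
    return(sol)
  }
  v <- res$x[seq_len(n)]
  v[twoside] <- v[twoside] - res$x[n + seq_along(twoside)]
  .flux_solution("optimal", stats::setNames(v, network$reactions$id),
                 res$objval)
}

#' Sample steady-state flux distributions (hit-and-run)
#'
#' Coordinate-free hit-and-run sampling over the steady-state polytope
#' \code{\{v : S v = 0, lb <= v <= ub\}}: starting from a parsimonious
#' solution, random directions are drawn in the null space of \code{S}
#' restricted to non-fixed reactions, the feasible segment is computed from
#' the bounds, and a uniform step is taken. The region must be bounded
#' (finite bounds); unbounded directions are rejected with an error. Samples
#' are recorded after a warm-up and with thinning; the chain is re-projected
#' onto the null space periodically to suppress numerical drift.
#'
#' @param network a \code{metabolic_network} with bounds applied (the
#'   personalized constraints, e.g. pinned VLDL secretion, live in the
#'   bounds).
#' @param n number of samples to return.
#' @param seed RNG seed; same seed, same sample matrix.
#' @param burnin warm-up steps discarded before recording.
#' @param thin chain steps per recorded sample.
#' @return object of class \code{flux_sample_set}: list with \code{samples}
#'   (n x reactions matrix), \code{seed}, \code{burnin}, \code{thin}.
#' @export
sample_fluxes <- function(network, n = 100, seed = 1, burnin = 100, thin = 5) {
  lu <- .lp_form(network)
  if (any(!is.finite(lu$lb)) || any(!is.finite(lu$ub)))
    stop("sampling requires a bounded region: make all bounds finite")
  start <- minimize_flux_sum(network)
  if (start$status != "optimal")
    stop("cannot sample: model is ", start$status)
  x <- start$fluxes
  nr <- length(x)
  freev <- which(lu$ub - lu$lb > 1e-9)
  if (length(freev) == 0) {
    samples <- matrix(rep(x, n), n, nr, byrow = TRUE,
                      dimnames = list(NULL, network$reactions$id))
    return(structure(list(samples = samples, seed = seed, burnin = burnin,
                          thin = thin), class = "flux_sample_set"))
  }
  Af <- as.matrix(network$S)[, freev, drop = FALSE]
  ## orthonormal null-space basis of the free-column stoichiometry via QR
  qa <- qr(t(Af))
  p <- ncol(Af)
  N <- if (qa$rank < p) {
    qr.Q(qa, complete = TRUE)[, seq(qa$rank + 1L, p), drop = FALSE]
  } else {
    matrix(numeric(0), p, 0)
  }
  if (ncol(N) == 0) {
    samples <- matrix(rep(x, n), n, nr, byrow = TRUE,
                      dimnames = list(NULL, network$reactions$id))
    return(structure(list(samples = samples, seed = seed, burnin = burnin,
                          thin = thin), class = "flux_sample_set"))
  }
  set.seed(seed)
  xp <- x[freev]          # moving point in free coordinates
  lbf <- lu$lb[freev]; ubf <- lu$ub[freev]
  samples <- matrix(NA_real_, n, nr, dimnames = list(NULL, network$reactions$id))
  total <- burnin + n * thin
  got <- 0L
  for (step in seq_len(total)) {
    d <- as.numeric(N %*% stats::rnorm(ncol(N)))
    nd <- sqrt(sum(d^2))
    if (nd < 1e-12) next
    d <- d / nd
    act <- abs(d) > 1e-12
    tlo <- (lbf[act] - xp[act]) / d[act]
    thi <- (ubf[act] - xp[act]) / d[act]
    tmin <- max(pmin(tlo, thi)); tmax <- min(pmax(tlo, thi))
    if (!is.finite(tmin) || !is.finite(tmax))
      stop("unbounded sampling direction detected")
    if (tmax < tmin) { tmin <- tmax <- 0 }
    xp <- xp + stats::runif(1, tmin, tmax) * d
    xp <- pmin(pmax(xp, lbf), ubf)
    if (step %% 100 == 0) {
      ## kill numerical drift off the null-space slice
      xp <- x[freev] + as.numeric(N %*% crossprod(N, xp - x[freev]))
      xp <- pmin(pmax(xp, lbf), ubf)
    }
    if (step > burnin && (step - burnin) %% thin == 0) {
      got <- got + 1L
      v <- x; v[freev] <- xp
      samples[got, ] <- v
    }
  }
  structure(list(samples = samples, seed = seed, burnin = burnin, thin = thin),
            class = "flux_sample_set")
}
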