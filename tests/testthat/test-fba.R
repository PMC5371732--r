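test_that("apply_bounds overwrites matched boundary reactions only", {
  net <- build_toy_hepatocyte_network()
  eb <- exchange_bounds("fa", "uptake", 0, 27)
  nb <- apply_bounds(net, eb)
  j <- match("EX_fa_up", nb$reactions$id)
  expect_equal(nb$reactions$upper[j], 27)
  interior <- nb$reactions$id == "BETAOX"
  expect_equal(nb$reactions$upper[interior],
               net$reactions$upper[net$reactions$id == "BETAOX"])
  # empty bounds leave the network unchanged; application is idempotent
  expect_identical(apply_bounds(net, eb[0, ]), net)
  expect_identical(apply_bounds(nb, eb), nb)
  expect_error(apply_bounds(net, exchange_bounds("nosuch", "uptake", 0, 1)),
               "no boundary reaction")
})

test_that("objective maximization on a capped chain hits the tighter cap", {
  net <- chain_network(up_cap = 5, sec_cap = 3)
  sol <- maximize_objective(net)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective, 3)
  expect_equal(unname(sol$fluxes), rep(3, 4))
  # a required secretion above the achievable input is infeasible
  net$reactions$lower[net$reactions$id == "EX_c_sec"] <- 6
  net$reactions$upper[net$reactions$id == "EX_c_sec"] <- 6
  expect_identical(maximize_objective(net)$status, "infeasible")
  expect_error(maximize_objective(net, "nonexistent"), "not in network")
})

test_that("FBA and parsimonious optima match vertex enumeration on all small fixtures", {
  for (net in all_small_networks()) {
    A <- as.matrix(net$S)
    lb <- net$reactions$lower; ub <- net$reactions$upper
    V <- enumerate_vertices(A, rep(0, nrow(A)), lb, ub)
    expect_gt(nrow(V), 0)
    j <- match(net$objective, net$reactions$id)
    sol <- maximize_objective(net)
    expect_equal(sol$objective, max(V[, j]), tolerance = 1e-6)
    # parsimonious solve with the objective pinned at its optimum: the flux
    # sum of an LP optimum is attained at some vertex of the pinned polytope
    pin <- setNames(sol$objective, net$objective)
    psol <- minimize_flux_sum(net, fixed_constraints = pin)
    expect_identical(psol$status, "optimal")
    lb2 <- lb; ub2 <- ub
    lb2[j] <- ub2[j] <- sol$objective
    V2 <- enumerate_vertices(A, rep(0, nrow(A)), lb2, ub2)
    expect_equal(psol$objective, min(rowSums(abs(V2))), tolerance = 1e-6)
  }
})

test_that("parallel routes are not double-used under flux-sum minimization", {
  net <- parallel_network()
  pin <- c(EX_b_sec = 4)
  sol <- minimize_flux_sum(net, fixed_constraints = pin)
  expect_identical(sol$status, "optimal")
  # total flux equals uptake + one-route conversion + secretion
  expect_equal(sol$objective, 12, tolerance = 1e-8)
  expect_equal(unname(sol$fluxes["R1"] + sol$fluxes["R2"]), 4, tolerance = 1e-8)
})

test_that("futile cycles carry zero flux under flux-sum minimization", {
  net <- cycle_network()
  sol <- minimize_flux_sum(net, fixed_constraints = c(EX_b_sec = 2))
  expect_identical(sol$status, "optimal")
  for (r in c("B2X", "X2Y", "Y2B"))
    expect_equal(unname(sol$fluxes[r]), 0, tolerance = 1e-9)
})

test_that("on a linear chain the parsimonious solution is the unique pathway", {
  net <- chain_network()
  msol <- maximize_objective(net)
  psol <- minimize_flux_sum(net, fixed_constraints = c(EX_c_sec = 3))
  expect_equal(psol$fluxes, msol$fluxes, tolerance = 1e-9)
})

test_that("the parsimonious flux sum lower-bounds sampled flux sums", {
  net <- build_toy_hepatocyte_network()
  nb <- apply_bounds(net, assemble_subject_bounds(fixture_subject()))
  psol <- minimize_flux_sum(nb)
  smp <- sample_fluxes(nb, n = 50, seed = 5)
  sums <- rowSums(abs(smp$samples))
  expect_true(all(sums >= psol$objective - 1e-6))
})

test_that("unknown pinned reactions are rejected", {
  expect_error(minimize_flux_sum(chain_network(),
                                 fixed_constraints = c(NOPE = 1)),
               "unknown reaction")
})
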