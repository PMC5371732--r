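test_that("the packaged hepatocyte network covers every core subsystem", {
  net <- build_toy_hepatocyte_network()
  core <- c("fatty-acid oxidation", "NNT", "GSR", "GPX/PRDX",
            "GSH de novo synthesis", "serine-glycine/one-carbon",
            "gluconeogenesis", "glycogenolysis", "ketogenesis",
            "oxidative phosphorylation", "VLDL assembly", "protein synthesis",
            "urea output", "exchange")
  expect_true(all(core %in% net$reactions$subsystem))
  expect_true(all(net$reactions$subsystem %in% subsystem_labels()))
  expect_gte(nrow(net$reactions), 40)
  expect_lte(nrow(net$reactions), 70)
  expect_identical(net$objective, "EX_vldltg_sec")
})

test_that("carbon is conserved in every non-boundary reaction", {
  net <- build_toy_hepatocyte_network()
  carb <- setNames(net$metabolites$carbons, net$metabolites$id)
  S <- as.matrix(net$S)
  internal <- !net$reactions$boundary
  imbalance <- t(S[, internal, drop = FALSE]) %*% carb[rownames(S)]
  expect_lt(max(abs(imbalance)), 1e-9)
})

test_that("the network is feasible under cohort-mean personalized bounds", {
  co <- generate_cohort(cohort_spec(86, seed = 1))
  mean_subject <- data.frame(
    id = "MEAN", sex = "male",
    weight = mean(co$weight), bmi = mean(co$bmi),
    liver_fat_pct = mean(co$liver_fat_pct), fat_mass = NA,
    vldl_tg_secretion = mean(co$vldl_tg_secretion),
    vldl_apob_secretion = mean(co$vldl_apob_secretion))
  net <- build_toy_hepatocyte_network()
  eb <- assemble_subject_bounds(mean_subject)
  rep <- validate_network(net, eb)
  expect_identical(nrow(rep$unmatched), 0L)
  expect_length(rep$orphan_metabolites, 0)
  sol <- minimize_flux_sum(apply_bounds(net, eb))
  expect_identical(sol$status, "optimal")
})

test_that("removing NNT and the pentose shunt breaks peroxide detoxification", {
  net <- build_toy_hepatocyte_network()
  eb <- assemble_subject_bounds(fixture_subject())
  nb <- apply_bounds(net, eb)
  expect_identical(minimize_flux_sum(nb)$status, "optimal")
  # close the two NADPH sources: GSR can no longer turn over GSSG while
  # beta-oxidation forces a positive H2O2 load
  kill <- match(c("NNT", "PPP"), nb$reactions$id)
  nb$reactions$lower[kill] <- nb$reactions$upper[kill] <- 0
  expect_identical(minimize_flux_sum(nb)$status, "infeasible")
})

test_that("raising the FA input monotonically raises the oxidative fluxes", {
  net <- build_toy_hepatocyte_network()
  eb <- assemble_subject_bounds(fixture_subject(fat_mass = 15))
  prev <- NULL
  watched <- c("BETAOX", "NNT", "GSR", "GPX", "EX_bhb_sec")
  for (fa in c(30, 40, 50, 60)) {
    sel <- eb$metabolite == "fa" & eb$direction == "uptake"
    eb$lower[sel] <- eb$upper[sel] <- fa
    sel <- eb$metabolite == "glycerol" & eb$direction == "uptake"
    eb$lower[sel] <- eb$upper[sel] <- fa / 3
    sol <- minimize_flux_sum(apply_bounds(net, eb))
    expect_identical(sol$status, "optimal")
    cur <- sol$fluxes[watched]
    if (!is.null(prev)) expect_true(all(cur >= prev - 1e-6))
    prev <- cur
  }
})

test_that("table and SBML renderings round-trip losslessly and agree", {
  net <- build_toy_hepatocyte_network()
  ftab <- tempfile(fileext = ".tsv")
  fsbml <- tempfile(fileext = ".xml")
  write_network(net, ftab)
  write_network(net, fsbml)
  back_tab <- load_network(ftab)
  back_sbml <- load_network(fsbml)
  for (back in list(back_tab, back_sbml)) {
    expect_identical(back$reactions$id, net$reactions$id)
    expect_identical(back$metabolites$id, net$metabolites$id)
    expect_equal(as.matrix(back$S), as.matrix(net$S), tolerance = 1e-12)
    expect_equal(back$reactions$lower, net$reactions$lower, tolerance = 1e-12)
    expect_equal(back$reactions$upper, net$reactions$upper, tolerance = 1e-12)
    expect_identical(back$reactions$subsystem, net$reactions$subsystem)
    expect_identical(back$reactions$reversible, net$reactions$reversible)
    expect_equal(back$metabolites$carbons, net$metabolites$carbons,
                 tolerance = 1e-12)
    expect_identical(back$objective, net$objective)
  }
})

test_that("malformed network files raise errors naming the offence", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\tlower\tupper\tsubsystem",
               "R1\t??not an equation\t0\t1\texchange"), f)
  expect_error(load_network(f), "cannot parse")
  f2 <- tempfile(fileext = ".tsv")
  writeLines("foo\tbar", f2)
  expect_error(load_network(f2), "lacks column")
  expect_error(load_network(tempfile()), "not found")
})

test_that("validation reports unmatched bound metabolites and blocked reactions", {
  net <- chain_network()
  eb <- exchange_bounds(c("a", "zz"), c("uptake", "uptake"), c(0, 0), c(5, 5))
  rep <- validate_network(net, eb)
  expect_identical(rep$unmatched$metabolite, "zz")
  # a reaction with no route to the boundary is blocked
  rx <- data.frame(
    id = c("EX_a_up", "A2B", "EX_b_sec", "A2X"),
    equation = c("-> a[c]", "a[c] -> b[c]", "b[c] ->", "a[c] -> x[c]"),
    lower = 0, upper = c(5, 100, 100, 100),
    subsystem = "exchange", stringsAsFactors = FALSE)
  net2 <- network_from_reactions(rx, carbons = c(a = 1, b = 1, x = 1))
  eb2 <- exchange_bounds(c("a", "b"), c("uptake", "secretion"),
                         c(0, 0), c(5, 100))
  rep2 <- validate_network(net2, eb2, check_blocked = TRUE)
  expect_true("A2X" %in% rep2$blocked)
  expect_false("A2B" %in% rep2$blocked)
})
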