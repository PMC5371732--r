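test_that("solve_cohort returns one optimal row per subject, deterministically", {
  co <- small_cohort(3, seed = 21)
  net <- build_toy_hepatocyte_network()
  fm <- solve_cohort(co, net, "min_sum")
  expect_identical(fm$status, rep("optimal", 3))
  expect_identical(dim(fm$fluxes), c(3L, nrow(net$reactions)))
  # identical subjects give identical rows
  co2 <- rbind(co[1, ], co[1, ]); co2$id <- c("A", "B")
  class(co2) <- class(co)
  fm2 <- solve_cohort(co2, net, "min_sum")
  expect_equal(fm2$fluxes[1, ], fm2$fluxes[2, ], tolerance = 1e-9)
})

test_that("sampled-mean mode is reproducible under a fixed seed", {
  co <- small_cohort(2, seed = 31)
  net <- build_toy_hepatocyte_network()
  fm1 <- solve_cohort(co, net, "sampled_mean", seed = 9, n_samples = 30)
  fm2 <- solve_cohort(co, net, "sampled_mean", seed = 9, n_samples = 30)
  expect_identical(fm1$fluxes, fm2$fluxes)
  expect_identical(fm1$status, rep("optimal", 2))
})

test_that("net fat influx is uptake minus FA-equivalent secretion", {
  net <- build_toy_hepatocyte_network()
  v <- setNames(numeric(nrow(net$reactions)), net$reactions$id)
  v["EX_fa_up"] <- 27
  v["EX_vldltg_sec"] <- 10 / 3   # 10 FA equivalents
  expect_equal(net_fat_influx(v, net), 17)
  v["EX_vldltg_sec"] <- 9        # uptake = secretion
  expect_equal(net_fat_influx(v, net), 0)
  v["EX_vldltg_sec"] <- 0
  expect_equal(net_fat_influx(v, net), 27)
  # networks without the tagged boundary reactions are an error
  expect_error(net_fat_influx(v[1:4], chain_network()), "tagged")
})

test_that("flux-phenotype correlations match a hand-computed Pearson formula", {
  fm <- structure(list(
    fluxes = cbind(lin = c(3, 5, 7, 9, 11), const = rep(2, 5),
                   noisy = c(1.2, 0.8, 2.4, 1.9, 0.3)),
    status = rep("optimal", 5), mode = "min_sum",
    ids = paste0("S", 1:5)), class = "flux_matrix")
  ph <- c(1, 2, 3, 4, 5)
  tab <- correlate_fluxes(fm, ph)
  expect_equal(tab$r[tab$reaction == "lin"], 1, tolerance = 1e-12)
  expect_true(is.na(tab$r[tab$reaction == "const"]))
  expect_match(tab$note[tab$reaction == "const"], "constant")
  expect_equal(tab$r[tab$reaction == "noisy"],
               pearson_reference(fm$fluxes[, "noisy"], ph), tolerance = 1e-12)
  expect_error(correlate_fluxes(fm, ph[1:3]), "length")
  fm$status[3:5] <- "infeasible"
  expect_error(correlate_fluxes(fm, ph), "fewer than 3")
})

test_that("failed solves are excluded pairwise with the n reported", {
  fm <- structure(list(
    fluxes = rbind(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2), NA, NA),
    status = c(rep("optimal", 4), "infeasible", "infeasible"),
    mode = "min_sum", ids = paste0("S", 1:6)), class = "flux_matrix")
  colnames(fm$fluxes) <- c("r1", "r2")
  tab <- correlate_fluxes(fm, c(1, 2, 3, 4, 10, 20))
  expect_identical(unique(tab$n), 4L)
})

test_that("randomizing FA leaves VLDL bounds untouched and vice versa", {
  co <- small_cohort(3, seed = 41)
  eb <- assemble_subject_bounds(co[2, ])
  ov_fa <- randomized_bounds_override("fa", co$id, c(10, 11, 12),
                                      c(9, 9, 9), c(9, 9, 9))
  eb_fa <- ov_fa(eb, co[2, ])
  expect_equal(eb_fa$upper[eb_fa$metabolite == "fa"], 11)
  expect_equal(eb_fa[eb_fa$metabolite == "vldl_tg", ],
               eb[eb$metabolite == "vldl_tg", ])
  expect_equal(eb_fa[eb_fa$metabolite == "apob", ],
               eb[eb$metabolite == "apob", ])
  ov_v <- randomized_bounds_override("vldl", co$id, c(10, 11, 12),
                                     c(0.3, 0.4, 0.5), c(0.2, 0.3, 0.4))
  eb_v <- ov_v(eb, co[2, ])
  expect_equal(eb_v[eb_v$metabolite == "fa", ], eb[eb$metabolite == "fa", ])
  expect_equal(eb_v$upper[eb_v$metabolite == "vldl_tg"], 0.4)
  expect_equal(eb_v$upper[eb_v$metabolite == "apob"], 0.3)
})

test_that("the randomized control is reproducible and attenuates correlations", {
  co <- generate_cohort(cohort_spec(24, seed = 51))
  net <- build_toy_hepatocyte_network()
  rc1 <- random_control(co, net, "both", reps = 2, seed = 6)
  rc2 <- random_control(co, net, "both", reps = 2, seed = 6)
  expect_identical(rc1$per_rep, rc2$per_rep)
  # real redox-HS correlations are positive under personalized inputs
  expect_true(all(rc1$real$r_hs > 0))
})
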