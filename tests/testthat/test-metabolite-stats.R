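test_that("log transform maps observed values and preserves missingness", {
  m <- matrix(c(1, exp(2), NA, 4), 2, 2,
              dimnames = list(c("a", "b"), c("m1", "m2")))
  lt <- log_transform(m)
  expect_equal(lt[1, 1], 0)
  expect_equal(lt[2, 1], 2)
  expect_true(is.na(lt[1, 2]))
  expect_identical(is.na(lt), is.na(m))
  m2 <- m; m2[2, 2] <- -1
  expect_error(log_transform(m2), "non-positive")
  # base-10 option changes scale, not sign or ordering
  lt10 <- log_transform(m, base = 10)
  expect_equal(lt10[2, 1], 2 / log(10, base = exp(1)), tolerance = 1e-12)
})

test_that("identical groups give t = 0 and p = 1", {
  m <- matrix(rep(c(5, 6, 7), 2), 6, 1, dimnames = list(NULL, "m"))
  g <- rep(c("low", "high"), each = 3)
  w <- welch_tests(log_transform(m), g)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
})

test_that("the Welch statistic matches the closed-form evaluation", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  m <- matrix(c(x, y), 6, 1, dimnames = list(NULL, "m"))
  g <- rep(c("low", "high"), each = 3)
  w <- welch_tests(m, g)
  ref <- welch_reference(y, x)     # high minus low
  expect_equal(w$t, ref$t, tolerance = 1e-12)
  expect_equal(w$df, ref$df, tolerance = 1e-12)
  expect_equal(w$p, ref$p, tolerance = 1e-12)
  expect_equal(w$log_diff, 1)
})

test_that("Welch p-values agree with the independent reference to 1e-9", {
  set.seed(404)
  for (rep in 1:40) {
    nx <- sample(3:20, 1); ny <- sample(3:20, 1)
    x <- rnorm(nx, sd = runif(1, 0.2, 3))
    y <- rnorm(ny, mean = runif(1, -1, 1), sd = runif(1, 0.2, 3))
    m <- matrix(c(x, y), nx + ny, 1, dimnames = list(NULL, "m"))
    g <- c(rep("low", nx), rep("high", ny))
    w <- welch_tests(m, g)
    ref <- welch_reference(y, x)
    expect_equal(w$t, ref$t, tolerance = 1e-9)
    expect_equal(w$p, ref$p, tolerance = 1e-9)
  }
})

test_that("metabolites with too few observations are skipped with a reason", {
  m <- matrix(c(1, NA, NA, NA, 2, 3, 4, 5), 4, 2,
              dimnames = list(NULL, c("sparse", "full")))
  g <- rep(c("low", "high"), each = 2)
  w <- welch_tests(m, g)
  expect_match(w$note[w$metabolite == "sparse"], "fewer than 2")
  expect_true(is.na(w$p[w$metabolite == "sparse"]))
  expect_identical(w$n_low[w$metabolite == "sparse"], 1L)
  expect_error(welch_tests(m, c("low", "mid", "high", "high")), "low")
})

test_that("the joint-detection rule excludes pairs below the threshold", {
  set.seed(11)
  n <- 40
  a <- rnorm(n); b <- a + rnorm(n, sd = 0.1)
  a[1:11] <- NA          # 29 joint detections with b
  cmat <- cbind(a = exp(a), b = exp(b), c = exp(rnorm(n)))
  lt <- log_transform(cmat)
  tab <- pairwise_correlations(lt, min_detected = 30)
  ab <- tab[tab$met1 == "a" & tab$met2 == "b", ]
  expect_identical(ab$n_joint, 29L)
  expect_true(ab$excluded)
  expect_true(is.na(ab$r))
  bc <- tab[tab$met1 == "b" & tab$met2 == "c", ]
  expect_false(bc$excluded)
  expect_error(pairwise_correlations(lt, min_detected = 2), "at least 3")
})

test_that("identical columns correlate perfectly; small cases match by hand", {
  x <- c(1.1, 2.3, 0.7, 4.2, 3.3)
  cmat <- cbind(p = exp(x), q = exp(x), z = exp(c(0.2, 1.5, 0.9, 2.2, 0.1)))
  lt <- log_transform(cmat)
  tab <- pairwise_correlations(lt, min_detected = 3)
  expect_equal(tab$r[tab$met1 == "p" & tab$met2 == "q"], 1, tolerance = 1e-12)
  expect_equal(tab$r[tab$met1 == "p" & tab$met2 == "z"],
               pearson_reference(x, c(0.2, 1.5, 0.9, 2.2, 0.1)),
               tolerance = 1e-12)
})

test_that("steatosis correlations carry sign, threshold and exclusion rules", {
  set.seed(21)
  n <- 86
  hs <- rlnorm(n, 1.5, 0.7)
  anti <- exp(-(hs - mean(hs)) / sd(hs) + rnorm(n, sd = 0.05))
  null <- exp(rnorm(n))
  sparse <- exp(rnorm(n)); sparse[1:60] <- NA
  lt <- log_transform(cbind(anti = anti, null = null, sparse = sparse))
  tab <- hs_correlations(lt, hs, min_detected = 30)
  expect_lt(tab$r[tab$metabolite == "anti"], -0.95)
  expect_true(tab$excluded[tab$metabolite == "sparse"])
  expect_false(tab$excluded[tab$metabolite == "null"])
})

test_that("missingness flows through the pipeline without imputation", {
  co <- small_cohort(20, seed = 61)
  mat <- generate_metabolome(co, seed = 3)
  n_missing <- sum(is.na(mat))
  expect_gt(n_missing, 0)
  lt <- log_transform(mat)
  expect_identical(sum(is.na(lt)), n_missing)
  g <- ifelse(co$liver_fat_pct >= 5.5, "high", "low")
  w <- welch_tests(lt, g)
  # per-metabolite group counts reflect only observed values
  expect_equal(w$n_low + w$n_high, colSums(!is.na(mat)), ignore_attr = TRUE)
})
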