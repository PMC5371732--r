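# Tiny fixture networks built in code. All are <= 6 reactions so LP optima
# can be cross-checked against exhaustive vertex enumeration.

# linear chain: uptake (cap 5) -> conversion -> secretion (cap 3)
chain_network <- function(up_cap = 5, sec_cap = 3) {
  rx <- data.frame(
    id = c("EX_a_up", "A2B", "B2C", "EX_c_sec"),
    equation = c("-> a[c]", "a[c] -> b[c]", "b[c] -> c[c]", "c[c] ->"),
    lower = 0, upper = c(up_cap, 100, 100, sec_cap),
    subsystem = "exchange", stringsAsFactors = FALSE)
  network_from_reactions(rx, carbons = c(a = 1, b = 1, c = 1),
                         objective = "EX_c_sec")
}

# two parallel single-step routes of equal length between a and b
parallel_network <- function() {
  rx <- data.frame(
    id = c("EX_a_up", "R1", "R2", "EX_b_sec"),
    equation = c("-> a[c]", "a[c] -> b[c]", "a[c] -> b[c]", "b[c] ->"),
    lower = 0, upper = c(4, 100, 100, 100),
    subsystem = "exchange", stringsAsFactors = FALSE)
  network_from_reactions(rx, carbons = c(a = 1, b = 1),
                         objective = "EX_b_sec")
}

# chain plus a closed 3-cycle that can carry futile flux
cycle_network <- function() {
  rx <- data.frame(
    id = c("EX_a_up", "A2B", "EX_b_sec", "B2X", "X2Y", "Y2B"),
    equation = c("-> a[c]", "a[c] -> b[c]", "b[c] ->",
                 "b[c] -> x[c]", "x[c] -> y[c]", "y[c] -> b[c]"),
    lower = 0, upper = c(2, 100, 100, 100, 100, 100),
    subsystem = "exchange", stringsAsFactors = FALSE)
  network_from_reactions(rx, carbons = c(a = 1, b = 1, x = 1, y = 1),
                         objective = "EX_b_sec")
}

# one degree of freedom: flux through the whole chain is a single interval
onedof_network <- function(lo = 0, hi = 3) {
  net <- chain_network(up_cap = hi, sec_cap = hi)
  net$reactions$lower[net$reactions$id == "EX_c_sec"] <- lo
  net
}

all_small_networks <- function() {
  list(chain = chain_network(), parallel = parallel_network(),
       cycle = cycle_network(), onedof = onedof_network())
}

# a small deterministic subject for bound assembly
fixture_subject <- function(weight = 92.4, bmi = 29.7, fat_mass = NA,
                            tg = 0.5, apob = 0.5, id = "T001") {
  data.frame(id = id, sex = "male", weight = weight, bmi = bmi,
             liver_fat_pct = 4, fat_mass = fat_mass,
             vldl_tg_secretion = tg, vldl_apob_secretion = apob,
             stringsAsFactors = FALSE)
}

small_cohort <- function(n = 4, seed = 11) {
  generate_cohort(cohort_spec(n_subjects = n, seed = seed))
}

# closed-form Welch test, written independently of stats::t.test
welch_reference <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# textbook Pearson correlation, independent of stats::cor
pearson_reference <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
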