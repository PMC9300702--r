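# synthetic-data generators: determinism, generative-law fidelity, validation

test_that("simulators are deterministic under a fixed seed", {
  s <- apms_scenario(n_background = 50, n_planted_surface = 3,
                     n_planted_endosomal = 3, n_planted_shared = 3, seed = 9)
  a <- simulate_apms(s)
  b <- simulate_apms(s)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)

  fs <- frap_scenario(n_cells = 4, seed = 9)
  expect_identical(simulate_frap(fs), simulate_frap(fs))

  as <- assay_scenario(seed = 9)
  expect_identical(simulate_assays(as), simulate_assays(as))
})

test_that("adding proteins does not reshuffle existing protein draws", {
  small <- apms_scenario(n_background = 20, n_planted_surface = 2,
                         n_planted_endosomal = 2, n_planted_shared = 2,
                         seed = 4)
  big <- apms_scenario(n_background = 60, n_planted_surface = 2,
                       n_planted_endosomal = 2, n_planted_shared = 2,
                       seed = 4)
  vs <- simulate_apms(small)$matrix$values
  vb <- simulate_apms(big)$matrix$values
  expect_identical(vs, vb[seq_len(nrow(vs)), ])
})

test_that("apms matrix has the three-group replicate design and planted truth", {
  s <- apms_scenario(n_background = 30, n_planted_surface = 4,
                     n_planted_endosomal = 5, n_planted_shared = 6,
                     n_replicates = 4, seed = 2)
  sim <- simulate_apms(s)
  m <- sim$matrix
  expect_equal(sort(unique(m$group)), c("control", "endosomal", "surface"))
  expect_equal(table(m$group)[["surface"]], 4)
  expect_equal(nrow(sim$truth), 15)
  expect_equal(sum(sim$truth$surface), 10)   # surface-only + shared
  expect_equal(sum(sim$truth$endosomal), 11) # endosomal-only + shared
  expect_equal(sum(sim$truth$surface & sim$truth$endosomal), 6)
})

test_that("planted enrichment elevates compartment means by the planted log2fc", {
  s <- apms_scenario(n_background = 0, n_planted_surface = 200,
                     n_planted_endosomal = 0, n_planted_shared = 0,
                     planted_log2fc = 3, noise_sd = 0.2,
                     dropout_midpoint = -Inf, seed = 5)
  m <- simulate_apms(s)$matrix
  lv <- log2(m$values)
  d_surface <- rowMeans(lv[, m$group == "surface"]) -
    rowMeans(lv[, m$group == "control"])
  d_endo <- rowMeans(lv[, m$group == "endosomal"]) -
    rowMeans(lv[, m$group == "control"])
  expect_equal(mean(d_surface), 3, tolerance = 0.05)
  expect_lt(abs(mean(d_endo)), 0.05)
})

test_that("observed background intensities match the dropout-truncated normal", {
  s <- apms_scenario(n_background = 4000, n_planted_surface = 0,
                     n_planted_endosomal = 0, n_planted_shared = 0, seed = 21)
  m <- simulate_apms(s)$matrix
  # one control cell per protein keeps draws independent for the KS test
  obs <- log2(m$values[, which(m$group == "control")[1]])
  obs <- obs[!is.na(obs)]
  oracle <- rejection_sample_observed(
    5e4, s$base_log2_mean, sqrt(s$base_log2_sd^2 + s$noise_sd^2),
    s$dropout_midpoint, s$dropout_slope, seed = 22)
  ks <- suppressWarnings(stats::ks.test(obs, oracle))
  expect_gt(ks$p.value, 1e-3)
  # overall missing rate matches the logistic-integrated expectation
  expected_missing <- stats::integrate(function(x)
    stats::dnorm(x, s$base_log2_mean,
                 sqrt(s$base_log2_sd^2 + s$noise_sd^2)) *
      (1 - stats::plogis(s$dropout_slope * (x - s$dropout_midpoint))),
    -Inf, Inf)$value
  n_cells <- length(m$values)
  emp <- mean(is.na(m$values))
  expect_lt(abs(emp - expected_missing),
            4 * sqrt(expected_missing * (1 - expected_missing) / n_cells) +
              0.005)
})

test_that("empirical dropout frequency follows the logistic curve in intensity bins", {
  # pin the true intensity of every cell (zero biological and replicate
  # spread) at a ladder of levels and read the detection frequency off the
  # simulated matrices; > 1e4 cells per level
  levels <- seq(20.5, 25, by = 1.5)
  s_template <- apms_scenario()
  for (i in seq_along(levels)) {
    s <- apms_scenario(n_background = 1000, n_planted_surface = 0,
                       n_planted_endosomal = 0, n_planted_shared = 0,
                       base_log2_mean = levels[i], base_log2_sd = 0,
                       noise_sd = 1e-9, seed = 40 + i)
    m <- simulate_apms(s)$matrix
    p_emp <- mean(!is.na(m$values))
    p_true <- plogis(s_template$dropout_slope *
                       (levels[i] - s_template$dropout_midpoint))
    n_cells <- length(m$values)
    expect_lt(abs(p_emp - p_true),
              4 * sqrt(pmax(p_true * (1 - p_true), 1e-4) / n_cells) + 0.005)
  }
})

test_that("frap traces follow the stated recovery law", {
  # F at t = 10 s equals b + Mf (1 - b)(1 - e^-1) for tau = 10, noise free
  sc <- frap_scenario(mobile_fraction = 0.6, tau_s = 10, bleach_floor = 0.2,
                      noise_sd = 0, n_cells = 1, frame_interval_s = 2,
                      n_post = 30, seed = 1)
  tr <- simulate_frap(sc)
  post <- tr[tr$phase == "post", ]
  t_rel <- post$time_s - post$time_s[1]
  f10 <- post$intensity[t_rel == 10]
  expect_equal(f10, 0.2 + 0.6 * 0.8 * (1 - exp(-1)), tolerance = 1e-12)
  # pre-bleach frames sit at 1
  expect_true(all(tr$intensity[tr$phase == "pre"] == 1))
})

test_that("immobile pool gives a flat post-bleach trace at the bleach floor", {
  sc <- frap_scenario(mobile_fraction = 0, bleach_floor = 0.3, noise_sd = 0,
                      n_cells = 2, seed = 1)
  tr <- simulate_frap(sc)
  expect_true(all(tr$intensity[tr$phase == "post"] == 0.3))
})

test_that("assay simulator reproduces planted fractions noise-free", {
  sc <- assay_scenario(internalized_fraction_ctrl = 0.2,
                       internalized_fraction_treat = 0.2,
                       surface_signal = 1, background_od = 0, noise_cv = 0,
                       seed = 1)
  sim <- simulate_assays(sc)
  est <- internalization_percent(sim$elisa, "ctrl")
  expect_equal(est$percent, 20, tolerance = 1e-12)
  # equal flux rates give zero percent change
  fl_c <- permeability_flux(
    sim$permeability[sim$permeability$condition == "ctrl", ])
  fl_t <- permeability_flux(
    sim$permeability[sim$permeability$condition == "treat", ])
  pc <- percent_change(fl_c$slope_per_h, fl_t$slope_per_h)
  expect_equal(pc$percent_change, 0, tolerance = 1e-12)
})

test_that("invalid scenario parameters are rejected", {
  expect_error(apms_scenario(noise_sd = 0), "noise_sd")
  expect_error(apms_scenario(n_background = -1), "counts")
  expect_error(apms_scenario(n_replicates = 1), "n_replicates")
  expect_error(apms_scenario(planted_log2fc = Inf), "finite")
  expect_error(frap_scenario(mobile_fraction = 1.2), "mobile_fraction")
  expect_error(frap_scenario(tau_s = 0), "tau_s")
  expect_error(frap_scenario(bleach_floor = 1), "bleach_floor")
  expect_error(frap_scenario(n_post = 1), "n_post")
  expect_error(assay_scenario(internalized_fraction_ctrl = -0.1), "fractions")
  expect_error(assay_scenario(sample_times_h = c(2, 2, 6)), "increasing")
  expect_error(assay_scenario(noise_cv = -1), "noise_cv")
})

test_that("frap traces and scenarios round-trip through their file formats", {
  sc <- frap_scenario(n_cells = 3, seed = 8)
  tr <- simulate_frap(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frap_csv(tr, path)
  back <- read_frap_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)

  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, ypath)
  sc2 <- read_scenario_yaml(ypath)
  expect_equal(unclass(sc2), unclass(sc), tolerance = 1e-12)
})
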