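# core LFQ statistics: filtering, transformation, imputation, ratios,
# testing, FDR, calling, background flags, volcano export

make_matrix <- function(values, groups = c("surface", "endosomal", "control"),
                        nr = 4, scale = "linear") {
  intensity_matrix(values, rep(groups, each = nr),
                   rep(seq_len(nr), times = length(groups)), scale = scale)
}

test_that("validity filter keeps proteins with enough replicates in any one group", {
  v <- matrix(NA_real_, 3, 12,
              dimnames = list(c("full_surface", "sparse", "edge"), NULL))
  v["full_surface", 1:4] <- 100               # 4/4 surface, 0 elsewhere
  v["sparse", c(1, 2, 5, 6, 9, 10)] <- 100    # 2/4 everywhere
  v["edge", c(5, 6, 7)] <- 100                # exactly 3/4 endosomal
  m <- make_matrix(v)
  f <- filter_by_valid_values(m, calling_params(min_valid = 3))
  expect_equal(rownames(f$values), c("full_surface", "edge"))
  expect_equal(ncol(f$values), 12)
  # min_valid = 0 is the row identity
  f0 <- filter_by_valid_values(m, calling_params(min_valid = 0))
  expect_equal(rownames(f0$values), rownames(v))
  # an empty result is legal
  f_all <- filter_by_valid_values(
    subset_proteins(m, "sparse"), calling_params(min_valid = 3))
  expect_equal(nrow(f_all$values), 0)
})

test_that("log2 transform maps values, preserves missingness, and round-trips", {
  v <- matrix(c(8, NA, 2, 4), 1, 12, dimnames = list("p1", NULL))
  m <- make_matrix(v)
  lm2 <- log2_transform(m)
  expect_equal(lm2$values["p1", 1], 3)
  expect_identical(unname(is.na(lm2$values)), unname(is.na(v)))
  expect_equal(lm2$scale, "log2")
  back <- unlog2_transform(lm2)
  expect_equal(back$values, m$values, tolerance = 1e-12)
  # non-positive present values are rejected with the cell identified
  v2 <- v; v2[1, 3] <- -1
  expect_error(log2_transform(make_matrix(v2)), "p1")
})

test_that("imputation draws from the per-column downshifted normal", {
  # large column: observed stats mu, sigma; draws must match
  # Normal(mu - 1.8 sigma, (0.3 sigma)^2) within 3 Monte-Carlo SEs
  set.seed(77)
  n_obs <- 2000; n_miss <- 20000
  col <- c(rnorm(n_obs, 25, 2), rep(NA_real_, n_miss))
  v <- matrix(rep(col, 12), ncol = 12,
              dimnames = list(sprintf("p%05d", seq_len(n_obs + n_miss)), NULL))
  m <- make_matrix(v, scale = "log2")
  imp <- impute_downshifted_normal(m, imputation_params(seed = 3))
  obs_mu <- mean(col[1:n_obs]); obs_sd <- sd(col[1:n_obs])
  drawn <- imp$values[(n_obs + 1):(n_obs + n_miss), 1]
  se_mean <- 0.3 * obs_sd / sqrt(n_miss)
  expect_lt(abs(mean(drawn) - (obs_mu - 1.8 * obs_sd)), 3 * se_mean)
  se_sd <- 0.3 * obs_sd / sqrt(2 * (n_miss - 1))
  expect_lt(abs(sd(drawn) - 0.3 * obs_sd), 3 * se_sd)
  # observed cells untouched
  expect_equal(imp$values[1:n_obs, 1], col[1:n_obs],
               ignore_attr = TRUE)
})

test_that("imputation is an identity on complete matrices and validates params", {
  v <- matrix(20 + seq_len(24) / 10, 2, 12,
              dimnames = list(c("a", "b"), NULL))
  m <- make_matrix(v, scale = "log2")
  expect_identical(impute_downshifted_normal(m)$values, m$values)
  expect_error(imputation_params(width = 0), "width")
  expect_error(imputation_params(downshift = -1), "downshift")
  # zero-SD column imputes the constant mean with a warning
  v2 <- matrix(5, 4, 12, dimnames = list(letters[1:4], NULL))
  v2[3, 1] <- NA
  expect_warning(
    imp <- impute_downshifted_normal(make_matrix(v2, scale = "log2")),
    "zero observed SD")
  expect_equal(imp$values[3, 1], 5)
  # a column with < 2 observed values is rejected
  v3 <- matrix(NA_real_, 3, 12, dimnames = list(letters[1:3], NULL))
  v3[1, ] <- 20
  expect_error(
    impute_downshifted_normal(make_matrix(v3, scale = "log2")),
    "fewer than 2 observed")
})

test_that("control ratios are paired log2 differences", {
  # linear (4, 8) vs control (2, 2) -> log2 ratios (1, 2)
  v <- matrix(0, 1, 6, dimnames = list("p1", NULL))
  m <- intensity_matrix(
    matrix(c(4, 8, 1, 1, 2, 2), 1, dimnames = list("p1", NULL)),
    rep(c("surface", "endosomal", "control"), each = 2),
    rep(1:2, 3), scale = "linear")
  r <- compute_ratios(log2_transform(m), "surface")
  expect_equal(unname(r["p1", ]), c(1, 2))
  # identical columns give zero ratios; constant shifts cancel
  lm2 <- log2_transform(m)
  lm2$values["p1", 5:6] <- lm2$values["p1", 1:2]
  expect_equal(unname(compute_ratios(lm2, "surface")["p1", ]), c(0, 0))
  shifted <- lm2
  shifted$values["p1", ] <- shifted$values["p1", ] + 7
  expect_equal(compute_ratios(shifted, "surface"),
               compute_ratios(lm2, "surface"))
  # unpaired mode compares with the control mean
  r_un <- compute_ratios(log2_transform(m), "surface", paired = FALSE)
  expect_equal(unname(r_un["p1", ]), c(1, 2))
})

test_that("one-sample t agrees with the independent t.test oracle", {
  expect_equal(unname(unlist(
    one_sample_ttest(c(0.5, -0.5, 0.3, -0.3))[c("t", "p")])), c(0, 1))
  set.seed(12)
  for (i in 1:25) {
    x <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    res <- one_sample_ttest(x)
    expect_equal(res$p, ttest_oracle_p(x), tolerance = 1e-10)
    expect_equal(res$t, unname(stats::t.test(x, mu = 0)$statistic),
                 tolerance = 1e-10)
  }
  # degenerate rows are flagged, not dropped
  res <- one_sample_ttest(rbind(c(1, 1, 1), c(0, 0, 0)))
  expect_true(all(res$degenerate))
  expect_equal(res$p, c(0, 1))
  expect_error(one_sample_ttest(matrix(1, 1, 1)), "at least 2")
})

test_that("BH q values match brute-force step-up enumeration", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(99)
  for (n in 1:12) {
    p <- runif(n)^2
    q <- bh_fdr(p)
    expect_equal(q, bh_brute_force(p), tolerance = 1e-12)
    # monotone non-decreasing along sorted p, and q >= p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p - 1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("interactor calling applies inclusive FC and strict p thresholds", {
  tab <- data.frame(
    protein = c("a", "b", "c", "d"),
    compartment = "surface",
    mean_log2_ratio = c(log2(1.6), log2(1.5), log2(3.0), log2(1.4)),
    t = 1, p = c(0.03, 0.049, 0.05, 0.001), q = c(0.06, 0.09, 0.09, 0.004),
    degenerate = FALSE)
  called <- call_interactors(tab, calling_params())
  expect_equal(called$interactor, c(TRUE, TRUE, FALSE, FALSE))
  # q-based calling mode
  called_q <- call_interactors(tab, calling_params(use_q = TRUE))
  expect_equal(called_q$interactor, c(FALSE, FALSE, FALSE, FALSE))
})

test_that("calling is monotone in compartment intensity", {
  set.seed(5)
  v <- matrix(2^rnorm(12, 25, 1), 1, 12, dimnames = list("p1", NULL))
  m <- make_matrix(v)
  fit1 <- fit_interactome(m, calling_params(min_valid = 0))
  tab1 <- fit1$enrichment
  # double every surface intensity: the surface call can only turn on
  v2 <- v; v2[1, 1:4] <- v2[1, 1:4] * 4
  fit2 <- fit_interactome(make_matrix(v2), calling_params(min_valid = 0))
  tab2 <- fit2$enrichment
  s1 <- tab1$interactor[tab1$compartment == "surface"]
  s2 <- tab2$interactor[tab2$compartment == "surface"]
  expect_true(s2 >= s1)
})

test_that("background flagging annotates without changing calls", {
  tab <- data.frame(protein = c("a", "b", "c"), compartment = "surface",
                    mean_log2_ratio = 1, t = 3, p = 0.01, q = 0.02,
                    degenerate = FALSE)
  tab <- call_interactors(tab)
  bg <- data.frame(protein = c("a", "b"), frequency = c(0.60, 0.30))
  flagged <- flag_background(tab, bg)
  expect_equal(flagged$background_flag, c(TRUE, FALSE, FALSE))
  expect_equal(flagged$interactor, tab$interactor)
  expect_error(flag_background(tab, data.frame(protein = "a",
                                               frequency = 1.2)),
               "\\[0, 1\\]")
})

test_that("volcano export is lossless and maps p to -log10", {
  tab <- data.frame(protein = c("a", "b"), compartment = "surface",
                    mean_log2_ratio = c(1, -0.5), t = c(3, -1),
                    p = c(0.01, 0.5), q = c(0.02, 0.5), degenerate = FALSE)
  tab <- flag_background(call_interactors(tab), NULL)
  v <- export_volcano(tab)
  expect_equal(v$y[1], 2)
  expect_equal(nrow(v), nrow(tab))
  expect_equal(v$interactor, tab$interactor)
  expect_equal(v$background_flag, tab$background_flag)
})

test_that("filter-log2-impute collapses to filter-log2 on complete data", {
  set.seed(8)
  v <- matrix(2^rnorm(60, 25, 1), 5, 12,
              dimnames = list(sprintf("p%d", 1:5), NULL))
  m <- make_matrix(v)
  a <- impute_downshifted_normal(
    log2_transform(filter_by_valid_values(m)), imputation_params(seed = 1))
  b <- log2_transform(filter_by_valid_values(m))
  expect_identical(a$values, b$values)
})
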