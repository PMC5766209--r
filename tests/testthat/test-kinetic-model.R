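test_that("splicing-rate draws follow the truncated normal contract", {
  set.seed(1)
  # degenerate sd: every draw is the mean
  expect_equal(draw_splicing_rate(5, kinetic_params(rate_sd = 0)),
               rep(0.169, 5))
  # moments at large n
  r <- draw_splicing_rate(1e5, kinetic_params())
  expect_true(all(r > 0))
  expect_lt(abs(mean(r) - 0.169) / 0.169, 0.01)
  expect_lt(abs(sd(r) - 0.048) / 0.048, 0.05)
  # fixed seed reproduces the sequence
  set.seed(33); a <- draw_splicing_rate(10, kinetic_params())
  set.seed(33); b <- draw_splicing_rate(10, kinetic_params())
  expect_identical(a, b)
  # a distribution dominated by the non-positive tail is refused
  expect_error(draw_splicing_rate(1, list(rate_mean = -0.1, rate_sd = 0.05)),
               "truncation")
})

test_that("closed-form upstream-first probability matches known values", {
  # equal rates, no delay: symmetric race
  expect_equal(p_upstream_first(0.169, 0.169, 0), 0.5)
  # competing exponentials at delay 0
  expect_equal(p_upstream_first(0.2, 0.1, 0), 2 / 3)
  # delay 0 in general is k_up / (k_up + k_down)
  expect_equal(p_upstream_first(0.3, 0.12, 0), 0.3 / 0.42)
  # default-rate pair with 150 nt exon and 3 kb downstream intron
  expect_equal(p_upstream_first(0.169, 0.169, pair_delay(150, 3000, 3.87)),
               0.5643, tolerance = 1e-4)
})

test_that("closed form agrees with a brute-force two-exponential simulation", {
  set.seed(202)
  grid <- expand.grid(k_up = c(0.08, 0.169, 0.3),
                      k_down = c(0.08, 0.169, 0.3),
                      delay = c(0, 0.8, 5))
  n <- 1e6
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- p_upstream_first(g$k_up, g$k_down, g$delay)
    est <- mean(rexp(n, g$k_up) < g$delay + rexp(n, g$k_down))
    expect_lt(abs(est - p), 3 * sqrt(p * (1 - p) / n) + 1e-9)
  }
})

test_that("upstream-first probability is monotone in delay and upstream rate", {
  delays <- seq(0, 10, by = 0.5)
  p <- p_upstream_first(0.169, 0.169, delays)
  expect_true(all(diff(p) >= 0))
  expect_gt(p_upstream_first(0.169, 0.169, 500), 1 - 1e-6)  # delay -> inf
  ks <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(p_upstream_first(ks, 0.169, 0.8)) >= 0))
})

test_that("per-pair read simulation is binomial around the order probability", {
  expect_equal(simulate_pair(rep(1, 5), 10), rep(0, 5))  # p_up = 1
  set.seed(5); a <- simulate_pair(0.4, 10)
  set.seed(5); b <- simulate_pair(0.4, 10)
  expect_identical(a, b)
  set.seed(6)
  reps <- replicate(1e4, simulate_pair(0.7, 10))  # p_downstream_first = 0.3
  expect_lt(abs(mean(reps) - 0.3), 0.01)
  expect_error(simulate_pair(0.5, 0), "n_reads")
})

test_that("null distribution is symmetric without delay and loses bias as txn grows", {
  pairs <- data.frame(pair_id = sprintf("p%d", 1:400), exon_len = 150,
                      dn_len = 1500, up_len = 1500, n_total = 50,
                      unique = TRUE)
  # effectively instantaneous transcription: no upstream-first bias
  fast <- simulate_null_distribution(pairs, kinetic_params(txn_rate = 1e7),
                                     n_reps = 10, seed = 2)
  m_fast <- mean(attr(fast, "fractions"))
  expect_lt(abs(m_fast - 0.5), 0.03)
  # default transcription rate: downstream-first fraction below 0.5
  slow <- simulate_null_distribution(pairs, kinetic_params(), n_reps = 10,
                                     seed = 3)
  expect_lt(mean(attr(slow, "fractions")), m_fast - 0.02)
  # non-unique pairs are excluded; missing lengths warn and skip
  pairs2 <- pairs; pairs2$unique[1:200] <- FALSE
  d <- simulate_null_distribution(pairs2, n_reps = 2, seed = 4)
  expect_equal(sum(d$counts), 200)
  pairs3 <- pairs; pairs3$exon_len[1] <- NA
  expect_warning(simulate_null_distribution(pairs3, n_reps = 2, seed = 5),
                 "skipped")
})

test_that("excess test has identity, scale and pooling behavior", {
  obs <- structure(list(bin_edges = seq(0, 1, 0.1),
                        counts = c(30, 25, 20, 18, 15, 14, 16, 19, 22, 28)),
                   class = "order_distribution")
  expect_equal(excess_test(obs, obs)$statistic, 0)
  expect_equal(excess_test(obs, obs)$p_value, 1)
  # doubling both histograms doubles the Pearson statistic
  sim <- structure(list(bin_edges = seq(0, 1, 0.1),
                        counts = c(20, 22, 24, 20, 18, 18, 20, 22, 21, 22)),
                   class = "order_distribution")
  t1 <- excess_test(obs, sim)
  obs2 <- obs; obs2$counts <- obs$counts * 2
  sim2 <- sim; sim2$counts <- sim$counts * 2
  t2 <- excess_test(obs2, sim2)
  expect_equal(t2$statistic, 2 * t1$statistic, tolerance = 1e-10)
  # sparse expected cells are pooled, reducing df
  sim_sparse <- sim
  sim_sparse$counts <- c(0.1, 0.1, 40, 40, 40, 40, 40, 40, 0.1, 0.1)
  tp <- excess_test(obs, sim_sparse)
  expect_lt(tp$df, length(obs$counts) - 1)
  expect_true(all(tp$expected_pooled >= 5))
  # mismatched bin edges refuse to compare
  bad <- structure(list(bin_edges = seq(0, 1, 0.05), counts = rep(10, 20)),
                   class = "order_distribution")
  expect_error(excess_test(obs, bad), "bin edges")
  # first/last-bin excess is observed minus scaled expected
  expect_equal(t1$first_bin_excess,
               obs$counts[1] - sim$counts[1] / sum(sim$counts) * sum(obs$counts))
})

test_that("steady-state intermediate ratio follows the square law", {
  expect_equal(steady_state_intermediate_ratio(0.2, 0.2), 1)
  expect_equal(steady_state_intermediate_ratio(0.2, 0.1), 4)
  expect_equal(steady_state_intermediate_ratio(0.1, 0.2), 0.25)
  # reciprocity
  expect_equal(steady_state_intermediate_ratio(0.3, 0.12),
               1 / steady_state_intermediate_ratio(0.12, 0.3))
  # forward integration of the two-intron scheme to steady state:
  # P -> I1 (k1), P -> I2 (k2), I1 -> M (k2), I2 -> M (k1), synthesis s
  k1 <- 0.2; k2 <- 0.1; s <- 1
  deriv <- function(t, y, parms) {
    list(c(s - (k1 + k2) * y[1],
           k1 * y[1] - k2 * y[2],
           k2 * y[1] - k1 * y[3]))
  }
  out <- deSolve::ode(c(P = 0, I1 = 0, I2 = 0), seq(0, 500, 10), deriv, NULL)
  fin <- out[nrow(out), ]
  expect_equal(unname(fin["I1"] / fin["I2"]),
               steady_state_intermediate_ratio(k1, k2), tolerance = 1e-3)
})

test_that("parameter sweep is seed-consistent and shows the transcription-rate effect", {
  set.seed(8)
  co <- generate_cohort(300, seed = 88)
  cc <- co$counts
  obs <- bin_distribution(cc$fraction_downstream_first, 20)
  grid <- data.frame(txn_rate = c(1.9, 3.87, 7.7))
  sw <- parameter_sweep(co$pairs, obs, grid, n_reps = 5, seed = 10)
  expect_equal(nrow(sw), 3)
  # upstream-first bias decreases (downstream-first mean rises) with txn rate
  expect_true(all(diff(sw$mean_fraction_downstream_first) > 0))
  # a single-point grid reproduces the same simulation for the derived seed
  one <- parameter_sweep(co$pairs, obs, data.frame(txn_rate = 3.87),
                         n_reps = 5, seed = 10)
  direct <- simulate_null_distribution(co$pairs, kinetic_params(),
                                       n_reps = 5,
                                       seed = spliceorder:::derive_seed(10, 1))
  expect_equal(attr(one, "distributions")[[1]]$counts, direct$counts)
})
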