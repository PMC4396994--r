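test_that("parameter validation enforces the model constraints", {
  expect_error(demographic_params(theta = 0, tau_d = 1), "theta")
  expect_error(demographic_params(theta = 1, rho = -1), "rho")
  expect_error(demographic_params(theta = 1, tau_d = 0.5, tau_m = 0.6),
               "tau_m <= tau_d")
  expect_error(demographic_params(theta = 1, lam = 2), "lam")
  expect_error(demographic_params(theta = 1, n1 = 0), "n1")
})

test_that("batches are deterministic and order-independent per seed", {
  p <- demographic_params(theta = 10, rho = 5, tau_d = 0.5,
                          tau_m = 0.05, lam = 0.05, n1 = 4, n2 = 4)
  b1 <- simulate_batch(p, 20, seed = 99)
  b2 <- simulate_batch(p, 20, seed = 99)
  expect_identical(lapply(b1, function(w) w$window$seqs),
                   lapply(b2, function(w) w$window$seqs))
  # a longer batch reproduces the shorter one's windows exactly
  b3 <- simulate_batch(p, 30, seed = 99)
  expect_identical(b1[[7]]$window$seqs, b3[[7]]$window$seqs)
  expect_identical(batch_stats(b1), batch_stats(b2))
})

test_that("panmictic segregating sites match the Watterson expectation", {
  # E[S] = theta * H_{n-1}, within 2 Monte-Carlo standard errors
  for (cfg in list(list(n1 = 1, n2 = 1, theta = 10),
                   list(n1 = 1, n2 = 1, theta = 150),
                   list(n1 = 5, n2 = 5, theta = 10),
                   list(n1 = 5, n2 = 5, theta = 150))) {
    p <- demographic_params(theta = cfg$theta, tau_d = 0,
                            n1 = cfg$n1, n2 = cfg$n2)
    st <- simulate_stats(p, 3000, seed = 11)
    expected <- cfg$theta * sum(1 / seq_len(cfg$n1 + cfg$n2 - 1))
    se <- sd(st$n_segsites) / sqrt(nrow(st))
    expect_lt(abs(mean(st$n_segsites) - expected), 2 * se)
  }
})

test_that("pairwise diversity equals theta for a panmictic pair", {
  p <- demographic_params(theta = 7, tau_d = 0, n1 = 1, n2 = 1)
  st <- simulate_stats(p, 4000, seed = 5)
  se <- sd(st$mean_dxy) / sqrt(nrow(st))
  expect_lt(abs(mean(st$mean_dxy) - 7), 2 * se)
})

test_that("no pulse means no migrant genealogies", {
  p <- demographic_params(theta = 5, tau_d = 0.5, lam = 0,
                          n1 = 5, n2 = 5)
  st <- simulate_stats(p, 500, seed = 3)
  expect_false(any(st$migrant_flag))
  # pulse scheduled at the divergence time itself is a no-op
  p2 <- demographic_params(theta = 5, tau_d = 0.5, tau_m = 0.5,
                           lam = 1, n1 = 5, n2 = 5)
  st2 <- simulate_stats(p2, 200, seed = 3)
  expect_false(any(st2$migrant_flag))
})

test_that("migrant-flag frequency matches the lineage-count oracle", {
  # without recombination, P(flag) = 1 - E[(1-lam)^K] where K is the
  # number of population-1 lineages at the pulse, a pure-death chain
  lam <- 0.05; tau_d <- 0.5; tau_m <- tau_d / 2; n1 <- 10
  p <- demographic_params(theta = 5, rho = 0, tau_d = tau_d,
                          tau_m = tau_m, lam = lam, n1 = n1, n2 = 5)
  st <- simulate_stats(p, 3000, seed = 17)
  set.seed(18)
  K <- lineage_count_at(n1, tau_m / 4, 30000)
  p_oracle <- 1 - mean((1 - lam)^K)
  p_hat <- mean(st$migrant_flag)
  se <- sqrt(p_hat * (1 - p_hat) / nrow(st) +
             var((1 - lam)^K) / length(K))
  expect_lt(abs(p_hat - p_oracle), 3 * se)
})

test_that("migrant-flag frequency is monotone in the migration probability", {
  lams <- c(0.001, 0.005, 0.01, 0.05, 0.1)
  freq <- vapply(seq_along(lams), function(i) {
    p <- demographic_params(theta = 5, tau_d = 0.5, tau_m = 0.05,
                            lam = lams[i], n1 = 10, n2 = 5)
    mean(simulate_stats(p, 1500, seed = 40 + i)$migrant_flag)
  }, numeric(1))
  expect_true(all(diff(freq) >= 0))
})

test_that("a full pulse at time ~0 makes population 1 panmictic with 2", {
  # lam = 1 with tau_m -> 0: the recipient samples become
  # indistinguishable from extra source-population samples
  p_pulse <- demographic_params(theta = 10, tau_d = 2, tau_m = 1e-9,
                                lam = 1, n1 = 5, n2 = 5)
  p_pan <- demographic_params(theta = 10, tau_d = 0, n1 = 5, n2 = 5)
  d_pulse <- simulate_stats(p_pulse, 1500, seed = 21)$mean_dxy
  d_pan <- simulate_stats(p_pan, 1500, seed = 22)$mean_dxy
  ks <- suppressWarnings(stats::ks.test(d_pulse, d_pan))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated S and pi distributions match msprime under panmixia", {
  n <- 10; theta <- 10; reps <- 4000
  p <- demographic_params(theta = theta, tau_d = 0, n1 = 5, n2 = 5)
  st <- simulate_stats(p, reps, seed = 31)
  ora <- msprime_s_pi(n, theta, reps, seed = 32)
  ks_s <- suppressWarnings(stats::ks.test(st$n_segsites, ora$S))
  expect_gt(ks_s$p.value, 0.01)
  pi_ours <- (st$mean_dxy * 25 + st$mean_dxx * 10 + st$mean_dyy * 10) / 45
  ks_pi <- suppressWarnings(stats::ks.test(pi_ours, ora$pi))
  expect_gt(ks_pi$p.value, 0.01)
})

test_that("mean gmin shows the documented parameter responses", {
  mc <- function(theta, tau_d, n2, seed)
    expected_gmin_mc(demographic_params(theta = theta, tau_d = tau_d,
                                        n1 = 10, n2 = n2),
                     800, seed)$mean_gmin
  # deep divergence pushes gmin towards unity
  expect_lt(mc(100, 0.04, 10, 51), mc(100, 8, 10, 52))
  # low-mutation downward bias
  expect_lt(mc(10, 1, 10, 53), mc(150, 1, 10, 54))
  # single source sequence sits closer to unity
  expect_gt(mc(100, 1, 1, 55), mc(100, 1, 10, 56))
})

test_that("expected_gmin_mc reports undefined windows", {
  # near-zero mutation rate: most windows carry no variation at all
  p <- demographic_params(theta = 0.01, tau_d = 0.1, n1 = 2, n2 = 2)
  r <- expected_gmin_mc(p, 200, seed = 8)
  expect_gt(r$n_undefined, 0)
  expect_equal(r$n_defined + r$n_undefined, 200)
})

test_that("ms-style dump has the expected block structure", {
  p <- demographic_params(theta = 5, tau_d = 0.2, n1 = 3, n2 = 2)
  b <- simulate_batch(p, 4, seed = 77)
  f <- tempfile()
  write_ms(b, f)
  lines <- readLines(f)
  expect_equal(sum(lines == "//"), 4)
  seg <- as.integer(sub("segsites: ", "", grep("^segsites:", lines,
                                               value = TRUE)))
  expect_equal(seg, vapply(b, function(w) w$n_segsites, integer(1)))
})
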