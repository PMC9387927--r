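test_that("strict diagonal networks are fully paired and shared best prey breaks pairing", {
  expect_true(ktw_pairing(eco_diagonal())$fully_paired)

  # two phages whose strongest link lands on the same bacterium
  eco <- ecosystem(
    data.frame(id = c("b1", "b2"), k = c(0.8, 0.5)),
    data.frame(id = c("p1", "p2"), beta = c(10, 10)),
    matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2))  # both strongest on b1
  rep <- ktw_pairing(eco)
  expect_false(rep$fully_paired)

  # one phage-free bacterium outside the matching is allowed (N = M + 1)
  eco2 <- ecosystem(
    data.frame(id = c("b1", "b2"), k = c(0.8, 0.5)),
    data.frame(id = "p1", beta = 10),
    matrix(c(0.5, 0), 1, 2))
  expect_true(ktw_pairing(eco2)$fully_paired)

  # a bacterium with predators that is nobody's best prey breaks pairing
  eco3 <- ecosystem(
    data.frame(id = c("b1", "b2"), k = c(0.8, 0.5)),
    data.frame(id = "p1", beta = 10),
    matrix(c(0.5, 0.2), 1, 2))
  expect_false(ktw_pairing(eco3)$fully_paired)
})

test_that("pairing is invariant under strain relabeling and reordering", {
  h <- cached_history("R", 0.5, 200, 21)
  comms <- harvest_communities(list(h), min_p = 1, limit = 30)
  set.seed(13)
  for (cm in comms) {
    eco <- cm$eco
    before <- ktw_pairing(eco)$fully_paired
    pb <- sample(nrow(eco$bacteria))
    pp <- sample(nrow(eco$phages))
    eco2 <- eco
    eco2$bacteria <- eco$bacteria[pb, , drop = FALSE]
    eco2$phages <- eco$phages[pp, , drop = FALSE]
    eco2$eta <- eco$eta[pp, pb, drop = FALSE]
    rownames(eco2$bacteria) <- rownames(eco2$phages) <- NULL
    expect_identical(ktw_pairing(eco2)$fully_paired, before)
  }
})

test_that("purely diagonal assembly (p = 0) is always fully paired", {
  expect_equal(ktw_fraction(cached_histories("R", 0, 150, 31)), 1.0)
})

test_that("growth-rate profile puts occupancy mass in the right bins and normalizes entries", {
  h1 <- run_assembly(assembly_config("R", 0, 1, seed = 2))
  prof1 <- growth_rate_profile(h1)
  k0 <- h1$events[[1]]$post_eco$bacteria$k[1]
  bin <- findInterval(k0, prof1$bin_edges)
  occupied <- which(prof1$N_B > 0)
  expect_true(bin %in% occupied)
  expect_equal(sum(prof1$N_B), mean(vapply(h1$events, function(e)
    nrow(e$post_eco$bacteria), integer(1))))

  prof <- growth_rate_profile(cached_history("R", 0.2, 200, 1))
  expect_equal(sum(prof$p_entry) * 0.1, 1, tolerance = 1e-12)
  # profile conservation: total occupancy equals average bacterial count
  s <- history_summary(cached_history("R", 0.2, 200, 1))
  expect_equal(sum(prof$N_B), mean(s$n_bacteria), tolerance = 1e-12)
})

test_that("occupancy and entry both favour fast growers in evolved communities", {
  prof <- growth_rate_profile(cached_histories("R", 0.2, 400, 44:47))
  hi <- prof$bin_mid > 0.7
  lo <- prof$bin_mid < 0.3
  expect_gt(mean(prof$N_B[hi]), mean(prof$N_B[lo]))
  expect_gt(mean(prof$p_entry[hi]), mean(prof$p_entry[lo]))
})

test_that("elimination-factor fit recovers synthetic exponential profiles", {
  mids <- seq(0.05, 0.95, by = 0.1)
  prof <- structure(list(bin_edges = seq(0, 1, 0.1), bin_mid = mids,
                         N_B = 3 * exp(mids / 0.2),
                         p_entry = rep(1, 10), n_steps = 1, n_entries = 10),
                    class = "growth_rate_profile")
  expect_equal(elimination_factor(prof)$E, 0.2, tolerance = 1e-10)

  # multiplicative lognormal noise: recovery within 10%
  set.seed(14)
  ok <- replicate(20, {
    noisy <- prof
    noisy$N_B <- noisy$N_B * exp(rnorm(10, 0, 0.1))
    abs(elimination_factor(noisy)$E - 0.2) / 0.2 < 0.1
  })
  expect_gte(mean(ok), 0.9)

  # flat profile: unbounded fit flagged
  flat <- prof
  flat$N_B <- rep(2, 10)
  ef <- elimination_factor(flat)
  expect_true(ef$flat)
  expect_identical(ef$E, Inf)

  # too few positive bins in the window is an error
  sparse <- prof
  sparse$N_B[prof$bin_mid >= 0.3 & prof$bin_mid <= 0.9] <- 0
  sparse$N_B[4] <- 1
  expect_error(elimination_factor(sparse), class = "ktwsim_invalid_input")
})

test_that("entry-advantage fit recovers its generator and vanishes for flat entry", {
  mids <- seq(0.05, 0.95, by = 0.1)
  s <- 3.2
  prof <- structure(list(bin_edges = seq(0, 1, 0.1), bin_mid = mids,
                         N_B = rep(1, 10), p_entry = 0.4 * exp(s * mids),
                         n_steps = 1, n_entries = 100),
                    class = "growth_rate_profile")
  fit <- entry_advantage(prof)
  expect_equal(fit$slope, s, tolerance = 1e-10)
  expect_equal(fit$G_A, s / (0.4 * exp(s * 0.3) * 0.1), tolerance = 1e-8)

  flat <- prof
  flat$p_entry <- rep(1, 10)
  expect_equal(entry_advantage(flat)$G_A, 0, tolerance = 1e-10)
})

test_that("diversity statistics aggregate sensibly and fall with cross-linking", {
  hs <- c(cached_histories("R", 0, 150, 31:32),
          cached_histories("R", 0.2, 200, 1:2),
          cached_histories("R", 1.0, 150, 3:4))
  ds <- diversity_stats(hs)
  expect_true(all(ds$max_diversity >= ds$avg_diversity))
  ds <- ds[order(ds$p), ]
  expect_true(all(diff(ds$avg_diversity) < 0))
})

test_that("resistant-invader fraction is 1 in model N and 0 at full connectivity", {
  expect_equal(resistant_invader_fraction(cached_history("N", 0.3, 400, 41)), 1)
  expect_equal(resistant_invader_fraction(cached_histories("R", 1.0, 150, 3:4)), 0)
})
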