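test_that("derivatives vanish at closed-form fixed points and respect absorbing zero", {
  # single bacterium at B* = 1 - alpha/k
  d <- glv_derivatives(eco_single(k = 0.5), community_state(B = 0.8))
  expect_equal(d$dB, 0, tolerance = 1e-15)

  # extinction is absorbing
  d0 <- glv_derivatives(eco_single(k = 0.5), community_state(B = 0))
  expect_identical(d0$dB, 0)

  # bacterium-phage pair at B* = delta/(beta eta), P* = (k(1-B*) - alpha)/eta
  d2 <- glv_derivatives(eco_pair(), community_state(B = 0.2, P = 0.6))
  expect_equal(max(abs(c(d2$dB, d2$dP))), 0, tolerance = 1e-15)

  # dimension mismatch is rejected
  expect_error(glv_derivatives(eco_single(), community_state(B = c(0.1, 0.2))),
               class = "ktwsim_invalid_input")
})

test_that("linear solver reproduces closed-form steady states", {
  ss <- solve_steady_state(eco_single(k = 0.5))
  expect_true(ss$feasible)
  expect_equal(ss$state$B, 0.8, tolerance = 1e-12)

  ss2 <- solve_steady_state(eco_pair(k = 0.5, beta = 10, eta = 0.5))
  expect_true(ss2$feasible)
  expect_equal(ss2$state$B, 0.2, tolerance = 1e-12)
  expect_equal(ss2$state$P, 0.6, tolerance = 1e-12)
})

test_that("competitive exclusion makes over-diverse systems infeasible", {
  # two bacteria sharing one resource cannot coexist
  expect_false(solve_steady_state(eco_two_bacteria())$feasible)

  set.seed(11)
  for (i in 1:20) {
    # more phages than bacteria: phage rows are linearly dependent
    n <- sample(1:3, 1)
    m <- n + sample(1:2, 1)
    eco <- ecosystem(
      data.frame(id = paste0("b", 1:n), k = runif(n, 0.2, 1)),
      data.frame(id = paste0("p", 1:m), beta = runif(m, 1, 50)),
      matrix(runif(m * n, 0.05, 0.95), m, n))
    res <- solve_steady_state(eco)
    expect_false(res$feasible)

    # N >= M + 2 bacteria on one shared resource: bacterial rows dependent
    n2 <- sample(3:5, 1)
    m2 <- n2 - 2
    eco2 <- ecosystem(
      data.frame(id = paste0("b", 1:n2), k = runif(n2, 0.2, 1)),
      if (m2 > 0) data.frame(id = paste0("p", 1:m2), beta = runif(m2, 1, 50)),
      if (m2 > 0) matrix(runif(m2 * n2, 0.05, 0.95), m2, n2))
    expect_false(solve_steady_state(eco2)$feasible)
  }
})

test_that("feasible steady states are genuine fixed points of the dynamics", {
  histories <- cached_histories("R", 0.2, 200, 1:2)
  comms <- harvest_communities(histories, limit = 100)
  for (cm in comms) {
    d <- glv_derivatives(cm$eco, cm$state)
    expect_lt(max(abs(c(d$dB, d$dP, 0))), 1e-9)
    expect_true(all(c(cm$state$B, cm$state$P) > 0))
  }
})

test_that("extinction integration removes the dynamically doomed strain", {
  # competitive exclusion: the slower grower dies
  out <- integrate_until_extinction(eco_two_bacteria(k1 = 0.8, k2 = 0.3),
                                    community_state(B = c(0.5, 0.5)))
  expect_identical(out$extinct_id, "b2")
  expect_true(all(c(out$state$B, out$state$P) >= 0))

  # negative net growth: a lone bacterium with k < alpha dies out
  eco <- ecosystem(data.frame(id = "b1", k = 0.05),
                   rates = global_rates(alpha = 0.1))
  out2 <- integrate_until_extinction(eco, community_state(B = 0.5))
  expect_identical(out2$extinct_id, "b1")

  # eliminate-the-winner triplet: parameters in the slow-grower-wins region,
  # started near the fast-grower/phage steady state, lose the fast grower
  trip <- ecosystem(
    bacteria = data.frame(id = c("S", "R"), k = c(0.8, 0.4)),
    phages = data.frame(id = "P", beta = 20),
    eta = matrix(c(0.8, 0.1), 1, 2))
  init <- community_state(B = c(0.0625, 1e-6), P = 0.8125)
  out3 <- integrate_until_extinction(trip, init)
  expect_identical(out3$extinct_id, "S")

  # a feasible system never crosses the threshold: non-convergence signal
  expect_error(
    integrate_until_extinction(eco_single(), community_state(B = 0.8),
                               t_max = 50),
    class = "ktwsim_nonconvergence")
})

test_that("resolution loop is a no-op on feasible systems and prunes infeasible ones", {
  eco <- eco_pair()
  st <- solve_steady_state(eco)$state
  res <- resolve_after_perturbation(eco, st)
  expect_identical(res$extinct_ids, character(0))
  expect_equal(res$state$B, st$B, tolerance = 1e-12)

  res2 <- resolve_after_perturbation(eco_two_bacteria(),
                                     community_state(B = c(0.5, 0.5)))
  expect_identical(res2$extinct_ids, "b2")
  expect_identical(res2$eco$bacteria$id, "b1")
  expect_equal(res2$state$B, 1 - 0.1 / 0.8, tolerance = 1e-10)

  # a hopeless invader (k < alpha, no phage relief) dies; residents persist
  resident <- eco_pair(k = 0.5, beta = 10, eta = 0.5)
  st0 <- solve_steady_state(resident)$state
  invaded <- ktwsim:::add_bacterium(resident, "b2", 0.05, 1L, numeric(1))
  res3 <- resolve_after_perturbation(
    invaded, community_state(c(st0$B, 1e-6), st0$P))
  expect_identical(res3$extinct_ids, "b2")
  expect_equal(res3$state$B, st0$B, tolerance = 1e-8)
  expect_equal(res3$state$P, st0$P, tolerance = 1e-8)

  # orphaned phages are removed with their last host
  eco4 <- ecosystem(
    data.frame(id = c("b1", "b2"), k = c(0.8, 0.05)),
    data.frame(id = "p1", beta = 10),
    matrix(c(0, 0.5), 1, 2))  # p1 only infects the doomed b2
  res4 <- resolve_after_perturbation(eco4,
                                     community_state(B = c(0.5, 1e-6), P = 0.1))
  expect_setequal(res4$extinct_ids, c("b2", "p1"))
  expect_identical(res4$eco$bacteria$id, "b1")
  expect_identical(nrow(res4$eco$phages), 0L)
})

test_that("long independent integration converges to the linear steady state", {
  skip_if_not_installed("deSolve")
  histories <- cached_histories("R", 0.2, 200, 1:2)
  comms <- harvest_communities(histories, max_b = 4, max_p = 4, min_p = 1,
                               limit = 40)
  expect_gte(length(comms), 20)
  set.seed(99)
  for (cm in comms) {
    ss <- solve_steady_state(cm$eco)
    expect_true(ss$feasible)
    target <- c(ss$state$B, ss$state$P)
    state <- community_state(
      ss$state$B * runif(length(ss$state$B), 0.9, 1.1),
      ss$state$P * runif(length(ss$state$P), 0.9, 1.1))
    # integrate in escalating chunks until the trajectory has settled;
    # weakly damped predator-prey spirals can relax very slowly
    for (t_chunk in c(5e3, rep(1e5, 8))) {
      fin <- oracle_integrate(cm$eco, state, t_end = t_chunk)
      n <- length(state$B)
      state <- community_state(pmax(fin[seq_len(n)], 0),
                               pmax(fin[-seq_len(n)], 0))
      if (max(abs(fin - target)) < 1e-6) break
    }
    expect_lt(max(abs(fin - target)), 1e-6)
  }
})

test_that("package resolution agrees with an independent lsodar resolution", {
  skip_if_not_installed("deSolve")
  # perturbed (infeasible) systems drawn from assembly snapshots, including
  # fully connected ones; both resolution routes must keep the same survivors
  histories <- c(cached_histories("R", 0.2, 200, 1:2),
                 cached_histories("R", 1.0, 150, 3:4))
  set.seed(7)
  cases <- 0L
  agree <- 0L
  for (h in histories) {
    for (ev in h$events) {
      if (cases >= 25L) break
      if (ev$discarded || ev$non_convergence) next
      if (length(ev$extinct_ids) == 0) next
      eco <- ev$pre_eco
      st <- ev$pre_state
      if (ev$invader_kind == "bacterium") {
        eco2 <- ktwsim:::add_bacterium(eco, ev$invader_id, ev$invader$k,
                                       ev$step, unname(ev$invader$links))
        init2 <- community_state(c(st$B, 1e-6), st$P)
      } else {
        eco2 <- ktwsim:::add_phage(eco, ev$invader_id, ev$invader$beta,
                                   ev$step, unname(ev$invader$links))
        init2 <- community_state(st$B, c(st$P, 1e-6))
      }
      mine <- resolve_after_perturbation(eco2, init2)
      ora <- oracle_resolve_survivors(eco2, init2)
      cases <- cases + 1L
      if (setequal(c(mine$eco$bacteria$id, mine$eco$phages$id), ora))
        agree <- agree + 1L
    }
  }
  expect_gte(cases, 20L)
  expect_gte(agree / cases, 0.9)
})

test_that("ecosystem JSON snapshots round-trip losslessly", {
  h <- cached_history("R", 0.3, 120, 5)
  ev <- h$events[[length(h$events)]]
  json <- ecosystem_to_json(ev$post_eco, ev$post_state)
  back <- ecosystem_from_json(json)
  expect_equal(back$eco$bacteria, ev$post_eco$bacteria, tolerance = 0)
  expect_equal(back$eco$phages, ev$post_eco$phages, tolerance = 0)
  expect_equal(back$eco$eta, ev$post_eco$eta, tolerance = 0)
  expect_equal(back$state$B, ev$post_state$B, tolerance = 0)
  expect_equal(back$state$P, ev$post_state$P, tolerance = 0)
  expect_equal(back$eco$rates$alpha, 0.1)

  # phage-free community round-trips too
  json2 <- ecosystem_to_json(eco_single())
  expect_identical(ecosystem_from_json(json2)$eco$bacteria$k, 0.5)
})

test_that("ecosystem validation rejects malformed communities", {
  expect_error(ecosystem(data.frame(id = "b1", k = 1.5)),
               class = "ktwsim_invalid_input")
  expect_error(ecosystem(data.frame(id = "b1", k = 0.5),
                         data.frame(id = "p1", beta = 100),
                         matrix(0.5, 1, 1)),
               class = "ktwsim_invalid_input")
  # a phage with no host is not a valid resident
  expect_error(ecosystem(data.frame(id = "b1", k = 0.5),
                         data.frame(id = "p1", beta = 10),
                         matrix(0, 1, 1)),
               class = "ktwsim_invalid_input")
})
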