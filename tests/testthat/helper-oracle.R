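# independent numerical-integration oracle based on deSolve (lsoda/lsodar);
# the package's own integrator is classical RK4, so agreement between the two
# is a genuine cross-check

oracle_rhs <- function(t, y, parms) {
  n <- parms$n; m <- parms$m
  B <- y[seq_len(n)]
  P <- if (m > 0) y[n + seq_len(m)] else numeric(0)
  tot <- sum(B)
  press <- if (m > 0) as.numeric(crossprod(parms$eta, P)) else numeric(n)
  dB <- B * (parms$k * (1 - tot) - parms$alpha - press)
  dP <- if (m > 0) P * (parms$beta * as.numeric(parms$eta %*% B) - parms$delta)
        else numeric(0)
  list(c(dB, dP))
}

oracle_parms <- function(eco) {
  list(n = n_bacteria(eco), m = n_phages(eco), k = eco$bacteria$k,
       beta = eco$phages$beta, eta = eco$eta,
       alpha = eco$rates$alpha, delta = eco$rates$delta)
}

# integrate to t_end and return the final state vector c(B, P); times are
# chunked so lsoda's per-interval step budget is not exhausted on long spans
oracle_integrate <- function(eco, init, t_end, rtol = 1e-10, atol = 1e-13) {
  sol <- suppressWarnings(
    deSolve::ode(y = c(init$B, init$P), times = seq(0, t_end, length.out = 21),
                 func = oracle_rhs, parms = oracle_parms(eco),
                 method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = 500000))
  unname(sol[nrow(sol), -1])
}

# independent resolution loop: linear feasibility + lsodar root-finding on
# the extinction threshold; returns the surviving strain ids
oracle_resolve_survivors <- function(eco, init, threshold = 1e-20,
                                     t_chunk = 1e6) {
  repeat {
    if (n_phages(eco) > 0) {
      orphan <- rowSums(eco$eta > 0) == 0
      if (any(orphan)) {
        init$P <- init$P[!orphan]
        eco <- ktwsim:::drop_strains(eco, phage_ids = eco$phages$id[orphan])
      }
    }
    if (n_bacteria(eco) == 0L) return(character(0))
    if (solve_steady_state(eco)$feasible)
      return(c(eco$bacteria$id, eco$phages$id))
    root <- function(t, y, parms) min(y) - threshold
    sol <- suppressWarnings(
      deSolve::ode(y = c(init$B, init$P),
                   times = seq(0, t_chunk, length.out = 101),
                   func = oracle_rhs, parms = oracle_parms(eco),
                   method = "lsodar", rootfunc = root,
                   rtol = 1e-10, atol = 1e-25, maxsteps = 50000))
    y <- unname(sol[nrow(sol), -1])
    idx <- which.min(y)
    n <- n_bacteria(eco)
    if (idx <= n) {
      init <- community_state(pmax(y[seq_len(n)][-idx], 0),
                              pmax(y[-seq_len(n)], 0))
      eco <- ktwsim:::drop_strains(eco, bact_ids = eco$bacteria$id[idx])
    } else {
      pidx <- idx - n
      init <- community_state(pmax(y[seq_len(n)], 0),
                              pmax(y[-seq_len(n)][-pidx], 0))
      eco <- ktwsim:::drop_strains(eco, phage_ids = eco$phages$id[pidx])
    }
  }
}

# asymptotic outcome of a triplet system by long integration from random
# positive initial conditions; returns an outcome label or NA when the
# initial conditions disagree or the survivor set is uninterpretable.
# Integration is done in log-density space: per-capita rates are smooth and
# bounded, so transient crashes to astronomically small densities (which
# underflow and stall a linear-space solver) become mild linear decay.
oracle_triplet_rhs_log <- function(t, z, parms) {
  y <- exp(pmin(z, 50))
  B <- y[1:2]; P <- y[3]
  list(c(parms$k * (1 - sum(B)) - parms$alpha - parms$eta * P,
         parms$beta * sum(parms$eta * B) - parms$delta))
}

oracle_triplet_outcome <- function(ts, n_init = 3, t_end = 2e4,
                                   surv_tol = 1e-6) {
  parms <- list(k = c(ts$k_S, ts$k_R), eta = c(ts$eta_S, ts$eta_R),
                beta = ts$beta, alpha = ts$rates$alpha,
                delta = ts$rates$delta)
  labels <- vapply(seq_len(n_init), function(i) {
    y0 <- c(runif(2, 0.05, 0.6), runif(1, 0.05, 0.6))
    sol <- suppressWarnings(
      deSolve::ode(y = log(y0), times = seq(0, t_end, length.out = 11),
                   func = oracle_triplet_rhs_log, parms = parms,
                   method = "lsoda", rtol = 1e-6, atol = 1e-6,
                   maxsteps = 50000))
    fin <- exp(unname(sol[nrow(sol), -1]))
    surv <- fin > surv_tol
    if (identical(surv, c(TRUE, TRUE, TRUE))) "COEXIST"
    else if (identical(surv, c(TRUE, FALSE, TRUE))) "S_EXCLUDES_R"
    else if (identical(surv, c(FALSE, TRUE, TRUE))) "R_EXCLUDES_S"
    else if (identical(surv, c(TRUE, FALSE, FALSE))) "PHAGE_LOST"
    else NA_character_
  }, character(1))
  if (anyNA(labels) || length(unique(labels)) != 1L) return(NA_character_)
  labels[1]
}

# draw a random triplet system away from the analytic outcome boundaries
random_triplet <- function(margin_min = 1e-3, rates = global_rates()) {
  repeat {
    ks <- sort(runif(2, rates$alpha + 0.02, 1))
    es <- runif(2, 0.01, 0.99)
    ts <- triplet_system(k_S = ks[2], k_R = ks[1], eta_S = es[1],
                         eta_R = es[2], beta = runif(1, 1, 50),
                         rates = rates)
    cl <- classify_triplet(ts)
    if (cl$margin > margin_min) return(list(ts = ts, outcome = cl$outcome))
  }
}
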