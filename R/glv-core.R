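#' Global community rates
#'
#' Rates shared by every strain, in units of the maximal possible bacterial
#' growth rate: `alpha` is the universal bacterial death rate (e.g. protist
#' grazing) and `delta` the phage decay rate.
#'
#' @param alpha Universal bacterial death rate, `alpha >= 0`. Default 0.1.
#' @param delta Phage decay rate, `delta > 0`. Default 1.
#' @return An object of class `global_rates`.
#' @export
#' @examples
#' global_rates()
global_rates <- function(alpha = 0.1, delta = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop_invalid("`alpha` must be a single non-negative number")
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta <= 0)
    stop_invalid("`delta` must be a single positive number")
  structure(list(alpha = as.numeric(alpha), delta = as.numeric(delta)),
            class = "global_rates")
}

#' Construct a phage-bacteria ecosystem
#'
#' An ecosystem is the full parameterization of a resident community: the
#' bacterial strains (growth rates `k`), phage strains (burst sizes `beta`),
#' the infection-rate matrix `eta` (phage-major, `M x N`, entries in `[0, 1)`
#' with exact zeros marking absent links), and the global rates. Bacterial
#' competition coefficients are identically 1 (one fully shared resource), so
#' they are not stored.
#'
#' @param bacteria A data.frame with columns `id` (character, unique), `k`
#'   (growth rate in `(0, 1]`) and optionally `birth_step`.
#' @param phages A data.frame with columns `id`, `beta` (burst size in
#'   `[1, 50]`) and optionally `birth_step`, or `NULL` for a phage-free
#'   community.
#' @param eta Numeric matrix of infection rates with one row per phage and one
#'   column per bacterium. Every phage row must contain at least one strictly
#'   positive entry (a phage with no host cannot be a resident).
#' @param rates A [global_rates()] object.
#' @return An object of class `ecosystem`.
#' @export
#' @examples
#' eco <- ecosystem(
#'   bacteria = data.frame(id = "b1", k = 0.5),
#'   phages   = data.frame(id = "p1", beta = 10),
#'   eta      = matrix(0.5, 1, 1)
#' )
#' eco
ecosystem <- function(bacteria, phages = NULL, eta = NULL,
                      rates = global_rates()) {
  bacteria <- as.data.frame(bacteria)
  if (is.null(bacteria$birth_step)) bacteria$birth_step <- 0L
  bacteria$id <- as.character(bacteria$id)
  if (is.null(phages) || nrow(as.data.frame(phages)) == 0L) {
    phages <- data.frame(id = character(0), beta = numeric(0),
                         birth_step = integer(0))
  } else {
    phages <- as.data.frame(phages)
    if (is.null(phages$birth_step)) phages$birth_step <- 0L
    phages$id <- as.character(phages$id)
  }
  if (is.null(eta)) eta <- matrix(numeric(0), nrow = 0, ncol = nrow(bacteria))
  eta <- as.matrix(eta)
  storage.mode(eta) <- "double"
  eco <- structure(list(bacteria = bacteria, phages = phages, eta = eta,
                        rates = rates),
                   class = "ecosystem")
  validate_ecosystem(eco)
  eco
}

#' Validate an ecosystem object
#'
#' Checks dimensions, parameter ranges (`0 < k <= 1`, `1 <= beta <= 50`,
#' `eta` in `[0, 1)`), uniqueness of strain ids, and that every phage has at
#' least one host.
#'
#' @param eco An [ecosystem()] object.
#' @return `eco`, invisibly. Signals a `ktwsim_invalid_input` error otherwise.
#' @export
validate_ecosystem <- function(eco) {
  if (!inherits(eco, "ecosystem")) stop_invalid("not an `ecosystem` object")
  n <- nrow(eco$bacteria)
  m <- nrow(eco$phages)
  if (anyDuplicated(c(eco$bacteria$id, eco$phages$id)))
    stop_invalid("strain ids must be unique")
  if (n > 0 && (any(eco$bacteria$k <= 0) || any(eco$bacteria$k > 1)))
    stop_invalid("bacterial growth rates must lie in (0, 1]")
  if (m > 0 && (any(eco$phages$beta < 1) || any(eco$phages$beta > 50)))
    stop_invalid("phage burst sizes must lie in [1, 50]")
  if (!identical(dim(eco$eta), c(m, n)) && !(m == 0 && ncol(eco$eta) == n))
    stop_invalid("`eta` must be an M x N matrix (phage-major)")
  if (length(eco$eta) && (any(eco$eta < 0) || any(eco$eta >= 1)))
    stop_invalid("`eta` entries must lie in [0, 1)")
  if (m > 0 && any(apply(eco$eta > 0, 1, sum) == 0))
    stop_invalid("every phage must infect at least one bacterium")
  invisible(eco)
}

#' @export
print.ecosystem <- function(x, ...) {
  cat(sprintf("<ecosystem> %d bacteria, %d phages (alpha = %g, delta = %g)\n",
              nrow(x$bacteria), nrow(x$phages),
              x$rates$alpha, x$rates$delta))
  invisible(x)
}

#' Number of bacterial / phage strains in an ecosystem
#' @param eco An [ecosystem()] object.
#' @return Integer count.
#' @export
n_bacteria <- function(eco) nrow(eco$bacteria)

#' @rdname n_bacteria
#' @export
n_phages <- function(eco) nrow(eco$phages)

#' Community state
#'
#' Population densities (in units of the environmental carrying capacity) for
#' every resident strain, aligned with the ecosystem's strain ordering.
#'
#' @param B Numeric vector of bacterial densities (all `>= 0`).
#' @param P Numeric vector of phage densities (all `>= 0`).
#' @return An object of class `community_state`.
#' @export
community_state <- function(B, P = numeric(0)) {
  B <- as.numeric(B); P <- as.numeric(P)
  if (any(B < 0) || any(P < 0))
    stop_invalid("densities must be non-negative")
  structure(list(B = B, P = P), class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("<community_state> %d bacteria, %d phages\n",
              length(x$B), length(x$P)))
  invisible(x)
}

check_state_dims <- function(eco, state) {
  if (length(state$B) != n_bacteria(eco) || length(state$P) != n_phages(eco))
    stop_invalid("state dimensions do not match the ecosystem")
}

#' Generalized Lotka-Volterra derivatives
#'
#' Evaluates the right-hand side of the community dynamics
#' \deqn{dB_i/dt = k_i B_i (1 - \sum_j B_j) - \alpha B_i -
#'       B_i \sum_k \eta_{ki} P_k,\qquad
#'       dP_k/dt = P_k \sum_m \beta_k \eta_{km} B_m - \delta P_k.}
#'
#' @param eco An [ecosystem()] object.
#' @param state A [community_state()] matching `eco`.
#' @return A list with numeric vectors `dB` and `dP`.
#' @export
#' @examples
#' eco <- ecosystem(data.frame(id = "b1", k = 0.5))
#' glv_derivatives(eco, community_state(B = 0.8))  # at the fixed point
glv_derivatives <- function(eco, state) {
  check_state_dims(eco, state)
  d <- .glv_rhs_cpp(eco$bacteria$k, eco$rates$alpha, eco$eta,
                    eco$phages$beta, eco$rates$delta, state$B, state$P)
  list(dB = as.numeric(d$dB), dP = as.numeric(d$dP))
}

#' Linear steady-state feasibility solver
#'
#' Solves the linear steady-state equations obtained by dividing each
#' equation by its density: per bacterium
#' \eqn{k_i (1 - \sum_j B_j) - \alpha - \sum_k \eta_{ki} P_k = 0} and per
#' phage \eqn{\beta_k \sum_m \eta_{km} B_m = \delta}. The combined
#' `(N+M) x (N+M)` system is solved directly; the community is *feasible* iff
#' the system is non-degenerate and every solved density is strictly
#' positive. A system is flagged *degenerate* when its reciprocal condition
#' number falls below `1e-12` or a solved density lies in `[0, 1e-12)`.
#'
#' Competitive exclusion appears here as linear degeneracy: with more phages
#' than bacteria the phage rows are dependent, and with `N >= M + 2` bacteria
#' the bacterial rows are dependent (one shared resource), so such systems
#' are never feasible.
#'
#' @param eco An [ecosystem()] object.
#' @return A list of class `steady_state_result` with elements `feasible`,
#'   `degenerate`, and `state` (a [community_state()], only when feasible).
#' @export
#' @examples
#' eco <- ecosystem(data.frame(id = "b1", k = 0.5))
#' solve_steady_state(eco)$state$B  # 1 - alpha/k = 0.8
solve_steady_state <- function(eco) {
  n <- n_bacteria(eco)
  m <- n_phages(eco)
  if (n == 0L && m == 0L) {
    return(structure(list(feasible = TRUE, degenerate = FALSE,
                          state = community_state(numeric(0), numeric(0))),
                     class = "steady_state_result"))
  }
  k <- eco$bacteria$k
  alpha <- eco$rates$alpha
  delta <- eco$rates$delta
  # rows 1..n: bacterium i -> sum_j k_i B_j + sum_l eta_li P_l = k_i - alpha
  # rows n+1..n+m: phage l -> sum_j beta_l eta_lj B_j = delta
  A <- matrix(0, n + m, n + m)
  A[seq_len(n), seq_len(n)] <- matrix(k, n, n)
  if (m > 0) {
    A[seq_len(n), n + seq_len(m)] <- t(eco$eta)
    A[n + seq_len(m), seq_len(n)] <- eco$phages$beta * eco$eta
  }
  b <- c(k - alpha, rep(delta, m))
  rc <- tryCatch(rcond(A), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12) {
    return(structure(list(feasible = FALSE, degenerate = TRUE, state = NULL),
                     class = "steady_state_result"))
  }
  x <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(x)) {
    return(structure(list(feasible = FALSE, degenerate = TRUE, state = NULL),
                     class = "steady_state_result"))
  }
  degenerate <- any(x >= 0 & x < 1e-12)
  feasible <- !degenerate && all(x > 0)
  state <- if (feasible)
    community_state(B = x[seq_len(n)], P = if (m > 0) x[n + seq_len(m)] else numeric(0))
  structure(list(feasible = feasible, degenerate = degenerate, state = state),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("<steady_state_result> feasible = %s, degenerate = %s\n",
              x$feasible, x$degenerate))
  invisible(x)
}

#' Integrate the dynamics until one strain goes extinct
#'
#' Integrates the community dynamics with the classical fourth-order
#' Runge-Kutta method (fixed inner step `h`, halved within a step whenever a
#' density would fall below `-1e-12`, with tiny negatives clipped to zero)
#' until one strain's density first falls below `threshold`. If several
#' strains cross in the same step, only the one with the smallest density is
#' reported. Intended for communities whose linear steady state is infeasible
#' (something must go extinct).
#'
#' @param eco An [ecosystem()] object.
#' @param init A positive [community_state()] to start from.
#' @param threshold Extinction threshold (default `1e-20`).
#' @param h RK4 step size in model time units (default 0.01).
#' @param t_max Maximum integration horizon before a `ktwsim_nonconvergence`
#'   error (carrying the diagnostic state) is signalled. Default `1e7`.
#' @return A list with `extinct_kind` (`"bacterium"` or `"phage"`),
#'   `extinct_index`, `extinct_id`, `t` (time of crossing), and `state` (the
#'   full [community_state()] at that moment).
#' @export
integrate_until_extinction <- function(eco, init, threshold = 1e-20,
                                       h = 0.01, t_max = 1e7) {
  check_state_dims(eco, init)
  res <- .rk4_until_extinction_cpp(eco$bacteria$k, eco$rates$alpha, eco$eta,
                                   eco$phages$beta, eco$rates$delta,
                                   init$B, init$P, threshold, h, t_max)
  if (!isTRUE(res$converged)) {
    stop_nonconvergence(
      sprintf("no extinction within t_max = %g time units", t_max),
      state = community_state(res$B, res$P))
  }
  kind <- if (isTRUE(res$extinct_is_bacterium)) "bacterium" else "phage"
  id <- if (kind == "bacterium") eco$bacteria$id[res$extinct_index]
        else eco$phages$id[res$extinct_index]
  list(extinct_kind = kind,
       extinct_index = res$extinct_index,
       extinct_id = id,
       t = res$t,
       state = community_state(res$B, res$P))
}

# drop strains by id, keeping eta consistent; returns the reduced ecosystem
drop_strains <- function(eco, bact_ids = character(0), phage_ids = character(0)) {
  keep_b <- !(eco$bacteria$id %in% bact_ids)
  keep_p <- !(eco$phages$id %in% phage_ids)
  eco$bacteria <- eco$bacteria[keep_b, , drop = FALSE]
  eco$phages <- eco$phages[keep_p, , drop = FALSE]
  eco$eta <- eco$eta[keep_p, keep_b, drop = FALSE]
  rownames(eco$bacteria) <- NULL
  rownames(eco$phages) <- NULL
  eco
}

#' Resolve a perturbed community to a feasible steady state
#'
#' After a perturbation (typically the addition of an invader at its inoculum
#' density) the community may no longer admit a feasible steady state. This
#' routine alternates between [solve_steady_state()] and
#' [integrate_until_extinction()]: if the linear solution is feasible the
#' community is updated to it; otherwise the dynamics are integrated until
#' the first strain drops below `threshold`, that strain is removed, and the
#' loop repeats. Phages left without any host after a removal decay
#' deterministically (`dP/dt = -delta P`) and are removed immediately.
#' Each iteration removes at least one strain, so the loop terminates.
#'
#' @inheritParams integrate_until_extinction
#' @return A list with `eco` (the surviving [ecosystem()]), `state` (its
#'   feasible steady state), and `extinct_ids` (character vector, in order of
#'   removal).
#' @export
resolve_after_perturbation <- function(eco, init, threshold = 1e-20,
                                       h = 0.01, t_max = 1e7) {
  check_state_dims(eco, init)
  extinct <- character(0)
  repeat {
    # orphan phages (no surviving host) decay deterministically
    if (n_phages(eco) > 0) {
      orphan <- rowSums(eco$eta > 0) == 0
      if (any(orphan)) {
        ids <- eco$phages$id[orphan]
        extinct <- c(extinct, ids)
        init$P <- init$P[!orphan]
        eco <- drop_strains(eco, phage_ids = ids)
      }
    }
    if (n_bacteria(eco) == 0L) {
      return(list(eco = eco, state = community_state(numeric(0), numeric(0)),
                  extinct_ids = extinct))
    }
    ss <- solve_steady_state(eco)
    if (ss$feasible) {
      return(list(eco = eco, state = ss$state, extinct_ids = extinct))
    }
    out <- integrate_until_extinction(eco, init, threshold = threshold,
                                      h = h, t_max = t_max)
    extinct <- c(extinct, out$extinct_id)
    if (out$extinct_kind == "bacterium") {
      init <- community_state(out$state$B[-out$extinct_index], out$state$P)
      eco <- drop_strains(eco, bact_ids = out$extinct_id)
    } else {
      init <- community_state(out$state$B, out$state$P[-out$extinct_index])
      eco <- drop_strains(eco, phage_ids = out$extinct_id)
    }
  }
}
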