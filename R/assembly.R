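#' Assembly run configuration
#'
#' Parameters of a sequential-invasion simulation. Each invasion attempt
#' introduces either a bacterium or a phage (equiprobably); invaders start at
#' the inoculum density `1e-6` on top of the previous steady state, and the
#' community is resolved back to a feasible steady state before the next
#' attempt.
#'
#' @param model `"N"` (nested: invading bacteria are resistant to all
#'   resident phages) or `"R"` (random: every resident phage attacks the
#'   invading bacterium independently with probability `p`).
#' @param p Cross-link probability in `[0, 1]`.
#' @param n_steps Number of invasion attempts (`>= 1`).
#' @param seed Integer RNG seed; the full history is reproducible from it.
#' @param inoculum Initial density of every invader (default `1e-6`).
#' @param threshold Extinction threshold for the dynamics (default `1e-20`).
#' @param rates A [global_rates()] object.
#' @param h RK4 step size passed to the extinction integrator.
#' @param t_max Integration horizon passed to the extinction integrator.
#' @return An object of class `assembly_config`.
#' @export
assembly_config <- function(model = c("R", "N"), p = 0, n_steps = 100L,
                            seed = 1L, inoculum = 1e-6, threshold = 1e-20,
                            rates = global_rates(), h = 0.01, t_max = 1e7) {
  model <- match.arg(model)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_invalid("`p` must be a single number in [0, 1]")
  if (!is.numeric(n_steps) || n_steps < 1)
    stop_invalid("`n_steps` must be >= 1")
  if (!is.numeric(inoculum) || inoculum <= 0)
    stop_invalid("`inoculum` must be > 0")
  structure(list(model = model, p = p, n_steps = as.integer(n_steps),
                 seed = as.integer(seed), inoculum = inoculum,
                 threshold = threshold, rates = rates, h = h, t_max = t_max),
            class = "assembly_config")
}

#' Sample invader strain parameters
#'
#' `sample_bacterium()` draws a maximal growth rate `k ~ Uniform[0, 1]`;
#' `sample_phage()` draws a burst size `beta ~ Uniform[1, 50]`. Both consume
#' the global RNG stream (seed it with `set.seed()` for reproducibility).
#'
#' @param birth_step Invasion step recorded for the strain.
#' @return A one-row data.frame describing the strain (without an id, which
#'   is assigned by the assembly loop).
#' @export
#' @examples
#' set.seed(1)
#' sample_bacterium()$k
sample_bacterium <- function(birth_step = 0L) {
  data.frame(k = runif(1), birth_step = as.integer(birth_step))
}

#' @rdname sample_bacterium
#' @export
sample_phage <- function(birth_step = 0L) {
  data.frame(beta = runif(1, 1, 50), birth_step = as.integer(birth_step))
}

#' Initialize a single-bacterium ecosystem
#'
#' The simulation starts from one bacterium at its non-zero steady state
#' `B* = 1 - alpha/k`, which requires `k > alpha`; the growth rate is
#' rejection-sampled from Uniform\[0, 1\] until that holds.
#'
#' @param config An [assembly_config()].
#' @return A list with `eco` (an [ecosystem()]) and `state` (its steady
#'   state).
#' @export
initialize_ecosystem <- function(config) {
  alpha <- config$rates$alpha
  repeat {
    k <- runif(1)
    if (k > alpha) break
  }
  eco <- ecosystem(bacteria = data.frame(id = "b1", k = k, birth_step = 0L),
                   rates = config$rates)
  list(eco = eco, state = community_state(B = 1 - alpha / k))
}

#' Wire an invading bacterium into the resident phage community
#'
#' Model N: invading bacteria are resistant to every resident phage, so the
#' new infection column is all zero. Model R: each resident phage attacks the
#' invader independently with probability `p`; each realized link gets an
#' independent strength `eta ~ Uniform(0, 1)`, fixed for the strain pair's
#' lifetime. One uniform deviate is consumed per resident phage, then one per
#' realized link.
#'
#' @param eco The resident [ecosystem()].
#' @param model `"N"` or `"R"`.
#' @param p Cross-link probability.
#' @return Numeric vector of length `n_phages(eco)`: the new `eta` column.
#' @export
wire_invading_bacterium <- function(eco, model, p) {
  m <- n_phages(eco)
  col <- numeric(m)
  if (model == "R" && m > 0 && p > 0) {
    link <- runif(m) < p
    col[link] <- runif(sum(link))
  }
  col
}

#' Wire an invading phage onto the resident bacteria
#'
#' A new phage attacks any predator-free resident bacterium with probability
#' 1 and every other bacterium with probability `p` (a feasible resident
#' community can hold at most one predator-free bacterium, by competitive
#' exclusion among phage-free competitors). Each realized link gets an
#' independent strength `eta ~ Uniform(0, 1)`. If no predator-free bacterium
#' exists and no probabilistic link is realized, the all-zero row marks a
#' discarded invasion attempt (a resident phage must have a host). One
#' uniform deviate is consumed per resident bacterium, then one per realized
#' link.
#'
#' @param eco The resident [ecosystem()].
#' @param p Cross-link probability.
#' @return Numeric vector of length `n_bacteria(eco)`: the new `eta` row
#'   (all-zero means the attempt must be discarded).
#' @export
wire_invading_phage <- function(eco, p) {
  n <- n_bacteria(eco)
  row <- numeric(n)
  if (n == 0L) return(row)
  predator_free <- if (n_phages(eco) > 0) colSums(eco$eta > 0) == 0
                   else rep(TRUE, n)
  link <- runif(n) < p
  link[predator_free] <- TRUE
  row[link] <- runif(sum(link))
  row
}

add_bacterium <- function(eco, id, k, birth_step, eta_col) {
  eco$bacteria <- rbind(eco$bacteria,
                        data.frame(id = id, k = k,
                                   birth_step = as.integer(birth_step)))
  eco$eta <- if (nrow(eco$eta) == 0L)
    matrix(numeric(0), nrow = 0, ncol = ncol(eco$eta) + 1L)
  else cbind(eco$eta, eta_col)
  dimnames(eco$eta) <- NULL
  rownames(eco$bacteria) <- NULL
  eco
}

add_phage <- function(eco, id, beta, birth_step, eta_row) {
  eco$phages <- rbind(eco$phages,
                      data.frame(id = id, beta = beta,
                                 birth_step = as.integer(birth_step)))
  eco$eta <- rbind(eco$eta, eta_row)
  dimnames(eco$eta) <- NULL
  rownames(eco$phages) <- NULL
  eco
}

#' Run a sequential-invasion assembly simulation
#'
#' Starting from a single resident bacterium, performs `n_steps` invasion
#' attempts. At each step a bacterium or a phage is chosen with probability
#' 1/2 each, its parameters and wiring are sampled, it is added at the
#' inoculum density on top of the previous steady state, and
#' [resolve_after_perturbation()] restores a feasible community. Every
#' attempt (including discarded phage attempts with no host and failed
#' invasions) consumes one step of the invasion-trial time axis.
#'
#' The RNG draw order per step is fixed (invader kind, parameters, wiring
#' Bernoullis, link strengths) so that a history is bit-reproducible from
#' `config$seed`.
#'
#' @param config An [assembly_config()].
#' @return An object of class `assembly_history`: a list with `config`,
#'   `initial_eco`, `initial_state` and `events`, where each event records
#'   the step, invader kind/id/parameters/wiring, success flag, extinct
#'   strain ids, pre/post states and the post-event ecosystem snapshot.
#' @export
#' @examples
#' h <- run_assembly(assembly_config(model = "R", p = 0.2, n_steps = 30,
#'                                   seed = 42))
#' tail(history_summary(h), 3)
run_assembly <- function(config) {
  set.seed(config$seed)
  ini <- initialize_ecosystem(config)
  eco <- ini$eco
  state <- ini$state
  next_b <- 2L  # "b1" is the founder
  next_p <- 1L
  events <- vector("list", config$n_steps)

  for (step in seq_len(config$n_steps)) {
    pre_state <- state
    pre_eco <- eco
    invade_bacterium <- runif(1) < 0.5

    if (invade_bacterium) {
      pars <- sample_bacterium(birth_step = step)
      id <- paste0("b", next_b); next_b <- next_b + 1L
      links <- wire_invading_bacterium(eco, config$model, config$p)
      invader <- list(kind = "bacterium", id = id, k = pars$k,
                      links = setNames(links, eco$phages$id))
      eco2 <- add_bacterium(eco, id, pars$k, step, links)
      init2 <- community_state(c(state$B, config$inoculum), state$P)
      discarded <- FALSE
    } else {
      pars <- sample_phage(birth_step = step)
      id <- paste0("p", next_p); next_p <- next_p + 1L
      links <- wire_invading_phage(eco, config$p)
      invader <- list(kind = "phage", id = id, beta = pars$beta,
                      links = setNames(links, eco$bacteria$id))
      discarded <- all(links == 0)
      if (!discarded) {
        eco2 <- add_phage(eco, id, pars$beta, step, links)
        init2 <- community_state(state$B, c(state$P, config$inoculum))
      }
    }

    non_convergence <- FALSE
    extinct_ids <- character(0)
    if (!discarded) {
      res <- tryCatch(
        resolve_after_perturbation(eco2, init2, threshold = config$threshold,
                                   h = config$h, t_max = config$t_max),
        ktwsim_nonconvergence = function(e) NULL)
      if (is.null(res)) {
        non_convergence <- TRUE  # attempt skipped, community unchanged
      } else {
        eco <- res$eco
        state <- res$state
        extinct_ids <- res$extinct_ids
      }
    }
    success <- !discarded && !non_convergence &&
      id %in% c(eco$bacteria$id, eco$phages$id)

    events[[step]] <- list(
      step = step,
      invader_kind = invader$kind,
      invader_id = id,
      invader = invader,
      success = success,
      discarded = discarded,
      non_convergence = non_convergence,
      extinct_ids = extinct_ids,
      pre_state = pre_state,
      post_state = state,
      pre_eco = pre_eco,
      post_eco = eco)
  }

  structure(list(config = config, initial_eco = ini$eco,
                 initial_state = ini$state, events = events),
            class = "assembly_history")
}

#' @export
print.assembly_history <- function(x, ...) {
  cat(sprintf(
    "<assembly_history> model %s, p = %g, %d invasion attempts (seed %d)\n",
    x$config$model, x$config$p, length(x$events), x$config$seed))
  invisible(x)
}

#' Per-step summary of an assembly history
#'
#' @param history An [run_assembly()] history.
#' @return A data.frame with one row per invasion attempt: `step`,
#'   `invader_kind`, `success`, `n_extinct`, `n_bacteria`, `n_phages`
#'   (post-event counts).
#' @export
history_summary <- function(history) {
  ev <- history$events
  data.frame(
    step = vapply(ev, `[[`, integer(1), "step"),
    invader_kind = vapply(ev, `[[`, character(1), "invader_kind"),
    success = vapply(ev, `[[`, logical(1), "success"),
    n_extinct = vapply(ev, function(e) length(e$extinct_ids), integer(1)),
    n_bacteria = vapply(ev, function(e) nrow(e$post_eco$bacteria), integer(1)),
    n_phages = vapply(ev, function(e) nrow(e$post_eco$phages), integer(1)))
}
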