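# small hand-built ecosystems used across test files

eco_single <- function(k = 0.5, alpha = 0.1) {
  ecosystem(data.frame(id = "b1", k = k),
            rates = global_rates(alpha = alpha))
}

eco_pair <- function(k = 0.5, beta = 10, eta = 0.5) {
  ecosystem(data.frame(id = "b1", k = k),
            data.frame(id = "p1", beta = beta),
            matrix(eta, 1, 1))
}

eco_two_bacteria <- function(k1 = 0.8, k2 = 0.3) {
  ecosystem(data.frame(id = c("b1", "b2"), k = c(k1, k2)))
}

eco_diagonal <- function(k = c(0.8, 0.5), beta = c(10, 20),
                         eta = c(0.5, 0.3)) {
  ecosystem(data.frame(id = paste0("b", seq_along(k)), k = k),
            data.frame(id = paste0("p", seq_along(beta)), beta = beta),
            diag(eta))
}

# memoised assembly runs shared across test files (helpers are sourced once
# per session, so expensive ensembles are generated a single time)
.run_cache <- new.env(parent = emptyenv())

cached_history <- function(model, p, n_steps, seed) {
  key <- paste(model, p, n_steps, seed, sep = "|")
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_assembly(
      assembly_config(model = model, p = p, n_steps = n_steps, seed = seed))
  }
  .run_cache[[key]]
}

cached_histories <- function(model, p, n_steps, seeds) {
  lapply(seeds, function(s) cached_history(model, p, n_steps, s))
}

# harvest feasible post-event communities (with their logged steady states)
# from assembly runs, optionally capped in size
harvest_communities <- function(histories, max_b = Inf, max_p = Inf,
                                min_b = 1L, min_p = 0L, limit = Inf) {
  out <- list()
  for (h in histories) {
    for (ev in h$events) {
      eco <- ev$post_eco
      nb <- nrow(eco$bacteria); np <- nrow(eco$phages)
      if (nb < min_b || np < min_p || nb > max_b || np > max_p) next
      out[[length(out) + 1L]] <- list(eco = eco, state = ev$post_state)
      if (length(out) >= limit) return(out)
    }
  }
  out
}
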