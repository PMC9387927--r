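#' Two-bacteria / one-shared-phage triplet system
#'
#' The minimal motif behind eliminate-the-winner events: a fast grower `S`
#' (growth rate `k_S`), a slower grower `R` (`k_R < k_S`), and one phage
#' infecting both with rates `eta_S` and `eta_R`.
#'
#' @param k_S,k_R Growth rates, `alpha < k_R < k_S <= 1` (both bacteria must
#'   be viable alone).
#' @param eta_S,eta_R Infection rates of the shared phage, in `(0, 1)`.
#' @param beta Burst size of the shared phage, in `[1, 50]`.
#' @param rates A [global_rates()] object.
#' @return An object of class `triplet_system`.
#' @export
triplet_system <- function(k_S, k_R, eta_S, eta_R, beta,
                           rates = global_rates()) {
  if (!(k_R < k_S) || k_S > 1 || k_R <= 0)
    stop_invalid("growth rates must satisfy 0 < k_R < k_S <= 1")
  if (k_R <= rates$alpha)
    stop_invalid("both bacteria must be viable alone (k > alpha)")
  if (any(c(eta_S, eta_R) <= 0) || any(c(eta_S, eta_R) >= 1))
    stop_invalid("infection rates must lie in (0, 1)")
  if (beta < 1 || beta > 50)
    stop_invalid("burst size must lie in [1, 50]")
  structure(list(k_S = k_S, k_R = k_R, eta_S = eta_S, eta_R = eta_R,
                 beta = beta, rates = rates),
            class = "triplet_system")
}

# interior (three-strain) equilibrium of the triplet; may have non-positive
# components, in which case coexistence is infeasible
triplet_interior <- function(t) {
  alpha <- t$rates$alpha; delta <- t$rates$delta
  den <- t$eta_R * t$k_S - t$eta_S * t$k_R
  if (den == 0) return(NULL)  # equal "effective exposure": degenerate
  x <- alpha * (t$eta_R - t$eta_S) / den          # free resource 1 - B_S - B_R
  P <- (t$k_S * x - alpha) / t$eta_S
  dd <- t$eta_S - t$eta_R
  if (dd == 0) return(NULL)
  B_S <- (delta / t$beta - t$eta_R * (1 - x)) / dd
  B_R <- (t$eta_S * (1 - x) - delta / t$beta) / dd
  list(B_S = B_S, B_R = B_R, P = P)
}

#' Classify the asymptotic outcome of a triplet motif
#'
#' Determines the long-run outcome of the fast-grower/slow-grower/shared-
#' phage system from closed-form invasibility conditions derived from the
#' steady-state equations:
#'
#' * `q1 = beta * eta_S * (1 - alpha/k_S) - delta`: growth rate of the phage
#'   introduced into the `S`-alone state. If `q1 <= 0` the phage cannot
#'   establish on the competitively dominant host and is lost
#'   (**PHAGE_LOST**: `S` wins alone).
#' * Otherwise the `(S, phage)` pair equilibrium exists
#'   (`B_S* = delta/(beta eta_S)`, `P* = (k_S(1 - B_S*) - alpha)/eta_S`);
#'   `s_R = k_R (1 - B_S*) - alpha - eta_R P*` is the invasion rate of `R`.
#'   If `s_R <= 0`, `R` cannot enter (**S_EXCLUDES_R**).
#' * Otherwise, if the `(R, phage)` pair equilibrium exists
#'   (`q2 = beta * eta_R * (1 - alpha/k_R) - delta > 0`) and `S` cannot
#'   re-invade it (`s_S = k_S (1 - B_R*) - alpha - eta_S P_R* <= 0`), the
#'   slower grower eliminates the winner (**R_EXCLUDES_S**).
#' * In all remaining cases every boundary state is invasible, the system is
#'   permanent, and all three strains persist (**COEXIST**).
#'
#' Points landing exactly on a boundary (a decision quantity equal to zero)
#' are assigned to COEXIST when the interior equilibrium is non-negative,
#' else to the surviving competitor's region.
#'
#' @param t A [triplet_system()].
#' @return A list of class `triplet_outcome` with `outcome` (one of
#'   `"COEXIST"`, `"S_EXCLUDES_R"`, `"R_EXCLUDES_S"`, `"PHAGE_LOST"`) and
#'   `margin`, the smallest absolute decision quantity on the path taken
#'   (small margins flag near-boundary parameter points).
#' @export
#' @examples
#' t <- triplet_system(k_S = 0.8, k_R = 0.4, eta_S = 0.8, eta_R = 0.1,
#'                     beta = 20)
#' classify_triplet(t)$outcome  # the slower grower eliminates the winner
classify_triplet <- function(t) {
  if (!inherits(t, "triplet_system")) stop_invalid("not a `triplet_system`")
  alpha <- t$rates$alpha; delta <- t$rates$delta
  margins <- numeric(0)
  tie <- function() {
    # exact-boundary tie rule: coexistence if the interior point is feasible
    int <- triplet_interior(t)
    !is.null(int) && all(unlist(int) >= 0)
  }
  out <- function(outcome) {
    structure(list(outcome = outcome, margin = min(abs(margins))),
              class = "triplet_outcome")
  }

  q1 <- t$beta * t$eta_S * (1 - alpha / t$k_S) - delta
  margins <- c(margins, q1)
  if (q1 < 0 || (q1 == 0 && !tie())) return(out("PHAGE_LOST"))

  B_Sp <- delta / (t$beta * t$eta_S)
  P_Sp <- (t$k_S * (1 - B_Sp) - alpha) / t$eta_S
  s_R <- t$k_R * (1 - B_Sp) - alpha - t$eta_R * P_Sp
  margins <- c(margins, s_R)
  if (s_R < 0 || (s_R == 0 && !tie())) return(out("S_EXCLUDES_R"))

  q2 <- t$beta * t$eta_R * (1 - alpha / t$k_R) - delta
  margins <- c(margins, q2)
  if (q2 > 0) {
    B_Rp <- delta / (t$beta * t$eta_R)
    P_Rp <- (t$k_R * (1 - B_Rp) - alpha) / t$eta_R
    s_S <- t$k_S * (1 - B_Rp) - alpha - t$eta_S * P_Rp
    margins <- c(margins, s_S)
    if (s_S < 0 || (s_S == 0 && !tie())) return(out("R_EXCLUDES_S"))
  }
  out("COEXIST")
}

#' @export
print.triplet_outcome <- function(x, ...) {
  cat(sprintf("<triplet_outcome> %s (boundary margin %.3g)\n",
              x$outcome, x$margin))
  invisible(x)
}

#' Outcome phase diagram of the triplet motif
#'
#' Classifies the triplet outcome on a grid of ratios
#' `eta_R/eta_S` (phage exposure of the slow relative to the fast grower)
#' and `k_R/k_S` (relative growth rate), at fixed `k_S`, `eta_S` and `beta`.
#' Grid points whose implied `k_R` would not be viable alone
#' (`k_R <= alpha`) are marked `NA`.
#'
#' @param k_S Growth rate of the fast grower (default 0.9).
#' @param eta_S Infection rate of the shared phage on `S` (default 0.6).
#' @param beta Burst size (default 15).
#' @param rates A [global_rates()] object.
#' @param eta_ratio,k_ratio Grid coordinates, each strictly inside `(0, 1)`.
#' @return A data.frame with columns `eta_ratio`, `k_ratio`, `outcome`
#'   (factor with the four outcome levels).
#' @export
triplet_phase_diagram <- function(k_S = 0.9, eta_S = 0.6, beta = 15,
                                  rates = global_rates(),
                                  eta_ratio = seq(0.025, 0.975, by = 0.05),
                                  k_ratio = seq(0.025, 0.975, by = 0.05)) {
  if (any(eta_ratio <= 0) || any(eta_ratio >= 1) ||
      any(k_ratio <= 0) || any(k_ratio >= 1))
    stop_invalid("grid ratios must lie strictly inside (0, 1)")
  grid <- expand.grid(eta_ratio = eta_ratio, k_ratio = k_ratio,
                      KEEP.OUT.ATTRS = FALSE)
  levs <- c("COEXIST", "S_EXCLUDES_R", "R_EXCLUDES_S", "PHAGE_LOST")
  grid$outcome <- factor(vapply(seq_len(nrow(grid)), function(i) {
    k_R <- grid$k_ratio[i] * k_S
    if (k_R <= rates$alpha) return(NA_character_)
    t <- triplet_system(k_S = k_S, k_R = k_R, eta_S = eta_S,
                        eta_R = grid$eta_ratio[i] * eta_S, beta = beta,
                        rates = rates)
    classify_triplet(t)$outcome
  }, character(1)), levels = levs)
  grid
}

#' Count shared-phage triplet motifs in an ecosystem
#'
#' Number of (bacterium pair, phage) combinations in which one phage infects
#' both bacteria — the minimal structure enabling eliminate-the-winner
#' events. For a fully connected network with `n` bacteria and `m` phages
#' this is `m * n * (n - 1) / 2`.
#'
#' @param eco An [ecosystem()] object.
#' @return Integer count.
#' @export
count_shared_phage_triplets <- function(eco) {
  if (n_phages(eco) == 0L) return(0L)
  deg <- rowSums(eco$eta > 0)
  as.integer(sum(choose(deg, 2)))
}

#' Detect eliminate-the-winner events in an assembly history
#'
#' Scans every invasion event for the signature of the triplet mechanism:
#' the fastest-growing *resident* bacterium `S` (the invader is excluded
#' from the `S` role) goes extinct while at least one slower resident
#' bacterium survives, and a phage present in the perturbed community (a
#' resident or the invader itself) infects both `S` and a surviving slower
#' grower `R`. When several candidate phages exist the one with the largest
#' predation strength `beta * eta` on `S` is taken, and among its surviving
#' slower hosts the one with the largest `beta * eta` link.
#'
#' @param history An [run_assembly()] history.
#' @return A data.frame with one row per event: `step`, `trigger`
#'   (`"phage_invasion"` or `"bacterium_invasion"`), `eliminated_id`,
#'   `survivor_id`, `common_phage_id`, `k_S`, `k_R`, `ratio_k` (`k_R/k_S`),
#'   `eta_S`, `eta_R`, `ratio_eta` (`eta_R/eta_S`).
#' @export
detect_elimination_events <- function(history) {
  rows <- list()
  for (ev in history$events) {
    if (ev$discarded || ev$non_convergence || length(ev$extinct_ids) == 0)
      next
    pre <- ev$pre_eco
    if (nrow(pre$bacteria) < 2L) next
    i_S <- which.max(pre$bacteria$k)
    id_S <- pre$bacteria$id[i_S]
    if (!(id_S %in% ev$extinct_ids)) next
    k_S <- pre$bacteria$k[i_S]
    surv <- ev$post_eco$bacteria
    surv <- surv[surv$k < k_S & surv$id %in% pre$bacteria$id, , drop = FALSE]
    if (nrow(surv) == 0L) next

    # candidate phages: residents plus an invading phage, with eta_S > 0
    cand <- data.frame(phage_id = character(0), beta = numeric(0),
                       eta_S = numeric(0))
    if (nrow(pre$phages) > 0) {
      cand <- data.frame(phage_id = pre$phages$id, beta = pre$phages$beta,
                         eta_S = pre$eta[, i_S])
    }
    if (ev$invader_kind == "phage" && !is.null(ev$invader$links)) {
      cand <- rbind(cand, data.frame(
        phage_id = ev$invader_id, beta = ev$invader$beta,
        eta_S = unname(ev$invader$links[id_S])))
    }
    cand <- cand[cand$eta_S > 0, , drop = FALSE]
    if (nrow(cand) == 0L) next

    # eta of each candidate phage on each surviving slower grower
    best <- NULL
    for (j in order(cand$beta * cand$eta_S, decreasing = TRUE)) {
      pid <- cand$phage_id[j]
      eta_on <- function(bid) {
        if (pid == ev$invader_id && ev$invader_kind == "phage") {
          v <- ev$invader$links[bid]
          if (is.na(v)) 0 else unname(v)
        } else {
          r <- match(pid, pre$phages$id)
          ci <- match(bid, pre$bacteria$id)
          if (is.na(ci)) 0 else pre$eta[r, ci]
        }
      }
      eta_R <- vapply(surv$id, eta_on, numeric(1))
      if (any(eta_R > 0)) {
        rbest <- which.max(cand$beta[j] * eta_R)
        best <- list(phage_id = pid, beta = cand$beta[j],
                     eta_S = cand$eta_S[j],
                     survivor_id = surv$id[rbest], k_R = surv$k[rbest],
                     eta_R = unname(eta_R[rbest]))
        break
      }
    }
    if (is.null(best)) next
    rows[[length(rows) + 1L]] <- data.frame(
      step = ev$step,
      trigger = paste0(ev$invader_kind, "_invasion"),
      eliminated_id = id_S,
      survivor_id = best$survivor_id,
      common_phage_id = best$phage_id,
      beta = best$beta,
      k_S = k_S, k_R = best$k_R, ratio_k = best$k_R / k_S,
      eta_S = best$eta_S, eta_R = best$eta_R,
      ratio_eta = best$eta_R / best$eta_S)
  }
  if (length(rows) == 0L) {
    return(data.frame(step = integer(0), trigger = character(0),
                      eliminated_id = character(0), survivor_id = character(0),
                      common_phage_id = character(0), beta = numeric(0),
                      k_S = numeric(0),
                      k_R = numeric(0), ratio_k = numeric(0),
                      eta_S = numeric(0), eta_R = numeric(0),
                      ratio_eta = numeric(0)))
  }
  do.call(rbind, rows)
}
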