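#' Kill-the-winner pairing of strongest links
#'
#' For each phage the strongest prey link is the bacterium maximizing the
#' predation strength `beta * eta`; for each bacterium the strongest
#' predator is the phage maximizing the same quantity. The community is
#' *fully paired* when these strongest links define a perfect matching
#' between all phages and an equal number of bacteria (every phage's best
#' prey reciprocates as that bacterium's worst enemy), with at most one
#' phage-free bacterium allowed outside the matching — the self-organized
#' "kill the winner" structure of specialized predator-prey pairs.
#'
#' @param eco An [ecosystem()] object with at least one phage and one
#'   bacterium.
#' @return A list of class `pairing_report`: `fully_paired` (flag), `pairs`
#'   (data.frame of mutual strongest pairs, `phage_id`/`bacterium_id`), and
#'   `unpaired` (ids of strains outside the matching).
#' @export
#' @examples
#' eco <- ecosystem(
#'   bacteria = data.frame(id = c("b1", "b2"), k = c(0.8, 0.5)),
#'   phages = data.frame(id = c("p1", "p2"), beta = c(10, 20)),
#'   eta = diag(c(0.5, 0.3))
#' )
#' ktw_pairing(eco)$fully_paired
ktw_pairing <- function(eco) {
  n <- n_bacteria(eco)
  m <- n_phages(eco)
  if (n == 0L || m == 0L)
    stop_invalid("pairing requires at least one bacterium and one phage")
  W <- eco$phages$beta * eco$eta  # M x N predation strengths
  best_prey <- apply(W, 1, which.max)                  # per phage
  has_pred <- colSums(eco$eta > 0) > 0
  best_pred <- rep(NA_integer_, n)                     # per bacterium
  best_pred[has_pred] <- apply(W[, has_pred, drop = FALSE], 2, which.max)

  mutual <- vapply(seq_len(m), function(ph) {
    pr <- best_prey[ph]
    has_pred[pr] && best_pred[pr] == ph
  }, logical(1))
  matched_b <- unique(best_prey[mutual])
  pairs <- data.frame(phage_id = eco$phages$id[mutual],
                      bacterium_id = eco$bacteria$id[best_prey[mutual]])
  unpaired_b <- setdiff(seq_len(n), matched_b)
  fully <- all(mutual) &&
    !anyDuplicated(best_prey) &&
    all(!has_pred[unpaired_b]) &&
    length(unpaired_b) <= 1L
  unpaired <- c(eco$phages$id[!mutual], eco$bacteria$id[unpaired_b])
  structure(list(fully_paired = fully, pairs = pairs, unpaired = unpaired),
            class = "pairing_report")
}

#' @export
print.pairing_report <- function(x, ...) {
  cat(sprintf("<pairing_report> fully_paired = %s (%d mutual pairs)\n",
              x$fully_paired, nrow(x$pairs)))
  invisible(x)
}

#' Fraction of logged communities with full kill-the-winner pairing
#'
#' Over one or more assembly histories, evaluates [ktw_pairing()] on every
#' logged post-event community containing at least one phage and one
#' bacterium (phage-free states carry no pairing information) and returns
#' the fraction that is fully paired.
#'
#' @param histories An `assembly_history` or a list of them.
#' @return Fraction in `[0, 1]` (`NaN` if no community qualifies).
#' @export
ktw_fraction <- function(histories) {
  if (inherits(histories, "assembly_history")) histories <- list(histories)
  paired <- 0L
  total <- 0L
  for (h in histories) {
    for (ev in h$events) {
      eco <- ev$post_eco
      if (nrow(eco$phages) == 0L || nrow(eco$bacteria) == 0L) next
      total <- total + 1L
      if (ktw_pairing(eco)$fully_paired) paired <- paired + 1L
    }
  }
  paired / total
}

#' Growth-rate occupancy and entry profiles
#'
#' Bins the growth-rate axis `[0, 1]` into bins of width `delta_k` and
#' computes, per bin: `N_B`, the time-averaged number of resident bacteria
#' (averaged over every logged invasion step), and `p_entry`, the
#' distribution of growth rates of bacteria that successfully entered the
#' system, normalized so that `sum(p_entry) * delta_k = 1`.
#'
#' @param history An [run_assembly()] history (or a list of histories, whose
#'   events are pooled).
#' @param delta_k Bin width (default 0.1).
#' @return A list of class `growth_rate_profile` with `bin_edges`, `bin_mid`,
#'   `N_B`, `p_entry`, `n_steps` (events averaged over) and `n_entries`.
#' @export
growth_rate_profile <- function(history, delta_k = 0.1) {
  if (inherits(history, "assembly_history")) history <- list(history)
  edges <- seq(0, 1, by = delta_k)
  if (abs(edges[length(edges)] - 1) > 1e-12) edges <- c(edges, 1)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  entries <- numeric(nb)
  n_steps <- 0L
  n_entries <- 0L
  bin_of <- function(k) pmin(pmax(findInterval(k, edges, left.open = FALSE), 1L), nb)
  for (h in history) {
    for (ev in h$events) {
      n_steps <- n_steps + 1L
      kk <- ev$post_eco$bacteria$k
      if (length(kk)) {
        tb <- tabulate(bin_of(kk), nbins = nb)
        counts <- counts + tb
      }
      if (ev$success && ev$invader_kind == "bacterium") {
        entries[bin_of(ev$invader$k)] <- entries[bin_of(ev$invader$k)] + 1
        n_entries <- n_entries + 1L
      }
    }
  }
  N_B <- if (n_steps > 0) counts / n_steps else counts
  p_entry <- if (n_entries > 0) entries / (n_entries * delta_k) else entries
  structure(list(bin_edges = edges,
                 bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 N_B = N_B, p_entry = p_entry,
                 n_steps = n_steps, n_entries = n_entries),
            class = "growth_rate_profile")
}

# log-linear least-squares fit of y > 0 against bin midpoints restricted to
# the window [lo, hi]; returns NULL when fewer than min_bins positive bins
loglinear_fit <- function(mid, y, lo = 0.3, hi = 0.9, min_bins = 3L) {
  sel <- mid >= lo & mid <= hi & y > 0
  if (sum(sel) < min_bins) return(NULL)
  fit <- lm(log(y[sel]) ~ mid[sel])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       residual = sqrt(mean(fit$residuals^2)), bins_used = sum(sel))
}

#' Elimination factor E
#'
#' Least-squares fit of the exponential growth-rate occupancy profile
#' `N_B(k) proportional to exp(k / E)` on the window `k` in `[0.3, 0.9]`
#' (bins with zero counts are excluded from the log-linear fit). `E` is the
#' inverse of the fitted log-slope: a *larger* `E` means a *flatter* profile,
#' i.e. relatively more slow growers and a stronger eliminate-the-winner
#' effect; `E ~ 0.2` corresponds to the steep profile of the classical
#' kill-the-winner regime. A slope below `1e-8` is reported as an unbounded
#' (flat-profile) fit with `E = Inf`.
#'
#' @param profile A [growth_rate_profile()].
#' @param lo,hi Fit window on `k` (defaults 0.3 and 0.9).
#' @return A list of class `elimination_fit` with `E`, `slope`, `residual`,
#'   `bins_used`, `flat` (flag). Signals `ktwsim_invalid_input` when fewer
#'   than 3 positive bins lie in the window.
#' @export
elimination_factor <- function(profile, lo = 0.3, hi = 0.9) {
  fit <- loglinear_fit(profile$bin_mid, profile$N_B, lo, hi)
  if (is.null(fit))
    stop_invalid("need at least 3 positive N_B bins in the fit window")
  flat <- abs(fit$slope) < 1e-8
  structure(list(E = if (flat) Inf else 1 / fit$slope,
                 slope = fit$slope, residual = fit$residual,
                 bins_used = fit$bins_used, flat = flat),
            class = "elimination_fit")
}

#' @export
print.elimination_fit <- function(x, ...) {
  cat(sprintf("<elimination_fit> E = %.4g (slope %.4g, %d bins)\n",
              x$E, x$slope, x$bins_used))
  invisible(x)
}

#' Entry advantage of fast growers
#'
#' Log-linear fit of the entry distribution `p_entry(k)` on `k` in
#' `[0.3, 0.9]`; the entry advantage is the fitted slope normalized by the
#' fitted entry probability mass at `k = 0.3`:
#' `G_A = slope / (p_entry_fit(0.3) * delta_k)`. A flat entry profile gives
#' `G_A = 0`.
#'
#' @param profile A [growth_rate_profile()].
#' @param delta_k Bin width used for the normalization (default inferred
#'   from the profile).
#' @param lo,hi Fit window on `k`.
#' @return A list of class `entry_advantage_fit` with `G_A`, `slope`,
#'   `p_entry_at_lo`, `bins_used`.
#' @export
entry_advantage <- function(profile, delta_k = NULL, lo = 0.3, hi = 0.9) {
  if (is.null(delta_k)) delta_k <- diff(profile$bin_edges[1:2])
  fit <- loglinear_fit(profile$bin_mid, profile$p_entry, lo, hi)
  if (is.null(fit))
    stop_invalid("need at least 3 positive p_entry bins in the fit window")
  p_lo <- exp(fit$intercept + fit$slope * lo)
  structure(list(G_A = fit$slope / (p_lo * delta_k),
                 slope = fit$slope, p_entry_at_lo = p_lo,
                 bins_used = fit$bins_used),
            class = "entry_advantage_fit")
}

#' Diversity statistics of assembly runs
#'
#' Time-averaged and maximal total strain counts (bacteria + phages) per
#' run, aggregated over runs sharing the same model and cross-link
#' probability.
#'
#' @param histories A list of `assembly_history` objects.
#' @return A data.frame with one row per (model, p): `model`, `p`, `n_runs`,
#'   `avg_diversity` (mean over runs of the time-averaged count),
#'   `max_diversity` (mean over runs of the per-run maximum).
#' @export
diversity_stats <- function(histories) {
  if (inherits(histories, "assembly_history")) histories <- list(histories)
  per_run <- do.call(rbind, lapply(histories, function(h) {
    tot <- vapply(h$events, function(ev)
      nrow(ev$post_eco$bacteria) + nrow(ev$post_eco$phages), integer(1))
    data.frame(model = h$config$model, p = h$config$p,
               avg = mean(tot), max = max(tot))
  }))
  agg <- aggregate(cbind(avg, max) ~ model + p, data = per_run, FUN = mean)
  n <- aggregate(avg ~ model + p, data = per_run, FUN = length)
  out <- data.frame(model = agg$model, p = agg$p, n_runs = n$avg,
                    avg_diversity = agg$avg, max_diversity = agg$max)
  out[order(out$model, out$p), , drop = FALSE]
}

#' Fraction of diversity-increasing bacterial invaders that are resistant
#'
#' Among successful bacterial invasions that increased the total strain
#' count, the fraction whose infection column was all zero at entry (the
#' invader was resistant to every resident phage). Model N gives 1 by
#' construction; in Model R the fraction stays near 1 for small and moderate
#' `p` and is forced to 0 at `p = 1`.
#'
#' @param history An `assembly_history` or list of them.
#' @return Fraction in `[0, 1]` (`NaN` when no qualifying event exists).
#' @export
resistant_invader_fraction <- function(history) {
  if (inherits(history, "assembly_history")) history <- list(history)
  resistant <- 0L
  total <- 0L
  for (h in history) {
    for (ev in h$events) {
      if (!ev$success || ev$invader_kind != "bacterium") next
      pre_tot <- nrow(ev$pre_eco$bacteria) + nrow(ev$pre_eco$phages)
      post_tot <- nrow(ev$post_eco$bacteria) + nrow(ev$post_eco$phages)
      if (post_tot <= pre_tot) next
      total <- total + 1L
      if (all(ev$invader$links == 0)) resistant <- resistant + 1L
    }
  }
  resistant / total
}
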