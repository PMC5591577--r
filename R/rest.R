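#' Replica exchange with solute tempering (REST)
#'
#' Hamiltonian replica exchange in which only the hot region's
#' interactions are scaled.  The hot region is the solute: the ligand
#' plus the designated flexible pocket residue (region HOT_RESIDUE), so
#' both the ligand linker torsion and the side-chain rotamer flips are
#' tempered.  Each replica m runs at the common thermal temperature
#' under the scaled Hamiltonian
#' \deqn{E_m = r\,e_{ss} + \sqrt{r}\,e_{sw} + e_{ww}, \quad
#'       r = \beta_m/\beta_0,}
#' the REST2 scaling.  Neighbor swaps exchange configurations, so the
#' ladder-position-0 frames always sample the physical (unscaled)
#' ensemble and feed all downstream estimators directly.
#'
#' @name rest
NULL

#' Replica ladder
#'
#' @param n_replicas number of replicas (>= 1)
#' @param t_base thermal temperature, K (first rung)
#' @param t_max highest effective temperature, K
#' @param swap_every MC steps between neighbor-swap epochs
#' @return object of class \code{replica_ladder} with ascending
#'   \code{effective_temperatures} (geometric spacing) and the
#'   per-replica scale factors \code{r = t_base / t_eff}
#' @export
replica_ladder <- function(n_replicas = 6, t_base = 298.15, t_max = 1200,
                           swap_every = 100) {
  stopifnot(n_replicas >= 1, t_base > 0, swap_every > 0)
  teff <- if (n_replicas == 1) t_base else {
    stopifnot(t_max > t_base)
    t_base * (t_max / t_base)^((seq_len(n_replicas) - 1) / (n_replicas - 1))
  }
  structure(list(n_replicas = as.integer(n_replicas),
                 effective_temperatures = teff,
                 r = t_base / teff,
                 swap_every = as.integer(swap_every)),
            class = "replica_ladder")
}

#' @export
print.replica_ladder <- function(x, ...) {
  cat(sprintf("replica_ladder: %d replicas, T_eff %s K, swap every %d steps\n",
              x$n_replicas,
              paste(sprintf("%.0f", x$effective_temperatures), collapse = "/"),
              x$swap_every))
  invisible(x)
}

#' REST2-scaled energy
#'
#' \code{r * e_ss + sqrt(r) * e_sw + e_ww} with \code{r} the inverse
#' effective-temperature ratio in (0, 1]; \code{r = 1} returns the
#' unscaled total.
#'
#' @param decomp an \code{energy_decomposition}
#' @param beta_ratio the scale factor r in (0, 1]
#' @return scaled total energy, kcal/mol
#' @export
scaled_energy <- function(decomp, beta_ratio) {
  if (beta_ratio <= 0 || beta_ratio > 1)
    stop("beta_ratio must be in (0, 1]")
  beta_ratio * decomp$e_ss + sqrt(beta_ratio) * decomp$e_sw + decomp$e_ww
}

#' Attempt a configuration swap between neighboring replicas
#'
#' Hamiltonian exchange at the common thermal temperature: the
#' acceptance exponent is
#' \deqn{\Delta = \beta_0\,[E_m(x_n) - E_m(x_m) + E_n(x_m) - E_n(x_n)]}
#' with \eqn{E_k} the k-scaled Hamiltonian, accepted with probability
#' \code{min(1, exp(-delta))}.  The environment-environment component
#' cancels exactly.
#'
#' @param state_m,state_n lists with an \code{energy_decomposition}
#'   \code{$decomp} and scale factor \code{$r} for the two neighbors
#' @param temperature thermal temperature, K
#' @param draw uniform(0,1) random draw (default drawn from R's RNG)
#' @return list with \code{delta} (the exponent), \code{accepted}, and
#'   the two (possibly exchanged) states
#' @export
attempt_swap <- function(state_m, state_n, temperature = 298.15,
                         draw = runif(1)) {
  Em <- function(d, r) r * d$e_ss + sqrt(r) * d$e_sw + d$e_ww
  delta <- (Em(state_n$decomp, state_m$r) - Em(state_m$decomp, state_m$r) +
            Em(state_m$decomp, state_n$r) - Em(state_n$decomp, state_n$r)) /
    kT(temperature)
  accepted <- delta <= 0 || draw < exp(-delta)
  if (accepted) {
    tmp <- state_m$decomp; state_m$decomp <- state_n$decomp
    state_n$decomp <- tmp
  }
  list(delta = delta, accepted = accepted, state_m = state_m,
       state_n = state_n)
}

#' Run a REST simulation
#'
#' Runs \code{n_replicas} coupled chains under REST2-scaled Hamiltonians
#' with alternating even/odd neighbor swaps, and returns the demuxed
#' physical (ladder-position-0) ensemble plus swap statistics.  With a
#' single replica the output follows the identical RNG path as
#' \code{\link{run_chain}}.
#'
#' @param system a \code{toy_system}; the hot region (LIGAND or
#'   HOT_RESIDUE atoms) must be non-empty
#' @param cfg a \code{chain_config}
#' @param ladder a \code{replica_ladder}
#' @param moves list of \code{move_spec}
#' @return object of class \code{rest_result}: \code{$trajectory} is the
#'   physical-ensemble \code{mc_trajectory}; \code{$swap_stats} gives
#'   per-neighbor-pair acceptance; \code{$swap_log} the full exchange
#'   record; \code{$permutation} the replica-to-walker permutation at
#'   each epoch; \code{$replica_frames} per-replica frames when
#'   requested.
#' @export
run_rest <- function(system, cfg, ladder = replica_ladder(),
                     moves = default_moves(system)) {
  if (!any(system$atoms$region %in% c("LIGAND", "HOT_RESIDUE")))
    stop("hot region is empty: REST would be a no-op")
  raw <- engine_driver(system, moves, cfg, ladder_r = ladder$r,
                       swap_every = if (ladder$n_replicas > 1)
                         ladder$swap_every else 0L)
  traj <- new_trajectory(raw, system, moves, cfg)
  sl <- as.data.frame(raw$swap_log)
  stats <- if (nrow(sl)) {
    agg <- stats::aggregate(accepted ~ pair, sl,
                            function(a) c(attempts = length(a),
                                          accepts = sum(a)))
    data.frame(pair = agg$pair, attempts = agg$accepted[, "attempts"],
               accepts = agg$accepted[, "accepts"],
               ratio = agg$accepted[, "accepts"] /
                 agg$accepted[, "attempts"])
  } else data.frame(pair = integer(), attempts = integer(),
                    accepts = integer(), ratio = numeric())
  rf <- raw$replica_frames
  if (!is.null(rf))
    rf <- lapply(rf, frames_to_df, tnames = raw$torsion_names)
  structure(list(trajectory = traj, ladder = ladder, swap_stats = stats,
                 swap_log = sl, permutation = raw$permutation,
                 replica_frames = rf),
            class = "rest_result")
}

#' @export
print.rest_result <- function(x, ...) {
  print(x$ladder)
  if (nrow(x$swap_stats))
    cat("swap acceptance:",
        paste(sprintf("%d-%d %.2f", x$swap_stats$pair, x$swap_stats$pair + 1,
                      x$swap_stats$ratio), collapse = ", "), "\n")
  print(x$trajectory)
  invisible(x)
}
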