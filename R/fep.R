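#' Free energy perturbation over a lambda ladder
#'
#' Alchemical free energies are estimated with the Zwanzig exponential
#' average.  Each window simulates the system at one lambda value and
#' accumulates, for every recorded physical-ensemble frame, the energy
#' gaps to both neighboring windows (double-wide sampling), so one pass
#' over the ladder yields both the forward and the backward total and
#' their disagreement (hysteresis) as a convergence diagnostic.
#'
#' @name fep
NULL

#' Lambda schedule
#'
#' @param n number of equally spaced windows (default 11), or use
#'   \code{values} for an explicit schedule
#' @param values strictly ascending values starting at 0 and ending at 1
#' @return numeric vector of class \code{lambda_schedule}
#' @export
lambda_schedule <- function(n = 11, values = NULL) {
  v <- if (is.null(values)) seq(0, 1, length.out = n) else as.numeric(values)
  if (length(v) < 1 || v[1] != 0 || v[length(v)] != 1 ||
      any(diff(v) <= 0))
    stop("schedule must ascend strictly from 0 to 1")
  structure(v, class = "lambda_schedule")
}

#' Zwanzig free energy estimator
#'
#' \deqn{\Delta G = -kT \ln \langle e^{-\Delta E / kT} \rangle}
#' evaluated with a max-shift (log-sum-exp) guard; the standard error
#' comes from block averaging (default 10 blocks).
#'
#' @param delta_e_samples energy gaps, kcal/mol
#' @param temperature K
#' @param n_blocks number of blocks for the error estimate
#' @return list with \code{dG} (kcal/mol), \code{stderr}, \code{n}
#' @export
zwanzig <- function(delta_e_samples, temperature = 298.15, n_blocks = 10) {
  if (!length(delta_e_samples)) stop("no samples")
  if (temperature <= 0) stop("temperature must be positive")
  kt <- kT(temperature)
  est <- function(x) {
    z <- -x / kt
    m <- max(z)
    -kt * (m + log(mean(exp(z - m))))
  }
  n <- length(delta_e_samples)
  nb <- max(1, min(n_blocks, n))
  blk <- split(delta_e_samples, cut(seq_len(n), nb, labels = FALSE))
  bg <- vapply(blk, est, numeric(1))
  se <- if (nb > 1) sd(bg) / sqrt(nb) else 0
  list(dG = est(delta_e_samples), stderr = se, n = n)
}

#' Run one FEP window
#'
#' Simulates the system at \code{lambda_i} (plain MC or REST) and stores
#' the perturbation energies to the neighboring windows for every
#' recorded physical-ensemble frame.  With REST enabled only the
#' ladder-position-0 frames contribute.
#'
#' @param system a \code{toy_system}
#' @param map a non-empty \code{alchemical_map}
#' @param lambda_i window coupling value
#' @param neighbors length-2 list/vector (lambda_prev, lambda_next); use
#'   NA at the schedule boundaries
#' @param cfg a \code{chain_config}
#' @param ladder optional \code{replica_ladder} for REST sampling
#' @param moves list of \code{move_spec}
#' @return list of class \code{fep_window} with \code{lambda},
#'   \code{de_fwd}, \code{de_bwd} (kcal/mol per frame; NULL at the
#'   boundaries) and the window \code{trajectory}
#' @export
run_window <- function(system, map, lambda_i, neighbors, cfg,
                       ladder = NULL, moves = default_moves(system)) {
  if (is.null(map) || (is.null(map$atoms) && is.null(map$torsions)))
    stop("alchemical map is empty")
  lp <- neighbors[[1]]; ln <- neighbors[[2]]
  raw <- engine_driver(system, moves, cfg,
                       ladder_r = if (is.null(ladder)) 1 else ladder$r,
                       swap_every = if (is.null(ladder) ||
                                        ladder$n_replicas == 1) 0L
                                    else ladder$swap_every,
                       map = map, lambda = lambda_i,
                       lambda_prev = if (is.na(lp)) NULL else lp,
                       lambda_next = if (is.na(ln)) NULL else ln)
  structure(list(lambda = lambda_i,
                 lambda_prev = lp, lambda_next = ln,
                 de_bwd = raw$de_prev, de_fwd = raw$de_next,
                 trajectory = new_trajectory(raw, system, moves, cfg)),
            class = "fep_window")
}

#' Run all windows of one leg
#'
#' @param system the leg's \code{toy_system} (complex or unbound ligand)
#' @param map an \code{alchemical_map}
#' @param schedule a \code{lambda_schedule}
#' @param cfg a \code{chain_config}; window w runs with seed
#'   \code{cfg$seed + w}
#' @param ladder optional \code{replica_ladder}
#' @param leg label, "COMPLEX" or "UNBOUND"
#' @param moves list of \code{move_spec}
#' @return a \code{free_energy_result} (see \code{\link{assemble_leg}})
#' @export
run_leg <- function(system, map, schedule, cfg, ladder = NULL,
                    leg = "COMPLEX", moves = default_moves(system)) {
  nv <- length(schedule)
  windows <- vector("list", nv)
  for (w in seq_len(nv)) {
    wcfg <- cfg
    wcfg$seed <- cfg$seed + w
    nb <- c(if (w > 1) schedule[w - 1] else NA,
            if (w < nv) schedule[w + 1] else NA)
    windows[[w]] <- run_window(system, map, schedule[w], nb, wcfg,
                               ladder = ladder, moves = moves)
  }
  assemble_leg(windows, temperature = cfg$temperature, leg = leg,
               schedule = schedule)
}

#' Assemble per-window estimates into a leg total
#'
#' Forward increments come from the lambda-increasing perturbations of
#' windows 1..n-1, backward increments from the lambda-decreasing
#' perturbations of windows 2..n.  The leg total is the symmetrized
#' value \code{(forward - backward) / 2} (the backward sum estimates the
#' reverse transformation); the hysteresis \code{|forward + backward|}
#' is the forward/reverse disagreement.  Window standard errors combine
#' in quadrature.
#'
#' @param windows list of \code{fep_window} covering the schedule
#'   contiguously
#' @param temperature K
#' @param leg label, "COMPLEX" or "UNBOUND"
#' @param schedule the \code{lambda_schedule} the windows must cover
#' @param n_blocks block count for the per-window error estimate
#' @return object of class \code{free_energy_result} with the per-window
#'   table, forward/backward totals, symmetrized \code{total},
#'   \code{stderr} and \code{hysteresis}
#' @export
assemble_leg <- function(windows, temperature = 298.15, leg = "COMPLEX",
                         schedule = NULL, n_blocks = 10) {
  lam <- vapply(windows, `[[`, numeric(1), "lambda")
  if (is.unsorted(lam, strictly = length(lam) > 1))
    stop("windows must be ordered by lambda")
  if (!is.null(schedule) && !isTRUE(all.equal(as.numeric(schedule), lam)))
    stop("windows do not cover the lambda schedule contiguously")
  nv <- length(windows)
  tab <- data.frame(lambda = lam, dG_fwd = NA_real_, se_fwd = NA_real_,
                    dG_bwd = NA_real_, se_bwd = NA_real_)
  for (w in seq_len(nv)) {
    if (!is.null(windows[[w]]$de_fwd)) {
      z <- zwanzig(windows[[w]]$de_fwd, temperature, n_blocks)
      tab$dG_fwd[w] <- z$dG; tab$se_fwd[w] <- z$stderr
    }
    if (!is.null(windows[[w]]$de_bwd)) {
      z <- zwanzig(windows[[w]]$de_bwd, temperature, n_blocks)
      tab$dG_bwd[w] <- z$dG; tab$se_bwd[w] <- z$stderr
    }
  }
  if (nv > 1 && (any(is.na(tab$dG_fwd[-nv])) || any(is.na(tab$dG_bwd[-1]))))
    stop("gap in the window ladder")
  fwd <- sum(tab$dG_fwd[-nv]); se_f <- sqrt(sum(tab$se_fwd[-nv]^2))
  bwd <- sum(tab$dG_bwd[-1]);  se_b <- sqrt(sum(tab$se_bwd[-1]^2))
  if (nv == 1) { fwd <- 0; bwd <- 0; se_f <- 0; se_b <- 0 }
  structure(list(leg = leg, windows = tab,
                 forward = fwd, backward = bwd,
                 total = (fwd - bwd) / 2,
                 stderr = sqrt(se_f^2 + se_b^2) / 2,
                 hysteresis = abs(fwd + bwd),
                 temperature = temperature),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("free_energy_result [%s]: dG = %.3f +- %.3f kcal/mol (fwd %.3f, rev %.3f, hysteresis %.3f)\n",
              x$leg, x$total, x$stderr, x$forward, -x$backward,
              x$hysteresis))
  invisible(x)
}

#' @export
summary.free_energy_result <- function(object, ...) {
  print(object)
  print(object$windows, digits = 4)
  invisible(object)
}

#' Relative binding free energy from the thermodynamic cycle
#'
#' \deqn{\Delta\Delta G = \Delta G_{mut}(complex) - \Delta G_{mut}(unbound)}
#' with the leg errors combined in quadrature.
#'
#' @param complex_leg,unbound_leg \code{free_energy_result}s for the two
#'   legs (same mutation, same schedule)
#' @return object of class \code{binding_cycle} with \code{ddg} and
#'   \code{stderr}
#' @export
ddg_binding <- function(complex_leg, unbound_leg) {
  if (!isTRUE(all.equal(complex_leg$windows$lambda,
                        unbound_leg$windows$lambda)))
    stop("legs use different lambda schedules")
  structure(list(complex_leg = complex_leg, unbound_leg = unbound_leg,
                 ddg = complex_leg$total - unbound_leg$total,
                 stderr = sqrt(complex_leg$stderr^2 + unbound_leg$stderr^2)),
            class = "binding_cycle")
}

#' @export
print.binding_cycle <- function(x, ...) {
  cat(sprintf("binding_cycle: ddG = %.3f +- %.3f kcal/mol (complex %.3f, unbound %.3f)\n",
              x$ddg, x$stderr, x$complex_leg$total, x$unbound_leg$total))
  invisible(x)
}

#' Run a full relative binding free energy calculation
#'
#' Runs the complex leg (REST-sampled by default, with the ligand and
#' the flexible pocket residue in the hot region) and the unbound leg
#' (the ligand alone with the same force field) over the same schedule
#' and assembles the thermodynamic cycle.
#'
#' @param complex_system the pocket complex
#' @param map an \code{alchemical_map} for the mutation
#' @param cfg a \code{chain_config}
#' @param schedule a \code{lambda_schedule}
#' @param ladder \code{replica_ladder} for the complex leg; NULL
#'   disables REST
#' @param unbound_steps MC steps for the unbound leg (its landscape is
#'   one rotor, so the default reuses \code{cfg$n_steps})
#' @return a \code{binding_cycle}
#' @export
run_binding_cycle <- function(complex_system, map, cfg,
                              schedule = lambda_schedule(),
                              ladder = replica_ladder(),
                              unbound_steps = cfg$n_steps) {
  cleg <- run_leg(complex_system, map, schedule, cfg, ladder = ladder,
                  leg = "COMPLEX")
  lig_atoms <- which(complex_system$atoms$region == "LIGAND")
  unb <- unbound_ligand(complex_system)
  umap <- remap_alchemical(map, lig_atoms)
  ucfg <- cfg
  ucfg$n_steps <- as.integer(unbound_steps)
  ucfg$seed <- cfg$seed + 500
  uleg <- run_leg(unb, umap, schedule, ucfg, ladder = NULL,
                  leg = "UNBOUND")
  ddg_binding(cleg, uleg)
}

# re-index an alchemical map onto a subset of atoms
remap_alchemical <- function(map, keep) {
  remap <- match(seq_len(max(keep, map$atoms$atom)), keep)
  if (!is.null(map$atoms)) {
    map$atoms$atom <- remap[map$atoms$atom]
    if (any(is.na(map$atoms$atom)))
      stop("alchemical map touches atoms outside the subset")
  }
  map
}
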