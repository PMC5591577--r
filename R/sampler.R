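#' Metropolis Monte Carlo sampling
#'
#' The sampler proposes symmetric rigid-body (translate/rotate) and
#' torsional moves over the mobile degrees of freedom.  Torsion moves
#' draw either a small perturbation or, with a configurable flip
#' probability, a large jump of +-120 or 180 degrees between rotamer
#' wells -- the move class that, combined with REST tempering, carries
#' the sampler between binding modes.
#'
#' @name sampler
NULL

#' Metropolis acceptance rule
#'
#' Accept if \code{rng_draw < min(1, exp(-delta_e / kT))}; downhill moves
#' (delta_e <= 0) are accepted unconditionally, which also guards the
#' exponential against overflow.
#'
#' @param delta_e energy change, kcal/mol (vectorized)
#' @param temperature K
#' @param rng_draw uniform(0,1) draw(s)
#' @return logical vector
#' @export
metropolis_accept <- function(delta_e, temperature, rng_draw) {
  if (any(temperature <= 0)) stop("temperature must be positive")
  delta_e <= 0 | rng_draw < exp(-delta_e / kT(temperature))
}

#' Move specification
#'
#' @param kind one of "TRANSLATE", "ROTATE", "TORSION"
#' @param target for TORSION moves the torsion index; for rigid-body
#'   moves an integer vector of atom indices forming the moved body
#' @param max_displacement maximum displacement (Angstrom for TRANSLATE,
#'   degrees otherwise); must be positive unless zero is wanted for a
#'   deliberate null move
#' @param weight relative sampling probability (normalized internally)
#' @return object of class \code{move_spec}
#' @export
move_spec <- function(kind, target, max_displacement, weight = 1) {
  kind <- match.arg(kind, c("TRANSLATE", "ROTATE", "TORSION"))
  if (max_displacement < 0) stop("max_displacement must be non-negative")
  if (weight <= 0) stop("weight must be positive")
  structure(list(kind = kind, target = target,
                 max_displacement = max_displacement, weight = weight),
            class = "move_spec")
}

#' Default move mix for a system
#'
#' 40% ligand rigid-body moves (translate up to 0.15 Angstrom, rotate up
#' to 15 degrees, split evenly), 40% ligand torsion perturbations (up to
#' 15 degrees) and 20% hot-residue torsion moves, consistent with
#' roughly 40% acceptance on the default pocket.  Systems without a
#' given move class redistribute its weight over the others.
#'
#' @param system a \code{toy_system}
#' @param rigid_body include ligand rigid-body moves (default TRUE when
#'   any environment atoms exist; pointless for an isolated ligand)
#' @return list of \code{move_spec}
#' @export
default_moves <- function(system,
                          rigid_body = any(system$atoms$region == "ENVIRONMENT")) {
  sol <- system$atoms$region
  tt <- system$torsions
  tor_region <- if (nrow(tt)) {
    vapply(seq_len(nrow(tt)), function(t) {
      a <- as.integer(tt[t, c("a1", "a2", "a3", "a4")])
      if (any(sol[a] == "HOT_RESIDUE")) "HOT_RESIDUE" else "LIGAND"
    }, character(1))
  } else character()
  lig_t <- which(tor_region == "LIGAND")
  hot_t <- which(tor_region == "HOT_RESIDUE")
  moves <- list()
  lig_atoms <- which(sol == "LIGAND" & system$atoms$mobile)
  if (rigid_body && length(lig_atoms)) {
    moves <- c(moves,
               list(move_spec("TRANSLATE", lig_atoms, 0.15, 0.2),
                    move_spec("ROTATE", lig_atoms, 15, 0.2)))
  }
  for (t in lig_t)
    moves <- c(moves, list(move_spec("TORSION", t, 15, 0.4 / length(lig_t))))
  for (t in hot_t)
    moves <- c(moves, list(move_spec("TORSION", t, 15, 0.2 / length(hot_t))))
  if (!length(moves)) stop("system has no mobile degrees of freedom")
  moves
}

#' Chain configuration
#'
#' @param n_steps number of MC steps (> 0)
#' @param temperature thermal temperature, K
#' @param seed integer RNG seed (mandatory: no silent nondeterminism)
#' @param record_every recording stride in steps
#' @param equil_fraction fraction of the chain discarded before
#'   recording (default 0.2)
#' @param flip_prob probability that a torsion move proposes a +-120/180
#'   degree flip instead of a small perturbation
#' @param record_positions record full coordinates at each frame
#' @param record_all_replicas record per-replica trajectories (REST)
#' @return object of class \code{chain_config}
#' @export
chain_config <- function(n_steps, temperature = 298.15, seed,
                         record_every = 10, equil_fraction = 0.2,
                         flip_prob = 0.1, record_positions = FALSE,
                         record_all_replicas = FALSE) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_steps > 0, temperature > 0, record_every > 0,
            equil_fraction >= 0, equil_fraction < 1,
            flip_prob >= 0, flip_prob <= 1)
  structure(list(n_steps = as.integer(n_steps), temperature = temperature,
                 seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 equil_fraction = equil_fraction, flip_prob = flip_prob,
                 record_positions = record_positions,
                 record_all_replicas = record_all_replicas),
            class = "chain_config")
}

# Translate move specs into the engine's parallel arrays
engine_moves <- function(system, moves) {
  kinds <- c(TRANSLATE = 0L, ROTATE = 1L, TORSION = 2L)
  kind <- vapply(moves, function(m) kinds[[m$kind]], integer(1))
  tor <- rep(-1L, length(moves))
  atoms <- vector("list", length(moves))
  for (m in seq_along(moves)) {
    mv <- moves[[m]]
    if (mv$kind == "TORSION") {
      t <- as.integer(mv$target)
      if (t < 1 || t > nrow(system$torsions)) stop("no such torsion: ", t)
      if (!all(system$atoms$mobile[system$moving[[t]]]))
        stop("torsion ", t, " moves immobile atoms")
      tor[m] <- t - 1L
      atoms[[m]] <- as.integer(system$moving[[t]]) - 1L
    } else {
      a <- as.integer(mv$target)
      if (!all(system$atoms$mobile[a])) stop("move targets immobile atoms")
      atoms[[m]] <- a - 1L
    }
  }
  list(kind = kind, atoms = atoms, tor = tor,
       max = vapply(moves, `[[`, numeric(1), "max_displacement"),
       weight = vapply(moves, `[[`, numeric(1), "weight"))
}

# Shared driver behind run_chain / run_rest / run_window
engine_driver <- function(system, moves, cfg, ladder_r = 1,
                          swap_every = 0L, map = NULL, lambda = 0,
                          lambda_prev = NULL, lambda_next = NULL) {
  pos <- as.matrix(system$atoms[, c("x", "y", "z")])
  p <- system$pairs
  em <- engine_moves(system, moves)
  tt <- system$torsions
  tor_atoms <- if (nrow(tt)) {
    matrix(as.integer(as.matrix(tt[, c("a1", "a2", "a3", "a4")])) - 1L,
           ncol = 4)
  } else matrix(integer(), 0, 4)
  tor_moving <- lapply(system$moving, function(m) as.integer(m) - 1L)
  sub <- alchemical_subset(system, map)
  raw <- engine_run(
    pos, as.integer(p$i) - 1L, as.integer(p$j) - 1L, as.integer(p$class),
    pair_table(system, map, lambda),
    if (is.null(lambda_prev)) NULL else pair_table(system, map, lambda_prev),
    if (is.null(lambda_next)) NULL else pair_table(system, map, lambda_next),
    tor_atoms, tor_moving, as.integer(torsion_classes(system)),
    torsion_table(system, map, lambda),
    if (is.null(lambda_prev)) NULL else torsion_table(system, map, lambda_prev),
    if (is.null(lambda_next)) NULL else torsion_table(system, map, lambda_next),
    as.integer(sub$pairs) - 1L, as.integer(sub$torsions) - 1L,
    em$kind, em$atoms, em$tor, em$max, em$weight, cfg$flip_prob,
    ladder_r, as.integer(swap_every),
    cfg$n_steps, cfg$temperature, cfg$seed,
    cfg$record_every, cfg$equil_fraction,
    cfg$record_positions, cfg$record_all_replicas)
  raw$torsion_names <- if (nrow(tt)) rownames(tt) else character()
  raw
}

frames_to_df <- function(fr, tnames) {
  df <- as.data.frame(fr)
  names(df) <- c("step", if (length(tnames)) tnames else character(),
                 "e_ss", "e_sw", "e_ww", "accepted")
  df$accepted <- as.logical(df$accepted)
  df
}

#' Run a plain Metropolis Monte Carlo chain
#'
#' @param system a \code{toy_system}
#' @param cfg a \code{chain_config}
#' @param moves list of \code{move_spec} (default \code{default_moves})
#' @return object of class \code{mc_trajectory}: \code{$frames} is a
#'   data.frame with the step index, one column of dihedral angles
#'   (degrees) per torsion, the energy decomposition and the acceptance
#'   flag; \code{$acceptance} reports the per-move acceptance ratios.
#' @export
run_chain <- function(system, cfg, moves = default_moves(system)) {
  raw <- engine_driver(system, moves, cfg)
  new_trajectory(raw, system, moves, cfg)
}

new_trajectory <- function(raw, system, moves, cfg) {
  acc <- data.frame(
    kind = vapply(moves, `[[`, character(1), "kind"),
    attempts = as.integer(raw$attempts[1, ]),
    accepts = as.integer(raw$accepts[1, ]))
  acc$ratio <- ifelse(acc$attempts > 0, acc$accepts / acc$attempts, NA)
  final <- system
  final$atoms[, c("x", "y", "z")] <- raw$final_positions
  structure(list(frames = frames_to_df(raw$frames, raw$torsion_names),
                 positions = raw$positions,
                 acceptance = acc, config = cfg,
                 final_system = final),
            class = "mc_trajectory")
}

#' @export
print.mc_trajectory <- function(x, ...) {
  cat(sprintf("mc_trajectory: %d frames, %d steps at %.2f K\n",
              nrow(x$frames), x$config$n_steps, x$config$temperature))
  by_kind <- stats::aggregate(cbind(attempts, accepts) ~ kind,
                              x$acceptance, sum)
  for (i in seq_len(nrow(by_kind)))
    cat(sprintf("  %-9s acceptance %.3f (%d/%d)\n", by_kind$kind[i],
                by_kind$accepts[i] / max(1, by_kind$attempts[i]),
                by_kind$accepts[i], by_kind$attempts[i]))
  invisible(x)
}

#' Propose a single Monte Carlo move (reference implementation)
#'
#' R-level mirror of the engine's proposal step, returning the trial
#' system and the energy change computed incrementally from only the
#' interactions involving moved atoms.  Uses R's RNG.
#'
#' @param system a \code{toy_system}
#' @param move a \code{move_spec}
#' @param flip_prob probability of a torsional flip proposal
#' @return list with \code{trial} (the trial \code{toy_system}),
#'   \code{delta_e} (an \code{energy_decomposition} of the change) and
#'   \code{moved} (atom indices displaced)
#' @export
propose_move <- function(system, move, flip_prob = 0.1) {
  if (move$kind == "TORSION") {
    t <- as.integer(move$target)
    moved <- system$moving[[t]]
  } else moved <- as.integer(move$target)
  if (!all(system$atoms$mobile[moved]))
    stop("move targets immobile atoms")
  e_old <- moved_energy(system, moved)
  trial <- if (move$kind == "TRANSLATE") {
    transform_atoms(system, moved, shift = runif(3, -1, 1) * move$max_displacement)
  } else if (move$kind == "ROTATE") {
    cen <- colMeans(system$atoms[moved, c("x", "y", "z")])
    ax <- rnorm(3)
    transform_atoms(system, moved, axis = ax,
                    angle = runif(1, -1, 1) * move$max_displacement,
                    center = as.numeric(cen))
  } else {
    delta <- if (runif(1) < flip_prob) sample(c(120, -120, 180), 1)
             else runif(1, -1, 1) * move$max_displacement
    tt <- system$torsions[move$target, ]
    pos <- as.matrix(system$atoms[, c("x", "y", "z")])
    transform_atoms(system, moved, axis = pos[tt$a3, ] - pos[tt$a2, ],
                    angle = delta, center = pos[tt$a2, ])
  }
  e_new <- moved_energy(trial, moved)
  list(trial = trial,
       delta_e = energy_decomposition(e_new$e_ss - e_old$e_ss,
                                      e_new$e_sw - e_old$e_sw,
                                      e_new$e_ww - e_old$e_ww),
       moved = moved)
}

# energy of the pair/torsion terms that can change when `moved` displace
# rigidly together
moved_energy <- function(system, moved) {
  p <- system$pairs
  inset <- seq_len(nrow(system$atoms)) %in% moved
  aff <- xor(inset[p$i], inset[p$j])
  pt <- pair_table(system)[aff, , drop = FALSE]
  pos <- as.matrix(system$atoms[, c("x", "y", "z")])
  e <- c(0, 0, 0)
  if (any(aff)) {
    d <- pos[p$i[aff], , drop = FALSE] - pos[p$j[aff], , drop = FALSE]
    ep <- pair_energy_from_table(pt, rowSums(d * d))
    for (k in 0:2) e[k + 1] <- e[k + 1] + sum(ep[p$class[aff] == k])
  }
  tt <- system$torsions
  if (nrow(tt)) {
    cnt <- apply(tt[, c("a1", "a2", "a3", "a4")], 1,
                 function(a) sum(inset[as.integer(a)]))
    taff <- which(cnt > 0 & cnt < 4)
    if (length(taff)) {
      th <- torsion_angles(system)[taff]
      et <- torsion_energy(th, tt$V1[taff], tt$V2[taff], tt$V3[taff])
      tc <- torsion_classes(system)[taff]
      for (k in 0:2) e[k + 1] <- e[k + 1] + sum(et[tc == k])
    }
  }
  energy_decomposition(e[1], e[2], e[3])
}
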