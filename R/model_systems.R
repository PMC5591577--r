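#' Toy model systems: isolated rotors and the hydrophobic pocket complex
#'
#' The pocket complex abstracts a fragment-bound hydrophobic protein
#' pocket: a rigid cage of apolar sites (the environment), a three-site
#' side-chain rotor with a 3-fold torsion chi (the flexible pocket
#' residue, region HOT_RESIDUE), and a two-ring ligand joined by a linker
#' torsion phi carrying one mutable substituent site.  All coordinates
#' are generated deterministically from a specification and a seed.
#'
#' @name model_systems
NULL

#' Toy substituent parameter sets
#'
#' Synthetic OPLS-flavored parameters for the mutable substituent site.
#' These are fixture definitions for the toy pocket (monotone sigma
#' H < F < CL < BR so that bulkier substituents couple sterically to the
#' side-chain rotor); they are not parameters of any real molecule.
#'
#' @return data.frame with columns label, charge (e), sigma (Angstrom),
#'   epsilon (kcal/mol)
#' @export
substituent_table <- function() {
  data.frame(
    label = c("H", "F", "CL", "BR", "CH3"),
    charge = c(0.06, -0.12, -0.09, -0.09, 0.00),
    sigma = c(2.42, 2.94, 3.40, 3.47, 3.50),
    epsilon = c(0.03, 0.061, 0.30, 0.47, 0.066),
    stringsAsFactors = FALSE)
}

substituent_params <- function(label) {
  tab <- substituent_table()
  i <- match(toupper(label), tab$label)
  if (is.na(i)) stop("unknown substituent: ", label)
  tab[i, ]
}

#' Isolated single-rotor system
#'
#' Four atoms in a chain forming one torsion; no nonbonded interactions
#' (all charges and well depths zero).  The system energy is exactly the
#' torsion energy, which makes it the oracle test system for sampling
#' and free energy estimators.
#'
#' @param V1,V2,V3 Fourier amplitudes, kcal/mol
#' @param angle initial dihedral in degrees
#' @return a \code{toy_system} with a single mobile torsion
#' @export
make_rotor <- function(V1 = 0, V2 = 0, V3 = 0, angle = 0) {
  atoms <- data.frame(
    x = c(-0.5, 0, 1.5, 2.0),
    y = c(1.4, 0, 0, 1.4),
    z = c(0, 0, 0, 0),
    charge = 0, sigma = 3.5, epsilon = 0,
    region = "LIGAND", mobile = TRUE)
  sys <- toy_system(atoms,
                    fragments = list(c(1L, 2L), c(3L, 4L)),
                    torsions = data.frame(a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L,
                                          V1 = V1, V2 = V2, V3 = V3),
                    exclusions = rbind(c(1, 2), c(2, 3), c(3, 4),
                                       c(1, 3), c(2, 4)),
                    pairs14 = rbind(c(1, 4)))
  set_torsion(sys, 1, angle)
}

#' Pocket complex specification
#'
#' @param n_cage_sites number of cage sites on the hemispherical shell
#' @param cage_radius shell radius, Angstrom
#' @param cage_sigma,cage_epsilon LJ parameters of cage sites
#' @param ring_sigma,ring_epsilon LJ parameters of ring carbons
#' @param phi_V,chi_V length-3 Fourier amplitudes of the linker torsion
#'   phi and the side-chain torsion chi, kcal/mol
#' @param cage_center center of the hemispherical shell (the pocket
#'   floor lies below the ligand plane)
#' @param rotor_base position of the side-chain anchor atom at the cage
#'   wall
#' @param rotor_target point the rotor axis leans toward; the tip swings
#'   on a cone about this axis, approaching the ligand substituent site
#'   in one rotamer and the pocket wall in another
#' @param jitter amplitude of the seeded cage-coordinate jitter, Angstrom
#' @return object of class \code{pocket_spec}
#' @export
pocket_spec <- function(n_cage_sites = 14, cage_radius = 6.5,
                        cage_sigma = 3.5, cage_epsilon = 0.12,
                        ring_sigma = 3.55, ring_epsilon = 0.07,
                        phi_V = c(2.0, 0, 1.5), chi_V = c(0, 0, 4.0),
                        cage_center = c(0, 0, -1.2),
                        rotor_base = c(6.6, -5.3, -2.0),
                        rotor_target = c(3.0, 2.5, 1.5),
                        jitter = 0.15) {
  structure(as.list(environment()), class = "pocket_spec")
}

#' Generate the pocket complex for a substituent
#'
#' Builds the cage + rotor + two-ring ligand system deterministically for
#' a given specification and seed.  Atom order: ligand ring A (1-6),
#' ring B (7-12), substituent site (13), rotor (14-16), cage sites
#' (17 onward).  The linker torsion phi is torsion 1 and the side-chain
#' torsion chi is torsion 2.
#'
#' @param spec a \code{pocket_spec}
#' @param substituent substituent label (see \code{\link{substituent_table}})
#' @param seed integer seed for the cage jitter
#' @return a \code{toy_system}
#' @export
make_pocket_complex <- function(spec = pocket_spec(), substituent = "F",
                                seed = 1L) {
  sub <- substituent_params(substituent)
  hex <- function(center, start_deg, radius = 1.4) {
    ang <- (start_deg + seq(0, 300, by = 60)) * pi / 180
    cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang), center[3])
  }
  ringA <- hex(c(-2.9, 0, 0), 0)      # A1 points +x toward the linker
  ringB <- hex(c(1.5, 0, 0), 180)     # B1 points -x toward the linker
  # substituent at the meta position of ring B (ring atom 3, the
  # rotor-facing side), displaced radially outward
  bsub <- 3L
  dirX <- (ringB[bsub, ] - c(1.5, 0, 0)) / 1.4
  posX <- ringB[bsub, ] + 1.5 * dirX
  # side-chain rotor: anchored at the cage wall beside the substituent;
  # chi swings the tip atom on a wide cone (~114 degree bond angle).
  # The tip is built at the cone azimuth nearest the substituent site
  # and the (fixed) anchor is placed so that this rotamer reads
  # chi = 180 degrees, matching the rotamer labels used throughout.
  r1 <- spec$rotor_base
  ax <- spec$rotor_target - r1
  ax <- ax / sqrt(sum(ax^2))
  r2 <- r1 + 1.5 * ax
  cone_c <- r2 + 1.5 * 0.41 * ax
  v <- posX - cone_c
  e_x <- v - sum(v * ax) * ax          # perp direction toward X
  e_x <- e_x / sqrt(sum(e_x^2))
  r3 <- cone_c + 1.5 * 0.91 * e_x      # tip at the X-facing azimuth
  anchor_pos <- r1 - 1.5 * (0.41 * ax + 0.91 * e_x)
  if (abs(circular_distance(dihedral_angle(anchor_pos, r1, r2, r3), 180)) > 1)
    anchor_pos <- r1 - 1.5 * (0.41 * ax - 0.91 * e_x)

  # tip positions of the chi = 60 and chi = 300 rotamers, for carving
  # the shell: the side chain replaces the pocket wall around the
  # rotamers it must be able to reach (60 and 180), while the third
  # 3-fold position (300) stays pressed against the wall
  cand <- lapply(c(120, -120), function(a)
    as.numeric(rotation_matrix(r1 - r2, a) %*% (r3 - r2)) + r2)
  is60 <- vapply(cand, function(p)
    circular_distance(dihedral_angle(anchor_pos, r1, r2, p), 60),
    numeric(1))
  tip60 <- cand[[which.min(is60)]]
  tip300 <- cand[[which.max(is60)]]

  # cage site 1 is the fixed anchor; the rest form the jittered shell,
  # pushed radially outward where it would crowd the reachable rotamers
  shell <- cage_sites(spec, seed)
  for (k in seq_len(nrow(shell))) {
    for (pt in list(r3, tip60, r2)) {
      d <- sqrt(sum((shell[k, ] - pt)^2))
      if (d < 3.5) {
        dir <- shell[k, ] - spec$cage_center
        dir <- dir / sqrt(sum(dir^2))
        while (sqrt(sum((shell[k, ] - pt)^2)) < 3.5)
          shell[k, ] <- shell[k, ] + 0.25 * dir
      }
    }
  }
  # the shell site nearest the third rotamer position becomes a wall
  # contact pressing against it, so the side chain has two reachable
  # rotamers (60, 180) like a buried leucine
  wall <- which.min(colSums((t(shell) - tip300)^2))
  shell[wall, ] <- tip300 + 2.85 * (tip300 - cone_c) /
    sqrt(sum((tip300 - cone_c)^2))
  cage <- rbind(anchor_pos, shell)
  anchor <- 1L

  pos <- rbind(ringA, ringB, posX, r1, r2, r3, cage)
  n_lig <- 13L
  n <- nrow(pos)
  cage_idx <- seq(17L, n)
  atoms <- data.frame(
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = c(rep(0, 12), sub$charge, 0, -0.05, 0.05, rep(0, length(cage_idx))),
    sigma = c(rep(spec$ring_sigma, 12), sub$sigma, rep(3.3, 3),
              rep(spec$cage_sigma, length(cage_idx))),
    epsilon = c(rep(spec$ring_epsilon, 12), sub$epsilon, rep(0.1, 3),
                rep(spec$cage_epsilon, length(cage_idx))),
    region = c(rep("LIGAND", n_lig), rep("HOT_RESIDUE", 3),
               rep("ENVIRONMENT", length(cage_idx))),
    mobile = c(rep(TRUE, n_lig), FALSE, TRUE, TRUE,
               rep(FALSE, length(cage_idx))))
  # charge-neutral ligand: the attachment carbon balances the substituent
  atoms$charge[6 + bsub] <- -sub$charge

  # bond graph (for 1-2/1-3 exclusions and 1-4 pairs)
  ringbonds <- function(off) cbind(off + 1:6, off + c(2:6, 1))
  bonds <- rbind(ringbonds(0L), ringbonds(6L),
                 c(1L, 7L),              # linker A1-B1
                 c(6L + bsub, 13L),      # substituent bond
                 c(14L, 15L), c(15L, 16L),
                 c(16L + anchor, 14L))   # rotor anchored to cage
  excl <- bonded_pairs(bonds, n, dist = c(1, 2))
  p14 <- bonded_pairs(bonds, n, dist = 3)

  torsions <- data.frame(
    a1 = c(2L, 16L + anchor), a2 = c(1L, 14L), a3 = c(7L, 15L),
    a4 = c(8L, 16L),
    V1 = c(spec$phi_V[1], spec$chi_V[1]),
    V2 = c(spec$phi_V[2], spec$chi_V[2]),
    V3 = c(spec$phi_V[3], spec$chi_V[3]))
  rownames(torsions) <- c("phi", "chi")

  fragments <- c(list(1:6), list(c(7:13)), list(14L), list(c(15L, 16L)),
                 as.list(cage_idx))
  sys <- toy_system(atoms, fragments, torsions, excl, p14)
  sys$spec <- spec
  sys$substituent <- toupper(sub$label)
  sys
}

# deterministic hemispherical shell (z <= 0) of cage sites: golden-angle
# spiral plus a small seeded jitter (one site is reserved for the fixed
# rotor anchor, so the shell holds n_cage_sites - 1)
cage_sites <- function(spec, seed) {
  m <- spec$n_cage_sites - 1L
  k <- seq_len(m)
  z <- -(k - 0.5) / m                    # z/R in (-1, 0)
  th <- k * pi * (3 - sqrt(5))           # golden angle
  rho <- sqrt(1 - z^2)
  base <- spec$cage_radius * cbind(rho * cos(th), rho * sin(th), z)
  base <- sweep(base, 2, spec$cage_center, `+`)
  jit <- with_seed(seed, matrix(runif(3 * m, -spec$jitter, spec$jitter), m, 3))
  base + jit
}

# evaluate expr with a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

# all pairs at the given bond-graph distances
bonded_pairs <- function(bonds, n, dist) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    adj[[bonds[b, 1]]] <- c(adj[[bonds[b, 1]]], bonds[b, 2])
    adj[[bonds[b, 2]]] <- c(adj[[bonds[b, 2]]], bonds[b, 1])
  }
  out <- NULL
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n); d[s] <- 0L; frontier <- s
    for (step in seq_len(max(dist))) {
      nxt <- setdiff(unique(unlist(adj[frontier])), which(!is.na(d)))
      if (!length(nxt)) break
      d[nxt] <- step; frontier <- nxt
    }
    hit <- which(d %in% dist & seq_len(n) > s)
    if (length(hit)) out <- rbind(out, cbind(s, hit))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

#' Build the alchemical map for a substituent swap
#'
#' Single-topology mutation of the substituent site (atom 13) and its
#' attachment carbon (charge balance) from one substituent to another.
#'
#' @param system a pocket complex (or its unbound ligand subset)
#' @param from,to substituent labels
#' @param sub_atom,attach_atom atom indices of the substituent site and
#'   its attachment carbon
#' @return an \code{alchemical_map}
#' @export
substituent_map <- function(system, from, to, sub_atom = 13L,
                            attach_atom = 9L) {
  a <- substituent_params(from)
  b <- substituent_params(to)
  alchemical_map(atoms = data.frame(
    atom = c(sub_atom, attach_atom),
    charge_A = c(a$charge, -a$charge),
    charge_B = c(b$charge, -b$charge),
    sigma_A = c(a$sigma, system$atoms$sigma[attach_atom]),
    sigma_B = c(b$sigma, system$atoms$sigma[attach_atom]),
    epsilon_A = c(a$epsilon, system$atoms$epsilon[attach_atom]),
    epsilon_B = c(b$epsilon, system$atoms$epsilon[attach_atom])))
}

#' Extract the unbound ligand from a complex
#'
#' Keeps only the LIGAND atoms (the unbound leg of the thermodynamic
#' cycle: the ligand alone, in vacuum, with the same force field).
#' @param system a \code{toy_system}
#' @return a \code{toy_system} containing the ligand only
#' @export
unbound_ligand <- function(system) {
  subset_system(system, which(system$atoms$region == "LIGAND"))
}

#' Subset a system to a set of atoms
#'
#' Retains fragments, torsions, exclusions and 1-4 pairs that lie fully
#' inside the kept atom set; indices are remapped.
#' @param system a \code{toy_system}
#' @param keep integer atom indices to keep
#' @return a \code{toy_system}
#' @export
subset_system <- function(system, keep) {
  keep <- sort(unique(as.integer(keep)))
  remap <- rep(NA_integer_, nrow(system$atoms))
  remap[keep] <- seq_along(keep)
  frag <- lapply(system$fragments, function(f) remap[f][!is.na(remap[f])])
  frag <- frag[lengths(frag) > 0]
  tt <- system$torsions
  tin <- apply(tt[, c("a1", "a2", "a3", "a4")], 1,
               function(a) all(!is.na(remap[as.integer(a)])))
  tt <- tt[tin, , drop = FALSE]
  for (cc in c("a1", "a2", "a3", "a4")) tt[[cc]] <- remap[tt[[cc]]]
  subp <- function(m) {
    if (!nrow(m)) return(m)
    ok <- !is.na(remap[m[, 1]]) & !is.na(remap[m[, 2]])
    cbind(remap[m[ok, 1]], remap[m[ok, 2]])
  }
  toy_system(system$atoms[keep, , drop = FALSE], frag, tt,
             subp(system$exclusions), subp(system$pairs14))
}

#' Exact free energy change and Boltzmann density for an isolated rotor
#'
#' Partition functions by trapezoidal quadrature of exp(-V/kT) on a fine
#' angular grid; the free energy difference between two torsion parameter
#' sets is -kT ln(Z_B/Z_A).
#'
#' @param V_A,V_B length-3 Fourier amplitude vectors
#' @param temperature K
#' @param grid_deg grid spacing in degrees (default 0.1)
#' @return list with \code{dG} (kcal/mol), \code{theta} (grid, degrees),
#'   \code{density_A}, \code{density_B} (per-degree densities integrating
#'   to 1), \code{Z_A}, \code{Z_B}
#' @export
rotor_oracle <- function(V_A, V_B, temperature = 298.15, grid_deg = 0.1) {
  beta <- 1 / kT(temperature)
  theta <- seq(0, 360, by = grid_deg)
  zdens <- function(V) {
    w <- exp(-beta * torsion_energy(theta, V[1], V[2], V[3]))
    Z <- trapz_uniform(w, grid_deg)
    list(Z = Z, dens = w / Z)
  }
  A <- zdens(V_A); B <- zdens(V_B)
  list(dG = -kT(temperature) * log(B$Z / A$Z), theta = theta,
       density_A = A$dens, density_B = B$dens, Z_A = A$Z, Z_B = B$Z)
}

trapz_uniform <- function(y, h) h * (sum(y) - (y[1] + y[length(y)]) / 2)

#' Probability mass of a Boltzmann rotor in angular bins
#'
#' Integrates the quadrature density of \code{\link{rotor_oracle}} over
#' circular bins; used as the reference distribution in sampling tests.
#' @param V length-3 Fourier amplitudes
#' @param temperature K
#' @param breaks bin edges in degrees, spanning [0, 360]
#' @return bin probabilities summing to 1
#' @export
rotor_bin_probs <- function(V, temperature = 298.15,
                            breaks = seq(0, 360, by = 10)) {
  orc <- rotor_oracle(V, V, temperature, grid_deg = 0.05)
  cum <- c(0, cumsum((orc$density_A[-1] + orc$density_A[-length(orc$density_A)]) /
                       2 * 0.05))
  cdf <- function(x) cum[pmin(length(cum), pmax(1, round(x / 0.05) + 1))]
  p <- diff(vapply(breaks, cdf, numeric(1)))
  p / sum(p)
}

#' Grid scan of the pocket (phi, chi) energy landscape
#'
#' Evaluates the total energy on a regular (phi, chi) grid with the
#' ligand and rotor placed at each torsion combination, and locates the
#' local minima (grid points below all 8 circular neighbors).
#'
#' @param system a pocket complex
#' @param step grid spacing in degrees (default 10)
#' @return list with \code{phi}, \code{chi} (grid values), \code{energy}
#'   (matrix), and \code{minima} (data.frame phi, chi, energy)
#' @export
landscape_scan <- function(system, step = 10) {
  phi <- chi <- seq(0, 360 - step, by = step)
  E <- matrix(NA_real_, length(phi), length(chi))
  for (i in seq_along(phi)) {
    si <- set_torsion(system, 1, phi[i])
    for (j in seq_along(chi)) {
      sij <- set_torsion(si, 2, chi[j])
      E[i, j] <- total_energy(sij)$total
    }
  }
  n <- length(phi)
  mins <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    nb <- expand.grid(di = -1:1, dj = -1:1)
    nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
    ii <- (i - 1 + nb$di) %% n + 1
    jj <- (j - 1 + nb$dj) %% n + 1
    if (all(E[i, j] < E[cbind(ii, jj)]))
      mins <- rbind(mins, data.frame(phi = phi[i], chi = chi[j],
                                     energy = E[i, j]))
  }
  list(phi = phi, chi = chi, energy = E,
       minima = mins[order(mins$energy), ])
}

#' Verify the two-minimum structure of a pocket landscape
#'
#' Grid-scans the (phi, chi) landscape and checks that at least two
#' distinct local minima exist whose connecting barrier exceeds a
#' threshold (default 2 kT at 298.15 K).  The barrier is found by
#' flood-filling the periodic grid from the global minimum upward: the
#' level at which the second minimum joins the same basin is the saddle.
#'
#' @param system a pocket complex
#' @param min_barrier_kT required barrier in units of kT
#' @param temperature K
#' @param step grid spacing in degrees
#' @return list with \code{ok}, \code{barrier_kcal}, \code{minima}
#' @export
check_pocket_landscape <- function(system, min_barrier_kT = 2,
                                   temperature = 298.15, step = 10) {
  ls <- landscape_scan(system, step)
  if (is.null(ls$minima) || nrow(ls$minima) < 2)
    return(list(ok = FALSE, barrier_kcal = 0, minima = ls$minima))
  E <- ls$energy
  n <- nrow(E)
  idx <- function(v) (v - 1) %% n + 1
  gmin <- which(E == min(E), arr.ind = TRUE)[1, ]
  # the second mode is the lowest minimum in a different side-chain
  # rotamer (chi differing by more than 50 degrees): the barrier of
  # interest is the one between binding modes, not between twist
  # sub-states of the same rotamer
  gchi <- ls$chi[gmin[2]]
  dchi <- pmin(abs(ls$minima$chi - gchi), 360 - abs(ls$minima$chi - gchi))
  other <- ls$minima[dchi > 50, , drop = FALSE]
  if (!nrow(other))
    return(list(ok = FALSE, barrier_kcal = 0, minima = ls$minima))
  second <- other[1, ]
  si <- match(second$phi, ls$phi); sj <- match(second$chi, ls$chi)
  # flood fill below an energy level from the global minimum
  reaches <- function(level) {
    seen <- matrix(FALSE, n, n)
    stack <- list(gmin)
    seen[gmin[1], gmin[2]] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- idx(cur[1] + d[1]); nj <- idx(cur[2] + d[2])
        if (!seen[ni, nj] && E[ni, nj] <= level) {
          seen[ni, nj] <- TRUE
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
    seen[si, sj]
  }
  levels <- sort(unique(as.vector(E)))
  lo <- E[si, sj]
  saddle <- levels[which(vapply(levels, reaches, logical(1)))[1]]
  barrier <- saddle - E[si, sj]
  list(ok = barrier >= min_barrier_kT * kT(temperature),
       barrier_kcal = barrier, minima = ls$minima)
}
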