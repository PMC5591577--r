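#' Reduced OPLS-style force field over rigid fragments
#'
#' A toy system is a set of point particles carrying partial charges and
#' Lennard-Jones parameters, partitioned into rigid fragments that are
#' joined by rotatable torsions.  The only degrees of freedom are the
#' torsion angles and rigid-body placement of mobile bodies; bond lengths
#' and angles never change.  Every atom belongs to exactly one region:
#' \code{LIGAND}, \code{HOT_RESIDUE} (a flexible pocket side chain that
#' the REST hot region may include), or \code{ENVIRONMENT}.
#'
#' @name forcefield
NULL

REGIONS <- c("LIGAND", "HOT_RESIDUE", "ENVIRONMENT")

#' Construct a toy system
#'
#' @param atoms data.frame with columns \code{x,y,z} (coordinates, Angstrom),
#'   \code{charge} (e), \code{sigma} (Angstrom, > 0), \code{epsilon}
#'   (kcal/mol, >= 0), \code{region} (one of LIGAND, HOT_RESIDUE,
#'   ENVIRONMENT) and \code{mobile} (logical).
#' @param fragments list of integer vectors partitioning the atom indices
#'   into rigid bodies.
#' @param torsions data.frame with columns \code{a1,a2,a3,a4} (atom indices,
#'   bonded in sequence; the rotatable bond is a2-a3 and must join two
#'   rigid fragments) and Fourier amplitudes \code{V1,V2,V3} (kcal/mol).
#'   May have zero rows.
#' @param exclusions two-column integer matrix of 1-2/1-3 pairs whose
#'   nonbonded interaction is omitted.
#' @param pairs14 two-column integer matrix of 1-4 pairs scaled by 0.5.
#' @return object of class \code{toy_system}
#' @export
toy_system <- function(atoms, fragments, torsions = NULL,
                       exclusions = NULL, pairs14 = NULL) {
  n <- nrow(atoms)
  stopifnot(n >= 1, all(c("x", "y", "z", "charge", "sigma", "epsilon",
                          "region", "mobile") %in% names(atoms)))
  atoms$region <- as.character(atoms$region)
  if (!all(atoms$region %in% REGIONS))
    stop("atom region must be one of ", paste(REGIONS, collapse = ", "))
  if (any(atoms$sigma <= 0)) stop("sigma must be positive")
  if (any(atoms$epsilon < 0)) stop("epsilon must be non-negative")

  frag_ids <- sort(unlist(fragments))
  if (!identical(as.integer(frag_ids), seq_len(n)))
    stop("fragments must partition the atom indices 1..n")

  if (is.null(torsions))
    torsions <- data.frame(a1 = integer(), a2 = integer(), a3 = integer(),
                           a4 = integer(), V1 = numeric(), V2 = numeric(),
                           V3 = numeric())
  exclusions <- normalize_pairs(exclusions)
  pairs14 <- normalize_pairs(pairs14)
  if (nrow(exclusions) && nrow(pairs14)) {
    key <- function(m) paste(m[, 1], m[, 2])
    if (length(intersect(key(exclusions), key(pairs14))))
      stop("exclusions and 1-4 pairs must be disjoint")
  }

  sys <- structure(list(atoms = atoms, fragments = fragments,
                        torsions = torsions, exclusions = exclusions,
                        pairs14 = pairs14),
                   class = "toy_system")
  sys$moving <- torsion_moving_sets(sys)
  sys$pairs <- build_pair_list(sys)
  sys
}

normalize_pairs <- function(p) {
  if (is.null(p) || (is.matrix(p) && nrow(p) == 0))
    return(matrix(integer(), 0, 2))
  p <- matrix(as.integer(p), ncol = 2)
  t(apply(p, 1, sort))
}

# For each torsion, the atoms displaced when the angle changes: the
# fragments on the a3 side of the fragment tree whose edges are the
# rotatable bonds.  Requires the fragment graph to be acyclic.
torsion_moving_sets <- function(sys) {
  nt <- nrow(sys$torsions)
  if (nt == 0) return(list())
  frag_of <- integer(nrow(sys$atoms))
  for (f in seq_along(sys$fragments)) frag_of[sys$fragments[[f]]] <- f
  edges <- cbind(frag_of[sys$torsions$a2], frag_of[sys$torsions$a3])
  if (any(edges[, 1] == edges[, 2]))
    stop("rotatable bond a2-a3 must join two different rigid fragments")
  lapply(seq_len(nt), function(t) {
    # fragments reachable from frag(a3) without crossing edge t
    reach <- edges[t, 2]
    repeat {
      nb <- c(edges[-t, 2][edges[-t, 1] %in% reach],
              edges[-t, 1][edges[-t, 2] %in% reach])
      nb <- setdiff(unique(nb), reach)
      if (!length(nb)) break
      reach <- c(reach, nb)
    }
    if (edges[t, 1] %in% reach)
      stop("fragment graph has a cycle through torsion ", t)
    sort(unlist(sys$fragments[reach]))
  })
}

# All non-excluded i<j pairs with their 1-4 scale factor and region class
# (0 = solute-solute, 1 = solute-environment, 2 = environment-environment).
build_pair_list <- function(sys) {
  n <- nrow(sys$atoms)
  if (n < 2)
    return(data.frame(i = integer(), j = integer(), scale = numeric(),
                      class = integer()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- data.frame(i = idx[, "row"], j = idx[, "col"], scale = 1)
  key <- paste(p$i, p$j)
  if (nrow(sys$exclusions))
    p <- p[!(key %in% paste(sys$exclusions[, 1], sys$exclusions[, 2])), ]
  key <- paste(p$i, p$j)
  if (nrow(sys$pairs14))
    p$scale[key %in% paste(sys$pairs14[, 1], sys$pairs14[, 2])] <- 0.5
  sol <- sys$atoms$region != "ENVIRONMENT"
  p$class <- ifelse(sol[p$i] & sol[p$j], 0L,
                    ifelse(!sol[p$i] & !sol[p$j], 2L, 1L))
  rownames(p) <- NULL
  p
}

# torsion class by majority region of the four atoms; a 2-2 tie counts as
# solute-solute because solute atoms are present
torsion_classes <- function(sys) {
  if (nrow(sys$torsions) == 0) return(integer())
  sol <- sys$atoms$region != "ENVIRONMENT"
  apply(sys$torsions[, c("a1", "a2", "a3", "a4")], 1, function(a) {
    s <- sum(sol[as.integer(a)])
    if (s >= 2) 0L else if (s == 1) 2L else 2L
  })
}

#' OPLS Fourier torsion energy
#'
#' \eqn{V(\theta) = V_1/2 (1+\cos\theta) + V_2/2 (1-\cos 2\theta) +
#' V_3/2 (1+\cos 3\theta)}, periodic with period 360 degrees.
#'
#' @param angle dihedral angle in degrees (wrapped internally)
#' @param V1,V2,V3 Fourier amplitudes, kcal/mol
#' @return energy in kcal/mol
#' @export
torsion_energy <- function(angle, V1, V2, V3) {
  th <- angle * pi / 180
  V1 / 2 * (1 + cos(th)) + V2 / 2 * (1 - cos(2 * th)) +
    V3 / 2 * (1 + cos(3 * th))
}

#' Nonbonded pair energy (Lennard-Jones 12-6 + Coulomb)
#'
#' Geometric combination rules for sigma and epsilon; Coulomb constant
#' 332.06 kcal A mol^-1 e^-2; 1-4 pairs scaled by 0.5 for both terms.
#'
#' @param r separation in Angstrom (> 0)
#' @param q1,q2 partial charges, e
#' @param sigma1,sigma2 LJ diameters, Angstrom
#' @param eps1,eps2 LJ well depths, kcal/mol
#' @param scale14 scale factor (1 for ordinary pairs, 0.5 for 1-4 pairs)
#' @return energy in kcal/mol
#' @export
nonbonded_pair_energy <- function(r, q1, q2, sigma1, sigma2, eps1, eps2,
                                  scale14 = 1) {
  if (any(r <= 0)) stop("overlapping particles: separation must be positive")
  sig <- sqrt(sigma1 * sigma2)
  eps <- sqrt(eps1 * eps2)
  sr6 <- (sig / r)^6
  scale14 * (COULOMB * q1 * q2 / r + 4 * eps * (sr6^2 - sr6))
}

#' Dihedral angle from four points
#'
#' Standard atan2 convention; result in degrees on [0, 360).
#' @param p1,p2,p3,p4 numeric 3-vectors
#' @return angle in degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- crossprod3(b1, b2)
  n2 <- crossprod3(b2, b3)
  m1 <- crossprod3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap an angle to [0, 360)
#' @param a angle in degrees
#' @return wrapped angle
#' @export
wrap_angle <- function(a) a %% 360

#' Current torsion angles of a system
#' @param system a \code{toy_system}
#' @return named numeric vector of angles in degrees, one per torsion
#' @export
torsion_angles <- function(system) {
  pos <- as.matrix(system$atoms[, c("x", "y", "z")])
  tt <- system$torsions
  if (nrow(tt) == 0) return(numeric())
  setNames(vapply(seq_len(nrow(tt)), function(t) {
    dihedral_angle(pos[tt$a1[t], ], pos[tt$a2[t], ], pos[tt$a3[t], ],
                   pos[tt$a4[t], ])
  }, numeric(1)), rownames(tt))
}

#' Region-decomposed total potential energy
#'
#' Sums all non-excluded nonbonded pairs and all torsion terms, split into
#' solute-solute (\code{e_ss}), solute-environment (\code{e_sw}) and
#' environment-environment (\code{e_ww}) components, where the solute is
#' the union of the LIGAND and HOT_RESIDUE regions.  A pair is ss if both
#' atoms are solute, ww if both are environment, sw otherwise; a torsion
#' is classed by the majority region of its four atoms (tie counts as ss).
#' Solute-internal torsions therefore enter \code{e_ss} and are tempered
#' by REST scaling.
#'
#' @param system a \code{toy_system}
#' @param map optional \code{alchemical_map}
#' @param lambda alchemical coupling parameter in [0, 1] (used with map)
#' @return object of class \code{energy_decomposition} with fields
#'   \code{e_ss}, \code{e_sw}, \code{e_ww} and \code{total}
#' @export
total_energy <- function(system, map = NULL, lambda = 0) {
  pt <- pair_table(system, map, lambda)
  vt <- torsion_table(system, map, lambda)
  pos <- as.matrix(system$atoms[, c("x", "y", "z")])
  p <- system$pairs
  e <- c(0, 0, 0)
  if (nrow(p)) {
    d <- pos[p$i, , drop = FALSE] - pos[p$j, , drop = FALSE]
    r2 <- rowSums(d * d)
    if (any(r2 == 0)) stop("overlapping particles: separation must be positive")
    ep <- pair_energy_from_table(pt, r2)
    for (k in 0:2) e[k + 1] <- e[k + 1] + sum(ep[p$class == k])
  }
  if (nrow(system$torsions)) {
    th <- torsion_angles(system) * pi / 180
    et <- vt[, 1] / 2 * (1 + cos(th)) + vt[, 2] / 2 * (1 - cos(2 * th)) +
      vt[, 3] / 2 * (1 + cos(3 * th))
    tc <- torsion_classes(system)
    for (k in 0:2) e[k + 1] <- e[k + 1] + sum(et[tc == k])
  }
  energy_decomposition(e[1], e[2], e[3])
}

# evaluate the tabulated pair form: qq/r + e1 f(s1, r^6/g1) + e2 f(s2, r^6/g2)
# with f(s, x) = 1/(s+x)^2 - 1/(s+x)
pair_energy_from_table <- function(pt, r2) {
  r <- sqrt(r2)
  r6 <- r2 * r2 * r2
  e <- pt[, "qq"] / r
  for (term in c(1, 2)) {
    ei <- pt[, paste0("e", term)]
    use <- ei != 0
    if (any(use)) {
      x <- pmax(pt[use, paste0("s", term)], 0) + r6[use] / pt[use, paste0("g", term)]
      e[use] <- e[use] + ei[use] * (1 / x^2 - 1 / x)
    }
  }
  e
}

#' @rdname total_energy
#' @param e_ss,e_sw,e_ww energy components in kcal/mol
#' @export
energy_decomposition <- function(e_ss, e_sw, e_ww) {
  structure(list(e_ss = e_ss, e_sw = e_sw, e_ww = e_ww,
                 total = e_ss + e_sw + e_ww),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("energy (kcal/mol): total %.6f  [ss %.6f | sw %.6f | ww %.6f]\n",
              x$total, x$e_ss, x$e_sw, x$e_ww))
  invisible(x)
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("toy_system: %d atoms (%s), %d rigid fragments, %d torsions\n",
              nrow(x$atoms),
              paste(sprintf("%d %s", table(factor(x$atoms$region, REGIONS)),
                            tolower(REGIONS)), collapse = ", "),
              length(x$fragments), nrow(x$torsions)))
  invisible(x)
}

#' Apply a rigid transformation to selected atoms
#'
#' Rotation by \code{angle} degrees about a unit \code{axis} through
#' \code{center}, followed by \code{shift}.
#' @param system a \code{toy_system}
#' @param atoms integer indices of atoms to move
#' @param shift length-3 translation (Angstrom)
#' @param axis length-3 rotation axis (need not be normalized)
#' @param angle rotation angle in degrees
#' @param center rotation center
#' @return modified \code{toy_system}
#' @export
transform_atoms <- function(system, atoms = seq_len(nrow(system$atoms)),
                            shift = c(0, 0, 0), axis = c(0, 0, 1),
                            angle = 0, center = c(0, 0, 0)) {
  pos <- as.matrix(system$atoms[atoms, c("x", "y", "z")])
  if (angle != 0) {
    R <- rotation_matrix(axis, angle)
    pos <- sweep(pos, 2, center) %*% t(R)
    pos <- sweep(pos, 2, center, `+`)
  }
  pos <- sweep(pos, 2, shift, `+`)
  system$atoms[atoms, c("x", "y", "z")] <- pos
  system
}

rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Set a torsion to a given angle
#'
#' Rotates the torsion's moving atoms about the a2-a3 bond so that the
#' dihedral becomes \code{angle} degrees.
#' @param system a \code{toy_system}
#' @param torsion torsion index
#' @param angle target dihedral in degrees
#' @return modified \code{toy_system}
#' @export
set_torsion <- function(system, torsion, angle) {
  tt <- system$torsions[torsion, ]
  cur <- torsion_angles(system)[torsion]
  pos <- as.matrix(system$atoms[, c("x", "y", "z")])
  axis <- pos[tt$a2, ] - pos[tt$a3, ]   # right-handed for the a3-side atoms
  transform_atoms(system, atoms = system$moving[[torsion]],
                  axis = axis, angle = wrap_angle(angle - cur),
                  center = pos[tt$a2, ])
}
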