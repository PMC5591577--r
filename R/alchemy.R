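#' Alchemical maps: single-topology parameter mutations
#'
#' An alchemical map describes how a subset of atoms and torsions changes
#' between two end states A and B of a single-topology mutation (e.g. a
#' halogen substituent swap).  Charges, LJ parameters and torsion
#' amplitudes are interpolated linearly in the coupling parameter lambda;
#' pairs involving an atom with a vanishing LJ endpoint use a separation-
#' shifted soft-core potential so that the energy stays finite as the
#' atom decouples.
#'
#' @name alchemy
NULL

#' Construct an alchemical map
#'
#' @param atoms data.frame with columns \code{atom} (index into the
#'   system), \code{charge_A,charge_B}, \code{sigma_A,sigma_B},
#'   \code{epsilon_A,epsilon_B} and optionally \code{softcore} (logical;
#'   forced TRUE when either epsilon endpoint is zero).
#' @param torsions data.frame with columns \code{torsion} (index),
#'   \code{V1_A,V2_A,V3_A,V1_B,V2_B,V3_B}.
#' @return object of class \code{alchemical_map}
#' @export
alchemical_map <- function(atoms = NULL, torsions = NULL) {
  if (!is.null(atoms)) {
    need <- c("atom", "charge_A", "charge_B", "sigma_A", "sigma_B",
              "epsilon_A", "epsilon_B")
    stopifnot(all(need %in% names(atoms)))
    if (is.null(atoms$softcore)) atoms$softcore <- FALSE
    atoms$softcore <- atoms$softcore | atoms$epsilon_A == 0 |
      atoms$epsilon_B == 0
    if (anyDuplicated(atoms$atom)) stop("duplicate atom in alchemical map")
  }
  if (!is.null(torsions)) {
    need <- c("torsion", "V1_A", "V2_A", "V3_A", "V1_B", "V2_B", "V3_B")
    stopifnot(all(need %in% names(torsions)))
    if (anyDuplicated(torsions$torsion))
      stop("duplicate torsion in alchemical map")
  }
  structure(list(atoms = atoms, torsions = torsions),
            class = "alchemical_map")
}

#' Reverse an alchemical map (swap the A and B end states)
#' @param map an \code{alchemical_map}
#' @return the reversed map
#' @export
reverse_map <- function(map) {
  sw <- function(df, a_cols, b_cols) {
    tmp <- df[a_cols]; df[a_cols] <- df[b_cols]; df[b_cols] <- tmp; df
  }
  if (!is.null(map$atoms))
    map$atoms <- sw(map$atoms, c("charge_A", "sigma_A", "epsilon_A"),
                    c("charge_B", "sigma_B", "epsilon_B"))
  if (!is.null(map$torsions))
    map$torsions <- sw(map$torsions, c("V1_A", "V2_A", "V3_A"),
                       c("V1_B", "V2_B", "V3_B"))
  map
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  lambda
}

#' Interpolate alchemical parameters at a coupling value
#'
#' Linear mixing of charges, LJ parameters and torsion amplitudes:
#' lambda = 0 reproduces state A exactly, lambda = 1 state B.
#'
#' @param map an \code{alchemical_map}
#' @param lambda coupling parameter in [0, 1]
#' @return list with data.frames \code{atoms} (atom, charge, sigma,
#'   epsilon, softcore) and \code{torsions} (torsion, V1, V2, V3)
#' @export
interpolate <- function(map, lambda) {
  check_lambda(lambda)
  out <- list(atoms = NULL, torsions = NULL)
  mix <- function(a, b) (1 - lambda) * a + lambda * b
  if (!is.null(map$atoms))
    out$atoms <- data.frame(
      atom = map$atoms$atom,
      charge = mix(map$atoms$charge_A, map$atoms$charge_B),
      sigma = mix(map$atoms$sigma_A, map$atoms$sigma_B),
      epsilon = mix(map$atoms$epsilon_A, map$atoms$epsilon_B),
      softcore = map$atoms$softcore)
  if (!is.null(map$torsions))
    out$torsions <- data.frame(
      torsion = map$torsions$torsion,
      V1 = mix(map$torsions$V1_A, map$torsions$V1_B),
      V2 = mix(map$torsions$V2_A, map$torsions$V2_B),
      V3 = mix(map$torsions$V3_A, map$torsions$V3_B))
  out
}

# Per-atom charge/sigma/epsilon at both end states (unmapped atoms have
# identical A and B parameters), plus the per-atom softcore flag.
endpoint_atom_params <- function(system, map) {
  a <- system$atoms
  p <- list(qA = a$charge, qB = a$charge, sA = a$sigma, sB = a$sigma,
            eA = a$epsilon, eB = a$epsilon,
            soft = rep(FALSE, nrow(a)))
  if (!is.null(map) && !is.null(map$atoms)) {
    i <- map$atoms$atom
    p$qA[i] <- map$atoms$charge_A; p$qB[i] <- map$atoms$charge_B
    p$sA[i] <- map$atoms$sigma_A;  p$sB[i] <- map$atoms$sigma_B
    p$eA[i] <- map$atoms$epsilon_A; p$eB[i] <- map$atoms$epsilon_B
    p$soft[i] <- map$atoms$softcore
  }
  p
}

# Tabulated pair parameters at a given lambda.  Each pair's energy is
#   qq/r + e1*f(s1, r^6/g1) + e2*f(s2, r^6/g2),  f(s,x) = 1/(s+x)^2 - 1/(s+x)
# Ordinary pairs use one plain LJ term (s = 0); pairs involving a
# soft-core atom use the two-term separation-shifted form whose A term is
# switched off linearly as lambda grows (alpha = 0.5, power-6 shift).
pair_table <- function(system, map = NULL, lambda = 0) {
  check_lambda(lambda)
  p <- system$pairs
  np <- nrow(p)
  out <- matrix(0, np, 7,
                dimnames = list(NULL, c("qq", "e1", "s1", "g1", "e2", "s2", "g2")))
  if (np == 0) return(out)
  ep <- endpoint_atom_params(system, map)
  qi <- (1 - lambda) * ep$qA[p$i] + lambda * ep$qB[p$i]
  qj <- (1 - lambda) * ep$qA[p$j] + lambda * ep$qB[p$j]
  out[, "qq"] <- COULOMB * qi * qj * p$scale
  soft <- ep$soft[p$i] | ep$soft[p$j]
  # plain pairs: combine the lambda-interpolated atomic parameters
  if (any(!soft)) {
    k <- which(!soft)
    si <- (1 - lambda) * ep$sA[p$i[k]] + lambda * ep$sB[p$i[k]]
    sj <- (1 - lambda) * ep$sA[p$j[k]] + lambda * ep$sB[p$j[k]]
    ei <- (1 - lambda) * ep$eA[p$i[k]] + lambda * ep$eB[p$i[k]]
    ej <- (1 - lambda) * ep$eA[p$j[k]] + lambda * ep$eB[p$j[k]]
    out[k, "e1"] <- 4 * sqrt(ei * ej) * p$scale[k]
    out[k, "g1"] <- (si * sj)^3   # (sqrt(si*sj))^6
    out[k, "g2"] <- 1
  }
  if (any(soft)) {
    k <- which(soft)
    eA <- 4 * sqrt(ep$eA[p$i[k]] * ep$eA[p$j[k]]) * p$scale[k]
    eB <- 4 * sqrt(ep$eB[p$i[k]] * ep$eB[p$j[k]]) * p$scale[k]
    out[k, "e1"] <- (1 - lambda) * eA
    out[k, "s1"] <- SOFTCORE_ALPHA * lambda
    out[k, "g1"] <- (ep$sA[p$i[k]] * ep$sA[p$j[k]])^3
    out[k, "e2"] <- lambda * eB
    out[k, "s2"] <- SOFTCORE_ALPHA * (1 - lambda)
    out[k, "g2"] <- (ep$sB[p$i[k]] * ep$sB[p$j[k]])^3
  }
  out
}

# Torsion Fourier amplitudes at lambda (n_torsions x 3 matrix)
torsion_table <- function(system, map = NULL, lambda = 0) {
  check_lambda(lambda)
  V <- as.matrix(system$torsions[, c("V1", "V2", "V3")])
  if (!is.null(map) && !is.null(map$torsions) && nrow(map$torsions)) {
    i <- map$torsions$torsion
    VA <- as.matrix(map$torsions[, c("V1_A", "V2_A", "V3_A")])
    VB <- as.matrix(map$torsions[, c("V1_B", "V2_B", "V3_B")])
    V[i, ] <- (1 - lambda) * VA + lambda * VB
  }
  V
}

# Indices of pairs and torsions whose parameters differ between two pair
# tables (the alchemical subset used for double-wide perturbation energies).
alchemical_subset <- function(system, map) {
  if (is.null(map)) return(list(pairs = integer(), torsions = integer()))
  mut_atoms <- if (!is.null(map$atoms)) map$atoms$atom else integer()
  p <- system$pairs
  pairs <- which(p$i %in% mut_atoms | p$j %in% mut_atoms)
  torsions <- if (!is.null(map$torsions)) map$torsions$torsion else integer()
  list(pairs = pairs, torsions = as.integer(torsions))
}
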