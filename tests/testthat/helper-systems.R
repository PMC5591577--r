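# Randomized small systems for property tests: a handful of atoms in
# well-separated positions, random regions and LJ/charge parameters,
# two rigid fragments joined by one torsion.
random_system <- function(n_extra = 4, seed = 1) {
  set.seed(seed)
  # torsion chain atoms 1-4 plus scattered environment/solute atoms
  base <- data.frame(
    x = c(-0.5, 0, 1.5, 2.0), y = c(1.4, 0, 0, 1.4), z = 0)
  extra <- data.frame(
    x = runif(n_extra, 3.5, 8), y = runif(n_extra, -4, 4),
    z = runif(n_extra, -4, 4))
  atoms <- rbind(base, extra)
  n <- nrow(atoms)
  atoms$charge <- round(runif(n, -0.3, 0.3), 3)
  atoms$sigma <- round(runif(n, 2.5, 3.8), 3)
  atoms$epsilon <- round(runif(n, 0, 0.4), 3)
  atoms$region <- sample(c("LIGAND", "HOT_RESIDUE", "ENVIRONMENT"), n,
                         replace = TRUE)
  atoms$region[1:4] <- "LIGAND"
  atoms$mobile <- TRUE
  frags <- c(list(c(1L, 2L), c(3L, 4L)), as.list(seq_len(n_extra) + 4L))
  tors <- data.frame(a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L,
                     V1 = runif(1, -1, 2), V2 = runif(1, -1, 2),
                     V3 = runif(1, -1, 2))
  toy_system(atoms, frags, tors,
             exclusions = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 3), c(2, 4)),
             pairs14 = rbind(c(1, 4)))
}

# brute-force single-loop total energy, independent of the package's
# region-decomposed path
brute_total <- function(system, map = NULL, lambda = 0) {
  pos <- as.matrix(system$atoms[, c("x", "y", "z")])
  par <- list(q = system$atoms$charge, s = system$atoms$sigma,
              e = system$atoms$epsilon)
  if (!is.null(map) && !is.null(map$atoms)) {
    ip <- interpolate(map, lambda)$atoms
    par$q[ip$atom] <- ip$charge
    par$s[ip$atom] <- ip$sigma
    par$e[ip$atom] <- ip$epsilon
  }
  tot <- 0
  ex <- rbind(system$exclusions)
  exkey <- if (nrow(ex)) paste(ex[, 1], ex[, 2]) else character()
  p14 <- rbind(system$pairs14)
  p14key <- if (nrow(p14)) paste(p14[, 1], p14[, 2]) else character()
  n <- nrow(pos)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    key <- paste(i, j)
    if (key %in% exkey) next
    sc <- if (key %in% p14key) 0.5 else 1
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    tot <- tot + nonbonded_pair_energy(r, par$q[i], par$q[j], par$s[i],
                                       par$s[j], par$e[i], par$e[j], sc)
  }
  Vt <- torsion_table(system, map, lambda)
  ang <- torsion_angles(system)
  for (t in seq_along(ang))
    tot <- tot + unname(torsion_energy(ang[t], Vt[t, 1], Vt[t, 2], Vt[t, 3]))
  tot
}

# quick rotor torsion-mutation map
rotor_map <- function(V_A, V_B) {
  alchemical_map(torsions = data.frame(
    torsion = 1, V1_A = V_A[1], V2_A = V_A[2], V3_A = V_A[3],
    V1_B = V_B[1], V2_B = V_B[2], V3_B = V_B[3]))
}

# chi-square GOF against reference bin probabilities, pooling
# low-probability reference bins (if any) into one category
chisq_pval <- function(fractions, n, p) {
  pool <- p < 5e-3
  if (any(pool)) {
    obs <- c(fractions[!pool] * n, sum(fractions[pool]) * n)
    p <- c(p[!pool], sum(p[pool]))
  } else obs <- fractions * n
  suppressWarnings(stats::chisq.test(obs, p = p)$p.value)
}

# integrated autocorrelation time (in frames) of a series, truncated at
# the first small autocorrelation
iat <- function(x) {
  x <- x - mean(x)
  if (sd(x) == 0) return(1)
  ac <- stats::acf(x, lag.max = min(length(x) %/% 4, 2000),
                   plot = FALSE)$acf[, 1, 1]
  s <- 1
  for (k in seq(2, length(ac))) {
    if (ac[k] < 0.05) break
    s <- s + 2 * ac[k]
  }
  s
}

# effective sample size of a binary (or bounded) series from block
# averaging: compares the observed block-mean variance with the
# independent-sample variance
ess_block <- function(x, n_blocks = 20) {
  bm <- vapply(split(x, cut(seq_along(x), n_blocks, labels = FALSE)),
               mean, numeric(1))
  v_block <- stats::var(bm) / n_blocks
  v_iid <- stats::var(x)
  if (v_block <= 0) return(length(x))
  max(n_blocks, min(length(x), v_iid / v_block))
}
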