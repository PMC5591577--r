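#' Binding-mode and benchmarking analytics
#'
#' Dihedral-angle distributions characterize the binding modes sampled
#' by the Monte Carlo engine; rotamer populations yield the symmetric-
#' mode entropy term; and computed relative binding free energies are
#' benchmarked against an IC50-derived experimental scale after mean
#' offset.
#'
#' @name analysis
NULL

#' Circular histogram of a sampled dihedral
#'
#' @param traj an \code{mc_trajectory}, or a numeric vector of angles in
#'   degrees
#' @param torsion torsion name or column index (when \code{traj} is a
#'   trajectory)
#' @param bin_width bin width in degrees; must divide 360 (default 10)
#' @return object of class \code{dihedral_histogram} with \code{breaks}
#'   (edges tiling [0, 360]) and \code{fraction} per bin (sums to 1)
#' @export
dihedral_histogram <- function(traj, torsion = 1, bin_width = 10) {
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  angles <- if (inherits(traj, "mc_trajectory")) {
    trajectory_angles(traj, torsion)
  } else as.numeric(traj)
  if (!length(angles)) stop("no angles to histogram")
  breaks <- seq(0, 360, by = bin_width)
  cnt <- tabulate(findInterval(wrap_angle(angles), breaks,
                               rightmost.closed = TRUE),
                  nbins = length(breaks) - 1)
  structure(list(torsion = torsion, breaks = breaks,
                 fraction = cnt / sum(cnt), n = length(angles)),
            class = "dihedral_histogram")
}

#' @export
print.dihedral_histogram <- function(x, ...) {
  top <- order(x$fraction, decreasing = TRUE)[1:min(3, length(x$fraction))]
  cat(sprintf("dihedral_histogram (%s): %d frames, top bins %s\n",
              as.character(x$torsion), x$n,
              paste(sprintf("[%g,%g) %.2f", x$breaks[top],
                            x$breaks[top + 1], x$fraction[top]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.dihedral_histogram <- function(x, ...) {
  mids <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  graphics::barplot(x$fraction, names.arg = mids, space = 0,
                    xlab = "dihedral (degrees)", ylab = "fraction", ...)
  invisible(x)
}

# angle column of the w-th torsion (numeric index counts torsions, not
# data.frame columns) or by torsion name
trajectory_angles <- function(traj, torsion) {
  ang_cols <- setdiff(names(traj$frames),
                      c("step", "e_ss", "e_sw", "e_ww", "accepted"))
  col <- if (is.numeric(torsion)) ang_cols[torsion] else
    if (torsion %in% ang_cols) torsion else NA
  if (is.na(col)) stop("unknown torsion: ", torsion)
  traj$frames[[col]]
}

#' Default binding-mode centers
#'
#' The canonical mode centers of the pocket complex: the planar and
#' twisted linker states (phi 180 and 330 degrees; the fixture's two
#' twisted basins both map onto the 330 center under nearest-center
#' assignment) and the two reachable side-chain rotamers (chi 60 and
#' 180 degrees).
#' @return named list with elements \code{phi} and \code{chi}
#' @export
default_mode_centers <- function() {
  list(phi = c(180, 330), chi = c(60, 180))
}

circular_distance <- function(a, b) {
  d <- abs(wrap_angle(a) - wrap_angle(b))
  pmin(d, 360 - d)
}

#' Binding-mode populations and symmetric-mode entropy
#'
#' Assigns each frame to the nearest mode center on the circle (ties
#' broken toward the lower-indexed center) and reports the entropy term
#' \deqn{T\Delta S = -T k \sum_i p_i \ln p_i}
#' in kcal/mol relative to a single-mode reference (for which it is 0);
#' it is maximal, kT ln M, when the M modes are equally populated --
#' the free-energy cost of losing M symmetric binding modes.
#'
#' @param angles numeric vector of sampled angles (degrees), or an
#'   \code{mc_trajectory} with \code{torsion} naming the column
#' @param mode_centers mode centers in degrees (>= 1)
#' @param temperature K
#' @param torsion torsion name when \code{angles} is a trajectory
#' @return object of class \code{mode_assignment} with \code{centers},
#'   \code{population} (sums to 1), \code{assignment} (per frame) and
#'   \code{TdS} (kcal/mol)
#' @export
mode_populations_entropy <- function(angles, mode_centers,
                                     temperature = 298.15, torsion = 1) {
  if (inherits(angles, "mc_trajectory"))
    angles <- trajectory_angles(angles, torsion)
  if (!length(angles)) stop("no angles to assign")
  if (!length(mode_centers)) stop("need at least one mode center")
  d <- vapply(mode_centers, circular_distance, numeric(length(angles)),
              a = angles)
  d <- matrix(d, nrow = length(angles))
  assign <- apply(d, 1, which.min)   # which.min takes the first on ties
  pop <- tabulate(assign, nbins = length(mode_centers)) / length(angles)
  nz <- pop > 0
  TdS <- -kT(temperature) * sum(pop[nz] * log(pop[nz]))
  structure(list(centers = mode_centers, population = pop,
                 assignment = assign, TdS = TdS,
                 temperature = temperature),
            class = "mode_assignment")
}

#' @export
print.mode_assignment <- function(x, ...) {
  cat(sprintf("mode populations: %s; T*dS = %.3f kcal/mol\n",
              paste(sprintf("%g deg %.3f", x$centers, x$population),
                    collapse = ", "), x$TdS))
  invisible(x)
}

#' IC50-derived experimental free energy (relative scale)
#'
#' \code{RT * ln(IC50 in uM)}.  The additive constant implied by the
#' micromolar reference unit is irrelevant downstream because the
#' benchmark statistics remove the mean offset.
#'
#' @param ic50_uM IC50 in micromolar (> 0)
#' @param temperature K
#' @return kcal/mol on the relative scale
#' @export
experimental_dg <- function(ic50_uM, temperature = 298.15) {
  if (any(!is.na(ic50_uM) & ic50_uM <= 0)) stop("IC50 must be positive")
  kT(temperature) * log(ic50_uM)
}

#' Read a benchmark table
#'
#' CSV with header \code{compound,ddg_kcal,ic50_uM,ki_uM}; missing
#' measurements as NA.  The packaged fixture
#' (\code{system.file("extdata", "fragment_series_benchmark.csv", package =
#' "restfep")}) transcribes the published comparison table for the
#' fragment series.
#'
#' @param path CSV file path
#' @return data.frame of benchmark records
#' @export
read_benchmark <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound", "ddg_kcal", "ic50_uM")
  if (!all(need %in% names(df)))
    stop("benchmark table needs columns ", paste(need, collapse = ", "))
  if (any(!is.na(df$ic50_uM) & df$ic50_uM <= 0))
    stop("IC50 must be positive")
  df
}

#' Benchmark computed ddG against experiment
#'
#' Converts IC50 to the experimental relative free-energy scale, offsets
#' the computed values to the same mean, and reports the mean unsigned
#' error, RMSE and Pearson correlation.  Records without a measured
#' IC50 are dropped.
#'
#' @param records data.frame from \code{\link{read_benchmark}} (or with
#'   the same columns)
#' @param temperature K
#' @return object of class \code{benchmark_stats} with \code{offset},
#'   \code{mue}, \code{rmse}, \code{pearson_r}, \code{n} and the
#'   per-compound \code{table}
#' @export
benchmark_stats <- function(records, temperature = 298.15) {
  rec <- records[!is.na(records$ddg_kcal) & !is.na(records$ic50_uM), ]
  if (nrow(rec) < 2) stop("need at least two complete records")
  rec$dg_exp <- experimental_dg(rec$ic50_uM, temperature)
  offset <- mean(rec$dg_exp) - mean(rec$ddg_kcal)
  rec$ddg_offset <- rec$ddg_kcal + offset
  diff <- rec$ddg_offset - rec$dg_exp
  structure(list(offset = offset,
                 mue = mean(abs(diff)),
                 rmse = sqrt(mean(diff^2)),
                 pearson_r = cor(rec$ddg_kcal, rec$dg_exp),
                 n = nrow(rec), table = rec,
                 temperature = temperature),
            class = "benchmark_stats")
}

#' @export
print.benchmark_stats <- function(x, ...) {
  cat(sprintf("benchmark (n = %d): MUE %.2f, RMSE %.2f kcal/mol, Pearson r %.2f (offset %.2f)\n",
              x$n, x$mue, x$rmse, x$pearson_r, x$offset))
  invisible(x)
}

#' @export
plot.benchmark_stats <- function(x, ...) {
  plot(x$table$dg_exp, x$table$ddg_offset,
       xlab = "experimental RT ln(IC50) (kcal/mol)",
       ylab = "computed ddG, mean-offset (kcal/mol)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::text(x$table$dg_exp, x$table$ddg_offset, x$table$compound,
                 pos = 3, cex = 0.8)
  invisible(x)
}

#' Starting-structure consistency check
#'
#' Repeats of the same mutation started from different initial
#' conformations should agree; the check passes when the maximum
#' pairwise difference of the totals is within tolerance (default three
#' times the combined standard error of the widest pair).
#'
#' @param results list of \code{free_energy_result} or
#'   \code{binding_cycle} objects, or a numeric vector of totals
#' @param tol_kcal tolerance in kcal/mol; when NULL, three times the
#'   combined stderr of the most discrepant pair
#' @return list with \code{pass}, \code{spread} (max pairwise absolute
#'   difference), \code{tol} and the \code{totals}
#' @export
starting_structure_consistency <- function(results, tol_kcal = NULL) {
  totals <- if (is.numeric(results)) results else
    vapply(results, function(r) if (inherits(r, "binding_cycle")) r$ddg
           else r$total, numeric(1))
  if (length(totals) < 2) stop("need at least two results")
  errs <- if (is.numeric(results)) rep(0, length(results)) else
    vapply(results, `[[`, numeric(1), "stderr")
  dm <- abs(outer(totals, totals, `-`))
  spread <- max(dm)
  if (is.null(tol_kcal)) {
    worst <- which(dm == spread, arr.ind = TRUE)[1, ]
    tol_kcal <- 3 * sqrt(errs[worst[1]]^2 + errs[worst[2]]^2)
  }
  list(pass = spread <= tol_kcal, spread = spread, tol = tol_kcal,
       totals = totals)
}
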