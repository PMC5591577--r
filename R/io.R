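#' File formats
#'
#' Systems round-trip through a structured key-value text format;
#' coordinates can additionally be exported as standard XYZ;
#' trajectories, swap logs and perturbation samples are tab-separated
#' tables with a header line; run configuration is YAML.
#'
#' @name io
NULL

#' Write a toy system to a structured text file
#'
#' The format is line-oriented: \code{section} headers in brackets
#' followed by whitespace-separated tables with a header row.  Sections:
#' \code{[atoms]} (x y z charge sigma epsilon region mobile),
#' \code{[fragments]} (fragment id per line: space-separated atom
#' indices), \code{[torsions]} (a1 a2 a3 a4 V1 V2 V3 name),
#' \code{[exclusions]} and \code{[pairs14]} (atom index pairs).
#'
#' @param system a \code{toy_system}
#' @param path output file
#' @return the path, invisibly
#' @export
write_system <- function(system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# restfep toy system")
  w("[atoms]")
  a <- system$atoms
  w("x y z charge sigma epsilon region mobile")
  for (i in seq_len(nrow(a)))
    w(paste(format(c(a$x[i], a$y[i], a$z[i], a$charge[i], a$sigma[i],
                     a$epsilon[i]), digits = 17), collapse = " "),
      " ", a$region[i], " ", as.integer(a$mobile[i]))
  w("[fragments]")
  for (f in system$fragments) w(paste(f, collapse = " "))
  w("[torsions]")
  w("a1 a2 a3 a4 V1 V2 V3 name")
  tt <- system$torsions
  for (t in seq_len(nrow(tt)))
    w(paste(c(tt$a1[t], tt$a2[t], tt$a3[t], tt$a4[t],
              format(c(tt$V1[t], tt$V2[t], tt$V3[t]), digits = 17),
              rownames(tt)[t]), collapse = " "))
  w("[exclusions]")
  for (i in seq_len(nrow(system$exclusions)))
    w(paste(system$exclusions[i, ], collapse = " "))
  w("[pairs14]")
  for (i in seq_len(nrow(system$pairs14)))
    w(paste(system$pairs14[i, ], collapse = " "))
  invisible(path)
}

#' Read a toy system written by \code{\link{write_system}}
#' @param path input file
#' @return a \code{toy_system}
#' @export
read_system <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sec <- cumsum(grepl("^\\[", lines))
  names(sec) <- NULL
  blocks <- split(lines, sec)
  out <- list()
  for (b in blocks) {
    name <- sub("\\]$", "", sub("^\\[", "", b[1]))
    out[[name]] <- b[-1]
  }
  at <- out$atoms[-1]   # drop header row
  am <- do.call(rbind, strsplit(at, "\\s+"))
  atoms <- data.frame(
    x = as.numeric(am[, 1]), y = as.numeric(am[, 2]),
    z = as.numeric(am[, 3]), charge = as.numeric(am[, 4]),
    sigma = as.numeric(am[, 5]), epsilon = as.numeric(am[, 6]),
    region = am[, 7], mobile = am[, 8] == "1")
  fragments <- lapply(strsplit(out$fragments, "\\s+"), as.integer)
  torsions <- NULL
  tnames <- NULL
  if (length(out$torsions) > 1) {
    tm <- do.call(rbind, strsplit(out$torsions[-1], "\\s+"))
    torsions <- data.frame(
      a1 = as.integer(tm[, 1]), a2 = as.integer(tm[, 2]),
      a3 = as.integer(tm[, 3]), a4 = as.integer(tm[, 4]),
      V1 = as.numeric(tm[, 5]), V2 = as.numeric(tm[, 6]),
      V3 = as.numeric(tm[, 7]))
    tnames <- tm[, 8]
  }
  pairs_of <- function(x) {
    if (!length(x)) return(NULL)
    matrix(as.integer(unlist(strsplit(x, "\\s+"))), ncol = 2, byrow = TRUE)
  }
  sys <- toy_system(atoms, fragments, torsions,
                    pairs_of(out$exclusions), pairs_of(out$pairs14))
  if (!is.null(tnames)) rownames(sys$torsions) <- tnames
  sys
}

#' Export coordinates as standard XYZ
#'
#' Count line, comment line, then one \code{element x y z} line per
#' atom.  Elements encode the region: C for ligand, N for the hot
#' residue, O for environment sites.
#'
#' @param system a \code{toy_system}
#' @param path output file
#' @param comment comment-line text
#' @return the path, invisibly
#' @export
write_xyz <- function(system, path, comment = "restfep toy system") {
  el <- c(LIGAND = "C", HOT_RESIDUE = "N", ENVIRONMENT = "O")
  a <- system$atoms
  lines <- c(nrow(a), comment,
             sprintf("%s %12.6f %12.6f %12.6f", el[a$region],
                     a$x, a$y, a$z))
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory as a tab-separated table
#' @param traj an \code{mc_trajectory}
#' @param path output file (".gz" suffix compresses)
#' @return the path, invisibly
#' @export
write_trajectory <- function(traj, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  df <- traj$frames
  df$accepted <- as.integer(df$accepted)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a trajectory table written by \code{\link{write_trajectory}}
#' @param path input file
#' @return data.frame of frames
#' @export
read_trajectory <- function(path) {
  df <- read.delim(path)
  df$accepted <- as.logical(df$accepted)
  df
}

#' Read a YAML run configuration
#'
#' Top-level keys: \code{seed} (mandatory for sampling commands),
#' \code{system} (either \code{file:} or a pocket description with
#' \code{substituent}, \code{seed}), \code{sampler} (\code{n_steps},
#' \code{temperature}, \code{record_every}, \code{equil_fraction},
#' \code{flip_prob}), \code{rest} (\code{n_replicas}, \code{t_max},
#' \code{swap_every}), \code{fep} (\code{n_windows}, \code{from},
#' \code{to}), \code{analysis} (\code{bin_width}, \code{mode_centers}),
#' \code{output} (directory).  Unknown keys are rejected.
#'
#' @param path YAML file
#' @return validated config list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "system", "sampler", "rest", "fep", "analysis",
             "output", "benchmark")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  sub_known <- list(
    system = c("file", "substituent", "seed", "kind", "V1", "V2", "V3"),
    sampler = c("n_steps", "temperature", "record_every",
                "equil_fraction", "flip_prob"),
    rest = c("n_replicas", "t_max", "swap_every", "enabled"),
    fep = c("n_windows", "from", "to", "unbound_steps"),
    analysis = c("bin_width", "mode_centers", "torsion"),
    benchmark = c("file", "temperature"))
  for (k in names(sub_known)) {
    if (!is.null(cfg[[k]])) {
      bad <- setdiff(names(cfg[[k]]), sub_known[[k]])
      if (length(bad))
        stop("unknown config keys under '", k, "': ",
             paste(bad, collapse = ", "))
    }
  }
  cfg
}

#' Write a reproducibility manifest
#'
#' Records the effective configuration, seed and package version next
#' to a command's outputs so the run can be replayed exactly.
#'
#' @param config effective configuration list
#' @param dir output directory
#' @return manifest path, invisibly
#' @export
write_manifest <- function(config, dir) {
  man <- list(package = "restfep",
              version = as.character(utils::packageVersion("restfep")),
              config = config)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}
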