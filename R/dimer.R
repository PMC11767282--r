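#' @title Dimer-contact analysis of MD trajectories
#' @description Detects dimer (pair-contact) events on center-of-mass
#'   trajectories in periodic orthorhombic boxes, computes lifetime
#'   statistics, and summarizes gmx-style energy time series. A synthetic
#'   trajectory generator with scripted dimerization episodes provides
#'   ground-truth fixtures for validation.
#' @name dimer_dynamics
NULL

#' Construct a center-of-mass trajectory
#'
#' @param times Strictly increasing frame times in ps, uniformly spaced.
#' @param positions Numeric array `n_frames x n_molecules x 3` of per-frame
#'   molecular center-of-mass coordinates in nm.
#' @param box Per-frame orthorhombic box edge lengths in nm: either a
#'   length-3 vector (constant box) or an `n_frames x 3` matrix.
#' @return A `trajectory` list with elements `times`, `positions`, `box`
#'   (matrix), `dt` (ps), `n_molecules`.
#' @export
trajectory <- function(times, positions, box) {
  if (length(dim(positions)) != 3 || dim(positions)[3] != 3) {
    stop("positions must be an n_frames x n_molecules x 3 array", call. = FALSE)
  }
  n_frames <- dim(positions)[1]
  if (length(times) != n_frames) {
    stop("times length must match the number of frames", call. = FALSE)
  }
  if (n_frames > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("times must be strictly increasing", call. = FALSE)
    if (max(abs(dts - dts[1])) > 1e-9 * abs(dts[1])) {
      stop("frame times must be uniformly spaced", call. = FALSE)
    }
    dt <- dts[1]
  } else {
    dt <- NA_real_
  }
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3,
                                       byrow = TRUE)
  if (nrow(box) != n_frames || ncol(box) != 3) {
    stop("box must be a length-3 vector or an n_frames x 3 matrix",
         call. = FALSE)
  }
  if (any(box <= 0)) stop("box edges must be positive", call. = FALSE)
  structure(list(times = times, positions = positions, box = box,
                 dt = dt, n_molecules = dim(positions)[2]),
            class = "trajectory")
}

#' Mass-weighted center of mass
#'
#' @param atom_positions `n_atoms x 3` matrix of coordinates in nm.
#' @param masses Positive atomic masses in amu, one per atom.
#' @return Length-3 center-of-mass coordinate in nm.
#' @export
center_of_mass <- function(atom_positions, masses) {
  atom_positions <- matrix(as.numeric(atom_positions), ncol = 3)
  if (nrow(atom_positions) == 0 || nrow(atom_positions) != length(masses)) {
    stop("need one positive mass per atom", call. = FALSE)
  }
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  colSums(atom_positions * masses) / sum(masses)
}

#' Minimum-image distance in a periodic orthorhombic box
#'
#' Euclidean distance after wrapping each coordinate difference into
#' `[-L/2, L/2)`.
#'
#' @param p,q Length-3 coordinates in nm.
#' @param box Length-3 box edge lengths in nm.
#' @return Distance in nm.
#' @export
min_image_distance <- function(p, q, box) {
  if (any(box <= 0)) stop("box edges must be positive", call. = FALSE)
  d <- p - q
  d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# merge TRUE-runs of `close` that are separated by <= gap FALSE frames;
# returns a two-column matrix of (start_frame, end_frame) indices
.contact_runs <- function(close, gap) {
  r <- rle(close)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tv <- which(r$values)
  if (length(tv) == 0) return(matrix(integer(0), ncol = 2))
  runs <- cbind(starts[tv], ends[tv])
  if (gap > 0 && nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (k in 2:nrow(runs)) {
      if (runs[k, 1] - merged[nrow(merged), 2] - 1 <= gap) {
        merged[nrow(merged), 2] <- runs[k, 2]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
    runs <- merged
  }
  runs
}

#' Detect dimer-contact events
#'
#' For every unordered molecule pair, finds maximal runs of consecutive
#' frames whose minimum-image center-of-mass distance is below
#' `distance_cutoff`. Runs may bridge up to `gap_tolerance` consecutive
#' above-threshold frames. Runs whose lifetime reaches `min_lifetime_ns`
#' become events. The lifetime of a k-frame run is `k * dt` (equivalently
#' `end - start + dt`): each saved frame represents `dt` of residence, so a
#' single-frame contact has lifetime `dt`, not zero.
#'
#' @param traj A [trajectory()].
#' @param distance_cutoff Contact distance threshold in nm (default 0.7).
#' @param min_lifetime_ns Minimum event duration in ns (default 0.5).
#' @param gap_tolerance Number of consecutive above-threshold frames a run
#'   may bridge (default 0 = strict contiguity).
#' @return A `contact_events` data frame with columns `pair_i`, `pair_j`
#'   (1-based molecule indices, i < j), `start_ps`, `end_ps`, `lifetime_ns`,
#'   sorted by start time then pair; attribute `dt_ps`.
#' @export
detect_contact_events <- function(traj, distance_cutoff = 0.7,
                                  min_lifetime_ns = 0.5, gap_tolerance = 0) {
  if (!inherits(traj, "trajectory")) stop("need a trajectory", call. = FALSE)
  if (distance_cutoff <= 0) stop("distance_cutoff must be > 0", call. = FALSE)
  if (min_lifetime_ns < 0) stop("min_lifetime_ns must be >= 0", call. = FALSE)
  n_mol <- traj$n_molecules
  if (n_mol < 2) stop("need at least 2 molecules", call. = FALSE)
  dt <- traj$dt
  pos <- traj$positions
  box <- traj$box
  out <- list()
  for (i in seq_len(n_mol - 1)) {
    for (j in seq.int(i + 1, n_mol)) {
      d <- pos[, i, , drop = FALSE] - pos[, j, , drop = FALSE]
      dim(d) <- c(dim(pos)[1], 3)
      d <- d - box * round(d / box)
      dist <- sqrt(rowSums(d^2))
      runs <- .contact_runs(dist < distance_cutoff, gap_tolerance)
      if (nrow(runs) == 0) next
      start_t <- traj$times[runs[, 1]]
      end_t <- traj$times[runs[, 2]]
      life <- (end_t - start_t + dt) / 1000
      keep <- life >= min_lifetime_ns
      if (!any(keep)) next
      out[[length(out) + 1]] <- data.frame(
        pair_i = i, pair_j = j,
        start_ps = start_t[keep], end_ps = end_t[keep],
        lifetime_ns = life[keep])
    }
  }
  ev <- if (length(out) == 0) {
    data.frame(pair_i = integer(), pair_j = integer(), start_ps = numeric(),
               end_ps = numeric(), lifetime_ns = numeric())
  } else {
    do.call(rbind, out)
  }
  ev <- ev[order(ev$start_ps, ev$pair_i, ev$pair_j), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "dt_ps") <- dt
  class(ev) <- c("contact_events", "data.frame")
  ev
}

#' Lifetime statistics of contact events
#'
#' @param events A `contact_events` data frame (or anything with a
#'   `lifetime_ns` column).
#' @return A list `n_events`, `mean_lifetime_ns`, `sd_lifetime_ns` (mean and
#'   sd are `NA` for zero events; sd uses the sample n-1 denominator).
#' @export
event_stats <- function(events) {
  life <- events$lifetime_ns
  n <- length(life)
  list(
    n_events = n,
    mean_lifetime_ns = if (n > 0) mean(life) else NA_real_,
    sd_lifetime_ns = if (n > 1) stats::sd(life) else if (n == 1) 0 else NA_real_
  )
}

#' Summarize an MD time series (mean, RMSD, total drift)
#'
#' The reporting convention of MD energy analyses: `rmsd` is the root mean
#' square fluctuation about the mean (population formula), and `tot_drift`
#' is the least-squares slope of the series multiplied by the total time
#' span, i.e. the net change attributed to the linear trend.
#'
#' @param values Numeric series (e.g. kJ/mol).
#' @param times_ps Frame times in ps, same length.
#' @return A list `mean`, `rmsd`, `tot_drift`, in the units of `values`.
#' @export
timeseries_summary <- function(values, times_ps) {
  if (length(values) < 2 || length(values) != length(times_ps)) {
    stop("need equal-length series of at least 2 points", call. = FALSE)
  }
  m <- mean(values)
  rmsd <- sqrt(mean((values - m)^2))
  slope <- stats::cov(times_ps, values) / stats::var(times_ps)
  drift <- slope * (times_ps[length(times_ps)] - times_ps[1])
  list(mean = m, rmsd = rmsd, tot_drift = drift)
}

#' Generate a synthetic trajectory with scripted dimerization episodes
#'
#' Molecules perform independent Gaussian random walks inside a cubic
#' periodic box (reflective placement keeps coordinates in the primary
#' cell), except that during a scripted episode the second molecule of the
#' pair is pinned at the episode's contact distance (plus uniform jitter)
#' from the first. This provides trajectories whose ground-truth dimer
#' events are known by construction. Deterministic for a fixed seed.
#'
#' @param n_molecules Number of molecules (>= 2).
#' @param box_nm Cubic box edge length in nm (default 5, a typical small
#'   solvent box).
#' @param dt_ps Frame spacing in ps (default 5, a typical trajectory output
#'   stride).
#' @param n_frames Number of frames.
#' @param episodes List of episodes; each a list with `pair` (length-2
#'   molecule indices), `start`, `end` (1-based frame indices, inclusive),
#'   `distance` (contact distance in nm). Episodes for one pair must not
#'   overlap.
#' @param jitter_nm Half-width of the uniform jitter on the contact
#'   distance (default 0.05).
#' @param step_sd_nm Random-walk step standard deviation per frame
#'   (default 0.15).
#' @param seed Integer RNG seed.
#' @return A [trajectory()].
#' @export
generate_synthetic_trajectory <- function(n_molecules, box_nm = 5, dt_ps = 5,
                                          n_frames = 200, episodes = list(),
                                          jitter_nm = 0.05, step_sd_nm = 0.15,
                                          seed = 1) {
  if (n_molecules < 2) stop("need at least 2 molecules", call. = FALSE)
  for (ep in episodes) {
    if (ep$start < 1 || ep$end > n_frames || ep$end < ep$start) {
      stop("episode frames out of range", call. = FALSE)
    }
  }
  # reject overlapping episodes for the same pair
  if (length(episodes) > 1) {
    keys <- vapply(episodes, function(e) paste(sort(e$pair), collapse = "-"),
                   "")
    for (k in unique(keys)) {
      eps <- episodes[keys == k]
      iv <- t(vapply(eps, function(e) c(e$start, e$end), numeric(2)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
        stop("overlapping episodes for pair ", k, call. = FALSE)
      }
    }
  }
  .with_seed(seed, {
    pos <- array(0, dim = c(n_frames, n_molecules, 3))
    cur <- matrix(stats::runif(n_molecules * 3, 0, box_nm), ncol = 3)
    reflect <- function(x) {
      # fold into [0, box] by reflection
      x <- abs(x)
      period <- 2 * box_nm
      x <- x %% period
      ifelse(x > box_nm, period - x, x)
    }
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        cur <- reflect(cur + matrix(stats::rnorm(n_molecules * 3, 0,
                                                 step_sd_nm), ncol = 3))
      }
      for (ep in episodes) {
        if (f >= ep$start && f <= ep$end) {
          i <- min(ep$pair); j <- max(ep$pair)
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          r <- ep$distance + stats::runif(1, -jitter_nm, jitter_nm)
          cur[j, ] <- reflect(cur[i, ] + u * r)
        }
      }
      pos[f, , ] <- cur
    }
    trajectory(times = (seq_len(n_frames) - 1) * dt_ps, positions = pos,
               box = rep(box_nm, 3))
  })
}

#' Read a center-of-mass trajectory from CSV
#'
#' Expects the header
#' `frame,time_ps,mol_id,x_nm,y_nm,z_nm,box_x_nm,box_y_nm,box_z_nm` with one
#' row per (frame, molecule).
#'
#' @param path CSV file path.
#' @return A [trajectory()]; molecules are ordered by their first
#'   appearance of `mol_id`.
#' @export
read_com_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_ps", "mol_id", "x_nm", "y_nm", "z_nm",
            "box_x_nm", "box_y_nm", "box_z_nm")
  if (!all(need %in% names(raw))) {
    stop("COM CSV missing column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  frames <- sort(unique(raw$frame))
  mols <- unique(raw$mol_id)
  n_f <- length(frames); n_m <- length(mols)
  if (nrow(raw) != n_f * n_m) {
    stop("COM CSV is not complete: expected ", n_f * n_m,
         " rows (every molecule in every frame), got ", nrow(raw),
         call. = FALSE)
  }
  fi <- match(raw$frame, frames)
  mi <- match(raw$mol_id, mols)
  if (anyDuplicated(cbind(fi, mi))) {
    stop("duplicate (frame, mol_id) rows in COM CSV", call. = FALSE)
  }
  pos <- array(NA_real_, dim = c(n_f, n_m, 3))
  pos[cbind(fi, mi, 1)] <- raw$x_nm
  pos[cbind(fi, mi, 2)] <- raw$y_nm
  pos[cbind(fi, mi, 3)] <- raw$z_nm
  box <- matrix(NA_real_, n_f, 3)
  box[fi, ] <- cbind(raw$box_x_nm, raw$box_y_nm, raw$box_z_nm)
  times <- raw$time_ps[match(frames, raw$frame)]
  trajectory(times = times, positions = pos, box = box)
}

#' Read a multi-frame GRO file as a center-of-mass trajectory
#'
#' Parses concatenated fixed-column GRO frames (title, atom count, atom
#' lines, box line) and reduces each frame to per-molecule centers of mass.
#' Frame times are taken from `t=` stamps in the title lines when present,
#' otherwise from `dt_ps`.
#'
#' @param path GRO file path.
#' @param molecule_map Integer vector, one entry per atom, assigning each
#'   atom to a molecule index (1-based).
#' @param masses Positive atomic masses in amu, one per atom.
#' @param dt_ps Frame spacing used when the titles carry no `t=` stamp.
#' @return A [trajectory()].
#' @export
read_gro_frames <- function(path, molecule_map, masses, dt_ps = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  n_atoms <- length(molecule_map)
  if (length(masses) != n_atoms) {
    stop("molecule_map and masses must have one entry per atom", call. = FALSE)
  }
  frame_len <- n_atoms + 3  # title, count, atoms..., box
  if (length(lines) %% frame_len != 0) {
    stop("GRO file length is not a whole number of ", n_atoms,
         "-atom frames", call. = FALSE)
  }
  n_frames <- length(lines) %/% frame_len
  if (n_frames == 0) stop("empty GRO file", call. = FALSE)
  mols <- sort(unique(molecule_map))
  pos <- array(NA_real_, dim = c(n_frames, length(mols), 3))
  box <- matrix(NA_real_, n_frames, 3)
  times <- numeric(n_frames)
  have_t <- TRUE
  for (f in seq_len(n_frames)) {
    off <- (f - 1) * frame_len
    title <- lines[off + 1]
    m <- regmatches(title, regexec("t\\s*=\\s*([-0-9.eE+]+)", title))[[1]]
    if (length(m) >= 2) times[f] <- as.numeric(m[2]) else have_t <- FALSE
    count <- suppressWarnings(as.integer(trimws(lines[off + 2])))
    if (is.na(count) || count != n_atoms) {
      stop("frame ", f, ": atom count ", count, " does not match the ",
           n_atoms, "-atom molecule map", call. = FALSE)
    }
    at <- lines[off + 2 + seq_len(n_atoms)]
    xyz <- matrix(NA_real_, n_atoms, 3)
    xyz[, 1] <- as.numeric(substr(at, 21, 28))
    xyz[, 2] <- as.numeric(substr(at, 29, 36))
    xyz[, 3] <- as.numeric(substr(at, 37, 44))
    if (anyNA(xyz)) stop("frame ", f, ": malformed atom line", call. = FALSE)
    for (k in seq_along(mols)) {
      sel <- molecule_map == mols[k]
      pos[f, k, ] <- center_of_mass(xyz[sel, , drop = FALSE], masses[sel])
    }
    bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[off + frame_len]),
                                               "\\s+")[[1]]))
    if (length(bx) < 3 || anyNA(bx[1:3])) {
      stop("frame ", f, ": malformed box line", call. = FALSE)
    }
    box[f, ] <- bx[1:3]
  }
  if (!have_t) {
    if (is.null(dt_ps)) {
      stop("GRO titles carry no 't=' stamps; supply dt_ps", call. = FALSE)
    }
    times <- (seq_len(n_frames) - 1) * dt_ps
  }
  trajectory(times = times, positions = pos, box = box)
}

#' Write contact events to CSV
#'
#' @param events A `contact_events` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d frames x %d molecules, dt = %g ps, box %g x %g x %g nm\n",
    length(x$times), x$n_molecules, x$dt, x$box[1, 1], x$box[1, 2],
    x$box[1, 3]))
  invisible(x)
}
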