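test_that("center of mass is the mass-weighted mean", {
  expect_equal(center_of_mass(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1)),
               c(1, 0, 0))
  expect_equal(center_of_mass(rbind(c(5, 6, 7)), 12), c(5, 6, 7))
  expect_equal(center_of_mass(rbind(c(0, 0, 0), c(4, 0, 0)), c(1, 3)),
               c(3, 0, 0))
  expect_error(center_of_mass(rbind(c(0, 0, 0)), c(1, 2)), "one positive mass")
})

test_that("minimum-image distance wraps the periodic box", {
  expect_equal(min_image_distance(c(0, 0, 0), c(4.9, 0, 0), rep(5, 3)), 0.1)
  expect_equal(min_image_distance(c(1, 2, 3), c(1, 2, 3), rep(5, 3)), 0)
  expect_equal(min_image_distance(c(0, 0, 0), c(2.5, 2.5, 2.5), rep(5, 3)),
               2.5 * sqrt(3))
})

test_that("a constructed 200-frame contact yields one 1.000 ns event", {
  n_frames <- 300
  pos <- array(0, dim = c(n_frames, 2, 3))
  pos[, 1, ] <- 1
  pos[, 2, 1] <- 1.4   # 0.4 nm apart in x while in contact
  pos[, 2, 2:3] <- 1
  pos[201:n_frames, 2, 1] <- 3.5  # far apart afterwards
  traj <- trajectory(times = (0:(n_frames - 1)) * 5, positions = pos,
                     box = rep(5, 3))
  ev <- detect_contact_events(traj, distance_cutoff = 0.5,
                              min_lifetime_ns = 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$lifetime_ns, 1.000)
  expect_equal(ev$start_ps, 0)
  expect_equal(ev$end_ps, 995)
  # all distances above the cutoff: no events
  expect_equal(nrow(detect_contact_events(traj, distance_cutoff = 0.3,
                                          min_lifetime_ns = 0.5)), 0)
  # a 0.4 ns run under a 0.5 ns threshold is excluded
  pos2 <- pos
  pos2[81:n_frames, 2, 1] <- 3.5  # 80 frames x 5 ps = 0.4 ns
  traj2 <- trajectory((0:(n_frames - 1)) * 5, pos2, rep(5, 3))
  expect_equal(nrow(detect_contact_events(traj2, 0.5, 0.5)), 0)
  expect_equal(nrow(detect_contact_events(traj2, 0.5, 0.4)), 1)
})

test_that("detection matches the brute-force oracle on random trajectories", {
  set.seed(11)
  for (k in 1:20) {
    n_mol <- sample(2:6, 1)
    traj <- generate_synthetic_trajectory(
      n_molecules = n_mol, box_nm = 3, dt_ps = 5,
      n_frames = sample(c(100, 250), 1), step_sd_nm = 0.35,
      seed = 500 + k)
    for (gap in c(0, 2)) {
      got <- detect_contact_events(traj, distance_cutoff = 0.9,
                                   min_lifetime_ns = 0.05,
                                   gap_tolerance = gap)
      want <- oracle_contact_events(traj, 0.9, 0.05, gap)
      expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
    }
  }
})

test_that("event counts grow when the thresholds are loosened", {
  traj <- generate_synthetic_trajectory(n_molecules = 8, box_nm = 3,
                                        dt_ps = 5, n_frames = 400,
                                        step_sd_nm = 0.4, seed = 99)
  # lowering the duration threshold never drops events (same runs, wider
  # filter); loosening the distance cutoff raises the count on diffusive
  # trajectories like this one, though run merging keeps it from being a
  # strict pointwise guarantee
  counts_by_life <- vapply(
    c(0.5, 0.25, 0.1, 0),
    function(ml) nrow(detect_contact_events(traj, 0.7, ml)), 0L)
  expect_true(all(diff(counts_by_life) >= 0))
  n_strict <- nrow(detect_contact_events(traj, 0.7, 0.05))
  n_loose <- nrow(detect_contact_events(traj, 1.4, 0.05))
  expect_gt(n_loose, n_strict)
})

test_that("detection is invariant to time shifts and label permutations", {
  traj <- generate_synthetic_trajectory(
    n_molecules = 4, box_nm = 3, dt_ps = 5, n_frames = 200,
    episodes = list(list(pair = c(1, 3), start = 20, end = 80,
                         distance = 0.4),
                    list(pair = c(2, 4), start = 100, end = 170,
                         distance = 0.4)),
    step_sd_nm = 0.35, seed = 13)
  ev <- detect_contact_events(traj, 0.8, 0.1)
  expect_gt(nrow(ev), 0)
  shifted <- traj
  shifted$times <- traj$times + 1000
  ev_shift <- detect_contact_events(shifted, 0.8, 0.1)
  expect_equal(ev_shift$start_ps, ev$start_ps + 1000)
  expect_equal(ev_shift$lifetime_ns, ev$lifetime_ns)
  perm <- c(3, 1, 4, 2)
  permuted <- traj
  permuted$positions <- traj$positions[, perm, , drop = FALSE]
  ev_perm <- detect_contact_events(permuted, 0.8, 0.1)
  relabel <- cbind(match(ev$pair_i, perm), match(ev$pair_j, perm))
  relabel <- cbind(pmin(relabel[, 1], relabel[, 2]),
                   pmax(relabel[, 1], relabel[, 2]))
  key <- function(i, j, s) paste(i, j, s)
  expect_setequal(key(relabel[, 1], relabel[, 2], ev$start_ps),
                  key(ev_perm$pair_i, ev_perm$pair_j, ev_perm$start_ps))
  # events never overlap per pair, total event time within the span
  span_ns <- (max(traj$times) - min(traj$times) + traj$dt) / 1000
  for (p in unique(paste(ev$pair_i, ev$pair_j))) {
    sub <- ev[paste(ev$pair_i, ev$pair_j) == p, ]
    sub <- sub[order(sub$start_ps), ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$start_ps[-1] > sub$end_ps[-nrow(sub)]))
    }
    expect_lte(sum(sub$lifetime_ns), span_ns + 1e-12)
  }
})

test_that("event statistics use the sample standard deviation", {
  ev3 <- data.frame(lifetime_ns = c(1, 1, 1))
  st <- event_stats(ev3)
  expect_equal(st$n_events, 3)
  expect_equal(st$mean_lifetime_ns, 1)
  expect_equal(st$sd_lifetime_ns, 0)
  st2 <- event_stats(data.frame(lifetime_ns = c(0.5, 1.5)))
  expect_equal(st2$mean_lifetime_ns, 1)
  expect_equal(st2$sd_lifetime_ns, sqrt(0.5), tolerance = 1e-12)
  st0 <- event_stats(data.frame(lifetime_ns = numeric()))
  expect_equal(st0$n_events, 0)
  expect_true(is.na(st0$mean_lifetime_ns) && is.na(st0$sd_lifetime_ns))
})

test_that("time-series summary matches direct formulas", {
  t_ps <- seq(0, 1000, by = 10)
  const <- timeseries_summary(rep(-1046.65, length(t_ps)), t_ps)
  expect_equal(const$mean, -1046.65)
  expect_equal(const$rmsd, 0)
  expect_equal(const$tot_drift, 0)
  lin <- timeseries_summary(3 + 0.02 * t_ps, t_ps)
  expect_equal(lin$tot_drift, 0.02 * 1000, tolerance = 1e-9)
  set.seed(8)
  y <- rnorm(101, -270, 60)
  s <- timeseries_summary(y, t_ps)
  expect_equal(s$mean, sum(y) / length(y), tolerance = 1e-12)
  expect_equal(s$rmsd, sqrt(sum((y - mean(y))^2) / length(y)),
               tolerance = 1e-9)
  X <- cbind(1, t_ps)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(s$tot_drift, beta[2] * (max(t_ps) - min(t_ps)),
               tolerance = 1e-9)
})

test_that("synthetic trajectories honor their episode schedule", {
  traj <- generate_synthetic_trajectory(
    n_molecules = 4, box_nm = 5, dt_ps = 5, n_frames = 300,
    episodes = list(list(pair = c(1, 2), start = 50, end = 169,
                         distance = 0.5)),
    jitter_nm = 0.05, step_sd_nm = 0.1, seed = 21)
  ev <- detect_contact_events(traj, 0.7, 0.5)
  in_ep <- ev[ev$pair_i == 1 & ev$pair_j == 2, ]
  expect_equal(nrow(in_ep), 1)
  # the run covers the 120-frame scripted window; it may extend by the few
  # frames the random walks need to separate the pair past the cutoff
  expect_gte(in_ep$lifetime_ns, 120 * 5 / 1000)
  expect_lte(in_ep$lifetime_ns, 0.8)
  # determinism
  traj2 <- generate_synthetic_trajectory(
    n_molecules = 4, box_nm = 5, dt_ps = 5, n_frames = 300,
    episodes = list(list(pair = c(1, 2), start = 50, end = 169,
                         distance = 0.5)),
    jitter_nm = 0.05, step_sd_nm = 0.1, seed = 21)
  expect_identical(traj$positions, traj2$positions)
  expect_error(generate_synthetic_trajectory(
    2, episodes = list(list(pair = c(1, 2), start = 1, end = 50,
                            distance = 0.5),
                       list(pair = c(1, 2), start = 40, end = 80,
                            distance = 0.5))),
    "overlapping")
})

test_that("COM CSV round-trips and rejects incomplete frames", {
  traj <- generate_synthetic_trajectory(n_molecules = 3, n_frames = 10,
                                        seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_com_csv(traj, path)
  back <- read_com_csv(path)
  expect_equal(back$times, traj$times)
  expect_equal(back$positions, traj$positions, tolerance = 1e-12)
  expect_equal(back$box, traj$box, ignore_attr = TRUE)
  # drop one molecule's row in one frame
  lines <- readLines(path)
  writeLines(lines[-5], path)
  expect_error(read_com_csv(path), "not complete")
})

test_that("multi-frame GRO reading reproduces hand-computed COMs", {
  path <- system.file("extdata", "synthetic_trimer_frames.gro",
                      package = "photoyield")
  traj <- read_gro_frames(path, molecule_map = c(1, 1, 1),
                          masses = c(16, 1, 1))
  expect_equal(length(traj$times), 2)
  expect_equal(traj$times, c(0, 5))
  # hand-computed mass-weighted mean of frame 1
  expect_equal(traj$positions[1, 1, ],
               c(18.2 / 18, 18.4 / 18, 1), tolerance = 1e-9)
  expect_equal(traj$positions[2, 1, 1], 18.2 / 18 + 0.1, tolerance = 1e-9)
  expect_equal(traj$box[1, ], c(5, 5, 5))
  expect_error(read_gro_frames(path, c(1, 1), c(16, 1)), "frames")
})
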