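# Independent brute-force oracle for contact-event detection: plain
# per-frame scan with explicit gap bookkeeping, no shared code with
# detect_contact_events().
oracle_contact_events <- function(traj, cutoff, min_lifetime_ns,
                                  gap_tolerance = 0) {
  n_mol <- traj$n_molecules
  n_f <- length(traj$times)
  dt <- traj$dt
  rows <- list()
  for (i in seq_len(n_mol - 1)) {
    for (j in seq.int(i + 1, n_mol)) {
      close <- logical(n_f)
      for (f in seq_len(n_f)) {
        close[f] <- min_image_distance(traj$positions[f, i, ],
                                       traj$positions[f, j, ],
                                       traj$box[f, ]) < cutoff
      }
      start <- NA_integer_; last_close <- NA_integer_
      flush <- function(start, last_close) {
        life <- (traj$times[last_close] - traj$times[start] + dt) / 1000
        if (life >= min_lifetime_ns) {
          rows[[length(rows) + 1]] <<- data.frame(
            pair_i = i, pair_j = j,
            start_ps = traj$times[start], end_ps = traj$times[last_close],
            lifetime_ns = life)
        }
      }
      for (f in seq_len(n_f)) {
        if (close[f]) {
          if (is.na(start)) start <- f
          last_close <- f
        } else if (!is.na(start) && f - last_close > gap_tolerance) {
          flush(start, last_close)
          start <- NA_integer_; last_close <- NA_integer_
        }
      }
      if (!is.na(start)) flush(start, last_close)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pair_i = integer(), pair_j = integer(),
                      start_ps = numeric(), end_ps = numeric(),
                      lifetime_ns = numeric()))
  }
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$start_ps, ev$pair_i, ev$pair_j), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# Table fixtures rebuilt in code (printed transition tables)
steom_table <- function() {
  transition_table(
    molecule_id = c("BIMC", "BIMC", "BIMC-Protonated", "BIMC-Protonated"),
    kind = c("emission", "emission_experimental",
             "emission", "emission_experimental"),
    state_from = c(1, 1, 1, 1), state_to = c(0, 0, 0, 0),
    wavelength_nm = c(458.2, 454.0, 512.9, 514.0),
    oscillator_strength = c(1.2263, NA, 1.1905, NA),
    method = c("STEOM-DLPNO-CCSD", "experiment",
               "STEOM-DLPNO-CCSD", "experiment"))
}

steom_fixture_path <- function() {
  system.file("extdata", "bimc_transitions_steom.csv", package = "photoyield")
}
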