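#' Simulate a network of conductance-based cells
#'
#' Fixed-step 4th-order Runge-Kutta integration of single-compartment
#' cells coupled by ohmic edges (gap junctions or axial conductances).
#' Each cell is either free (its voltage obeys the current balance
#' `C dV/dt = -sum(I_ion) - sum_j Gc_ij (V - V_j) + I_inj`) or held in an
#' ideal voltage clamp (its voltage follows the command exactly and the
#' clamp current is reported as the residual of the current balance).
#' Gating variables of clamped cells keep evolving under the commanded
#' voltage. Gates start at steady state for the initial voltage.
#'
#' Stimulus and command inputs may be a numeric constant, a function of
#' time in seconds, or a [trace()] (its first channel, linearly
#' interpolated). Inputs are evaluated on the integrator's half-step grid
#' so the RK4 stages see exact values.
#'
#' @param cells list of [cell_spec()]s.
#' @param edges coupling edges: a matrix/data.frame with columns
#'   (`from`, `to`, `g`), cell indices 1-based and conductance in uS;
#'   `NULL` for uncoupled cells.
#' @param inj named list mapping cell index (as character or via position
#'   names `"1"`, `"2"`, ...) to an injected-current input (nA).
#' @param clamp named list mapping cell index to a voltage-command input
#'   (mV); clamped cells ignore `inj` in the voltage equation but it is
#'   subtracted from the reported clamp current.
#' @param duration total simulated time (s).
#' @param dt integration step (ms).
#' @param record_dt sampling interval of the returned trace (s); must be
#'   a multiple of `dt`.
#' @param v0 initial voltage (mV), scalar or per-cell vector.
#' @return a [trace()] with channels `V_<cellname>` (mV) for every cell
#'   and `I_<cellname>` (nA, clamp current) for clamped cells.
#' @export
simulate_network <- function(cells, edges = NULL, inj = list(),
                             clamp = list(), duration, dt = 0.05,
                             record_dt = 1e-3, v0 = -60) {
  stopifnot(all(vapply(cells, inherits, TRUE, "cell_spec")))
  ncell <- length(cells)
  nm <- vapply(cells, `[[`, "", "name")
  if (anyDuplicated(nm)) nm <- paste0(nm, seq_len(ncell))
  n_steps <- round(duration * 1000 / dt)
  record_every <- round(record_dt * 1000 / dt)
  if (abs(record_every * dt - record_dt * 1000) > 1e-9)
    stop("simulate_network: record_dt must be a multiple of dt")
  n_steps <- (n_steps %/% record_every) * record_every
  t_half <- (0:(2 * n_steps)) * (dt / 2) / 1000  # seconds

  sample_input <- function(x) {
    if (is.function(x)) x(t_half)
    else if (inherits(x, "trace")) trace_interp(x, names(x$channels)[1], t_half)
    else rep(as.numeric(x), length(t_half))
  }
  idx_of <- function(l) as.integer(names(l))
  inj_cells <- if (length(inj)) idx_of(inj) else integer(0)
  clamp_cells <- if (length(clamp)) idx_of(clamp) else integer(0)
  inj_mat <- if (length(inj)) vapply(inj, sample_input, numeric(length(t_half)))
             else matrix(0, 1, 1)
  cmd_mat <- if (length(clamp)) vapply(clamp, sample_input, numeric(length(t_half)))
             else matrix(0, 1, 1)
  em <- if (is.null(edges) || NROW(edges) == 0) matrix(0, 0, 3) else {
    em <- as.matrix(edges)[, 1:3, drop = FALSE]
    storage.mode(em) <- "double"
    em[, 1:2] <- em[, 1:2] - 1
    em
  }
  v0 <- rep_len(v0, ncell)

  res <- simulate_network_cpp(
    n_steps, dt, vapply(cells, `[[`, 0, "C"), channel_matrix(cells), em,
    inj_cells - 1L, inj_mat, clamp_cells - 1L, cmd_mat, v0,
    as.integer(record_every))

  ch <- c(lapply(seq_len(ncell), function(i) res$V[, i]),
          lapply(seq_along(clamp_cells), function(q) res$Iclamp[, q]))
  names(ch) <- c(paste0("V_", nm),
                 if (length(clamp_cells)) paste0("I_", nm[clamp_cells]))
  un <- stats::setNames(c(rep("mV", ncell), rep("nA", length(clamp_cells))),
                        names(ch))
  out <- trace(dt = res$dt_rec / 1000, channels = ch, units = un)
  attr(out, "gates_final") <- res$gates_final
  out
}

#' Coupled-pair ZAP experiment in current clamp
#'
#' Injects a ZAP current into the prejunctional cell of an electrically
#' coupled pair, records both voltages, and estimates the coupled
#' impedance profiles and the coupling coefficient; also simulates each
#' cell in isolation under the same stimulus for the isolated profiles
#' `Z1`, `Z2`.
#'
#' @param cell_pre,cell_post [cell_spec()]s (current goes into
#'   `cell_pre`).
#' @param gc junctional conductance (uS).
#' @param zap a [zap_params()] current command (nA).
#' @param dt integration step (ms).
#' @param record_dt trace sampling interval (s).
#' @param isolated also compute isolated-cell profiles (two extra runs).
#' @param pre_settle quiescent lead-in before the protocol (s),
#'   discarded from analysis; lets the cells settle at rest first.
#' @param settle quiescent tail after the protocol (s), included in the
#'   analysis window so the record ends back at rest.
#' @param smooth_bw profile smoothing bandwidth (Hz), see
#'   [spectral_ratio()].
#' @return list with the recorded `trace` (channels `V_pre`, `V_post`,
#'   `I_pre`) and `profiles`: frequency profiles `Zpre`, `Zpost`, `CC`
#'   (and `Z1`, `Z2` when `isolated`), plus `fits`: a [fit_resonance()]
#'   summary per profile.
#' @export
coupled_zap_currentclamp <- function(cell_pre, cell_post, gc, zap,
                                     dt = 0.05, record_dt = 1e-3,
                                     isolated = TRUE, pre_settle = 5,
                                     settle = 10, smooth_bw = 0) {
  stopifnot(inherits(zap, "zap_params"))
  izap <- zap_protocol(zap, baseline = 0, pre_settle = pre_settle)
  dur <- pre_settle + zap_duration(zap) + settle
  run1 <- function(cells, edges, inj) {
    tr <- simulate_network(cells, edges = edges, inj = inj,
                           duration = dur, dt = dt, record_dt = record_dt)
    attr(tr, "analysis_window") <- c(pre_settle, dur)
    tr
  }
  cp <- cell_pre; cp$name <- "pre"
  cq <- cell_post; cq$name <- "post"
  tr <- run1(list(cp, cq), cbind(1, 2, gc), list("1" = izap))
  tr$channels$I_pre <- izap(trace_time(tr))
  tr$units <- c(tr$units, I_pre = "nA")
  band <- c(zap$f_lo, zap$f_hi)
  prof <- list(
    Zpre = spectral_ratio(tr, "V_pre", "I_pre", band, quantity = "Zpre",
                          unit = "MOhm", smooth_bw = smooth_bw),
    Zpost = spectral_ratio(tr, "V_post", "I_pre", band, quantity = "Zpost",
                           unit = "MOhm", smooth_bw = smooth_bw),
    CC = spectral_ratio(tr, "V_post", "V_pre", band, quantity = "CC",
                        unit = "", smooth_bw = smooth_bw))
  if (isolated) {
    for (k in 1:2) {
      ck <- list(cell_pre, cell_post)[[k]]
      ck$name <- "iso"
      tk <- run1(list(ck), NULL, list("1" = izap))
      tk$channels$I_iso <- izap(trace_time(tk))
      tk$units <- c(tk$units, I_iso = "nA")
      prof[[paste0("Z", k)]] <-
        spectral_ratio(tk, "V_iso", "I_iso", band, quantity = paste0("Z", k),
                       unit = "MOhm", smooth_bw = smooth_bw)
    }
  }
  list(trace = tr, profiles = prof,
       fits = lapply(prof, fit_resonance))
}

#' Coupling-current ZAP experiment in dual voltage clamp
#'
#' The prejunctional cell is clamped with a ZAP voltage command, the
#' postjunctional cell is held at a constant potential, and the clamp
#' currents in both are recorded. With only the two clamped cells the
#' postjunctional current is `Gc * (V_pre - V_post)` plus a constant, so
#' its amplitude profile is flat; coupling both clamped cells to a third,
#' free resonant cell makes the measured coupling current inherit that
#' cell's resonance.
#'
#' @param cell_pre,cell_post clamped [cell_spec()]s.
#' @param zap_cmd a [zap_params()] voltage command (mV); typically
#'   `phase = "trough"` with offset at the range midpoint so the command
#'   starts from holding.
#' @param v_hold postjunctional holding potential (mV).
#' @param gc pre-post junctional conductance (uS).
#' @param third optional free [cell_spec()] coupled to both clamped
#'   cells.
#' @param gc3 conductance of each clamped-to-third edge (uS).
#' @param dt,record_dt integration / recording steps (ms, s).
#' @param pre_settle,settle quiescent lead-in / tail (s); see
#'   [coupled_zap_currentclamp()].
#' @param smooth_bw profile smoothing bandwidth (Hz).
#' @return list with the `trace` (channels `V_pre`, `V_post`, `I_pre`,
#'   `I_post`, and `V_3` when present) and `profiles`: `Zpre`
#'   (`|V_pre/I_pre|`, MOhm) and `Gc` (`|I_post/V_pre|`, uS).
#' @export
coupled_zap_voltageclamp <- function(cell_pre, cell_post, zap_cmd,
                                     v_hold = -60, gc = 0.02,
                                     third = NULL, gc3 = gc,
                                     dt = 0.05, record_dt = 1e-3,
                                     pre_settle = 5, settle = 10,
                                     smooth_bw = 0) {
  stopifnot(inherits(zap_cmd, "zap_params"))
  vzap <- zap_protocol(zap_cmd, baseline = v_hold, pre_settle = pre_settle)
  dur <- pre_settle + zap_duration(zap_cmd) + settle
  cp <- cell_pre; cp$name <- "pre"
  cq <- cell_post; cq$name <- "post"
  cells <- list(cp, cq)
  edges <- cbind(1, 2, gc)
  if (!is.null(third)) {
    c3 <- third; c3$name <- "3"
    cells <- c(cells, list(c3))
    edges <- rbind(edges, cbind(1, 3, gc3), cbind(2, 3, gc3))
  }
  tr <- simulate_network(cells, edges = edges,
                         clamp = list("1" = vzap, "2" = v_hold),
                         duration = dur, dt = dt, record_dt = record_dt,
                         v0 = v_hold)
  attr(tr, "analysis_window") <- c(pre_settle, dur)
  band <- c(zap_cmd$f_lo, zap_cmd$f_hi)
  prof <- list(
    Zpre = spectral_ratio(tr, "V_pre", "I_pre", band, quantity = "Zpre",
                          unit = "MOhm", smooth_bw = smooth_bw),
    Gc = spectral_ratio(tr, "I_post", "V_pre", band, quantity = "Gc",
                        unit = "uS", smooth_bw = smooth_bw))
  list(trace = tr, profiles = prof, fits = lapply(prof, fit_resonance))
}
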