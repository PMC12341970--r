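#' Ball-and-stick cable specification
#'
#' A spherical soma coupled to a single neurite divided into equal-length
#' cylindrical (or linearly tapering) compartments; used to quantify how
#' far the somatic voltage clamp controls a gap junction placed along the
#' neurite.
#'
#' @param geometry `"uniform"` (constant neurite diameter) or `"taper"`
#'   (diameter falling linearly from proximal to distal).
#' @param soma_diam soma diameter (um; sphere).
#' @param neurite_length neurite length (um).
#' @param n_comp number of neurite compartments.
#' @param diam uniform neurite diameter (um).
#' @param diam_range proximal and distal diameters for the taper (um).
#' @param R_m specific membrane resistance (Ohm cm^2).
#' @param R_a axial resistivity (Ohm cm).
#' @param C_m specific capacitance (uF/cm^2).
#' @return an object of class `"ball_and_stick"`.
#' @export
ball_and_stick <- function(geometry = c("uniform", "taper"),
                           soma_diam = 100, neurite_length = 1000,
                           n_comp = 101, diam = 10,
                           diam_range = c(20, 0.5),
                           R_m = 10000, R_a = 100, C_m = 1) {
  geometry <- match.arg(geometry)
  if (n_comp < 2) stop("ball_and_stick: need at least 2 compartments")
  if (any(c(soma_diam, neurite_length, diam, diam_range, R_m, R_a, C_m) <= 0))
    stop("ball_and_stick: all geometric and specific parameters must be > 0")
  structure(list(geometry = geometry, soma_diam = soma_diam,
                 neurite_length = neurite_length, n_comp = as.integer(n_comp),
                 diam = diam, diam_range = diam_range,
                 R_m = R_m, R_a = R_a, C_m = C_m),
            class = "ball_and_stick")
}

#' Discretize a ball-and-stick cable
#'
#' Computes per-compartment membrane conductances/capacitances from
#' areas (sphere surface for the soma, cylindrical side area per neurite
#' segment) and axial conductances between compartment midpoints from
#' the frustum formula `R = R_a * l / (pi * r_i * r_j)` (which is exact
#' for a linear taper). Node 1 is the soma; nodes `2 .. n_comp + 1` are
#' neurite compartments at midpoint positions.
#'
#' @param spec a [ball_and_stick()].
#' @return list with `g_m` (uS per node), `c_m` (nF per node), `g_ax`
#'   (uS between consecutive nodes, length `n_comp`), `pos` (um, midpoint
#'   position of each node along the neurite; 0 for the soma), `diam`
#'   (um per node) and `area` (cm^2 per node).
#' @export
build_cable <- function(spec) {
  stopifnot(inherits(spec, "ball_and_stick"))
  n <- spec$n_comp
  l_um <- spec$neurite_length / n
  mid <- (seq_len(n) - 0.5) * l_um
  d_um <- if (spec$geometry == "uniform") rep(spec$diam, n)
          else spec$diam_range[1] +
               diff(spec$diam_range) * mid / spec$neurite_length
  um <- 1e-4  # cm per um
  area_soma <- pi * (spec$soma_diam * um)^2
  area_seg <- pi * (d_um * um) * (l_um * um)
  area <- c(area_soma, area_seg)
  g_m <- area / spec$R_m * 1e6          # uS
  c_m <- area * spec$C_m * 1e3          # nF (uF -> nF)
  r <- d_um * um / 2
  # proximal face radius for the soma-to-first-segment half frustum
  r_prox <- if (spec$geometry == "uniform") r[1]
            else spec$diam_range[1] * um / 2
  l_cm <- l_um * um
  g_ax <- numeric(n)
  g_ax[1] <- pi * r_prox * r[1] / (spec$R_a * l_cm / 2) * 1e6
  if (n > 1)
    g_ax[2:n] <- pi * r[-n] * r[-1] / (spec$R_a * l_cm) * 1e6
  list(g_m = g_m, c_m = c_m, g_ax = g_ax,
       pos = c(0, mid), diam = c(spec$soma_diam, d_um), area = area)
}

#' Passive steady state of a somatically clamped cable
#'
#' Direct linear solve of the passive conductance network for one cable
#' with the soma held at `v` (deviation from rest, mV) and a sealed
#' distal end.
#'
#' @param spec a [ball_and_stick()].
#' @param v somatic voltage deviation (mV).
#' @return numeric vector of node voltages (soma first).
#' @export
cable_steady_state <- function(spec, v = 1) {
  cb <- build_cable(spec)
  n <- spec$n_comp
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    A[i, i] <- cb$g_m[i + 1]
    # proximal axial
    A[i, i] <- A[i, i] + cb$g_ax[i]
    if (i == 1) b[i] <- b[i] + cb$g_ax[1] * v else A[i, i - 1] <- -cb$g_ax[i]
    if (i < n) {
      A[i, i] <- A[i, i] + cb$g_ax[i + 1]
      A[i, i + 1] <- -cb$g_ax[i + 1]
    }
  }
  c(v, solve(A, b))
}

#' Apparent junctional conductance under dual somatic clamp
#'
#' Two identical passive cables are joined by a gap junction of true
#' conductance `gc_true` at the same neurite compartment of each; both
#' somas are ideally voltage clamped, a steady step is applied to cell 1
#' and the apparent conductance is the postjunctional somatic clamp
#' current change divided by the step:
#' `Gc_app = I_2 / (V_1 - V_hold)`. Obtained by direct linear solve of
#' the coupled passive network (steps are measured at steady state, so no
#' time stepping is needed).
#'
#' @param spec a [ball_and_stick()].
#' @param index neurite compartment (1-based, 1 = soma-adjacent,
#'   `n_comp` = distal tip) carrying the junction.
#' @param gc_true junctional conductance (uS).
#' @param v_step step amplitude (mV); immaterial for a passive network.
#' @return apparent conductance (uS).
#' @export
apparent_gc <- function(spec, index, gc_true, v_step = 10) {
  stopifnot(inherits(spec, "ball_and_stick"))
  n <- spec$n_comp
  if (index < 1 || index > n) stop("apparent_gc: junction index outside neurite")
  if (gc_true <= 0) stop("apparent_gc: gc_true must be > 0")
  cb <- build_cable(spec)
  # unknowns: neurite nodes of cell 1 (1..n) then cell 2 (n+1..2n);
  # somas fixed at v_step (cell 1) and 0 (cell 2)
  N <- 2 * n
  A <- matrix(0, N, N)
  b <- numeric(N)
  add_cable <- function(off, v_soma) {
    for (i in seq_len(n)) {
      r <- off + i
      A[r, r] <<- A[r, r] + cb$g_m[i + 1] + cb$g_ax[i]
      if (i == 1) b[r] <<- b[r] + cb$g_ax[1] * v_soma
      else A[r, r - 1] <<- -cb$g_ax[i]
      if (i < n) {
        A[r, r] <<- A[r, r] + cb$g_ax[i + 1]
        A[r, r + 1] <<- -cb$g_ax[i + 1]
      }
    }
  }
  add_cable(0, v_step)
  add_cable(n, 0)
  i1 <- index; i2 <- n + index
  A[i1, i1] <- A[i1, i1] + gc_true; A[i1, i2] <- A[i1, i2] - gc_true
  A[i2, i2] <- A[i2, i2] + gc_true; A[i2, i1] <- A[i2, i1] - gc_true
  vv <- solve(A, b)
  # postjunctional somatic clamp current change: axial current drawn from
  # the clamped soma (held at 0) by its depolarized first neurite node
  i_post <- cb$g_ax[1] * vv[n + 1]
  i_post / v_step
}

#' Space-clamp attenuation of the measured coupling conductance
#'
#' [apparent_gc()] evaluated across junction placements; the attenuation
#' ratio is `gc_true / apparent`.
#'
#' @param spec a [ball_and_stick()].
#' @param indices neurite compartments to test (default: all).
#' @param gc_true junctional conductance (uS).
#' @return data frame with `index`, `pos` (um), `apparent` (uS) and
#'   `attenuation`.
#' @export
attenuation_curve <- function(spec, indices = seq_len(spec$n_comp),
                              gc_true = 0.1) {
  cb <- build_cable(spec)
  app <- vapply(indices, function(i) apparent_gc(spec, i, gc_true), 0)
  data.frame(index = indices, pos = cb$pos[indices + 1],
             apparent = app, attenuation = gc_true / app)
}

# per-compartment resonant cells: Table-2-style channel densities applied
# to each compartment's area (reference area = C_point / C_m of the
# single-compartment resonator cell)
cable_cells <- function(spec, cell = resonator_cell(), prefix = "c") {
  cb <- build_cable(spec)
  a0 <- cell$C / (spec$C_m * 1e3)  # cm^2 of the point cell
  lapply(seq_along(cb$g_m), function(i) {
    sc <- cb$area[i] / a0
    chans <- lapply(cell$channels, function(ch) {
      ch$g_max <- ch$g_max * sc
      ch
    })
    cell_spec(C = cb$c_m[i], channels = chans,
              name = paste0(prefix, i - 1))
  })
}

#' Frequency profile of the apparent coupling conductance (resonant cable)
#'
#' Adds the resonant channel set to every compartment of both cables,
#' clamps both somas (ZAP command on cell 1, constant holding on cell 2)
#' and measures the apparent-conductance profile `|I_2(f)| / |V_1(f)|`.
#' Used to check that space-clamp filtering of a distal ohmic junction
#' does not by itself create a pronounced conductance resonance.
#'
#' @param spec a [ball_and_stick()]; modest compartment counts keep the
#'   run affordable.
#' @param index junction compartment.
#' @param gc_true junctional conductance (uS).
#' @param zap_cmd a [zap_params()] voltage command (mV).
#' @param v_hold holding potential (mV).
#' @param cell template [cell_spec()] supplying the channel densities.
#' @param pre_settle,settle quiescent lead-in / tail (s).
#' @param dt integration step (ms).
#' @return a [freq_profile()] of the apparent conductance (uS).
#' @export
apparent_gc_profile <- function(spec, index, gc_true, zap_cmd,
                                v_hold = -60, cell = resonator_cell(),
                                pre_settle = 5, settle = 10, dt = 0.05) {
  stopifnot(inherits(zap_cmd, "zap_params"))
  n <- spec$n_comp
  cells <- c(cable_cells(spec, cell, "a"), cable_cells(spec, cell, "b"))
  cb <- build_cable(spec)
  nn <- n + 1
  ax <- function(off) cbind(off + 1:n, off + 2:(n + 1), cb$g_ax)
  edges <- rbind(ax(0), ax(nn), cbind(1 + index, nn + 1 + index, gc_true))
  vzap <- zap_protocol(zap_cmd, baseline = v_hold, pre_settle = pre_settle)
  dur <- pre_settle + zap_duration(zap_cmd) + settle
  tr <- simulate_network(cells, edges = edges,
                         clamp = stats::setNames(list(vzap, v_hold),
                                                 c("1", as.character(nn + 1))),
                         duration = dur, dt = dt, record_dt = 1e-3,
                         v0 = v_hold)
  attr(tr, "analysis_window") <- c(pre_settle, dur)
  spectral_ratio(tr, paste0("I_b", 0), paste0("V_a", 0),
                 band = c(zap_cmd$f_lo, zap_cmd$f_hi),
                 quantity = "Gc", unit = "uS")
}
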