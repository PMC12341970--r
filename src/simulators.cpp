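#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Units throughout: mV, nA, uS, nF, ms.  g(uS)*V(mV) = I(nA); C(nF)*dV/dt(mV/ms) = I(nA).

// logistic steady state 1/(1 + exp((v - vh)/k))
static inline double xinf(double v, double vh, double k) {
  return 1.0 / (1.0 + std::exp((v - vh) / k));
}

// tau forms: 0 instantaneous, 1 constant ta, 2 ta + tb*xinf(v), 3 ta + tb/(1+exp((v-tc)/td))
static inline double tauv(double v, int form, double ta, double tb,
                          double tc, double td, double vh, double k,
                          double scale) {
  double t;
  switch (form) {
  case 1: t = ta; break;
  case 2: t = ta + tb * xinf(v, vh, k); break;
  case 3: t = ta + tb / (1.0 + std::exp((v - tc) / td)); break;
  default: t = 0.0;
  }
  return scale * t;
}

struct Gate {
  double vh, k;      // steady-state logistic parameters
  int p;             // exponent
  int form;          // tau form code
  double ta, tb, tc, td, scale;
  int sidx;          // index in gate-state vector; -1 => instantaneous
};

struct Chan {
  int cell;
  double g, E;       // uS, mV
  bool has_m, has_h;
  Gate m, h;
};

// Fixed-step RK4 simulation of a network of single-compartment
// Hodgkin-Huxley cells coupled by ohmic (gap-junction / axial) edges.
// Clamped cells follow their command exactly (ideal clamp); their clamp
// current is reported as the residual of the current balance.
//
// chan_mat: one row per channel:
//   cell(0-based), g, E,
//   m_vh, m_k, m_p, m_form, m_ta, m_tb, m_tc, m_td, m_scale,
//   has_h, h_vh, h_k, h_q, h_form, h_ta, h_tb, h_tc, h_td, h_scale   (22 cols)
// edges: rows (i, j, g) 0-based, each undirected edge listed once.
// inj / cmd: sampled on the half-step grid (2*n_steps + 1 values).
// [[Rcpp::export]]
List simulate_network_cpp(int n_steps, double dt, NumericVector C,
                          NumericMatrix chan_mat, NumericMatrix edges,
                          IntegerVector inj_cells, NumericMatrix inj,
                          IntegerVector clamp_cells, NumericMatrix cmd,
                          NumericVector V0, int record_every) {
  const int ncell = C.size();
  const int nchan = chan_mat.nrow();
  const int nedge = edges.nrow();
  const int ninj = inj_cells.size();
  const int nclamp = clamp_cells.size();

  std::vector<Chan> chans(nchan);
  int nstate_g = 0;
  for (int c = 0; c < nchan; ++c) {
    Chan ch;
    ch.cell = (int)chan_mat(c, 0);
    ch.g = chan_mat(c, 1);
    ch.E = chan_mat(c, 2);
    ch.has_m = !NumericVector::is_na(chan_mat(c, 3));
    if (ch.has_m) {
      ch.m.vh = chan_mat(c, 3); ch.m.k = chan_mat(c, 4);
      ch.m.p = (int)chan_mat(c, 5); ch.m.form = (int)chan_mat(c, 6);
      ch.m.ta = chan_mat(c, 7); ch.m.tb = chan_mat(c, 8);
      ch.m.tc = chan_mat(c, 9); ch.m.td = chan_mat(c, 10);
      ch.m.scale = chan_mat(c, 11);
      ch.m.sidx = (ch.m.form == 0) ? -1 : nstate_g++;
    }
    ch.has_h = chan_mat(c, 12) > 0.5;
    if (ch.has_h) {
      ch.h.vh = chan_mat(c, 13); ch.h.k = chan_mat(c, 14);
      ch.h.p = (int)chan_mat(c, 15); ch.h.form = (int)chan_mat(c, 16);
      ch.h.ta = chan_mat(c, 17); ch.h.tb = chan_mat(c, 18);
      ch.h.tc = chan_mat(c, 19); ch.h.td = chan_mat(c, 20);
      ch.h.scale = chan_mat(c, 21);
      ch.h.sidx = (ch.h.form == 0) ? -1 : nstate_g++;
    }
    chans[c] = ch;
  }

  // map cells to free-voltage state slots / clamp columns / injection columns
  std::vector<int> vidx(ncell, -1), clampcol(ncell, -1), injcol(ncell, -1);
  for (int i = 0; i < nclamp; ++i) clampcol[clamp_cells[i]] = i;
  for (int i = 0; i < ninj; ++i) injcol[inj_cells[i]] = i;
  int nfree = 0;
  for (int i = 0; i < ncell; ++i) if (clampcol[i] < 0) vidx[i] = nfree++;

  const int ns = nfree + nstate_g;
  std::vector<double> y(ns), k1(ns), k2(ns), k3(ns), k4(ns), yt(ns);

  // initial conditions: V0, gates at steady state for V0
  for (int i = 0; i < ncell; ++i) if (vidx[i] >= 0) y[vidx[i]] = V0[i];
  for (int c = 0; c < nchan; ++c) {
    double v = V0[chans[c].cell];
    if (chans[c].has_m && chans[c].m.sidx >= 0)
      y[nfree + chans[c].m.sidx] = xinf(v, chans[c].m.vh, chans[c].m.k);
    if (chans[c].has_h && chans[c].h.sidx >= 0)
      y[nfree + chans[c].h.sidx] = xinf(v, chans[c].h.vh, chans[c].h.k);
  }

  const int nrec = n_steps / record_every + 1;
  NumericMatrix Vout(nrec, ncell);
  NumericMatrix Iclamp(nrec, std::max(nclamp, 1));

  std::vector<double> Vnode(ncell), Imem(ncell);

  // derivative evaluation at half-step sample index `samp`
  auto deriv = [&](const std::vector<double> &yy, int samp,
                   std::vector<double> &dy) {
    for (int i = 0; i < ncell; ++i)
      Vnode[i] = (vidx[i] >= 0) ? yy[vidx[i]] : cmd(samp, clampcol[i]);
    std::fill(Imem.begin(), Imem.end(), 0.0);
    for (int c = 0; c < nchan; ++c) {
      const Chan &ch = chans[c];
      double v = Vnode[ch.cell], gate = 1.0;
      if (ch.has_m) {
        double m = (ch.m.sidx >= 0) ? yy[nfree + ch.m.sidx]
                                    : xinf(v, ch.m.vh, ch.m.k);
        for (int e = 0; e < ch.m.p; ++e) gate *= m;
        if (ch.m.sidx >= 0) {
          double tau = tauv(v, ch.m.form, ch.m.ta, ch.m.tb, ch.m.tc,
                            ch.m.td, ch.m.vh, ch.m.k, ch.m.scale);
          dy[nfree + ch.m.sidx] =
            (xinf(v, ch.m.vh, ch.m.k) - yy[nfree + ch.m.sidx]) / tau;
        }
      }
      if (ch.has_h) {
        double h = (ch.h.sidx >= 0) ? yy[nfree + ch.h.sidx]
                                    : xinf(v, ch.h.vh, ch.h.k);
        for (int e = 0; e < ch.h.p; ++e) gate *= h;
        if (ch.h.sidx >= 0) {
          double tau = tauv(v, ch.h.form, ch.h.ta, ch.h.tb, ch.h.tc,
                            ch.h.td, ch.h.vh, ch.h.k, ch.h.scale);
          dy[nfree + ch.h.sidx] =
            (xinf(v, ch.h.vh, ch.h.k) - yy[nfree + ch.h.sidx]) / tau;
        }
      }
      Imem[ch.cell] += ch.g * gate * (v - ch.E);
    }
    for (int e = 0; e < nedge; ++e) {
      int i = (int)edges(e, 0), j = (int)edges(e, 1);
      double ic = edges(e, 2) * (Vnode[i] - Vnode[j]);
      Imem[i] += ic;
      Imem[j] -= ic;
    }
    for (int i = 0; i < ncell; ++i) {
      if (vidx[i] < 0) continue;
      double iin = (injcol[i] >= 0) ? inj(samp, injcol[i]) : 0.0;
      dy[vidx[i]] = (-Imem[i] + iin) / C[i];
    }
  };

  // clamp current at a full step (state yy, sample index samp = 2*step)
  auto record = [&](const std::vector<double> &yy, int samp, int row) {
    deriv(yy, samp, k1);  // fills Vnode / Imem at this state
    for (int i = 0; i < ncell; ++i) Vout(row, i) = Vnode[i];
    for (int q = 0; q < nclamp; ++q) {
      int i = clamp_cells[q];
      double dvdt;
      int last = cmd.nrow() - 1;
      if (samp == 0) dvdt = (cmd(1, q) - cmd(0, q)) / (dt / 2.0);
      else if (samp >= last) dvdt = (cmd(last, q) - cmd(last - 1, q)) / (dt / 2.0);
      else dvdt = (cmd(samp + 1, q) - cmd(samp - 1, q)) / dt;
      double iin = (injcol[i] >= 0) ? inj(samp, injcol[i]) : 0.0;
      Iclamp(row, q) = C[i] * dvdt + Imem[i] - iin;
    }
  };

  record(y, 0, 0);
  int row = 1;
  for (int s = 0; s < n_steps; ++s) {
    int s0 = 2 * s;
    deriv(y, s0, k1);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    deriv(yt, s0 + 1, k2);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    deriv(yt, s0 + 1, k3);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + dt * k3[i];
    deriv(yt, s0 + 2, k4);
    for (int i = 0; i < ns; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if ((s + 1) % record_every == 0) {
      for (int i = 0; i < nfree; ++i)
        if (!std::isfinite(y[i]))
          stop("integration diverged (non-finite voltage) at t = %g ms",
               (s + 1) * dt);
      record(y, s0 + 2, row++);
    }
  }

  NumericVector gates_final(std::max(nstate_g, 1));
  for (int i = 0; i < nstate_g; ++i) gates_final[i] = y[nfree + i];
  return List::create(_["V"] = Vout, _["Iclamp"] = Iclamp,
                      _["dt_rec"] = dt * record_every,
                      _["gates_final"] = gates_final);
}

// Two coupled two-variable linear resonators (voltages relative to rest).
//   C dVi/dt = -gLi Vi - g1i wi - Gc (Vi - Vj) + Ii(t)
//   taui dwi/dt = Vi - wi
// mode 0 (current clamp): both voltages free, I1/I2 injected.
// mode 1 (dual voltage clamp): V1 follows cmd1, V2 follows cmd2; the
//   clamp currents are reported.
// inj1/inj2 or cmd1/cmd2 sampled on the half-step grid (2*n_steps+1).
// [[Rcpp::export]]
List simulate_linear_pair_cpp(int n_steps, double dt,
                              NumericVector p1, NumericVector p2, double Gc,
                              int mode,
                              NumericVector in1, NumericVector in2,
                              int record_every) {
  const double C1 = p1[0], gL1 = p1[1], g11 = p1[2], tau1 = p1[3];
  const double C2 = p2[0], gL2 = p2[1], g12 = p2[2], tau2 = p2[3];
  const int nrec = n_steps / record_every + 1;
  NumericMatrix out(nrec, 4); // V1 V2 I1 I2

  if (mode == 0) {
    double y[4] = {0, 0, 0, 0}; // V1 w1 V2 w2
    double k1[4], k2[4], k3[4], k4[4], yt[4];
    auto deriv = [&](const double *yy, int s, double *dy) {
      dy[0] = (-gL1 * yy[0] - g11 * yy[1] - Gc * (yy[0] - yy[2]) + in1[s]) / C1;
      dy[1] = (yy[0] - yy[1]) / tau1;
      dy[2] = (-gL2 * yy[2] - g12 * yy[3] - Gc * (yy[2] - yy[0]) + in2[s]) / C2;
      dy[3] = (yy[2] - yy[3]) / tau2;
    };
    out(0, 0) = 0; out(0, 1) = 0; out(0, 2) = in1[0]; out(0, 3) = in2[0];
    int row = 1;
    for (int s = 0; s < n_steps; ++s) {
      int s0 = 2 * s;
      deriv(y, s0, k1);
      for (int i = 0; i < 4; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
      deriv(yt, s0 + 1, k2);
      for (int i = 0; i < 4; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
      deriv(yt, s0 + 1, k3);
      for (int i = 0; i < 4; ++i) yt[i] = y[i] + dt * k3[i];
      deriv(yt, s0 + 2, k4);
      for (int i = 0; i < 4; ++i)
        y[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
      if ((s + 1) % record_every == 0) {
        out(row, 0) = y[0]; out(row, 1) = y[2];
        out(row, 2) = in1[s0 + 2]; out(row, 3) = in2[s0 + 2];
        ++row;
      }
    }
  } else {
    // states: w1, w2; V prescribed by commands
    double w1 = in1[0], w2 = in2[0]; // start at steady state for initial V
    double a1, a2, b1, b2, c1, c2, d1, d2, wt1, wt2;
    const int last = 2 * n_steps;
    auto iclamp = [&](int s, double ww1, double ww2, double *i1, double *i2) {
      double v1 = in1[s], v2 = in2[s], dv1, dv2;
      if (s == 0) { dv1 = (in1[1] - in1[0]) / (dt / 2); dv2 = (in2[1] - in2[0]) / (dt / 2); }
      else if (s >= last) { dv1 = (in1[last] - in1[last - 1]) / (dt / 2); dv2 = (in2[last] - in2[last - 1]) / (dt / 2); }
      else { dv1 = (in1[s + 1] - in1[s - 1]) / dt; dv2 = (in2[s + 1] - in2[s - 1]) / dt; }
      *i1 = C1 * dv1 + gL1 * v1 + g11 * ww1 + Gc * (v1 - v2);
      *i2 = C2 * dv2 + gL2 * v2 + g12 * ww2 + Gc * (v2 - v1);
    };
    double i1, i2;
    iclamp(0, w1, w2, &i1, &i2);
    out(0, 0) = in1[0]; out(0, 1) = in2[0]; out(0, 2) = i1; out(0, 3) = i2;
    int row = 1;
    for (int s = 0; s < n_steps; ++s) {
      int s0 = 2 * s;
      a1 = (in1[s0] - w1) / tau1;           a2 = (in2[s0] - w2) / tau2;
      wt1 = w1 + 0.5 * dt * a1;             wt2 = w2 + 0.5 * dt * a2;
      b1 = (in1[s0 + 1] - wt1) / tau1;      b2 = (in2[s0 + 1] - wt2) / tau2;
      wt1 = w1 + 0.5 * dt * b1;             wt2 = w2 + 0.5 * dt * b2;
      c1 = (in1[s0 + 1] - wt1) / tau1;      c2 = (in2[s0 + 1] - wt2) / tau2;
      wt1 = w1 + dt * c1;                   wt2 = w2 + dt * c2;
      d1 = (in1[s0 + 2] - wt1) / tau1;      d2 = (in2[s0 + 2] - wt2) / tau2;
      w1 += dt / 6.0 * (a1 + 2 * b1 + 2 * c1 + d1);
      w2 += dt / 6.0 * (a2 + 2 * b2 + 2 * c2 + d2);
      if ((s + 1) % record_every == 0) {
        iclamp(s0 + 2, w1, w2, &i1, &i2);
        out(row, 0) = in1[s0 + 2]; out(row, 1) = in2[s0 + 2];
        out(row, 2) = i1; out(row, 3) = i2;
        ++row;
      }
    }
  }
  colnames(out) = CharacterVector::create("V1", "V2", "I1", "I2");
  return List::create(_["out"] = out, _["dt_rec"] = dt * record_every);
}
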