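#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#define GRANET_HAVE_FTZ 1
#endif

using namespace Rcpp;

// Clock-driven network integrator.
//
// Granule-cell excitation uses the linear glutamate-diffusion cascade in
// modal coordinates: each presynaptic release injects into five modal state
// variables (the eigenmodes of the cascade matrix, computed in R); the
// transmitter concentration T is a fixed linear combination of the modes and
// drives AMPA and NMDA receptor stages integrated by exponential Euler.
// All double-exponential conductances are represented as rise/decay state
// pairs with exact per-step decay factors, so synaptic kinetics are exact
// between events. Spikes travel through per-edge delay queues (a ring of
// event buckets); gap junctions are resolved explicitly within each step
// from the previous-step potentials.

struct Csr {
  std::vector<int> off, tgt, dstep;
  std::vector<float> w;
  void load(List l, int npre) {
    IntegerVector pre = l["pre"], post = l["post"], ds = l["dstep"];
    NumericVector wv = l["w"];
    int ne = pre.size();
    std::vector<int> cnt(npre + 1, 0);
    for (int e = 0; e < ne; ++e) cnt[pre[e]]++;          // pre is 1-based
    off.assign(npre + 1, 0);
    for (int i = 0; i < npre; ++i) off[i + 1] = off[i] + cnt[i + 1];
    std::vector<int> cur(off.begin(), off.end() - 1);
    tgt.resize(ne); dstep.resize(ne); w.resize(ne);
    for (int e = 0; e < ne; ++e) {
      int p = pre[e] - 1, k = cur[p]++;
      tgt[k] = post[e] - 1; dstep[k] = ds[e]; w[k] = (float)wv[e];
    }
  }
};

struct Event { int tgt; float w; uint8_t syn; };
// syn codes: 0 MF->GrC release, 1 GABA on GrC, 2 MF->GoC AMPA,
//            3 GrC->GoC AMPA (AA+PF), 4 GABA on GoC

// [[Rcpp::export]]
List cpp_run_network(List net, List kin, List planl) {
#ifdef GRANET_HAVE_FTZ
  // flush denormal synaptic states to zero: exponentially decaying
  // conductances otherwise underflow into subnormals and stall the FPU
  unsigned int old_csr = _mm_getcsr();
  _mm_setcsr(old_csr | 0x8040);  // FTZ | DAZ
#endif
  const int n_grc = as<int>(net["n_grc"]);
  const int n_goc = as<int>(net["n_goc"]);
  const int n_fiber = as<int>(net["n_fiber"]);

  const double dt = as<double>(planl["dt_ms"]);
  const int n_steps = as<int>(planl["n_steps"]);
  const uint64_t seed = (uint64_t)as<double>(planl["seed"]);

  Csr mf_grc, mf_goc, goc_grc, aa_goc, pf_goc, goc_goc;
  mf_grc.load(net["mf_grc"], n_fiber);
  mf_goc.load(net["mf_goc"], n_fiber);
  goc_grc.load(net["goc_grc"], n_goc);
  aa_goc.load(net["aa_goc"], n_grc);
  pf_goc.load(net["pf_goc"], n_grc);
  goc_goc.load(net["goc_goc"], n_goc);

  IntegerVector gap_i = net["gap_i"], gap_j = net["gap_j"];
  NumericVector gap_g = net["gap_g"];
  const int n_gap = gap_i.size();
  // adjacency for spikelet transmission (both directions)
  std::vector<std::vector<std::pair<int, float> > > gap_adj(n_goc);
  for (int k = 0; k < n_gap; ++k) {
    gap_adj[gap_i[k] - 1].push_back(
        std::make_pair(gap_j[k] - 1, (float)gap_g[k]));
    gap_adj[gap_j[k] - 1].push_back(
        std::make_pair(gap_i[k] - 1, (float)gap_g[k]));
  }

  NumericVector mf_t = net["mf_spike_t"];
  IntegerVector mf_f = net["mf_spike_f"];
  const int n_mfspk = mf_t.size();

  // --- kinetic constants -------------------------------------------------
  NumericVector lam = kin["cascade_lambda"], inj = kin["cascade_inj"],
                outw = kin["cascade_out"];
  float cdec[5], cinj[5], cout[5];
  for (int k = 0; k < 5; ++k) {
    cdec[k] = (float)std::exp(lam[k] * dt);
    cinj[k] = (float)inj[k];
    cout[k] = (float)outw[k];
  }
  List ka = kin["ampa_grc"], kn = kin["nmda_grc"], kg = kin["gaba_grc"],
       km = kin["ampa_mf_goc"], kx = kin["ampa_grc_goc"], kq = kin["gaba_goc"],
       ke = kin["extra_goc"], kt = kin["tonic_grc"];
  auto f1 = [&](List l, const char* nm) { return (float)as<double>(l[nm]); };
  // receptor stages on GrC (driven by T)
  float a_c1r = (float)std::exp(-dt / as<double>(ka["tau_rise_ms"]));
  float a_c1d = (float)std::exp(-dt / as<double>(ka["tau_decay_ms"]));
  float a_c2r = (float)(as<double>(ka["tau_rise_ms"]) * (1 - a_c1r));
  float a_c2d = (float)(as<double>(ka["tau_decay_ms"]) * (1 - a_c1d));
  float a_norm = f1(ka, "norm");
  double n_taud_eff = as<double>(kn["tau_decay_eff_ms"]);
  float n_c1r = (float)std::exp(-dt / as<double>(kn["tau_rise_ms"]));
  float n_c1d = (float)std::exp(-dt / n_taud_eff);
  float n_c2r = (float)(as<double>(kn["tau_rise_ms"]) * (1 - n_c1r));
  float n_c2d = (float)(n_taud_eff * (1 - n_c1d));
  float n_norm = f1(kn, "norm");
  // GABA on GrC: three shared exponentials
  float g_df = (float)std::exp(-dt / as<double>(kg["tau_fast_ms"]));
  float g_ds = (float)std::exp(-dt / as<double>(kg["tau_slow_ms"]));
  float g_dr = (float)std::exp(-dt / as<double>(kg["tau_rise_ms"]));
  float g_cf = f1(kg, "amp_fast"), g_cs = f1(kg, "amp_slow");
  float e_gaba_grc = f1(kg, "e_rev_mv");
  // GoC AMPA stages (event-driven double exponentials)
  float m_c1r = (float)std::exp(-dt / as<double>(km["tau_rise_ms"]));
  float m_c1d = (float)std::exp(-dt / as<double>(km["tau_decay_ms"]));
  float m_norm = f1(km, "norm");
  float x_c1r = (float)std::exp(-dt / as<double>(kx["tau_rise_ms"]));
  float x_c1d = (float)std::exp(-dt / as<double>(kx["tau_decay_ms"]));
  float x_norm = f1(kx, "norm");
  float q_c1r = (float)std::exp(-dt / as<double>(kq["tau_rise_ms"]));
  float q_c1d = (float)std::exp(-dt / as<double>(kq["tau_fast_ms"]));
  float q_norm = f1(kq, "norm");
  float e_gaba_goc = f1(kq, "e_rev_mv");
  // extracortical inhibition on GoC
  bool extra_on = as<bool>(ke["enabled"]);
  float e_dec = (float)std::exp(-dt / as<double>(ke["tau_decay_ms"]));
  float e_peak = f1(ke, "peak_g_ns");
  double e_lambda = as<double>(ke["rate_per_ms"]) * dt;  // events per step
  float e_rev_extra = f1(ke, "e_rev_mv");
  // tonic inhibition on GrC
  float ton_g = as<bool>(kt["enabled"]) ? f1(kt, "g_ns") : 0.0f;
  float ton_e = f1(kt, "e_rev_mv");
  // NMDA Mg-block lookup table
  NumericVector mgt = kin["mg_table"];
  double mg_v0 = as<double>(kin["mg_v0"]), mg_dv = as<double>(kin["mg_dv"]);
  int mg_n = mgt.size();
  std::vector<float> mgtab(mgt.begin(), mgt.end());
  // release depression
  List rel = kin["release"];
  double rel_y0 = as<double>(rel["y0"]), rel_d = as<double>(rel["depression_frac"]),
         rel_tau = as<double>(rel["recovery_ms"]);

  List pg = kin["grc"], pq = kin["goc"];
  auto d1 = [&](List l, const char* nm) { return as<double>(l[nm]); };
  double gr_c = d1(pg, "c_pf"), gr_gl = d1(pg, "g_leak_ns"),
         gr_el = d1(pg, "e_leak_mv"), gr_th = d1(pg, "v_thresh_mv"),
         gr_re = d1(pg, "v_reset_mv"), gr_ref = d1(pg, "refractory_ms");
  double go_c = d1(pq, "c_pf"), go_gl = d1(pq, "g_leak_ns"),
         go_el = d1(pq, "e_leak_mv"), go_th = d1(pq, "v_thresh_mv"),
         go_re = d1(pq, "v_reset_mv"), go_ref = d1(pq, "refractory_ms"),
         go_b = d1(pq, "adapt_b_pa"), go_tw = d1(pq, "adapt_tau_ms"),
         go_id = d1(pq, "i_drive_pa"), go_blk = d1(pq, "block_v_mv"),
         go_spklt = pq.containsElementNamed("gap_spikelet_mv_ms") ?
           d1(pq, "gap_spikelet_mv_ms") : 0.0;
  const float f_spklt_c = (float)(go_spklt / go_c);  // dV per nS of coupling
  float go_wdec = (float)std::exp(-dt / go_tw);
  float shadow_c = (float)(dt / 20.0);   // 20-ms shadow for depol. block

  // hoisted single-precision neuron constants for the inner loops
  const float f_dtc_g = (float)(dt / gr_c), f_gl_g = (float)gr_gl,
              f_el_g = (float)gr_el, f_th_g = (float)gr_th,
              f_re_g = (float)gr_re, f_ref_g = (float)gr_ref,
              f_dt = (float)dt;
  const float f_dtc_o = (float)(dt / go_c), f_gl_o = (float)go_gl,
              f_el_o = (float)go_el, f_th_o = (float)go_th,
              f_re_o = (float)go_re, f_ref_o = (float)go_ref,
              f_b_o = (float)go_b, f_id_o = (float)go_id,
              f_blk_o = (float)go_blk;
  const float f_mg_v0 = (float)mg_v0, f_mg_idv = (float)(1.0 / mg_dv);
  const int mg_last = mg_n - 1;
  auto mgf = [&](float v) -> float {
    float u = (v - f_mg_v0) * f_mg_idv;
    if (u <= 0.0f) return mgtab[0];
    if (u >= (float)mg_last) return mgtab[mg_last];
    int i = (int)u; float fr = u - (float)i;
    return mgtab[i] + (mgtab[i + 1] - mgtab[i]) * fr;
  };

  // --- state -------------------------------------------------------------
  NumericVector v0g = net["v_init_grc"], v0o = net["v_init_goc"];
  std::vector<float> vg(v0g.begin(), v0g.end());
  std::vector<float> zc0(n_grc, 0), zc1(n_grc, 0), zc2(n_grc, 0),
      zc3(n_grc, 0), zc4(n_grc, 0);
  std::vector<float> ar(n_grc, 0), ad(n_grc, 0), nr(n_grc, 0), nd(n_grc, 0);
  std::vector<float> gf(n_grc, 0), gs(n_grc, 0), grr(n_grc, 0);
  std::vector<float> refg(n_grc, 0);

  std::vector<float> vo(v0o.begin(), v0o.end()), vo_prev(vo);
  std::vector<float> mr(n_goc, 0), md(n_goc, 0), xr(n_goc, 0), xd(n_goc, 0),
      qr(n_goc, 0), qd(n_goc, 0), xe(n_goc, 0), wadapt(n_goc, 0),
      refo(n_goc, 0), shadow(vo), gapcur(n_goc, 0);

  std::vector<double> relR(n_fiber, 1.0), rel_last(n_fiber, -1e9);

  // delay ring
  int max_d = 1;
  for (const Csr* c : {&mf_grc, &mf_goc, &goc_grc, &aa_goc, &pf_goc, &goc_goc})
    for (int d : c->dstep) max_d = std::max(max_d, d);
  int ring_n = max_d + 2;
  std::vector<std::vector<Event> > ring(ring_n);

  Rng rng(splitmix64(seed ^ 0xE47ULL));

  std::vector<int> spk_grc_cell, spk_goc_cell;
  std::vector<double> spk_grc_t, spk_goc_t;

  IntegerVector rec_g = planl["record_voltage_grc"], rec_o = planl["record_voltage_goc"];
  NumericMatrix vrec_g(rec_g.size() > 0 ? n_steps : 0, rec_g.size());
  NumericMatrix vrec_o(rec_o.size() > 0 ? n_steps : 0, rec_o.size());

  int mf_ptr = 0;
  std::vector<int> fired;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;

    // schedule mossy-fiber releases falling in [t, t+dt)
    while (mf_ptr < n_mfspk && mf_t[mf_ptr] < t + dt) {
      int f = mf_f[mf_ptr] - 1;
      // presynaptic resource recovery and depression
      if (rel_last[f] > -1e8)
        relR[f] = 1 - (1 - relR[f]) * std::exp(-(mf_t[mf_ptr] - rel_last[f]) / rel_tau);
      double y = rel_y0 * relR[f];
      relR[f] *= (1 - rel_d);
      rel_last[f] = mf_t[mf_ptr];
      for (int e = mf_grc.off[f]; e < mf_grc.off[f + 1]; ++e)
        ring[(s + mf_grc.dstep[e]) % ring_n].push_back(
            Event{mf_grc.tgt[e], (float)(y * mf_grc.w[e]), 0});
      for (int e = mf_goc.off[f]; e < mf_goc.off[f + 1]; ++e)
        ring[(s + mf_goc.dstep[e]) % ring_n].push_back(
            Event{mf_goc.tgt[e], mf_goc.w[e], 2});
      ++mf_ptr;
    }

    // deliver events due this step
    {
      std::vector<Event>& bucket = ring[s % ring_n];
      for (const Event& ev : bucket) {
        switch (ev.syn) {
          case 0:
            zc0[ev.tgt] += cinj[0] * ev.w; zc1[ev.tgt] += cinj[1] * ev.w;
            zc2[ev.tgt] += cinj[2] * ev.w; zc3[ev.tgt] += cinj[3] * ev.w;
            zc4[ev.tgt] += cinj[4] * ev.w;
            break;
          case 1:
            gf[ev.tgt] += g_cf * ev.w; gs[ev.tgt] += g_cs * ev.w;
            grr[ev.tgt] += (g_cf + g_cs) * ev.w;
            break;
          case 2:
            mr[ev.tgt] += m_norm * ev.w; md[ev.tgt] += m_norm * ev.w;
            break;
          case 3:
            xr[ev.tgt] += x_norm * ev.w; xd[ev.tgt] += x_norm * ev.w;
            break;
          case 4:
            qr[ev.tgt] += q_norm * ev.w; qd[ev.tgt] += q_norm * ev.w;
            break;
        }
      }
      bucket.clear();
    }

    // --- granule cells ---------------------------------------------------
    fired.clear();
    for (int i = 0; i < n_grc; ++i) {
      zc0[i] *= cdec[0]; zc1[i] *= cdec[1]; zc2[i] *= cdec[2];
      zc3[i] *= cdec[3]; zc4[i] *= cdec[4];
      float T = cout[0] * zc0[i] + cout[1] * zc1[i] + cout[2] * zc2[i] +
                cout[3] * zc3[i] + cout[4] * zc4[i];
      ar[i] = ar[i] * a_c1r + a_c2r * T;
      ad[i] = ad[i] * a_c1d + a_c2d * T;
      nr[i] = nr[i] * n_c1r + n_c2r * T;
      nd[i] = nd[i] * n_c1d + n_c2d * T;
      gf[i] *= g_df; gs[i] *= g_ds; grr[i] *= g_dr;
      float v = vg[i];
      float g_a = a_norm * (ad[i] - ar[i]);
      float g_n = n_norm * (nd[i] - nr[i]) * mgf(v);
      float g_g = gf[i] + gs[i] - grr[i];
      if (refg[i] > 0.0f) { refg[i] -= f_dt; vg[i] = f_re_g; continue; }
      // implicit (backward-Euler) membrane update: unconditionally stable
      // under arbitrarily large synaptic conductances
      float num = v + f_dtc_g * (f_gl_g * f_el_g + g_g * e_gaba_grc +
                                 ton_g * ton_e);
      float den = 1.0f + f_dtc_g * (f_gl_g + g_a + g_n + g_g + ton_g);
      v = num / den;
      if (v >= f_th_g) {
        spk_grc_cell.push_back(i + 1); spk_grc_t.push_back(t + dt);
        refg[i] = f_ref_g; v = f_re_g;
        fired.push_back(i);
      }
      vg[i] = v;
    }
    // propagate GrC spikes along ascending axons and parallel fibers
    for (int i : fired) {
      for (int e = aa_goc.off[i]; e < aa_goc.off[i + 1]; ++e)
        ring[(s + aa_goc.dstep[e]) % ring_n].push_back(
            Event{aa_goc.tgt[e], aa_goc.w[e], 3});
      for (int e = pf_goc.off[i]; e < pf_goc.off[i + 1]; ++e)
        ring[(s + pf_goc.dstep[e]) % ring_n].push_back(
            Event{pf_goc.tgt[e], pf_goc.w[e], 3});
    }

    // --- gap junctions (explicit, previous-step potentials) --------------
    std::fill(gapcur.begin(), gapcur.end(), 0.0f);
    for (int k = 0; k < n_gap; ++k) {
      float dij = (float)gap_g[k] * (vo_prev[gap_j[k] - 1] - vo_prev[gap_i[k] - 1]);
      gapcur[gap_i[k] - 1] += dij;
      gapcur[gap_j[k] - 1] -= dij;
    }
    vo_prev = vo;

    // --- Golgi cells -----------------------------------------------------
    for (int i = 0; i < n_goc; ++i) {
      mr[i] *= m_c1r; md[i] *= m_c1d;
      xr[i] *= x_c1r; xd[i] *= x_c1d;
      qr[i] *= q_c1r; qd[i] *= q_c1d;
      xe[i] *= e_dec;
      if (extra_on) {
        int nev = rng.rpois(e_lambda);
        if (nev) xe[i] += e_peak * nev;
      }
      wadapt[i] *= go_wdec;
      float v = vo[i];
      float g_e = md[i] - mr[i] + xd[i] - xr[i];
      float g_i = qd[i] - qr[i];
      float inum = f_gl_o * f_el_o + g_i * e_gaba_goc + xe[i] * e_rev_extra +
                   gapcur[i] - wadapt[i] + f_id_o;
      float gtot = f_gl_o + g_e + g_i + xe[i];
      float num = v + f_dtc_o * inum;
      float den = 1.0f + f_dtc_o * gtot;
      float vnew = num / den;
      // the depolarization-block shadow tracks the unreset equilibrium of
      // the synaptic + pacemaker drive (adaptation excluded: the block
      // stands in for sodium-channel inactivation under sustained drive)
      shadow[i] += shadow_c * ((inum + wadapt[i]) / gtot - shadow[i]);
      if (refo[i] > 0.0f) { refo[i] -= f_dt; vo[i] = f_re_o; continue; }
      if (vnew >= f_th_o) {
        if (shadow[i] < f_blk_o) {
          spk_goc_cell.push_back(i + 1); spk_goc_t.push_back(t + dt);
          refo[i] = f_ref_o; wadapt[i] += f_b_o;
          vnew = f_re_o;
          // spikelet: the action-potential waveform couples through the
          // junction as a voltage-time area (charge g * area into C)
          if (f_spklt_c > 0)
            for (size_t q = 0; q < gap_adj[i].size(); ++q) {
              int j = gap_adj[i][q].first;
              if (refo[j] <= 0.0f)
                vo[j] += f_spklt_c * gap_adj[i][q].second;
            }
          for (int e = goc_grc.off[i]; e < goc_grc.off[i + 1]; ++e)
            ring[(s + goc_grc.dstep[e]) % ring_n].push_back(
                Event{goc_grc.tgt[e], goc_grc.w[e], 1});
          for (int e = goc_goc.off[i]; e < goc_goc.off[i + 1]; ++e)
            ring[(s + goc_goc.dstep[e]) % ring_n].push_back(
                Event{goc_goc.tgt[e], goc_goc.w[e], 4});
        } else {
          vnew = f_th_o;  // depolarization block
        }
      }
      if (vnew > 200 || vnew < -200 || std::isnan(vnew))
        stop("numerical blow-up: |V| > 200 mV at GoC %d, t = %.2f ms", i + 1, t);
      vo[i] = vnew;
    }

    for (int k = 0; k < rec_g.size(); ++k) vrec_g(s, k) = vg[rec_g[k] - 1];
    for (int k = 0; k < rec_o.size(); ++k) vrec_o(s, k) = vo[rec_o[k] - 1];

    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

#ifdef GRANET_HAVE_FTZ
  _mm_setcsr(old_csr);
#endif
  return List::create(
      _["grc_cell"] = wrap(spk_grc_cell), _["grc_t"] = wrap(spk_grc_t),
      _["goc_cell"] = wrap(spk_goc_cell), _["goc_t"] = wrap(spk_goc_t),
      _["v_grc"] = vrec_g, _["v_goc"] = vrec_o);
}
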