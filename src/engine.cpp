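// Fast trial-stepping engine for the PROBE / MAX / FORGET / RL agents.
//
// The R package exposes every model operation as a plain R function and a
// pure-R engine composed from them (R/simulate.R); this file is a line-by-
// line transliteration of that engine used for large simulation studies and
// likelihood evaluation. Both engines draw variates from R's RNG in the
// same order, so seeded trajectories are identical.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double PROB_FLOOR = 1e-12;

struct Strategy {
  std::vector<double> sel;   // n_s * n_a
  std::vector<double> pred;  // n_s * n_a * n_o
  std::vector<double> ctx;   // n_c
};

struct TaskSetC {
  int id;
  int ltm_ix;  // -1 while unconfirmed
  std::vector<double> sel, pred, ctx;
  std::vector<double> pw;  // predictive effective-weight per (s, a) cell
  double lam, mu;
  int last_actor;
};

static int draw_categorical(const std::vector<double>& p) {
  double u = unif_rand();
  double cs = 0.0;
  for (size_t i = 0; i < p.size(); ++i) {
    cs += p[i];
    if (u < cs) return (int)i;
  }
  return (int)p.size() - 1;
}

static void policy(const double* q, int n_a, double beta, double eps,
                   std::vector<double>& out) {
  double mx = q[0];
  for (int a = 1; a < n_a; ++a) if (q[a] > mx) mx = q[a];
  double s = 0.0;
  for (int a = 0; a < n_a; ++a) { out[a] = std::exp(beta * (q[a] - mx)); s += out[a]; }
  for (int a = 0; a < n_a; ++a) out[a] = (1.0 - eps) * out[a] / s + eps / n_a;
}

// [[Rcpp::export]]
List cpp_agent_engine(IntegerVector stim, IntegerVector cue,
                      IntegerVector correct, int n_s, int n_a, int n_o,
                      int n_c, List params, int model_code,
                      bool predict_mode, IntegerVector resp_in,
                      IntegerVector out_in, double p_feedback) {
  const int T = stim.size();
  const bool is_probe = model_code == 0, is_max = model_code == 1;
  const bool is_forget = model_code == 2, is_rl = model_code == 3;

  IntegerVector resp(T), outc(T);
  NumericVector p_resp(T), p_corr(T);
  int n_created = 0;

  double beta = params["beta"], eps = params["epsilon"];
  double alpha_s = 0, alpha_p = 0, alpha_c = 0, tau = 0, delta = 0;
  double eta = 0, theta = 0, phi = 0, beta_actor = 0, omega = 0;
  int N = 1;
  bool weighted = true;
  alpha_s = params["alpha_s"];
  if (!is_rl) {
    alpha_p = params["alpha_p"];
    alpha_c = params["alpha_c"];
    tau = params["tau"];
    delta = params["delta"];
    N = params["n"];
  }
  double p0 = 1.0 / n_a, w0 = 2.0;
  if (params.containsElementNamed("pred_prior")) p0 = params["pred_prior"];
  if (params.containsElementNamed("pred_weight0")) w0 = params["pred_weight0"];
  if (is_probe || is_max) { eta = params["eta"]; theta = params["theta"]; }
  if (is_forget) {
    phi = params["phi"];
    beta_actor = params["beta_actor"];
    std::string lrn = as<std::string>(params["learning"]);
    weighted = lrn == "weighted";
  }
  if (is_rl) {
    omega = params["omega"];
    alpha_c = params["alpha_c"];
  }

  const double u_sel = 1.0 / n_a;
  const double u_ctx = n_c > 0 ? 1.0 / n_c : 0.0;
  // random-strategy outcome baseline: prior success probability of an
  // untried action (pred_prior, about 1/n_a under an injective mapping)
  std::vector<double> u_pred(n_o, (1.0 - p0) / (n_o - 1));
  u_pred[n_o - 1] = p0;
  std::vector<double> pol(n_a), polk(n_a);

  // ---------------- flat RL ----------------
  if (is_rl) {
    std::vector<double> q_sr(n_s * n_a, u_sel);
    int ncc = n_c > 0 ? n_c : 1;
    std::vector<double> q_scr((size_t)n_s * ncc * n_a, u_sel);
    std::vector<double> qmix(n_a);
    for (int t = 0; t < T; ++t) {
      int s = stim[t] - 1, cu = cue[t] - 1;
      for (int a = 0; a < n_a; ++a) {
        double q = q_sr[s * n_a + a];
        if (omega > 0 && cu >= 0)
          q = (1 - omega) * q + omega * q_scr[(s * ncc + cu) * n_a + a];
        qmix[a] = q;
      }
      policy(qmix.data(), n_a, beta, eps, pol);
      int a, o;
      if (predict_mode) { a = resp_in[t] - 1; o = out_in[t]; }
      else {
        a = draw_categorical(pol);
        double ppos = (a == correct[t] - 1) ? p_feedback : 1 - p_feedback;
        o = unif_rand() < ppos ? 1 : 0;
      }
      p_resp[t] = pol[a];
      p_corr[t] = pol[correct[t] - 1];
      resp[t] = a + 1; outc[t] = o;
      q_sr[s * n_a + a] += alpha_s * (o - q_sr[s * n_a + a]);
      if (omega > 0 && cu >= 0) {
        double& q = q_scr[(s * ncc + cu) * n_a + a];
        q += alpha_c * (o - q);
      }
    }
    return List::create(_["response"] = resp, _["outcome"] = outc,
                        _["p_response"] = p_resp, _["p_correct"] = p_corr);
  }

  // ---------------- task-set models ----------------
  std::vector<TaskSetC> sets;
  double lam0 = 1.0, mu0 = 1.0;
  int probe_ix = -1, actor_ix = -1, next_id = 1;
  std::vector<Strategy> ltm;
  bool seen[2] = {false, false};

  if (is_forget) {
    sets.resize(N);
    for (int k = 0; k < N; ++k) {
      sets[k].id = k + 1;
      sets[k].ltm_ix = -1;
      sets[k].sel.assign(n_s * n_a, u_sel);
      sets[k].pred.resize((size_t)n_s * n_a * n_o);
      for (size_t i = 0; i < (size_t)n_s * n_a; ++i)
        for (int o = 0; o < n_o; ++o) sets[k].pred[i * n_o + o] = u_pred[o];
      sets[k].pw.assign((size_t)n_s * n_a, w0);
      sets[k].ctx.assign(n_c, u_ctx);
      sets[k].lam = sets[k].mu = 1.0 / (N + 1);
      sets[k].last_actor = 0;
    }
    lam0 = mu0 = 1.0 / (N + 1);
  }

  std::vector<double> w(N + 1), lamv, muv;

  auto renorm_drop = [&](int ix) {
    // remove set ix, floor and renormalize both reliability vectors
    sets.erase(sets.begin() + ix);
    int m = (int)sets.size() + 1;
    std::vector<double> lam(m), mu(m);
    lam[0] = std::max(lam0, PROB_FLOOR);
    mu[0] = std::max(mu0, PROB_FLOOR);
    for (int i = 0; i < m - 1; ++i) {
      lam[i + 1] = std::max(sets[i].lam, PROB_FLOOR);
      mu[i + 1] = std::max(sets[i].mu, PROB_FLOOR);
    }
    double sl = 0, sm = 0;
    for (int i = 0; i < m; ++i) { sl += lam[i]; sm += mu[i]; }
    lam0 = lam[0] / sl; mu0 = mu[0] / sm;
    for (int i = 0; i < m - 1; ++i) {
      sets[i].lam = lam[i + 1] / sl;
      sets[i].mu = mu[i + 1] / sm;
    }
  };

  auto store_ltm = [&](TaskSetC& ts) {
    if (ts.ltm_ix < 0) {
      ltm.push_back(Strategy{ts.sel, ts.pred, ts.ctx});
      ts.ltm_ix = (int)ltm.size() - 1;
    } else {
      ltm[ts.ltm_ix].sel = ts.sel;
      ltm[ts.ltm_ix].pred = ts.pred;
      ltm[ts.ltm_ix].ctx = ts.ctx;
    }
  };

  auto evict_if_full = [&]() {
    if ((int)sets.size() <= N) return;
    int victim = 0;
    for (int i = 1; i < (int)sets.size(); ++i) {
      if (sets[i].last_actor < sets[victim].last_actor ||
          (sets[i].last_actor == sets[victim].last_actor &&
           sets[i].id < sets[victim].id))
        victim = i;
    }
    store_ltm(sets[victim]);
    if (actor_ix == victim) actor_ix = -1;
    else if (actor_ix > victim) actor_ix--;
    renorm_drop(victim);
  };

  auto make_probe = [&](int cu, int t) {
    TaskSetC ts;
    ts.id = next_id++;
    ts.ltm_ix = -1;
    ts.last_actor = t + 1;
    ts.lam = ts.mu = 0.0;
    ts.ctx.assign(n_c, u_ctx);
    size_t ns = (size_t)n_s * n_a, np = ns * n_o;
    ts.pw.assign(ns, w0);
    if (ltm.empty() || eta == 1.0) {
      ts.sel.assign(ns, u_sel);
      ts.pred.resize(np);
      for (size_t i = 0; i < ns; ++i)
        for (int o = 0; o < n_o; ++o) ts.pred[i * n_o + o] = u_pred[o];
    } else {
      std::vector<double> wk(ltm.size(), 1.0);
      if (cu >= 0) {
        double sw = 0;
        for (size_t k = 0; k < ltm.size(); ++k) { wk[k] = ltm[k].ctx[cu]; sw += wk[k]; }
        if (sw <= 0) wk.assign(ltm.size(), 1.0);
      }
      double sw = 0;
      for (double v : wk) sw += v;
      ts.sel.assign(ns, 0.0);
      ts.pred.assign(np, 0.0);
      for (size_t k = 0; k < ltm.size(); ++k) {
        double v = wk[k] / sw;
        for (size_t i = 0; i < ns; ++i) ts.sel[i] += v * ltm[k].sel[i];
        for (size_t i = 0; i < np; ++i) ts.pred[i] += v * ltm[k].pred[i];
      }
      for (size_t i = 0; i < ns; ++i) ts.sel[i] = (1 - eta) * ts.sel[i] + eta * u_sel;
      for (size_t i = 0; i < ns; ++i)
        for (int o = 0; o < n_o; ++o)
          ts.pred[i * n_o + o] = (1 - eta) * ts.pred[i * n_o + o] + eta * u_pred[o];
    }
    return ts;
  };

  for (int t = 0; t < T; ++t) {
    int s = stim[t] - 1, cu = cue[t] - 1;
    bool cue_changed = t > 0 && cue[t] > 0 && cue[t - 1] > 0 &&
      cue[t] != cue[t - 1];
    double tt = cue_changed ? tau + delta * (1 - tau) : tau;

    // ex-ante propagation + contextual reweighting
    int nt = (int)sets.size();
    if (nt == 0) {
      lam0 = 1.0;
    } else {
      int m = nt + 1;
      double off = tt / (m - 1);
      std::vector<double> mu(m), lam(m);
      mu[0] = mu0;
      for (int i = 0; i < nt; ++i) mu[i + 1] = sets[i].mu;
      for (int i = 0; i < m; ++i) {
        double acc = 0;
        for (int j = 0; j < m; ++j) acc += (i == j ? 1 - tt : off) * mu[j];
        lam[i] = acc;
      }
      if (cu >= 0) {
        lam[0] *= u_ctx;
        for (int i = 0; i < nt; ++i) lam[i + 1] *= sets[i].ctx[cu];
      }
      double sl = 0;
      for (int i = 0; i < m; ++i) { lam[i] = std::max(lam[i], PROB_FLOOR); sl += lam[i]; }
      lam0 = lam[0] / sl;
      for (int i = 0; i < nt; ++i) sets[i].lam = lam[i + 1] / sl;
    }

    if (is_forget) {
      // actor softmax over reliabilities; fixed collection, no creation
      double mx = sets[0].lam;
      for (int k = 1; k < N; ++k) if (sets[k].lam > mx) mx = sets[k].lam;
      double sw = 0;
      for (int k = 0; k < N; ++k) { w[k] = std::exp(beta_actor * (sets[k].lam - mx)); sw += w[k]; }
      for (int k = 0; k < N; ++k) w[k] /= sw;
      int a, o, actor = -1;
      if (predict_mode) {
        std::fill(pol.begin(), pol.end(), 0.0);
        for (int k = 0; k < N; ++k) {
          policy(&sets[k].sel[s * n_a], n_a, beta, eps, polk);
          for (int x = 0; x < n_a; ++x) pol[x] += w[k] * polk[x];
        }
        a = resp_in[t] - 1; o = out_in[t];
      } else {
        std::vector<double> wv(w.begin(), w.begin() + N);
        actor = N == 1 ? 0 : draw_categorical(wv);
        policy(&sets[actor].sel[s * n_a], n_a, beta, eps, pol);
        a = draw_categorical(pol);
        double ppos = (a == correct[t] - 1) ? p_feedback : 1 - p_feedback;
        o = unif_rand() < ppos ? 1 : 0;
      }
      p_resp[t] = pol[a];
      p_corr[t] = pol[correct[t] - 1];
      resp[t] = a + 1; outc[t] = o;
      if (actor >= 0) sets[actor].last_actor = t + 1;

      int oi = o;  // 0-based outcome index
      seen[oi] = true;
      double gamma0 = 1.0 / ((seen[0] ? 1 : 0) + (seen[1] ? 1 : 0));
      // ex-post
      {
        int m = N + 1;
        std::vector<double> mu(m);
        mu[0] = std::max(lam0 * gamma0, PROB_FLOOR);
        double sm = mu[0];
        for (int k = 0; k < N; ++k) {
          mu[k + 1] = std::max(sets[k].lam * sets[k].pred[((size_t)s * n_a + a) * n_o + oi], PROB_FLOOR);
          sm += mu[k + 1];
        }
        mu0 = mu[0] / sm;
        for (int k = 0; k < N; ++k) sets[k].mu = mu[k + 1] / sm;
      }
      // learning then decay
      for (int k = 0; k < N; ++k) {
        double step = weighted ? sets[k].mu : (k == actor ? 1.0 : 0.0);
        if (step > 0) {
          double& q = sets[k].sel[s * n_a + a];
          q += alpha_s * step * (o - q);
          size_t cell = (size_t)s * n_a + a;
          double wk = (1 - alpha_p) * sets[k].pw[cell] + step;
          for (int x = 0; x < n_o; ++x) {
            double& p = sets[k].pred[cell * n_o + x];
            p += step * ((x == oi ? 1.0 : 0.0) - p) / wk;
          }
          sets[k].pw[cell] = wk;
        }
      }
      for (int k = 0; k < N; ++k) {
        double phik = predict_mode ? phi * (1 - w[k]) : (k == actor ? 0.0 : phi);
        if (phik > 0) {
          for (double& v : sets[k].sel) v = (1 - phik) * v + phik * u_sel;
          for (size_t i = 0; i < (size_t)n_s * n_a; ++i)
            for (int x = 0; x < n_o; ++x) {
              double& v = sets[k].pred[i * n_o + x];
              v = (1 - phik) * v + phik * u_pred[x];
            }
          for (double& v : sets[k].pw) v = (1 - phik) * v + phik;
        }
      }
      if (cu >= 0) {
        for (int k = 0; k < N; ++k) {
          double& f = sets[k].ctx[cu];
          f += alpha_c * (sets[k].mu - f);
        }
      }
      continue;
    }

    // ----- PROBE / MAX control -----
    if (is_probe && probe_ix >= 0) {
      double lp = sets[probe_ix].lam;
      double mx_other = 0.0;
      int winner = -1;
      for (int i = 0; i < (int)sets.size(); ++i) {
        if (i != probe_ix && sets[i].lam > mx_other) { mx_other = sets[i].lam; winner = i; }
      }
      if (lp > 0.5) {  // confirm
        store_ltm(sets[probe_ix]);
        actor_ix = probe_ix;
        probe_ix = -1;
        evict_if_full();
      } else if (winner >= 0 && mx_other > 0.5) {  // discard
        int drop = probe_ix;
        probe_ix = -1;
        actor_ix = winner > drop ? winner - 1 : winner;
        renorm_drop(drop);
      }
    }

    // actor selection / creation
    bool create = false;
    if (is_max) {
      int best = -1;
      double mx = -1;
      for (int i = 0; i < (int)sets.size(); ++i)
        if (sets[i].lam > mx) { mx = sets[i].lam; best = i; }
      if (best >= 0 && mx >= lam0) actor_ix = best;
      else create = true;
    } else {
      int above = -1;
      for (int i = 0; i < (int)sets.size(); ++i)
        if (sets[i].lam > 0.5) { above = i; break; }
      if (above >= 0) actor_ix = above;
      else if (probe_ix >= 0) actor_ix = probe_ix;
      else create = true;
    }

    if (create) {
      TaskSetC ts = make_probe(cu, t);
      ++n_created;
      if (is_max) {
        ts.lam = lam0;
        ts.mu = mu0;
        sets.push_back(ts);
        double sl = lam0, sm = mu0;
        for (auto& st : sets) { sl += st.lam; sm += st.mu; }
        lam0 /= sl; mu0 /= sm;
        for (auto& st : sets) { st.lam /= sl; st.mu /= sm; }
        actor_ix = (int)sets.size() - 1;
        store_ltm(sets[actor_ix]);
        evict_if_full();
        if (actor_ix < 0) actor_ix = (int)sets.size() - 1;  // defensive
      } else {
        // maximum-entropy prior over the other monitored sets' lam
        double h = 0.0, sl = 0.0;
        int npos = 0;
        for (auto& st : sets) if (st.lam > 0) { sl += st.lam; ++npos; }
        if (npos > 1) {
          for (auto& st : sets) if (st.lam > 0) {
            double p = st.lam / sl;
            h -= p * std::log(p);
          }
        }
        double lam_prior = 1.0 / (2.0 + std::exp(h));
        lam_prior = (1 - theta) * lam_prior + theta * 0.5;
        double scale = 1 - lam_prior;
        lam0 *= scale;
        for (auto& st : sets) st.lam *= scale;
        ts.lam = lam_prior;
        sets.push_back(ts);
        probe_ix = actor_ix = (int)sets.size() - 1;
      }
    }
    sets[actor_ix].last_actor = t + 1;

    policy(&sets[actor_ix].sel[s * n_a], n_a, beta, eps, pol);
    int a, o;
    if (predict_mode) { a = resp_in[t] - 1; o = out_in[t]; }
    else {
      a = draw_categorical(pol);
      double ppos = (a == correct[t] - 1) ? p_feedback : 1 - p_feedback;
      o = unif_rand() < ppos ? 1 : 0;
    }
    p_resp[t] = pol[a];
    p_corr[t] = pol[correct[t] - 1];
    resp[t] = a + 1; outc[t] = o;

    int oi = o;
    seen[oi] = true;
    double gamma0 = 1.0 / ((seen[0] ? 1 : 0) + (seen[1] ? 1 : 0));
    {
      int nt2 = (int)sets.size(), m = nt2 + 1;
      std::vector<double> mu(m);
      mu[0] = std::max(lam0 * gamma0, PROB_FLOOR);
      double sm = mu[0];
      for (int i = 0; i < nt2; ++i) {
        mu[i + 1] = std::max(sets[i].lam * sets[i].pred[((size_t)s * n_a + a) * n_o + oi], PROB_FLOOR);
        sm += mu[i + 1];
      }
      mu0 = mu[0] / sm;
      for (int i = 0; i < nt2; ++i) sets[i].mu = mu[i + 1] / sm;
    }
    // actor-only learning
    {
      double& q = sets[actor_ix].sel[s * n_a + a];
      q += alpha_s * (o - q);
      size_t cell = (size_t)s * n_a + a;
      double wk = (1 - alpha_p) * sets[actor_ix].pw[cell] + 1.0;
      for (int x = 0; x < n_o; ++x) {
        double& p = sets[actor_ix].pred[cell * n_o + x];
        p += ((x == oi ? 1.0 : 0.0) - p) / wk;
      }
      sets[actor_ix].pw[cell] = wk;
    }
    if (cu >= 0) {
      for (auto& st : sets) {
        double& f = st.ctx[cu];
        f += alpha_c * (st.mu - f);
      }
    }
  }

  return List::create(_["response"] = resp, _["outcome"] = outc,
                      _["p_response"] = p_resp, _["p_correct"] = p_corr,
                      _["n_created"] = n_created);
}
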