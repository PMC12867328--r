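#include <Rcpp.h>
#include <cmath>
#include <vector>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
using namespace Rcpp;

// The exponentially decaying ADAM moments underflow into denormal floats on
// long-idle coordinates, which cripples throughput on x86; flush them to zero
// (they are ~1e-300 and far below any quantity of interest).
static void set_flush_denormals() {
#ifdef __SSE2__
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}

// Cell label codes shared with the R side (see R/world.R):
// 0 EMPTY, 1 BARRIER, 2 WALL_N, 3 WALL_E, 4 WALL_S, 5 WALL_W,
// 6 OUTSIDE (view only), 7 OCCLUDED (view only), 8 REWARD (view only, optional).
static inline bool blocks_sight(int code) { return code >= 1 && code <= 5; }

// Direction conventions: N=0 (0,+1), E=1 (+1,0), S=2 (0,-1), W=3 (-1,0).
static const int DX[4] = {0, 1, 0, -1};
static const int DY[4] = {1, 0, -1, 0};

// Supercover traversal of the segment between cell centres. A cell grazed
// exactly at a corner is skipped (it does not block); when the segment passes
// through a lattice corner the traversal steps diagonally. Comparisons between
// boundary-crossing times are exact integer cross-products, so corner events
// are detected without floating point.
static bool los_blocked_impl(const IntegerMatrix& cells, int x0, int y0,
                             int x1, int y1) {
  int dx = x1 - x0, dy = y1 - y0;
  int adx = dx < 0 ? -dx : dx, ady = dy < 0 ? -dy : dy;
  if (adx + ady <= 1) return false; // same or adjacent cell: nothing in between
  int sx = (dx > 0) - (dx < 0), sy = (dy > 0) - (dy < 0);
  int cx = x0, cy = y0;
  int i = 1, j = 1; // index of next vertical / horizontal boundary crossing
  while (true) {
    bool hasx = i <= adx, hasy = j <= ady;
    if (!hasx && !hasy) break;
    // t_x = (2i-1)/(2*adx), t_y = (2j-1)/(2*ady); compare cross-multiplied.
    long long tx = hasx ? (long long)(2 * i - 1) * ady : 0;
    long long ty = hasy ? (long long)(2 * j - 1) * adx : 0;
    if (hasx && (!hasy || tx < ty)) {
      cx += sx; ++i;
    } else if (hasy && (!hasx || ty < tx)) {
      cy += sy; ++j;
    } else {
      cx += sx; cy += sy; ++i; ++j; // exact corner: diagonal step
    }
    if (cx == x1 && cy == y1) break;
    if (blocks_sight(cells(cx, cy))) return true;
  }
  return false;
}

// [[Rcpp::export]]
bool los_blocked_cpp(IntegerMatrix cells, int x0, int y0, int x1, int y1) {
  if (x0 < 0 || y0 < 0 || x1 < 0 || y1 < 0 || x0 >= cells.nrow() ||
      x1 >= cells.nrow() || y0 >= cells.ncol() || y1 >= cells.ncol())
    stop("line_of_sight endpoints must lie inside the padded grid");
  return los_blocked_impl(cells, x0, y0, x1, y1);
}

// Occluded egocentric window: rows r = 0..H in front of the agent (row 0 is the
// agent's own row), columns c = -H..H lateral (left negative), aligned with the
// agent's heading. Cells beyond the padded grid are OUTSIDE; cells whose line
// of sight from the agent crosses a blocking cell are OCCLUDED.
// [[Rcpp::export]]
IntegerMatrix ego_view_cpp(IntegerMatrix cells, int x, int y, int d, int H,
                           int reward_x = -1, int reward_y = -1,
                           bool render_reward = false) {
  if (H < 1) stop("horizon H must be >= 1");
  if (d < 0 || d > 3) stop("invalid direction");
  int W = cells.nrow(), Hn = cells.ncol();
  if (x < 0 || y < 0 || x >= W || y >= Hn) stop("agent outside world");
  int fr = d, rt = (d + 1) & 3; // forward and rightward directions
  IntegerMatrix out(H + 1, 2 * H + 1);
  for (int r = 0; r <= H; ++r) {
    for (int c = -H; c <= H; ++c) {
      int px = x + r * DX[fr] + c * DX[rt];
      int py = y + r * DY[fr] + c * DY[rt];
      int lab;
      if (px < 0 || py < 0 || px >= W || py >= Hn) {
        lab = 6; // OUTSIDE
      } else if ((r != 0 || c != 0) && los_blocked_impl(cells, x, y, px, py)) {
        lab = 7; // OCCLUDED
      } else if (r == 0 && c == 0) {
        lab = 0; // the agent never occludes itself
      } else {
        lab = cells(px, py);
        if (render_reward && px == reward_x && py == reward_y) lab = 8;
      }
      out(r, c + H) = lab;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Episode runner. All SR tables are stored with columns indexed by the source
// state, i.e. Ms(target, source), so that the SR "row" of a state is a
// contiguous matrix column. Weight layout: allocentric block [0, N_A) then
// egocentric block [N_A, N_A + N_E). Tables and optimizer state are modified
// in place. Randomness comes from R's RNG so that set.seed() governs runs and
// pure-R reference implementations can reproduce draws exactly.
// ---------------------------------------------------------------------------

// Lesion variant codes (see R/agent.R): 0 FULL, 1 ALLO_ONLY, 2 EGO_ONLY,
// 3 EGO_QLEARNER, 4 NO_ADAM.

struct StepCtx {
  int NA_, NE_;
  bool use_allo, use_ego_sr, use_ego_onehot;
  double *MsA, *MsE;
  std::vector<double*> MA, ME; // per-action tables
  double *w, *m, *v;
};

static double q_one(const StepCtx& C, int cA, int d, int sE, int a) {
  double q = 0.0;
  if (C.use_allo) {
    int aA = (d + a) & 3; // R_d^{-1}(a): allocentric action for ego action a
    const double* col = C.MA[aA] + (size_t)cA * C.NA_;
    const double* wv = C.w;
    for (int i = 0; i < C.NA_; ++i) q += wv[i] * col[i];
  }
  if (C.use_ego_sr) {
    const double* col = C.ME[a] + (size_t)sE * C.NE_;
    const double* wv = C.w + C.NA_;
    for (int i = 0; i < C.NE_; ++i) q += wv[i] * col[i];
  } else if (C.use_ego_onehot) {
    q += C.w[C.NA_ + sE];
  }
  return q;
}

// TD update of one state-state SR column and the matching state-action column.
// Targets follow the next-state-indicator convention; on terminal transitions
// the bootstrap term is dropped. The state-action table bootstraps off the
// state-state table after the latter's concurrent update.
static void sr_update_pair(double* Ms, double* Ma, int n, int s, int s2,
                           double alpha, double gamma, bool done,
                           std::vector<double>& buf) {
  double gg = done ? 0.0 : gamma;
  const double* c2 = Ms + (size_t)s2 * n;
  for (int i = 0; i < n; ++i) buf[i] = gg * c2[i];
  buf[s2] += 1.0;
  double* cs = Ms + (size_t)s * n;
  for (int i = 0; i < n; ++i) cs[i] += alpha * (buf[i] - cs[i]);
  // state-action target re-reads the (possibly just-updated) column s2
  const double* c2b = Ms + (size_t)s2 * n;
  for (int i = 0; i < n; ++i) buf[i] = gg * c2b[i];
  buf[s2] += 1.0;
  double* ca = Ma + (size_t)s * n;
  for (int i = 0; i < n; ++i) ca[i] += alpha * (buf[i] - ca[i]);
}

// [[Rcpp::export]]
List run_episodes_cpp(int n_episodes, IntegerMatrix fwd_next,
                      IntegerVector view_idx, int reward_idx,
                      IntegerVector start_cells, LogicalMatrix region_masks,
                      NumericMatrix Ms_A, List MA_list, NumericMatrix Ms_E,
                      List ME_list, NumericVector w, NumericVector m,
                      NumericVector v, NumericVector t_step, List par,
                      bool learn = true, bool record_traj = false) {
  const int NA_ = fwd_next.nrow();
  const int variant = as<int>(par["variant"]);
  const bool use_allo = variant != 2;
  const bool use_ego_sr = (variant == 0 || variant == 2 || variant == 4);
  const bool use_ego_onehot = variant == 3;
  const bool use_ego = use_ego_sr || use_ego_onehot;
  const int NE_ = (int)w.size() - NA_;
  if (use_ego_sr && Ms_E.nrow() != NE_) stop("egocentric SR size mismatch");
  const double gammaA = as<double>(par["gamma_a"]);
  const double gammaE = as<double>(par["gamma_e"]);
  const double gammaQ = as<double>(par["gamma_q"]);
  const double alphaA = as<double>(par["alpha_a"]);
  const double alphaE = as<double>(par["alpha_e"]);
  const double eta = as<double>(par["eta"]);
  const double beta1 = as<double>(par["beta1"]);
  const double beta2 = as<double>(par["beta2"]);
  const double epsAdam = as<double>(par["eps_adam"]);
  const double epsExpl = as<double>(par["epsilon"]);
  const double tau = as<double>(par["tau"]);
  const int cap = as<int>(par["step_cap"]);
  const bool noSqrt = as<bool>(par["adam_no_sqrt"]);

  if ((int)w.size() != NA_ + NE_) stop("weight length mismatch");
  if (use_ego && (int)view_idx.size() != NA_ * 4)
    stop("view index table mismatch");

  StepCtx C;
  C.NA_ = NA_; C.NE_ = NE_;
  C.use_allo = use_allo; C.use_ego_sr = use_ego_sr;
  C.use_ego_onehot = use_ego_onehot;
  C.MsA = Ms_A.begin(); C.MsE = Ms_E.begin();
  C.w = w.begin(); C.m = m.begin(); C.v = v.begin();
  for (int a = 0; a < 4; ++a) {
    C.MA.push_back(NumericMatrix(MA_list[a]).begin());
    if (use_ego_sr) C.ME.push_back(NumericMatrix(ME_list[a]).begin());
    else C.ME.push_back(nullptr);
  }

  const int nstart = start_cells.size();
  const int nreg = region_masks.ncol();
  IntegerVector counted(n_episodes), primitive(n_episodes);
  LogicalVector truncated(n_episodes);
  IntegerMatrix region_counts(n_episodes, nreg);
  List trajs(record_traj ? n_episodes : 0);

  std::vector<double> bufA(NA_), bufE(NE_ > 0 ? NE_ : 1);
  std::vector<int> traj_c, traj_d, traj_a;

  set_flush_denormals();
  RNGScope rng;
  for (int ep = 0; ep < n_episodes; ++ep) {
    int cA = start_cells[(int)std::min((double)nstart - 1.0,
                                       std::floor(unif_rand() * nstart))];
    int d = (int)std::min(3.0, std::floor(unif_rand() * 4));
    int n_counted = 0, n_prim = 0;
    bool done = false;
    if (record_traj) { traj_c.clear(); traj_d.clear(); traj_a.clear(); }

    while (n_prim < cap && !done) {
      int sE = use_ego ? view_idx[cA * 4 + d] : 0;
      double q[4];
      for (int a = 0; a < 4; ++a) q[a] = q_one(C, cA, d, sE, a);
      // epsilon-softmax: one uniform for the branch, one for the draw
      int act;
      double u1 = unif_rand();
      if (u1 < epsExpl) {
        act = (int)std::min(3.0, std::floor(unif_rand() * 4));
      } else {
        double mx = q[0];
        for (int a = 1; a < 4; ++a) if (q[a] > mx) mx = q[a];
        double p[4], Z = 0.0;
        for (int a = 0; a < 4; ++a) { p[a] = std::exp((q[a] - mx) / tau); Z += p[a]; }
        double u2 = unif_rand() * Z, acc = 0.0;
        act = 3;
        for (int a = 0; a < 4; ++a) { acc += p[a]; if (u2 <= acc) { act = a; break; } }
      }
      // environment step
      int cA2, d2;
      if (act == 0) { cA2 = fwd_next(cA, d); d2 = d; }
      else { cA2 = cA; d2 = (d + act) & 3; }
      done = (cA2 == reward_idx);
      double r = done ? 1.0 : 0.0;
      int aA = (d + act) & 3;
      int sE2 = use_ego ? view_idx[cA2 * 4 + d2] : 0;

      if (record_traj) { traj_c.push_back(cA); traj_d.push_back(d); traj_a.push_back(act); }

      if (learn) {
        if (use_allo)
          sr_update_pair(C.MsA, C.MA[aA], NA_, cA, cA2, alphaA, gammaA, done, bufA);
        if (use_ego_sr)
          sr_update_pair(C.MsE, C.ME[act], NE_, sE, sE2, alphaE, gammaE, done, bufE);

        // semi-gradient Q-learning step on the post-SR-update features
        double qsa = q_one(C, cA, d, sE, act);
        double qmax = 0.0;
        if (!done) {
          qmax = q_one(C, cA2, d2, sE2, 0);
          for (int a = 1; a < 4; ++a) {
            double qq = q_one(C, cA2, d2, sE2, a);
            if (qq > qmax) qmax = qq;
          }
        }
        double delta = r + (done ? 0.0 : gammaQ * qmax) - qsa;

        const double* featA =
            use_allo ? C.MA[aA] + (size_t)cA * NA_ : nullptr;
        const double* featE =
            use_ego_sr ? C.ME[act] + (size_t)sE * NE_ : nullptr;
        if (variant == 4) { // plain semi-gradient step, no optimizer state
          t_step[0] += 1.0;
          if (featA) for (int i = 0; i < NA_; ++i) w[i] += eta * delta * featA[i];
          if (featE) for (int i = 0; i < NE_; ++i) w[NA_ + i] += eta * delta * featE[i];
        } else {
          t_step[0] += 1.0;
          double bc1 = 1.0 - std::pow(beta1, t_step[0]);
          double bc2 = 1.0 - std::pow(beta2, t_step[0]);
          int ntot = NA_ + NE_;
          for (int i = 0; i < ntot; ++i) {
            double gi = 0.0;
            if (i < NA_) { if (featA) gi = delta * featA[i]; }
            else if (featE) gi = delta * featE[i - NA_];
            else if (use_ego_onehot && i - NA_ == sE) gi = delta;
            m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
            v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
            double mhat = m[i] / bc1, vhat = v[i] / bc2;
            w[i] += noSqrt ? (vhat == 0.0 ? 0.0 : eta * mhat / vhat)
                           : eta * mhat / (std::sqrt(vhat) + epsAdam);
          }
        }
      }

      ++n_prim;
      if (act == 0) ++n_counted;
      for (int rg = 0; rg < nreg; ++rg)
        if (region_masks(cA2, rg))
          region_counts(ep, rg) = region_counts(ep, rg) + 1;
      cA = cA2; d = d2;
    }

    counted[ep] = n_counted;
    primitive[ep] = n_prim;
    truncated[ep] = !done;
    if (record_traj) {
      int L = traj_c.size();
      IntegerMatrix tm(L + 1, 3);
      for (int k = 0; k < L; ++k) {
        tm(k, 0) = traj_c[k]; tm(k, 1) = traj_d[k]; tm(k, 2) = traj_a[k];
      }
      tm(L, 0) = cA; tm(L, 1) = d; tm(L, 2) = -1;
      trajs[ep] = tm;
    }
  }

  return List::create(_["counted"] = counted, _["primitive"] = primitive,
                      _["truncated"] = truncated,
                      _["region_counts"] = region_counts,
                      _["trajectories"] = record_traj ? (SEXP)trajs : R_NilValue);
}
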