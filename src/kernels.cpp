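#include <Rcpp.h>
using namespace Rcpp;

// Segment endpoints never move in this engine: a microtubule is a static
// polyline plus two moving arclength offsets (treadmilling minus end,
// growing/shrinking plus end). A crossing between a tip ray and a stored
// segment is therefore a fixed point in space; only the timing decides
// whether it is a real collision. Both kernels predict lattice coverage at
// the tip's arrival time from the current per-microtubule kinematic state
// (positions at t0, state-dependent end speeds); the R side re-validates at
// event execution time, so a stale prediction can only cost a rescan, never
// a wrong collision.

static const double EPS_PAR = 1e-12;   // parallel-line cutoff on the cross product
static const double EPS_GEO = 1e-9;    // geometric slack, micrometres

// Straight-path pieces on the periodic rectangle: fast path for the piece
// walk used by every tip scan and meta-trajectory on planar domains.
// Returns a matrix with columns (face, px, py, dx, dy, len) plus the
// terminal point in the last row convention of the R-level walker.
// [[Rcpp::export]]
NumericMatrix cpp_rect_pieces(double L, double H, double x, double y,
                              double dx, double dy, double s, int maxp) {
  std::vector<double> rows;
  int np = 0;
  double rem = s;
  while (rem > 0 && np < maxp) {
    double t = rem;
    int wall = 0;
    if (dx < 0) { double tt = -x / dx; if (tt < t) { t = tt; wall = 1; } }
    if (dx > 0) { double tt = (L - x) / dx; if (tt < t) { t = tt; wall = 2; } }
    if (dy < 0) { double tt = -y / dy; if (tt < t) { t = tt; wall = 3; } }
    if (dy > 0) { double tt = (H - y) / dy; if (tt < t) { t = tt; wall = 4; } }
    if (t < 0) t = 0;
    rows.push_back(x); rows.push_back(y); rows.push_back(t);
    np++;
    rem -= t;
    x += t * dx; y += t * dy;
    if (wall == 0) break;
    if (wall == 1) x += L; else if (wall == 2) x -= L;
    else if (wall == 3) y += H; else y -= H;
    if (rem <= 1e-12) {
      // ended exactly on the seam: wrapped terminal point, no extra piece
      break;
    }
  }
  NumericMatrix out(np, 8);
  for (int i = 0; i < np; i++) {
    out(i, 0) = 1.0;
    out(i, 1) = rows[3 * i]; out(i, 2) = rows[3 * i + 1];
    out(i, 3) = dx; out(i, 4) = dy;
    out(i, 5) = rows[3 * i + 2];
    out(i, 6) = x; out(i, 7) = y;  // terminal point (same in every row)
  }
  return out;
}

// ---- event queue: binary min-heap on (time, type, id) --------------------

struct HeapEv {
  double t, aux;
  int ty, id, vr;
};

struct EventHeap {
  std::vector<HeapEv> v;
  static bool lt(const HeapEv &a, const HeapEv &b) {
    if (a.t != b.t) return a.t < b.t;
    if (a.ty != b.ty) return a.ty < b.ty;
    return a.id < b.id;
  }
};

// [[Rcpp::export]]
SEXP cpp_heap_new() {
  XPtr<EventHeap> p(new EventHeap(), true);
  return p;
}

// [[Rcpp::export]]
void cpp_heap_push(SEXP hp, double t, int ty, int id, int vr, double aux) {
  XPtr<EventHeap> p(hp);
  std::vector<HeapEv> &v = p->v;
  HeapEv e; e.t = t; e.ty = ty; e.id = id; e.vr = vr; e.aux = aux;
  v.push_back(e);
  size_t i = v.size() - 1;
  while (i > 0) {
    size_t par = (i - 1) / 2;
    if (EventHeap::lt(v[i], v[par])) { std::swap(v[i], v[par]); i = par; }
    else break;
  }
}

// returns (t, ty, id, vr, aux) or an empty vector when the queue is empty
// [[Rcpp::export]]
NumericVector cpp_heap_pop(SEXP hp) {
  XPtr<EventHeap> p(hp);
  std::vector<HeapEv> &v = p->v;
  if (v.empty()) return NumericVector(0);
  HeapEv top = v[0];
  v[0] = v.back();
  v.pop_back();
  size_t i = 0, n = v.size();
  while (true) {
    size_t l = 2 * i + 1, r = l + 1, c = i;
    if (l < n && EventHeap::lt(v[l], v[c])) c = l;
    if (r < n && EventHeap::lt(v[r], v[c])) c = r;
    if (c == i) break;
    std::swap(v[i], v[c]);
    i = c;
  }
  return NumericVector::create(top.t, (double)top.ty, (double)top.id,
                               (double)top.vr, top.aux);
}

// First hit of one tip-path piece (ray of length plen, offset off from the
// tip) against candidate segment rows. v_tip <= 0 means "evaluate coverage
// at t_now" (used for meta-trajectories). Ties within EPS_GEO go to the
// lowest microtubule id (bundle convention). Returns (dist, row, sG) or
// dist = -1 if no hit.
// [[Rcpp::export]]
NumericVector cpp_best_hit(double px, double py, double dx, double dy,
                           double plen, double off, double min_dist,
                           IntegerVector cand,
                           NumericVector s_px, NumericVector s_py,
                           NumericVector s_dx, NumericVector s_dy,
                           NumericVector s_s0, NumericVector s_send,
                           IntegerVector s_mt, LogicalVector s_alive,
                           NumericVector m_t0, NumericVector m_plus0,
                           NumericVector m_minus0, IntegerVector m_state,
                           LogicalVector m_alive,
                           double vp, double vm, double vt,
                           double t_now, double v_tip,
                           int self_mt, int excl_row) {
  double best = R_PosInf;
  int best_row = 0, best_mt = 0;
  double best_sG = 0.0;
  int n = cand.size();
  for (int k = 0; k < n; k++) {
    int r = cand[k] - 1;
    if (r + 1 == excl_row) continue;
    if (!s_alive[r]) continue;
    int mt = s_mt[r] - 1;
    if (!m_alive[mt]) continue;
    double den = dx * s_dy[r] - dy * s_dx[r];
    if (den < EPS_PAR && den > -EPS_PAR) continue;
    double qx = s_px[r] - px, qy = s_py[r] - py;
    double t_ray = (qx * s_dy[r] - qy * s_dx[r]) / den;
    if (t_ray < -1e-12 || t_ray > plen + 1e-12) continue;
    double dist = off + t_ray;
    if (dist <= min_dist) continue;
    if (dist > best + EPS_GEO) continue;
    double s_seg = (qx * dy - qy * dx) / den;
    if (s_seg < -EPS_GEO) continue;
    double sG = s_s0[r] + s_seg;
    if (sG > s_send[r] + EPS_GEO) continue;
    double t_arr = (v_tip > 0.0) ? t_now + dist / v_tip : t_now;
    double dtm = t_arr - m_t0[mt];
    double minus_p = m_minus0[mt] + dtm * vt;
    if (sG < minus_p - EPS_GEO) continue;
    double plus_p = m_plus0[mt] + dtm * (m_state[mt] == 1 ? vp : -vm);
    if (sG > plus_p + EPS_GEO) continue;
    if (dist < best - EPS_GEO ||
        (dist < best + EPS_GEO && (best_row == 0 || s_mt[r] < best_mt))) {
      if (dist < best) best = dist;
      best_row = r + 1;
      best_mt = s_mt[r];
      best_sG = sG;
    }
  }
  if (best_row == 0) return NumericVector::create(-1.0, 0.0, 0.0);
  return NumericVector::create(best, (double)best_row, best_sG);
}

// Crossings of a newly created (or re-extended) lattice ray with the stored
// future paths of all growing tips. Returns, per affected tip, the earliest
// arrival time at a crossing that the new lattice is predicted to cover.
// [[Rcpp::export]]
List cpp_seg_vs_paths(int g_face, double gx, double gy,
                      double gdx, double gdy,
                      double g_s0, double g_send, int g_mt,
                      LogicalVector tp_used, IntegerVector tp_mt,
                      IntegerVector tp_face,
                      NumericVector tp_px, NumericVector tp_py,
                      NumericVector tp_dx, NumericVector tp_dy,
                      NumericVector tp_s0, NumericVector tp_len,
                      NumericVector m_t0, NumericVector m_plus0,
                      NumericVector m_minus0, IntegerVector m_state,
                      LogicalVector m_alive,
                      double vp, double vm, double vt, double t_now) {
  std::vector<int> tips;
  std::vector<double> times, sGs, dists;
  int n = tp_used.size();
  for (int r = 0; r < n; r++) {
    if (!tp_used[r]) continue;
    if (tp_face[r] != g_face) continue;
    int tip = tp_mt[r] - 1;
    if (tip + 1 == g_mt) continue;
    if (!m_alive[tip] || m_state[tip] != 1) continue;
    double den = tp_dx[r] * gdy - tp_dy[r] * gdx;
    if (den < EPS_PAR && den > -EPS_PAR) continue;
    double qx = gx - tp_px[r], qy = gy - tp_py[r];
    double t_piece = (qx * gdy - qy * gdx) / den;
    if (t_piece < -1e-12 || t_piece > tp_len[r] + 1e-12) continue;
    double s_g = (qx * tp_dy[r] - qy * tp_dx[r]) / den;
    if (s_g < -EPS_GEO) continue;
    double sG = g_s0 + s_g;
    if (sG > g_send + EPS_GEO) continue;
    double s_hit_abs = tp_s0[r] + t_piece;
    double plus_now = m_plus0[tip] + (t_now - m_t0[tip]) * vp;
    if (s_hit_abs <= plus_now + EPS_GEO) continue;
    double t_arr = m_t0[tip] + (s_hit_abs - m_plus0[tip]) / vp;
    // predicted coverage of the new lattice at the tip's arrival
    int gm = g_mt - 1;
    double dtm = t_arr - m_t0[gm];
    double minus_p = m_minus0[gm] + dtm * vt;
    if (sG < minus_p - EPS_GEO) continue;
    double plus_p = m_plus0[gm] + dtm * (m_state[gm] == 1 ? vp : -vm);
    if (sG > plus_p + EPS_GEO) continue;
    tips.push_back(tip + 1);
    times.push_back(t_arr);
    sGs.push_back(sG);
    dists.push_back(s_hit_abs);
  }
  return List::create(_["tip"] = wrap(tips), _["time"] = wrap(times),
                      _["sG"] = wrap(sGs), _["dist"] = wrap(dists));
}
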