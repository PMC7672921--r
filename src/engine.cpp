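// Search engine: cached per-cluster inverse-correlation products and
// rank-k Woodbury evaluation of candidate design changes. Committed
// changes rebuild the affected cluster from scratch (cheap at m <= a few
// hundred), so the cache never drifts.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

struct Scen {
  int K, M, degree, p;
  double rho, tau;
};

static Scen scen_from_list(List s) {
  Scen sc;
  sc.K = as<int>(s["K"]);
  sc.M = as<int>(s["M"]);
  sc.degree = as<int>(s["degree"]);
  sc.rho = as<double>(s["rho"]);
  sc.tau = as<double>(s["tau"]);
  sc.p = sc.degree + 2;
  return sc;
}

// shifted Legendre time columns (an orthogonal reparameterization of the
// raw power basis; the treatment variance is basis-invariant)
static arma::mat basis_mat(const arma::vec& t, int degree) {
  const int m = t.n_elem;
  arma::mat B(m, degree + 1);
  arma::vec x = 2.0 * t - 1.0;
  B.col(0).ones();
  if (degree >= 1) B.col(1) = x;
  for (int n = 1; n < degree; ++n)
    B.col(n + 1) = ((2.0 * n + 1.0) * (x % B.col(n)) - n * B.col(n - 1)) /
                   (n + 1.0);
  return B;
}

struct Cluster {
  int c;                       // crossover slot, 1..M+1
  std::vector<int> slots;      // recruited slots, ascending, 1-based
  arma::vec times;
  arma::mat Z, Rinv, G, W;
  arma::vec u;                 // diag(Rinv)

  int m() const { return (int)slots.size(); }
  int idx_of(int slot) const {
    auto it = std::lower_bound(slots.begin(), slots.end(), slot);
    if (it == slots.end() || *it != slot) return -1;
    return (int)(it - slots.begin());
  }
};

struct Engine {
  Scen sc;
  std::vector<Cluster> cl;
  arma::mat Wtot, Winv;
  double cur_var;
  bool valid;

  int mirror(int k) const { return sc.K - 1 - k; }            // 0-based
  int mirror_slot(int s) const { return sc.M + 1 - s; }        // 1-based

  int n_total() const {
    int n = 0;
    for (const auto& C : cl) n += C.m();
    return n;
  }

  double zlast(const Cluster& C, int slot) const {
    return (slot >= C.c) ? 1.0 : 0.0;
  }

  arma::rowvec zrow(const Cluster& C, int slot) const {
    arma::vec t(1);
    t[0] = (double)slot / sc.M;
    arma::rowvec z(sc.p);
    z.cols(0, sc.degree) = basis_mat(t, sc.degree);
    z[sc.p - 1] = zlast(C, slot);
    return z;
  }

  void rebuild_cluster(int k) {
    Cluster& C = cl[k];
    const int m = C.m();
    const int p = sc.p;
    if (m == 0) {
      C.times.reset();
      C.Z.set_size(0, p);
      C.Rinv.reset();
      C.G.set_size(0, p);
      C.W.zeros(p, p);
      C.u.reset();
      return;
    }
    C.times.set_size(m);
    for (int i = 0; i < m; ++i) C.times[i] = (double)C.slots[i] / sc.M;
    C.Z.set_size(m, p);
    C.Z.cols(0, sc.degree) = basis_mat(C.times, sc.degree);
    for (int i = 0; i < m; ++i) C.Z(i, p - 1) = zlast(C, C.slots[i]);
    arma::mat R(m, m);
    for (int i = 0; i < m; ++i) {
      R(i, i) = 1.0;
      for (int j = i + 1; j < m; ++j) {
        double r = sc.rho * std::pow(sc.tau, std::abs(C.times[i] - C.times[j]));
        R(i, j) = r;
        R(j, i) = r;
      }
    }
    C.Rinv = arma::inv_sympd(R);
    C.G = C.Rinv * C.Z;
    C.W = C.Z.t() * C.G;
    C.u = C.Rinv.diag();
  }

  void init(const Scen& s, IntegerVector crossover, IntegerMatrix recruit) {
    sc = s;
    cl.assign(sc.K, Cluster());
    for (int k = 0; k < sc.K; ++k) {
      cl[k].c = crossover[k];
      for (int j = 0; j < sc.M; ++j)
        if (recruit(k, j) == 1) cl[k].slots.push_back(j + 1);
      rebuild_cluster(k);
    }
    refresh();
  }

  void refresh() {
    Wtot.zeros(sc.p, sc.p);
    for (const auto& C : cl) Wtot += C.W;
    arma::mat Wi;
    valid = arma::inv_sympd(Wi, Wtot);
    if (valid) {
      Winv = Wi;
      cur_var = Winv(sc.p - 1, sc.p - 1);
      if (!std::isfinite(cur_var) || cur_var <= 0.0) valid = false;
    }
  }

  // variance of the treatment coefficient after Wtot + U * C * U'
  // (Cinv = C^-1 supplied); returns <= 0 when the change is inadmissible
  double var_after(const arma::mat& U, const arma::mat& Cinv) const {
    const int p = sc.p;
    arma::vec q = Winv.col(p - 1);
    arma::mat B = U.t() * Winv * U;
    arma::mat Mi;
    if (!arma::inv(Mi, Cinv + B)) return -1.0;
    arma::vec y = U.t() * q;
    double v = cur_var - arma::dot(y, Mi * y);
    if (!std::isfinite(v) || v <= 0.0) return -1.0;
    return v;
  }

  // ---- batched add quantities for one cluster ------------------------
  // for each free slot: F = Rinv * corr-col, d0 = c'F, a0 = z - G'c
  struct AddBatch {
    std::vector<int> free_slots;           // ascending
    std::vector<int> col_of;               // slot -> column (or -1)
    arma::mat F;                           // m x f
    arma::vec d0;                          // f
    arma::mat A0;                          // p x f
  };

  AddBatch make_add_batch(int k) const {
    const Cluster& C = cl[k];
    AddBatch ab;
    ab.col_of.assign(sc.M + 2, -1);
    for (int s = 1; s <= sc.M; ++s)
      if (C.idx_of(s) < 0) {
        ab.col_of[s] = (int)ab.free_slots.size();
        ab.free_slots.push_back(s);
      }
    const int f = (int)ab.free_slots.size();
    const int m = C.m();
    ab.d0.zeros(f);
    ab.A0.set_size(sc.p, f);
    if (f == 0) return ab;
    arma::mat Cf(m, f);
    for (int j = 0; j < f; ++j) {
      double t = (double)ab.free_slots[j] / sc.M;
      for (int i = 0; i < m; ++i)
        Cf(i, j) = sc.rho * std::pow(sc.tau, std::abs(t - C.times[i]));
      ab.A0.col(j) = zrow(C, ab.free_slots[j]).t();
    }
    if (m > 0) {
      ab.F = C.Rinv * Cf;
      for (int j = 0; j < f; ++j) ab.d0[j] = arma::dot(Cf.col(j), ab.F.col(j));
      ab.A0 -= C.G.t() * Cf;
    } else {
      ab.F.set_size(0, f);
    }
    return ab;
  }

  // plain add of a free slot, from the current state: contributes
  // s * a a' with s = 1/(1 - d0); fills (a, cinv_entry); false if invalid
  bool add_cols(const AddBatch& ab, int j, arma::vec& a, double& cinv) const {
    double den = 1.0 - ab.d0[j];
    if (!(den > 1e-14)) return false;
    a = ab.A0.col(j);
    cinv = den;                            // Cinv entry = 1/s = 1 - d0
    return true;
  }

  // relocation within cluster k — remove recruited index i, add free col j
  // — optionally compounded with a +-1 shift of the same cluster's
  // cross-over (dd). Exact composition on the cached state: rank-1
  // removal downdate, rank-2 flip of the boundary observation's treatment
  // entry evaluated on the post-removal state, rank-1 addition evaluated
  // on the post-removal, post-flip state (the added row's treatment entry
  // uses the shifted cross-over). Writes up to 4 columns of U and the
  // matching Cinv diagonal blocks starting at col0; returns the number of
  // columns written (0 = infeasible).
  int reloc_shift_cols(int k, const AddBatch& ab, int i, int j, int dd,
                       arma::mat& U, arma::mat& Cinv, int col0) const {
    const Cluster& C = cl[k];
    double u = C.u[i];
    if (!(u > 0.0)) return 0;
    int cnew = C.c + dd;
    if (cnew < 1 || cnew > sc.M + 1) return 0;
    double Fi = ab.F(i, j);
    double den = 1.0 - ab.d0[j] + Fi * Fi / u;
    if (!(den > 1e-14)) return 0;
    arma::vec g = C.G.row(i).t();
    int nc = 0;
    U.col(col0) = g;
    Cinv(col0, col0) = -u;
    nc = 1;
    int s = ab.free_slots[j];
    arma::vec at = ab.A0.col(j) + g * (Fi / u);
    if (dd != 0) {
      int b = (dd == 1) ? C.c : C.c - 1;  // slot whose condition flips
      double delta = (dd == 1) ? -1.0 : 1.0;
      if (b >= 1 && b <= sc.M) {
        int bi = C.idx_of(b);
        if (bi >= 0 && bi != i) {
          double rbi = C.Rinv(bi, i);
          arma::vec gb = C.G.row(bi).t() - g * (rbi / u);
          double ub = C.u[bi] - rbi * rbi / u;
          arma::vec dz(sc.p, arma::fill::zeros);
          dz[sc.p - 1] = delta;
          U.col(col0 + nc) = gb;
          U.col(col0 + nc + 1) = dz;
          Cinv(col0 + nc, col0 + nc) = -ub;
          Cinv(col0 + nc, col0 + nc + 1) = 1.0;
          Cinv(col0 + nc + 1, col0 + nc) = 1.0;
          Cinv(col0 + nc + 1, col0 + nc + 1) = 0.0;
          nc += 2;
          // flip feeds back into the added row through G
          double wpb = ab.F(bi, j) - rbi * Fi / u;
          at[sc.p - 1] -= delta * wpb;
        } else if (s == b) {
          // the added participant itself sits on the flipped slot
          at[sc.p - 1] += delta;
        }
      }
    }
    U.col(col0 + nc) = at;
    Cinv(col0 + nc, col0 + nc) = den;
    return nc + 1;
  }

  // ---- greedy mirror-pair removal ------------------------------------
  bool best_remove_pair(int& best_k, int& best_slot, double& best_var) const {
    bool found = false;
    best_var = arma::datum::inf;
    arma::mat U(sc.p, 2);
    arma::mat Cinv(2, 2, arma::fill::zeros);
    for (int k = 0; k < sc.K / 2; ++k) {
      const Cluster& C = cl[k];
      const Cluster& Cm = cl[mirror(k)];
      for (int i = 0; i < C.m(); ++i) {
        int s = C.slots[i];
        int im = Cm.idx_of(mirror_slot(s));
        if (im < 0) stop("internal error: design lost reversal symmetry");
        double u1 = C.u[i], u2 = Cm.u[im];
        if (!(u1 > 0.0 && u2 > 0.0)) continue;
        U.col(0) = C.G.row(i).t();
        U.col(1) = Cm.G.row(im).t();
        Cinv(0, 0) = -u1;
        Cinv(1, 1) = -u2;
        double v = var_after(U, Cinv);
        if (v > 0.0 && v < best_var) {
          best_var = v;
          best_k = k;
          best_slot = s;
          found = true;
        }
      }
    }
    return found;
  }

  void commit_remove_pair(int k, int slot) {
    remove_slot(k, slot);
    remove_slot(mirror(k), mirror_slot(slot));
    rebuild_cluster(k);
    rebuild_cluster(mirror(k));
    refresh();
  }

  void remove_slot(int k, int slot) {
    auto& v = cl[k].slots;
    v.erase(std::lower_bound(v.begin(), v.end(), slot));
  }

  void add_slot(int k, int slot) {
    auto& v = cl[k].slots;
    v.insert(std::lower_bound(v.begin(), v.end(), slot), slot);
  }

  // ---- greedy mirror-pair addition -----------------------------------
  bool best_add_pair(int& best_k, int& best_slot, double& best_var) const {
    bool found = false;
    best_var = arma::datum::inf;
    arma::mat U(sc.p, 2);
    arma::mat Cinv(2, 2, arma::fill::zeros);
    arma::vec a1, a2;
    double c1, c2;
    for (int k = 0; k < sc.K / 2; ++k) {
      int km = mirror(k);
      AddBatch ab = make_add_batch(k);
      AddBatch abm = make_add_batch(km);
      for (size_t jj = 0; jj < ab.free_slots.size(); ++jj) {
        int s = ab.free_slots[jj];
        int jm = abm.col_of[mirror_slot(s)];
        if (jm < 0) stop("internal error: design lost reversal symmetry");
        if (!add_cols(ab, (int)jj, a1, c1)) continue;
        if (!add_cols(abm, jm, a2, c2)) continue;
        U.col(0) = a1;
        U.col(1) = a2;
        Cinv(0, 0) = c1;
        Cinv(1, 1) = c2;
        double v = var_after(U, Cinv);
        if (v > 0.0 && v < best_var) {
          best_var = v;
          best_k = k;
          best_slot = s;
          found = true;
        }
      }
    }
    return found;
  }

  void commit_add_pair(int k, int slot) {
    add_slot(k, slot);
    add_slot(mirror(k), mirror_slot(slot));
    rebuild_cluster(k);
    rebuild_cluster(mirror(k));
    refresh();
  }

  // ---- improvement moves ---------------------------------------------
  struct Move {
    int type = -1;    // 0 crossover shift, 1 within-cluster, 2 cross-cluster
    int k = -1, k2 = -1;
    int delta = 0;    // type 0
    int from = 0, to = 0;
    int cshift = 0;   // type 1: optional same-cluster cross-over shift
    double var = arma::datum::inf;
  };

  // crossover shift of half-cluster k by delta (mirror shifted by -delta)
  bool shift_cols(int k, int delta, arma::mat& U, arma::mat& Cinv,
                  int& ncol) const {
    const Cluster& C = cl[k];
    const Cluster& Cm = cl[mirror(k)];
    int cnew = C.c + delta;
    if (cnew < 1 || cnew > sc.M + 1) return false;
    int b = (delta == 1) ? C.c : C.c - 1;     // slot whose condition flips
    if (b < 1 || b > sc.M) return false;
    double dz = (delta == 1) ? -1.0 : 1.0;    // treatment column change
    int i = C.idx_of(b);
    int im = Cm.idx_of(mirror_slot(b));
    ncol = 0;
    if (i >= 0) {
      U.col(ncol) = C.G.row(i).t();
      arma::vec d(sc.p, arma::fill::zeros);
      d[sc.p - 1] = dz;
      U.col(ncol + 1) = d;
      Cinv(ncol, ncol) = -C.u[i];
      Cinv(ncol, ncol + 1) = 1.0;
      Cinv(ncol + 1, ncol) = 1.0;
      Cinv(ncol + 1, ncol + 1) = 0.0;
      ncol += 2;
    }
    if (im >= 0) {
      U.col(ncol) = Cm.G.row(im).t();
      arma::vec d(sc.p, arma::fill::zeros);
      d[sc.p - 1] = -dz;                      // mirror flips the other way
      U.col(ncol + 1) = d;
      Cinv(ncol, ncol) = -Cm.u[im];
      Cinv(ncol, ncol + 1) = 1.0;
      Cinv(ncol + 1, ncol) = 1.0;
      Cinv(ncol + 1, ncol + 1) = 0.0;
      ncol += 2;
    }
    return ncol > 0;                          // no recruited boundary: no-op
  }

  Move best_move(bool fam_cross, bool fam_reloc, bool fam_xcl) const {
    Move best;
    arma::mat U(sc.p, 4);
    arma::mat Cinv(4, 4);

    if (fam_cross) {
      for (int k = 0; k < sc.K / 2; ++k) {
        for (int dd = 0; dd < 2; ++dd) {
          int delta = (dd == 0) ? -1 : 1;
          int ncol = 0;
          Cinv.zeros();
          if (!shift_cols(k, delta, U, Cinv, ncol)) continue;
          double v = var_after(U.cols(0, ncol - 1),
                               Cinv.submat(0, 0, ncol - 1, ncol - 1));
          if (v > 0.0 && v < best.var) {
            best.type = 0;
            best.k = k;
            best.delta = delta;
            best.var = v;
          }
        }
      }
    }

    if (fam_reloc) {
      arma::mat U8(sc.p, 8);
      arma::mat Cinv8(8, 8);
      for (int k = 0; k < sc.K / 2; ++k) {
        int km = mirror(k);
        const Cluster& C = cl[k];
        const Cluster& Cm = cl[km];
        if (C.m() == 0) continue;
        AddBatch ab = make_add_batch(k);
        if (ab.free_slots.empty()) continue;
        AddBatch abm = make_add_batch(km);
        for (int i = 0; i < C.m(); ++i) {
          int im = Cm.idx_of(mirror_slot(C.slots[i]));
          if (im < 0) stop("internal error: design lost reversal symmetry");
          for (size_t jj = 0; jj < ab.free_slots.size(); ++jj) {
            int s = ab.free_slots[jj];
            int jm = abm.col_of[mirror_slot(s)];
            if (jm < 0) stop("internal error: design lost reversal symmetry");
            for (int dd = -1; dd <= 1; ++dd) {
              Cinv8.zeros();
              int n1 = reloc_shift_cols(k, ab, i, (int)jj, dd, U8, Cinv8, 0);
              if (!n1) continue;
              int n2 = reloc_shift_cols(km, abm, im, jm, -dd, U8, Cinv8, n1);
              if (!n2) continue;
              int nc = n1 + n2;
              double v = var_after(U8.cols(0, nc - 1),
                                   Cinv8.submat(0, 0, nc - 1, nc - 1));
              if (v > 0.0 && v < best.var) {
                best.type = 1;
                best.k = k;
                best.from = C.slots[i];
                best.to = s;
                best.cshift = dd;
                best.var = v;
              }
            }
          }
        }
      }
    }

    if (fam_xcl) {
      arma::vec a2, a2m;
      double c2, c2m;
      std::vector<AddBatch> batches(sc.K);
      std::vector<bool> have(sc.K, false);
      for (int k1 = 0; k1 < sc.K / 2; ++k1) {
        const Cluster& C1 = cl[k1];
        const Cluster& C1m = cl[mirror(k1)];
        for (int i = 0; i < C1.m(); ++i) {
          int im = C1m.idx_of(mirror_slot(C1.slots[i]));
          if (im < 0) stop("internal error: design lost reversal symmetry");
          if (!(C1.u[i] > 0.0 && C1m.u[im] > 0.0)) continue;
          for (int k2 = 0; k2 < sc.K / 2; ++k2) {
            if (k2 == k1) continue;
            if (!have[k2]) {
              batches[k2] = make_add_batch(k2);
              batches[mirror(k2)] = make_add_batch(mirror(k2));
              have[k2] = true;
            }
            const AddBatch& ab = batches[k2];
            const AddBatch& abm = batches[mirror(k2)];
            for (size_t jj = 0; jj < ab.free_slots.size(); ++jj) {
              int s = ab.free_slots[jj];
              int jm = abm.col_of[mirror_slot(s)];
              if (jm < 0)
                stop("internal error: design lost reversal symmetry");
              if (!add_cols(ab, (int)jj, a2, c2)) continue;
              if (!add_cols(abm, jm, a2m, c2m)) continue;
              U.col(0) = C1.G.row(i).t();
              U.col(1) = C1m.G.row(im).t();
              U.col(2) = a2;
              U.col(3) = a2m;
              Cinv.zeros();
              Cinv(0, 0) = -C1.u[i];
              Cinv(1, 1) = -C1m.u[im];
              Cinv(2, 2) = c2;
              Cinv(3, 3) = c2m;
              double v = var_after(U, Cinv);
              if (v > 0.0 && v < best.var) {
                best.type = 2;
                best.k = k1;
                best.k2 = k2;
                best.from = C1.slots[i];
                best.to = s;
                best.var = v;
              }
            }
          }
        }
      }
    }

    return best;
  }

  void commit_move(const Move& mv) {
    if (mv.type == 0) {
      cl[mv.k].c += mv.delta;
      cl[mirror(mv.k)].c = sc.M + 2 - cl[mv.k].c;
      rebuild_cluster(mv.k);
      rebuild_cluster(mirror(mv.k));
    } else if (mv.type == 1) {
      remove_slot(mv.k, mv.from);
      add_slot(mv.k, mv.to);
      remove_slot(mirror(mv.k), mirror_slot(mv.from));
      add_slot(mirror(mv.k), mirror_slot(mv.to));
      if (mv.cshift != 0) {
        cl[mv.k].c += mv.cshift;
        cl[mirror(mv.k)].c = sc.M + 2 - cl[mv.k].c;
      }
      rebuild_cluster(mv.k);
      rebuild_cluster(mirror(mv.k));
    } else {
      remove_slot(mv.k, mv.from);
      remove_slot(mirror(mv.k), mirror_slot(mv.from));
      add_slot(mv.k2, mv.to);
      add_slot(mirror(mv.k2), mirror_slot(mv.to));
      rebuild_cluster(mv.k);
      rebuild_cluster(mirror(mv.k));
      rebuild_cluster(mv.k2);
      rebuild_cluster(mirror(mv.k2));
    }
    refresh();
  }

  int sweep(bool fam_cross, bool fam_reloc, bool fam_xcl, double tol,
            int limit) {
    int applied = 0;
    while (applied < limit) {
      Move mv = best_move(fam_cross, fam_reloc, fam_xcl);
      if (mv.type < 0) break;
      double newprec = 1.0 / mv.var;
      double curprec = 1.0 / cur_var;
      if (!(newprec > curprec * (1.0 + tol))) break;
      commit_move(mv);
      if (!valid) stop("internal error: improvement move broke the model");
      ++applied;
    }
    return applied;
  }

  // ---- export ---------------------------------------------------------
  IntegerVector crossover_out() const {
    IntegerVector cr(sc.K);
    for (int k = 0; k < sc.K; ++k) cr[k] = cl[k].c;
    return cr;
  }

  IntegerMatrix recruit_out() const {
    IntegerMatrix rec(sc.K, sc.M);
    for (int k = 0; k < sc.K; ++k)
      for (int s : cl[k].slots) rec(k, s - 1) = 1;
    return rec;
  }
};

// [[Rcpp::export]]
List cpp_eval(List scen, IntegerVector crossover, IntegerMatrix recruit) {
  Engine E;
  E.init(scen_from_list(scen), crossover, recruit);
  if (!E.valid)
    return List::create(_["ok"] = false, _["variance"] = NA_REAL,
                        _["precision"] = NA_REAL);
  return List::create(_["ok"] = true, _["variance"] = E.cur_var,
                      _["precision"] = 1.0 / E.cur_var);
}

// [[Rcpp::export]]
List cpp_eval_many(List scen, List designs) {
  Scen sc = scen_from_list(scen);
  const int nd = designs.size();
  IntegerVector n(nd);
  NumericVector variance(nd), precision(nd);
  LogicalVector ok(nd);
  for (int d = 0; d < nd; ++d) {
    List ds = designs[d];
    IntegerVector cr = ds[0];
    IntegerMatrix rec = ds[1];
    int nn = 0;
    for (int i = 0; i < rec.size(); ++i) nn += rec[i];
    n[d] = nn;
    if (nn < sc.p) {
      ok[d] = false;
      variance[d] = NA_REAL;
      precision[d] = NA_REAL;
      continue;
    }
    Engine E;
    try {
      E.init(sc, cr, rec);
    } catch (...) {
      E.valid = false;
    }
    ok[d] = E.valid;
    variance[d] = E.valid ? E.cur_var : NA_REAL;
    precision[d] = E.valid ? 1.0 / E.cur_var : NA_REAL;
  }
  return List::create(_["n"] = n, _["ok"] = ok, _["variance"] = variance,
                      _["precision"] = precision);
}

// [[Rcpp::export]]
List cpp_sweep(List scen, IntegerVector crossover, IntegerMatrix recruit,
               bool fam_cross, bool fam_reloc, bool fam_xcl, double tol,
               int sweep_limit) {
  Engine E;
  E.init(scen_from_list(scen), crossover, recruit);
  if (!E.valid) stop("design is not identifiable");
  int moves = E.sweep(fam_cross, fam_reloc, fam_xcl, tol, sweep_limit);
  return List::create(
      _["crossover"] = E.crossover_out(), _["recruit"] = E.recruit_out(),
      _["variance"] = E.cur_var, _["precision"] = 1.0 / E.cur_var,
      _["moves"] = moves);
}

// [[Rcpp::export]]
List cpp_remove_pair(List scen, IntegerVector crossover,
                     IntegerMatrix recruit) {
  Engine E;
  E.init(scen_from_list(scen), crossover, recruit);
  if (!E.valid) stop("design is not identifiable");
  int k, slot;
  double var;
  if (!E.best_remove_pair(k, slot, var))
    return List::create(_["ok"] = false);
  E.commit_remove_pair(k, slot);
  return List::create(
      _["ok"] = true, _["crossover"] = E.crossover_out(),
      _["recruit"] = E.recruit_out(), _["variance"] = E.cur_var,
      _["precision"] = 1.0 / E.cur_var, _["cluster"] = k + 1,
      _["slot"] = slot);
}

// [[Rcpp::export]]
List cpp_add_pair(List scen, IntegerVector crossover, IntegerMatrix recruit) {
  Engine E;
  E.init(scen_from_list(scen), crossover, recruit);
  if (!E.valid) stop("design is not identifiable");
  int k, slot;
  double var;
  if (!E.best_add_pair(k, slot, var))
    return List::create(_["ok"] = false);
  E.commit_add_pair(k, slot);
  return List::create(
      _["ok"] = true, _["crossover"] = E.crossover_out(),
      _["recruit"] = E.recruit_out(), _["variance"] = E.cur_var,
      _["precision"] = 1.0 / E.cur_var, _["cluster"] = k + 1,
      _["slot"] = slot);
}

// [[Rcpp::export]]
List cpp_search(List scen, IntegerVector crossover, IntegerMatrix recruit,
                bool forward, double target, int floor_n, bool fam_cross,
                bool fam_reloc, bool fam_xcl, double tol, int sweep_limit,
                bool record_designs) {
  Engine E;
  E.init(scen_from_list(scen), crossover, recruit);
  if (!E.valid) stop("starting design is not identifiable");

  std::vector<std::string> types;
  std::vector<int> ns;
  std::vector<double> vars;
  List designs;
  bool cand_ok = false;
  IntegerVector cand_cr;
  IntegerMatrix cand_rec;
  double cand_var = NA_REAL;
  std::string status = forward ? "floor_reached" : "complete_reached";

  auto record = [&](const char* type) {
    types.push_back(type);
    ns.push_back(E.n_total());
    vars.push_back(E.cur_var);
    if (record_designs)
      designs.push_back(
          List::create(E.crossover_out(), E.recruit_out()));
  };
  auto note_candidate = [&]() {
    if (target > 0.0 && 1.0 / E.cur_var >= target) {
      cand_ok = true;
      cand_cr = E.crossover_out();
      cand_rec = E.recruit_out();
      cand_var = E.cur_var;
      return true;
    }
    return false;
  };

  E.sweep(fam_cross, fam_reloc, fam_xcl, tol, sweep_limit);
  record("sweep");
  bool start_hits = note_candidate();

  if (forward) {
    if (target > 0.0 && !start_hits) {
      status = "unachievable";
    } else {
      while (true) {
        if (E.n_total() - 2 < floor_n) {
          status = "floor_reached";
          break;
        }
        int k, slot;
        double var;
        if (!E.best_remove_pair(k, slot, var)) {
          status = "exhausted";
          break;
        }
        E.commit_remove_pair(k, slot);
        if (!E.valid) {
          status = "exhausted";
          break;
        }
        record("remove");
        E.sweep(fam_cross, fam_reloc, fam_xcl, tol, sweep_limit);
        record("sweep");
        if (target > 0.0 && !note_candidate()) {
          status = "target_crossed";
          break;
        }
      }
    }
  } else {
    if (start_hits) {
      status = "achieved";
    } else {
      while (true) {
        int k, slot;
        double var;
        if (!E.best_add_pair(k, slot, var)) {
          status = "complete_reached";
          break;
        }
        E.commit_add_pair(k, slot);
        record("add");
        E.sweep(fam_cross, fam_reloc, fam_xcl, tol, sweep_limit);
        record("sweep");
        if (note_candidate()) {
          status = "achieved";
          break;
        }
      }
    }
  }

  const int nrec = (int)types.size();
  CharacterVector type_out(nrec);
  IntegerVector n_out(nrec);
  NumericVector var_out(nrec), prec_out(nrec);
  for (int i = 0; i < nrec; ++i) {
    type_out[i] = types[i];
    n_out[i] = ns[i];
    var_out[i] = vars[i];
    prec_out[i] = 1.0 / vars[i];
  }

  List out = List::create(
      _["step_type"] = type_out, _["n"] = n_out, _["variance"] = var_out,
      _["precision"] = prec_out,
      _["designs"] = record_designs ? (SEXP)designs : R_NilValue,
      _["cand_ok"] = cand_ok, _["status"] = status,
      _["final_crossover"] = E.crossover_out(),
      _["final_recruit"] = E.recruit_out());
  if (cand_ok) {
    out["cand_crossover"] = cand_cr;
    out["cand_recruit"] = cand_rec;
    out["cand_precision"] = 1.0 / cand_var;
  }
  return out;
}
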