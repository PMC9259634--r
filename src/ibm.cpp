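// Exact Gillespie simulation of the eco-evolutionary individual-based model.
//
// Individuals carry d neutral trait components and, under selection, one
// adaptive trait. Events are individual births (rate b(1 - p(s - Theta_i)^2)
// clamped at 0, or constant b without selection) and deaths (per-capita rate
// N_i / K). A newborn copies the parental traits, each component mutating
// independently with probability mu by a Normal(0, sigma_mu^2) step, and
// settles with probability m on a uniformly chosen neighbour of the natal
// vertex. Uses R's RNG so runs are reproducible via set.seed().
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

inline int unif_index(int n) {
  // uniform integer in [0, n)
  int k = (int)std::floor(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Pool {
  int d;
  std::vector<double> u;        // ncap x d, row-major per individual
  std::vector<double> s;
  std::vector<double> brate;    // cached individual birth rate
  std::vector<int> vertex;      // 0-based vertex of each individual
  std::vector<int> pos;         // position within its vertex's member list
  std::vector<int> free_slots;

  int alloc() {
    if (!free_slots.empty()) {
      int idx = free_slots.back();
      free_slots.pop_back();
      return idx;
    }
    int idx = (int)s.size();
    u.resize(u.size() + d);
    s.push_back(0.0);
    brate.push_back(0.0);
    vertex.push_back(-1);
    pos.push_back(-1);
    return idx;
  }
};

} // namespace

// [[Rcpp::export]]
List simulate_ibm_cpp(List neighbors, NumericVector theta_v,
                      double b, double K, double p, double m,
                      double mu, double sigma_mu, int d, bool selection,
                      double t_end, NumericVector record_times,
                      bool final_traits) {
  const int M = neighbors.size();
  std::vector< std::vector<int> > nb(M);
  for (int i = 0; i < M; ++i) {
    IntegerVector v = neighbors[i];
    nb[i] = std::vector<int>(v.begin(), v.end());
  }

  Pool pool;
  pool.d = d;
  std::vector< std::vector<int> > members(M);
  std::vector<double> B(M, 0.0);  // per-vertex total birth rate

  const int K0 = (int)std::lround(K);
  for (int i = 0; i < M; ++i) {
    members[i].reserve(4 * K0);
    for (int k = 0; k < K0; ++k) {
      int idx = pool.alloc();
      for (int j = 0; j < d; ++j)
        pool.u[(size_t)idx * d + j] = R::rnorm(0.0, sigma_mu);
      double s0 = selection ? R::rnorm(0.0, sigma_mu) : 0.0;
      pool.s[idx] = s0;
      double br = selection
        ? std::max(0.0, b * (1.0 - p * (s0 - theta_v[i]) * (s0 - theta_v[i])))
        : b;
      pool.brate[idx] = br;
      pool.vertex[idx] = i;
      pool.pos[idx] = (int)members[i].size();
      members[i].push_back(idx);
      B[i] += br;
    }
  }

  const int R_n = record_times.size();
  NumericMatrix recN(R_n, M), rec_s_mean(R_n, M), rec_s_var(R_n, M);
  NumericMatrix rec_u_mean(R_n, M * d), rec_u_var(R_n, M * d);
  std::fill(recN.begin(), recN.end(), NA_REAL);
  std::fill(rec_s_mean.begin(), rec_s_mean.end(), NA_REAL);
  std::fill(rec_s_var.begin(), rec_s_var.end(), NA_REAL);
  std::fill(rec_u_mean.begin(), rec_u_mean.end(), NA_REAL);
  std::fill(rec_u_var.begin(), rec_u_var.end(), NA_REAL);

  std::vector<double> acc(d), acc2(d);
  auto record_state = [&](int r) {
    for (int i = 0; i < M; ++i) {
      int Ni = (int)members[i].size();
      recN(r, i) = Ni;
      if (Ni == 0) continue;
      double ssum = 0.0, ssum2 = 0.0;
      std::fill(acc.begin(), acc.end(), 0.0);
      std::fill(acc2.begin(), acc2.end(), 0.0);
      for (int k = 0; k < Ni; ++k) {
        int idx = members[i][k];
        double sv = pool.s[idx];
        ssum += sv; ssum2 += sv * sv;
        const double *up = &pool.u[(size_t)idx * d];
        for (int j = 0; j < d; ++j) { acc[j] += up[j]; acc2[j] += up[j] * up[j]; }
      }
      double sm = ssum / Ni;
      rec_s_mean(r, i) = sm;
      rec_s_var(r, i) = std::max(0.0, ssum2 / Ni - sm * sm);
      for (int j = 0; j < d; ++j) {
        // column layout j * M + i so the R side can reshape to
        // (records x vertices x traits) without transposition
        double um = acc[j] / Ni;
        rec_u_mean(r, j * M + i) = um;
        rec_u_var(r, j * M + i) = std::max(0.0, acc2[j] / Ni - um * um);
      }
    }
  };

  double t = 0.0;
  int rec_idx = 0;
  long total_pop = (long)M * K0;
  bool extinct = false;
  long long events = 0;

  while (t < t_end && !extinct) {
    double total = 0.0;
    for (int i = 0; i < M; ++i) {
      double Ni = (double)members[i].size();
      total += std::max(0.0, B[i]) + Ni * Ni / K;
    }
    if (total <= 0.0) { extinct = true; break; }
    double t_new = t + R::exp_rand() / total;
    while (rec_idx < R_n && record_times[rec_idx] <= t_new &&
           record_times[rec_idx] <= t_end)
      record_state(rec_idx++);
    if (t_new >= t_end) { t = t_end; break; }
    t = t_new;

    // choose vertex and event type
    double r1 = R::unif_rand() * total;
    int vi = -1;
    bool is_birth = false;
    for (int i = 0; i < M; ++i) {
      double Bi = std::max(0.0, B[i]);
      double Ni = (double)members[i].size();
      double Di = Ni * Ni / K;
      if (r1 < Bi) { vi = i; is_birth = true; break; }
      r1 -= Bi;
      if (r1 < Di) { vi = i; is_birth = false; break; }
      r1 -= Di;
    }
    if (vi < 0) { vi = M - 1; is_birth = false; }  // float round-off guard
    if (!is_birth && members[vi].empty()) continue;

    if (is_birth) {
      // parent proportional to individual birth rate
      int Ni = (int)members[vi].size();
      int parent = members[vi][Ni - 1];
      if (selection) {
        double r2 = r1;  // residual already < B[vi]
        for (int k = 0; k < Ni; ++k) {
          int idx = members[vi][k];
          if (r2 < pool.brate[idx]) { parent = idx; break; }
          r2 -= pool.brate[idx];
        }
      } else {
        parent = members[vi][unif_index(Ni)];
      }
      int child = pool.alloc();
      const double *pu = &pool.u[(size_t)parent * d];
      double *cu = &pool.u[(size_t)child * d];
      for (int j = 0; j < d; ++j) {
        double v = pu[j];
        if (R::unif_rand() < mu) v += R::rnorm(0.0, sigma_mu);
        cu[j] = v;
      }
      double cs = pool.s[parent];
      if (selection && R::unif_rand() < mu) cs += R::rnorm(0.0, sigma_mu);
      pool.s[child] = cs;
      int dest = vi;
      if (m > 0.0 && R::unif_rand() < m && !nb[vi].empty())
        dest = nb[vi][unif_index((int)nb[vi].size())];
      double br = selection
        ? std::max(0.0, b * (1.0 - p * (cs - theta_v[dest]) * (cs - theta_v[dest])))
        : b;
      pool.brate[child] = br;
      pool.vertex[child] = dest;
      pool.pos[child] = (int)members[dest].size();
      members[dest].push_back(child);
      B[dest] += br;
      ++total_pop;
    } else {
      int Ni = (int)members[vi].size();
      int k = unif_index(Ni);
      int victim = members[vi][k];
      B[vi] -= pool.brate[victim];
      int last = members[vi].back();
      members[vi][k] = last;
      pool.pos[last] = k;
      members[vi].pop_back();
      pool.free_slots.push_back(victim);
      --total_pop;
      if (total_pop == 0) {
        extinct = true;
        t_end = t;  // truncate
      }
    }

    if ((++events & 0xFFFFF) == 0) {  // periodic refresh against FP drift
      for (int i = 0; i < M; ++i) {
        double s0 = 0.0;
        for (int idx : members[i]) s0 += pool.brate[idx];
        B[i] = s0;
      }
      Rcpp::checkUserInterrupt();
    }
  }

  // record times at or before the final reached time
  while (rec_idx < R_n && record_times[rec_idx] <= t_end)
    record_state(rec_idx++);

  List fin = R_NilValue;
  if (final_traits && total_pop > 0) {
    IntegerVector fv((int)total_pop);
    NumericVector fs((int)total_pop);
    NumericMatrix fu((int)total_pop, d);
    int row = 0;
    for (int i = 0; i < M; ++i) {
      for (int idx : members[i]) {
        fv[row] = i + 1;
        fs[row] = pool.s[idx];
        for (int j = 0; j < d; ++j) fu(row, j) = pool.u[(size_t)idx * d + j];
        ++row;
      }
    }
    fin = List::create(_["vertex"] = fv, _["s"] = fs, _["u"] = fu);
  }

  return List::create(
    _["N"] = recN, _["s_mean"] = rec_s_mean, _["s_var"] = rec_s_var,
    _["u_mean"] = rec_u_mean, _["u_var"] = rec_u_var,
    _["t_final"] = t, _["extinct"] = extinct, _["n_events"] = (double)events,
    _["final_state"] = fin);
}
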