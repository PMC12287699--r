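#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact event-level simulation of one branch of codon evolution.
//
// Per-site substitution rates come from the scaled site-class rate matrices;
// insertion and deletion events each occur at rate ins_rate / del_rate per
// codon site (so the whole-sequence indel rate scales with current length).
// Insertion positions are uniform over the L+1 inter-codon slots, deletion
// start positions uniform over the L sites with length truncated at the
// right end. Indel lengths are geometric over k >= 1 codons with success
// probability q. Homology is tracked through integer column ids: every
// inserted codon receives a fresh id and the id of its left neighbour at
// insertion time is logged as an anchor so the caller can maintain a global
// column registry.
//
// Uses R's RNG throughout (RNGScope via Rcpp attributes) so results are
// reproducible under set.seed().

static inline int rgeom1(double q) {
  // geometric number of codons, support k >= 1, P(k) = q (1-q)^(k-1)
  if (q >= 1.0) return 1;
  double u = unif_rand();
  int k = 1 + (int)std::floor(std::log(u) / std::log(1.0 - q));
  return k < 1 ? 1 : k;
}

static inline int sample_cum(const std::vector<double>& w, double total) {
  double u = unif_rand() * total, acc = 0.0;
  int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return n - 1;
}

// [[Rcpp::export(name = ".evolve_branch_cpp")]]
List evolve_branch_cpp(IntegerVector states0, IntegerVector classes0,
                       IntegerVector ids0, double blen,
                       List Qs, NumericMatrix exit_rates,
                       NumericVector pi, NumericVector pclass,
                       double ins_rate, double del_rate, double q_geom,
                       int next_id) {
  const int S = pi.size();  // 61 sense codons
  std::vector<NumericMatrix> Q;
  for (int c = 0; c < Qs.size(); ++c) Q.push_back(as<NumericMatrix>(Qs[c]));

  std::vector<int> st(states0.begin(), states0.end());     // 1-based codon index
  std::vector<int> cl(classes0.begin(), classes0.end());   // 1-based class
  std::vector<int> id(ids0.begin(), ids0.end());

  std::vector<double> pivec(pi.begin(), pi.end());
  std::vector<double> pcl(pclass.begin(), pclass.end());

  int n_sub = 0, n_ins = 0, n_del = 0;
  std::vector<int> ins_anchor;          // left-neighbour id, 0 = front
  std::vector<std::vector<int> > ins_ids, ins_cls;
  std::vector<int> del_requested, del_applied;
  std::vector<int> ins_len;

  double t = 0.0;
  std::vector<double> rate;  // per-site substitution exit rate
  for (;;) {
    int L = (int)st.size();
    if (L == 0) break;  // everything deleted; nothing left to evolve
    rate.resize(L);
    double subtot = 0.0;
    for (int i = 0; i < L; ++i) {
      rate[i] = exit_rates(st[i] - 1, cl[i] - 1);
      subtot += rate[i];
    }
    double instot = ins_rate * L, deltot = del_rate * L;
    double total = subtot + instot + deltot;
    t += exp_rand() / total;
    if (t >= blen) break;

    double u = unif_rand() * total;
    if (u < subtot) {
      // substitution at a site chosen proportionally to its exit rate
      int i = sample_cum(rate, subtot);
      int from = st[i] - 1, c = cl[i] - 1;
      NumericMatrix& Qc = Q[c];
      double ui = unif_rand() * rate[i], acc = 0.0;
      int to = from;
      for (int j = 0; j < S; ++j) {
        if (j == from) continue;
        acc += Qc(from, j);
        if (ui <= acc) { to = j; break; }
      }
      if (to != from) { st[i] = to + 1; ++n_sub; }
    } else if (u < subtot + instot) {
      // insertion of k codons at a uniform inter-codon slot
      int slot = (int)std::floor(unif_rand() * (L + 1));
      if (slot > L) slot = L;
      int k = rgeom1(q_geom);
      std::vector<int> nid(k), nst(k), ncl(k);
      for (int j = 0; j < k; ++j) {
        nid[j] = next_id++;
        nst[j] = sample_cum(pivec, 1.0) + 1;
        ncl[j] = sample_cum(pcl, 1.0) + 1;
      }
      ins_anchor.push_back(slot == 0 ? 0 : id[slot - 1]);
      ins_ids.push_back(nid);
      ins_cls.push_back(ncl);
      ins_len.push_back(k);
      st.insert(st.begin() + slot, nst.begin(), nst.end());
      cl.insert(cl.begin() + slot, ncl.begin(), ncl.end());
      id.insert(id.begin() + slot, nid.begin(), nid.end());
      ++n_ins;
    } else {
      // deletion starting at a uniform site, truncated at the right end
      int start = (int)std::floor(unif_rand() * L);
      if (start >= L) start = L - 1;
      int k = rgeom1(q_geom);
      int applied = std::min(k, L - start);
      del_requested.push_back(k);
      del_applied.push_back(applied);
      st.erase(st.begin() + start, st.begin() + start + applied);
      cl.erase(cl.begin() + start, cl.begin() + start + applied);
      id.erase(id.begin() + start, id.begin() + start + applied);
      ++n_del;
    }
  }

  List ins_ids_out(ins_ids.size()), ins_cls_out(ins_cls.size());
  for (size_t i = 0; i < ins_ids.size(); ++i) {
    ins_ids_out[i] = wrap(ins_ids[i]);
    ins_cls_out[i] = wrap(ins_cls[i]);
  }
  return List::create(
    _["states"] = wrap(st), _["classes"] = wrap(cl), _["ids"] = wrap(id),
    _["n_sub"] = n_sub, _["n_ins"] = n_ins, _["n_del"] = n_del,
    _["ins_anchor"] = wrap(ins_anchor), _["ins_ids"] = ins_ids_out,
    _["ins_classes"] = ins_cls_out, _["ins_len"] = wrap(ins_len),
    _["del_requested"] = wrap(del_requested),
    _["del_applied"] = wrap(del_applied),
    _["next_id"] = next_id);
}
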