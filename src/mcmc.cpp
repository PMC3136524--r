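// Reaction-swap Metropolis core. A state is a fixed-size subset of a reaction
// pool; a proposal removes one uniformly chosen member and adds one uniformly
// chosen non-member (symmetric), and is accepted iff every ensemble constraint
// holds, which gives the uniform distribution over the constrained set.
// The distinct-metabolite count is maintained incrementally; viability is
// delegated to an R closure (which caches LP results by genotype).

#include <Rcpp.h>
#include <map>
#include <vector>

using namespace Rcpp;

static inline int unif_idx(int k) {
  int i = (int) (unif_rand() * k);
  return i >= k ? k - 1 : i;
}

// [[Rcpp::export(name = ".mcmc_core")]]
List mcmc_core(const List& rxn_mets,          // per pool reaction: 1-based metabolite indices
               const IntegerVector& start,    // 1-based reaction indices into the pool
               int n_met,
               int max_metabolites,           // -1 = unconstrained
               Nullable<Function> viability_fun,
               double burn_in_d, double thin_d, int n_save,
               int visit_interval)            // 0 = no visit tracking
{
  const int n_pool = rxn_mets.size();
  const int n_g = start.size();
  if (n_g <= 0) stop("empty start genotype");
  if (n_g >= n_pool) stop("pool leaves no room to swap");

  std::vector<std::vector<int>> mets(n_pool);
  for (int r = 0; r < n_pool; ++r) {
    IntegerVector v = rxn_mets[r];
    mets[r].assign(v.begin(), v.end());
  }

  std::vector<int> members(start.begin(), start.end());
  std::vector<char> is_member(n_pool + 1, 0);
  for (int r : members) {
    if (r < 1 || r > n_pool) stop("start genotype index out of range");
    if (is_member[r]) stop("duplicate reaction in start genotype");
    is_member[r] = 1;
  }
  std::vector<int> nonmembers;
  nonmembers.reserve(n_pool - n_g);
  for (int r = 1; r <= n_pool; ++r) if (!is_member[r]) nonmembers.push_back(r);

  std::vector<int> counts(n_met + 1, 0);
  int m_cur = 0;
  for (int r : members)
    for (int met : mets[r - 1])
      if (counts[met]++ == 0) ++m_cur;

  bool use_viab = viability_fun.isNotNull();
  Function viab = use_viab ? Function(viability_fun.get()) : Function("identity");

  const long long burn_in = (long long) burn_in_d;
  const long long thin = (long long) thin_d;
  const long long total_steps = burn_in + thin * (long long) n_save;
  IntegerMatrix saved(n_save, n_g);
  int saved_rows = 0;
  double attempted_sampling = 0, accepted_sampling = 0;

  std::map<std::vector<int>, int> visits;
  std::vector<int> key;

  IntegerVector proposal(n_g);

  for (long long step = 1; step <= total_steps && saved_rows < n_save; ++step) {
    bool sampling = step > burn_in;
    int i = unif_idx(n_g);
    int j = unif_idx((int) nonmembers.size());
    int r_out = members[i], r_in = nonmembers[j];

    // incremental metabolite-count update (exact under any out/in overlap)
    int m_new = m_cur;
    for (int met : mets[r_out - 1]) if (--counts[met] == 0) --m_new;
    for (int met : mets[r_in - 1])  if (counts[met]++ == 0) ++m_new;

    bool ok = (max_metabolites < 0) || (m_new <= max_metabolites);
    if (ok && use_viab) {
      for (int t = 0; t < n_g; ++t) proposal[t] = members[t];
      proposal[i] = r_in;
      ok = as<bool>(viab(proposal));
    }

    if (sampling) ++attempted_sampling;
    if (ok) {
      members[i] = r_in;
      nonmembers[j] = r_out;
      m_cur = m_new;
      if (sampling) ++accepted_sampling;
    } else { // revert the count update; m_cur was never committed
      for (int met : mets[r_in - 1])  --counts[met];
      for (int met : mets[r_out - 1]) ++counts[met];
    }

    if (sampling) {
      long long s = step - burn_in;
      if (visit_interval > 0 && s % visit_interval == 0) {
        key = members;
        std::sort(key.begin(), key.end());
        ++visits[key];
      }
      if (s % thin == 0 && saved_rows < n_save) {
        key = members;
        std::sort(key.begin(), key.end());
        for (int t = 0; t < n_g; ++t) saved(saved_rows, t) = key[t];
        ++saved_rows;
      }
    }
    if (step % 100000 == 0) checkUserInterrupt();
  }

  List out = List::create(
    _["genotypes"] = saved,
    _["acceptance_rate"] = attempted_sampling > 0 ? accepted_sampling / attempted_sampling : NA_REAL,
    _["final_members"] = IntegerVector(members.begin(), members.end()),
    _["final_metabolites"] = m_cur);

  if (visit_interval > 0) {
    int ns = visits.size();
    IntegerMatrix states(ns, n_g);
    IntegerVector vcounts(ns);
    int row = 0;
    for (auto& kv : visits) {
      for (int t = 0; t < n_g; ++t) states(row, t) = kv.first[t];
      vcounts[row] = kv.second;
      ++row;
    }
    out["visit_states"] = states;
    out["visit_counts"] = vcounts;
  }
  return out;
}
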