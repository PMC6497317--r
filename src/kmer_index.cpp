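// k-mer pseudoalignment core: canonical k-mer index over a reference set and
// intersection-based compatibility mapping of (paired) reads, aggregated into
// equivalence classes.  k is capped at 31 so a k-mer packs into 2*k <= 62 bits.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or anything else: k-mer not encodable
  }
}

struct KmerIndex {
  int k;
  std::vector<std::string> ref_ids;
  std::vector<int> ref_len;
  // canonical k-mer -> sorted unique 0-based reference indices
  std::unordered_map<uint64_t, std::vector<int>> table;
};

// call f(canonical_kmer) for every encodable k-mer position of seq
template <typename F>
void for_each_canonical(const char* s, int n, int k, F f) {
  uint64_t fwd = 0, rc = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  int run = 0;  // length of current run of encodable bases
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
    if (++run >= k) f(fwd < rc ? fwd : rc);
  }
}

void intersect_sorted(std::vector<int>& a, const std::vector<int>& b) {
  std::size_t i = 0, j = 0, o = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (b[j] < a[i]) ++j;
    else { a[o++] = a[i]; ++i; ++j; }
  }
  a.resize(o);
}

// compatibility set of one mate; informative = had >= 1 indexed k-mer
bool mate_compat(const KmerIndex& idx, const char* s, int n,
                 std::vector<int>& out) {
  bool informative = false, empty = false;
  out.clear();
  for_each_canonical(s, n, idx.k, [&](uint64_t km) {
    if (empty) return;
    auto it = idx.table.find(km);
    if (it == idx.table.end()) return;  // absent k-mer skipped (error tolerance)
    if (!informative) { out = it->second; informative = true; }
    else intersect_sorted(out, it->second);
    if (out.empty()) empty = true;
  });
  return informative;
}

}  // namespace

// [[Rcpp::export]]
SEXP kmer_index_build_cpp(CharacterVector ids, CharacterVector seqs, int k) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  int n = seqs.size();
  idx->ref_ids.reserve(n);
  idx->ref_len.reserve(n);
  for (int r = 0; r < n; ++r) {
    const char* s = CHAR(STRING_ELT(seqs, r));
    int len = LENGTH(STRING_ELT(seqs, r));
    idx->ref_ids.push_back(as<std::string>(ids[r]));
    idx->ref_len.push_back(len);
    if (len < k) continue;  // skipped record (caller warns)
    for_each_canonical(s, len, k, [&](uint64_t km) {
      std::vector<int>& v = idx->table[km];
      if (v.empty() || v.back() != r) v.push_back(r);
    });
  }
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
List kmer_index_info_cpp(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return List::create(
    _["k"] = idx->k,
    _["n_kmers"] = (double)idx->table.size(),
    _["ref_ids"] = wrap(idx->ref_ids),
    _["ref_lengths"] = wrap(idx->ref_len));
}

// 1-based reference indices holding a given k-mer (canonicalized); for tests
// [[Rcpp::export]]
IntegerVector kmer_entry_cpp(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("k-mer length must equal index k");
  IntegerVector none(0);
  uint64_t fwd = 0, rc = 0;
  const int k = idx->k, shift = 2 * (k - 1);
  for (int i = 0; i < k; ++i) {
    int c = base_code(kmer[i]);
    if (c < 0) return none;
    fwd = (fwd << 2) | (uint64_t)c;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << shift);
  }
  auto it = idx->table.find(fwd < rc ? fwd : rc);
  if (it == idx->table.end()) return none;
  IntegerVector out(it->second.size());
  for (std::size_t i = 0; i < it->second.size(); ++i) out[i] = it->second[i] + 1;
  return out;
}

// Map fragments (single- or paired-end) and aggregate equivalence classes.
// frag_class: class id (1-based), 0 = unmapped, -1 = too short.
// [[Rcpp::export]]
List map_fragments_cpp(SEXP xp, CharacterVector r1, Nullable<CharacterVector> r2) {
  XPtr<KmerIndex> idx(xp);
  const int n = r1.size();
  const bool paired = r2.isNotNull();
  CharacterVector m2;
  if (paired) {
    m2 = r2.get();
    if (m2.size() != n) stop("mate files have different numbers of reads");
  }

  std::map<std::vector<int>, int> class_of;  // refs -> class id (1-based)
  std::vector<std::vector<int>> class_refs;
  std::vector<double> class_count;
  IntegerVector frag_class(n);
  double n_unmapped = 0, n_too_short = 0;
  std::vector<int> c1, c2;

  for (int i = 0; i < n; ++i) {
    const char* s1 = CHAR(STRING_ELT(r1, i));
    int l1 = LENGTH(STRING_ELT(r1, i));
    const char* s2 = NULL;
    int l2 = 0;
    if (paired) { s2 = CHAR(STRING_ELT(m2, i)); l2 = LENGTH(STRING_ELT(m2, i)); }

    bool ok1 = l1 >= idx->k, ok2 = paired && l2 >= idx->k;
    if (!ok1 && !ok2) { frag_class[i] = -1; n_too_short += 1; continue; }

    bool inf1 = ok1 && mate_compat(*idx, s1, l1, c1);
    bool inf2 = ok2 && mate_compat(*idx, s2, l2, c2);

    std::vector<int>* res = NULL;
    if (inf1 && inf2) { intersect_sorted(c1, c2); res = &c1; }
    else if (inf1) res = &c1;
    else if (inf2) res = &c2;

    if (res == NULL || res->empty()) { frag_class[i] = 0; n_unmapped += 1; continue; }

    auto ins = class_of.insert({*res, (int)class_refs.size() + 1});
    if (ins.second) { class_refs.push_back(*res); class_count.push_back(0); }
    int id = ins.first->second;
    class_count[id - 1] += 1;
    frag_class[i] = id;
  }

  List refs_out(class_refs.size());
  for (std::size_t c = 0; c < class_refs.size(); ++c) {
    IntegerVector v(class_refs[c].size());
    for (std::size_t j = 0; j < class_refs[c].size(); ++j) v[j] = class_refs[c][j] + 1;
    refs_out[c] = v;
  }
  return List::create(
    _["class_refs"] = refs_out,
    _["class_count"] = wrap(class_count),
    _["frag_class"] = frag_class,
    _["n_unmapped"] = n_unmapped,
    _["n_too_short"] = n_too_short);
}

// Substitution errors at a fixed per-base rate, drawn from R's RNG so results
// are reproducible under set.seed().  Only A/C/G/T bases are mutated.
// [[Rcpp::export]]
CharacterVector add_errors_cpp(CharacterVector reads, double rate) {
  RNGScope scope;
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = reads.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    buf.assign(s, len);
    for (int j = 0; j < len; ++j) {
      if (R::unif_rand() < rate) {
        int c = base_code(buf[j]);
        if (c < 0) continue;
        int sub = (c + 1 + (int)(R::unif_rand() * 3)) % 4;  // a different base
        buf[j] = bases[sub];
      }
    }
    out[i] = buf;
  }
  return out;
}
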