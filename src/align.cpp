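#include <Rcpp.h>
using namespace Rcpp;

// Ungapped both-strand alignment with a bounded Hamming mismatch count.
// Bases outside {A,C,G,T} (notably N) never match, not even themselves.

static inline bool base_match(char a, char b) {
  if (a != b) return false;
  return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// mismatches of q placed at offset off on ref; early exit once above limit
static inline int mm_at(const std::string& q, const std::string& ref,
                        size_t off, int limit) {
  int mm = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    if (!base_match(q[i], ref[off + i])) {
      if (++mm > limit) return mm;
    }
  }
  return mm;
}

struct Hit {
  int mm;
  int start;
  int strand;   // 0 = plus, 1 = minus
  int ref_idx;  // 0-based input order
};

static inline bool hit_less(const Hit& a, const Hit& b) {
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.start != b.start) return a.start < b.start;
  if (a.strand != b.strand) return a.strand < b.strand;
  return a.ref_idx < b.ref_idx;
}

static void scan_ref(const std::string& q, const std::string& qrc,
                     const std::string& ref, int ref_idx, int max_mm,
                     std::vector<Hit>& out) {
  if (q.size() == 0 || q.size() > ref.size()) return;
  size_t n_off = ref.size() - q.size() + 1;
  for (size_t off = 0; off < n_off; ++off) {
    int mm = mm_at(q, ref, off, max_mm);
    if (mm <= max_mm) out.push_back({mm, (int)off, 0, ref_idx});
    mm = mm_at(qrc, ref, off, max_mm);
    if (mm <= max_mm) out.push_back({mm, (int)off, 1, ref_idx});
  }
}

// All end-to-end placements of one query (both strands) on a set of
// references, sorted by (mismatches, start, + before -, reference order).
// [[Rcpp::export]]
DataFrame cpp_align_all(std::string query, CharacterVector refs, int max_mm) {
  std::string qrc = revcomp(query);
  std::vector<Hit> hits;
  for (int r = 0; r < refs.size(); ++r)
    scan_ref(query, qrc, as<std::string>(refs[r]), r, max_mm, hits);
  std::sort(hits.begin(), hits.end(), hit_less);
  int n = hits.size();
  IntegerVector ref_idx(n), start(n), mm(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    ref_idx[i] = hits[i].ref_idx + 1;
    start[i]   = hits[i].start;
    strand[i]  = hits[i].strand == 0 ? "+" : "-";
    mm[i]      = hits[i].mm;
  }
  return DataFrame::create(_["ref_idx"] = ref_idx, _["start"] = start,
                           _["strand"] = strand, _["mismatches"] = mm);
}

// Hierarchical first-hit-wins assignment: for each query walk the ordered
// reference sets, stop at the first set with >= 1 hit, and report the best
// hit there under the deterministic tie-break. Category 0 = unaligned.
// [[Rcpp::export]]
List cpp_cascade(CharacterVector queries, List ref_sets, int max_mm) {
  int nq = queries.size(), ns = ref_sets.size();
  std::vector<std::vector<std::string>> sets(ns);
  for (int s = 0; s < ns; ++s) {
    CharacterVector cv = ref_sets[s];
    sets[s].reserve(cv.size());
    for (int r = 0; r < cv.size(); ++r)
      sets[s].push_back(as<std::string>(cv[r]));
  }
  IntegerVector category(nq), ref_idx(nq), start(nq), mm(nq);
  CharacterVector strand(nq);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    std::string qrc = revcomp(q);
    bool assigned = false;
    for (int s = 0; s < ns && !assigned; ++s) {
      std::vector<Hit> hits;
      for (size_t r = 0; r < sets[s].size(); ++r)
        scan_ref(q, qrc, sets[s][r], (int)r, max_mm, hits);
      if (!hits.empty()) {
        Hit best = hits[0];
        for (size_t h = 1; h < hits.size(); ++h)
          if (hit_less(hits[h], best)) best = hits[h];
        category[i] = s + 1;
        ref_idx[i]  = best.ref_idx + 1;
        start[i]    = best.start;
        strand[i]   = best.strand == 0 ? "+" : "-";
        mm[i]       = best.mm;
        assigned = true;
      }
    }
    if (!assigned) {
      category[i] = 0;
      ref_idx[i] = NA_INTEGER;
      start[i] = NA_INTEGER;
      mm[i] = NA_INTEGER;
      strand[i] = NA_STRING;
    }
  }
  return List::create(_["category"] = category, _["ref_idx"] = ref_idx,
                      _["start"] = start, _["strand"] = strand,
                      _["mismatches"] = mm);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}
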