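#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

// Gapless seed-and-extend placement of short reads on a single reference.
// The reference may be circular-extended by the caller; positions returned
// are 1-based starts on the (extended) forward strand.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

struct Cand {
  int start;   // 0-based start on reference
  int strand;  // 0 = '+', 1 = '-'
  bool operator<(const Cand& o) const {
    if (start != o.start) return start < o.start;
    return strand < o.strand;
  }
  bool operator==(const Cand& o) const {
    return start == o.start && strand == o.strand;
  }
};

struct Hit {
  int start;
  int strand;
  int matches;
};

// [[Rcpp::export]]
List cpp_place_reads(CharacterVector reads, std::string ref, std::string ref_index,
                     int k, double min_identity, int max_hits, int stride) {
  const int n = reads.size();
  const int reflen = (int) ref.size();

  // k-mer index over ref_index (soft-masked positions appear as non-ACGT and
  // break k-mer runs, so masked regions never seed)
  std::unordered_map<uint64_t, std::vector<int>> index;
  if (reflen >= k) {
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t key = 0;
    int run = 0;
    for (int i = 0; i < reflen; i++) {
      int c = base_code(ref_index[(size_t) i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) c) & mask;
      run++;
      if (run >= k) index[key].push_back(i - k + 1);
    }
  }

  std::vector<int> out_read, out_start, out_alen, out_match;
  std::vector<int> out_strand;

  std::string rc;
  std::vector<Cand> cands;
  std::vector<Hit> hits;

  for (int r = 0; r < n; r++) {
    const char* sp = CHAR(STRING_ELT(reads, r));
    std::string s(sp);
    const int L = (int) s.size();
    if (L < k || L > reflen) continue;

    rc.assign((size_t) L, 'N');
    for (int i = 0; i < L; i++) rc[(size_t) i] = comp_base(s[(size_t)(L - 1 - i)]);

    cands.clear();
    for (int strand = 0; strand < 2; strand++) {
      const std::string& q = (strand == 0) ? s : rc;
      int last_off = L - k;
      for (int off = 0; off <= last_off; off += stride) {
        // always include the final offset so the read tail can seed
        int o = off;
        bool final_extra = false;
        if (off + stride > last_off && off != last_off) final_extra = true;
        for (int pass = 0; pass < (final_extra ? 2 : 1); pass++) {
          if (pass == 1) o = last_off;
          uint64_t key = 0;
          bool ok = true;
          for (int j = 0; j < k; j++) {
            int c = base_code(q[(size_t)(o + j)]);
            if (c < 0) { ok = false; break; }
            key = (key << 2) | (uint64_t) c;
          }
          if (ok) {
            auto it = index.find(key);
            if (it != index.end()) {
              for (int p : it->second) {
                int st = p - o;
                if (st < 0 || st + L > reflen) continue;
                cands.push_back({st, strand});
              }
            }
          }
          if (!final_extra) break;
        }
      }
    }
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    hits.clear();
    for (const Cand& cd : cands) {
      const std::string& q = (cd.strand == 0) ? s : rc;
      int m = 0;
      for (int i = 0; i < L; i++) {
        char a = q[(size_t) i];
        if (a != 'N' && a == ref[(size_t)(cd.start + i)]) m++;
      }
      double ident = (double) m / (double) L;
      if (ident >= min_identity) hits.push_back({cd.start, cd.strand, m});
    }
    if (hits.empty()) continue;

    std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
      if (a.matches != b.matches) return a.matches > b.matches;
      if (a.start != b.start) return a.start < b.start;
      return a.strand < b.strand;
    });
    int keep = std::min((int) hits.size(), max_hits);
    for (int i = 0; i < keep; i++) {
      out_read.push_back(r + 1);
      out_start.push_back(hits[(size_t) i].start + 1);
      out_strand.push_back(hits[(size_t) i].strand);
      out_alen.push_back(L);
      out_match.push_back(hits[(size_t) i].matches);
    }
  }

  return List::create(
    _["read"] = wrap(out_read),
    _["start"] = wrap(out_start),
    _["strand"] = wrap(out_strand),
    _["aligned_length"] = wrap(out_alen),
    _["matches"] = wrap(out_match));
}
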