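#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <set>
#include <cstdint>
using namespace Rcpp;

// Gapless matching of reads against a set of L1 5' reference sequences.
// Substitutions only (no gaps). Seed-and-extend: any gapless match of
// length >= min_len with <= max_mm mismatches contains an exact k-mer with
// k = floor((min_len - max_mm) / (max_mm + 1)), so an exact k-mer index
// over the references finds every qualifying diagonal.

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'a': return 't';
    case 'C': return 'G'; case 'c': return 'g';
    case 'G': return 'C'; case 'g': return 'c';
    case 'T': return 'A'; case 't': return 'a';
    default: return 'N';
  }
}

struct Best {
  int len = 0, mm = 0, ref = -1, ref_off = -1, read_off = -1;
  bool antisense = false;
  // order: longer match wins, then fewer mismatches, then lower ref index,
  // then sense before antisense (all deterministic)
  bool better_than(const Best& o) const {
    if (ref < 0) return false;
    if (o.ref < 0) return true;
    if (len != o.len) return len > o.len;
    if (mm != o.mm) return mm < o.mm;
    if (ref != o.ref) return ref < o.ref;
    return !antisense && o.antisense;
  }
};

// Longest window with <= max_mm mismatches along one diagonal.
// read[i] vs ref[i + diag] for i in [i0, i1).
static void scan_diagonal(const std::string& read, const std::string& ref,
                          int diag, int min_len, int max_mm,
                          int ref_idx, bool antisense, Best& best) {
  int i0 = std::max(0, -diag);
  int i1 = std::min((int)read.size(), (int)ref.size() - diag);
  if (i1 - i0 < min_len) return;
  // two-pointer over mismatch positions
  std::vector<int> mmpos;
  int left = i0, nmm = 0;
  size_t mm_lo = 0; // index into mmpos of first mismatch inside window
  for (int i = i0; i < i1; ++i) {
    char a = read[i], b = ref[i + diag];
    bool is_mm = !(a == b && base2bit(a) >= 0);
    if (is_mm) { mmpos.push_back(i); ++nmm; }
    while (nmm > max_mm) { // shrink from the left past the oldest mismatch
      left = mmpos[mm_lo] + 1;
      ++mm_lo;
      --nmm;
    }
    int len = i - left + 1;
    if (len >= min_len) {
      Best cand;
      cand.len = len; cand.mm = nmm; cand.ref = ref_idx;
      cand.ref_off = left + diag; cand.read_off = left;
      cand.antisense = antisense;
      if (cand.better_than(best)) best = cand;
    }
  }
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > KmerIndex;

static void index_refs(const std::vector<std::string>& refs, int k,
                       KmerIndex& idx) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string& s = refs[r];
    uint64_t key = 0; int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx[key].push_back(std::make_pair((int)r, (int)(i + 1 - k)));
    }
  }
}

static void match_one_orientation(const std::string& read,
                                  const std::vector<std::string>& refs,
                                  const KmerIndex& idx, int k,
                                  int min_len, int max_mm, bool antisense,
                                  Best& best) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::set<std::pair<int, int> > seen; // (ref, diag) already scanned
  uint64_t key = 0; int run = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    int b = base2bit(read[i]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run < k) continue;
    KmerIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    int read_pos = (int)(i + 1 - k);
    for (size_t j = 0; j < it->second.size(); ++j) {
      int r = it->second[j].first;
      int diag = it->second[j].second - read_pos;
      if (seen.insert(std::make_pair(r, diag)).second)
        scan_diagonal(read, refs[r], diag, min_len, max_mm, r, antisense, best);
    }
  }
}

// [[Rcpp::export(name = ".cpp_match_reads")]]
DataFrame cpp_match_reads(CharacterVector reads, CharacterVector refs,
                          int min_len, int max_mm) {
  int k = (min_len - max_mm) / (max_mm + 1);
  if (k < 4) k = 4;
  if (k > 32) k = 32;
  std::vector<std::string> R(refs.size());
  for (int i = 0; i < refs.size(); ++i) R[i] = as<std::string>(refs[i]);
  KmerIndex idx;
  index_refs(R, k, idx);

  int n = reads.size();
  IntegerVector ref_index(n), len(n), mm(n), ref_off(n), read_off(n);
  LogicalVector anti(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    Best best;
    match_one_orientation(s, R, idx, k, min_len, max_mm, false, best);
    std::string rc(s.rbegin(), s.rend());
    for (size_t j = 0; j < rc.size(); ++j) rc[j] = comp(rc[j]);
    match_one_orientation(rc, R, idx, k, min_len, max_mm, true, best);
    if (best.ref < 0) {
      ref_index[i] = NA_INTEGER; len[i] = NA_INTEGER; mm[i] = NA_INTEGER;
      ref_off[i] = NA_INTEGER; read_off[i] = NA_INTEGER; anti[i] = NA_LOGICAL;
    } else {
      ref_index[i] = best.ref + 1;
      len[i] = best.len; mm[i] = best.mm;
      ref_off[i] = best.ref_off; read_off[i] = best.read_off;
      anti[i] = best.antisense;
    }
  }
  return DataFrame::create(
    _["ref_index"] = ref_index, _["match_length"] = len,
    _["mismatches"] = mm, _["ref_offset"] = ref_off,
    _["read_offset"] = read_off, _["antisense"] = anti,
    _["stringsAsFactors"] = false);
}
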