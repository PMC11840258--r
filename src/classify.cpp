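// k-mer index over a transcript set and read -> equivalence-class assignment.
//
// Reads from a near-identical gene family hit dozens to thousands of
// transcripts, so per-kmer voting over the whole read is too slow. Instead,
// candidates come from max_mismatches+1 pairwise-disjoint anchor k-mers: a
// transcript matching the read with <= max_mismatches substitutions must be
// mismatch-free on at least one anchor window (pigeonhole), hence appears in
// that anchor's hit list at the implied offset. Every candidate
// (transcript, offset) is then verified by exact mismatch counting with
// early exit; the equivalence class is the set of transcripts attaining the
// minimal mismatch count (<= max_mismatches). Completeness requires
// read length >= (max_mismatches + 1) * k; shorter reads fall back to fewer
// anchors (still exact for the candidates found).

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <sstream>
#include <cstring>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;
  // kmer -> list of (transcript index, position), both 0-based
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> map;
};

// enumerate valid (ACGT-only) k-mers of s, calling f(code, pos)
template <typename F>
static void for_each_kmer(const std::string& s, int k, F f) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;  // valid bases accumulated
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) f(code, i - k + 1);
  }
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector sequences, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->seqs.reserve(sequences.size());
  for (R_xlen_t i = 0; i < sequences.size(); ++i)
    idx->seqs.push_back(as<std::string>(sequences[i]));
  for (int t = 0; t < (int)idx->seqs.size(); ++t) {
    for_each_kmer(idx->seqs[t], k, [&](uint64_t code, int pos) {
      idx->map[code].emplace_back(t, pos);
    });
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
IntegerVector cpp_lookup_kmer(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  if ((int)kmer.size() != idx->k) stop("query length must equal k");
  uint64_t code = 0;
  for (char c : kmer) {
    int b = base_code(c);
    if (b < 0) return IntegerVector(0);
    code = (code << 2) | (uint64_t)b;
  }
  auto it = idx->map.find(code);
  if (it == idx->map.end()) return IntegerVector(0);
  std::vector<int> tids;
  for (auto& p : it->second) tids.push_back(p.first + 1);  // 1-based
  std::sort(tids.begin(), tids.end());
  tids.erase(std::unique(tids.begin(), tids.end()), tids.end());
  return wrap(tids);
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return (int)idx->map.size();
}

static inline int count_mismatches(const std::string& read,
                                   const std::string& seq,
                                   int offset, int cap) {
  const int L = (int)read.size();
  if (std::memcmp(read.data(), seq.data() + offset, L) == 0) return 0;
  int mm = 0;
  for (int i = 0; i < L; ++i) {
    if (read[i] != seq[offset + i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

static bool kmer_code_at(const std::string& s, int pos, int k, uint64_t* out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[pos + i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  *out = code;
  return true;
}

// [[Rcpp::export]]
List cpp_classify(SEXP xp, CharacterVector reads, int max_mismatches) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  const R_xlen_t n = reads.size();
  IntegerVector class_id(n, NA_INTEGER);
  IntegerVector best_mm(n, NA_INTEGER);

  // per-read scratch, epoch-marked so no clearing is needed between reads
  const int nT = (int)idx->seqs.size();
  std::vector<int> mark(nT, -1), mm_of(nT), off_of(nT);
  std::vector<int> cand, class_tids;
  // distinct equivalence classes, keyed by the raw bytes of the sorted
  // member vector
  std::unordered_map<std::string, int> class_ids;
  std::vector<std::vector<int>> class_members;
  // identical reads are frequent at depth: memoise read -> (class, mm)
  std::unordered_map<std::string, std::pair<int, int>> memo;

  for (R_xlen_t r = 0; r < n; ++r) {
    const char* rp = CHAR(STRING_ELT(reads, r));
    std::string read(rp);
    const int L = (int)read.size();
    if (L < k) continue;
    auto hit_memo = memo.find(read);
    if (hit_memo != memo.end()) {
      if (hit_memo->second.first > 0) {
        class_id[r] = hit_memo->second.first;
        best_mm[r] = hit_memo->second.second;
      }
      continue;
    }

    int a = std::min(max_mismatches + 1, L / k);
    if (a < 1) a = 1;

    cand.clear();
    int best = max_mismatches + 2;
    for (int i = 0; i < a; ++i) {
      int p = (a == 1) ? 0 : (int)((long long)i * (L - k) / (a - 1));
      uint64_t code;
      if (!kmer_code_at(read, p, k, &code)) continue;
      auto it = idx->map.find(code);
      if (it == idx->map.end()) continue;
      for (auto& hit : it->second) {
        const int tid = hit.first;
        int off = hit.second - p;
        if (off < 0) continue;
        if (off + L > (int)idx->seqs[tid].size()) continue;
        if (mark[tid] == (int)r) {
          if (off == off_of[tid]) continue;      // same anchor window again
          int mm = count_mismatches(read, idx->seqs[tid], off, max_mismatches);
          if (mm < mm_of[tid]) mm_of[tid] = mm;
          if (mm < best) best = mm;
          continue;
        }
        mark[tid] = (int)r;
        off_of[tid] = off;
        int mm = count_mismatches(read, idx->seqs[tid], off, max_mismatches);
        mm_of[tid] = mm;
        cand.push_back(tid);
        if (mm < best) best = mm;
      }
    }
    if (best > max_mismatches) {
      memo.emplace(std::move(read), std::make_pair(0, 0));
      continue;
    }

    // class = every transcript within max_mismatches, with its mismatch
    // count; encoded as tid * (max_mm + 1) + mm so one sorted int vector
    // uniquely keys the weighted class
    class_tids.clear();
    for (int tid : cand)
      if (mm_of[tid] <= max_mismatches)
        class_tids.push_back(tid * (max_mismatches + 1) + mm_of[tid]);
    std::sort(class_tids.begin(), class_tids.end());

    std::string key((const char*)class_tids.data(),
                    class_tids.size() * sizeof(int));
    auto ins = class_ids.emplace(std::move(key), (int)class_members.size() + 1);
    if (ins.second) class_members.push_back(class_tids);
    class_id[r] = ins.first->second;
    best_mm[r] = best;
    memo.emplace(std::move(read), std::make_pair(ins.first->second, best));
  }
  const int mstride = max_mismatches + 1;
  List classes(class_members.size());
  List class_mm(class_members.size());
  for (size_t i = 0; i < class_members.size(); ++i) {
    const std::vector<int>& cm = class_members[i];
    IntegerVector tids(cm.size()), mms(cm.size());
    for (size_t j = 0; j < cm.size(); ++j) {
      tids[j] = cm[j] / mstride + 1;
      mms[j] = cm[j] % mstride;
    }
    classes[i] = tids;
    class_mm[i] = mms;
  }
  return List::create(_["class_id"] = class_id, _["best_mm"] = best_mm,
                      _["classes"] = classes, _["class_mm"] = class_mm);
}

// Minimal-mismatch split of a read between two anchored parents.
// mml[b] = mismatches of read[0..b) vs left parent, mmr[b] = of read[b..L).
// Returns the b in [0, L] minimising mml[b] + mmr[b] (ties -> smallest b).

// [[Rcpp::export]]
IntegerVector cpp_best_split(std::string read, std::string left, std::string right,
                             int off_left, int off_right) {
  const int L = (int)read.size();
  if (off_left < 0 || off_left + L > (int)left.size() ||
      off_right < 0 || off_right + L > (int)right.size())
    stop("anchored window out of range");
  std::vector<int> mml(L + 1, 0), mmr(L + 1, 0);
  for (int i = 0; i < L; ++i)
    mml[i + 1] = mml[i] + (read[i] != left[off_left + i]);
  for (int i = L - 1; i >= 0; --i)
    mmr[i] = mmr[i + 1] + (read[i] != right[off_right + i]);
  int best_b = 0, best_tot = mml[0] + mmr[0];
  for (int b = 1; b <= L; ++b) {
    int tot = mml[b] + mmr[b];
    if (tot < best_tot) { best_tot = tot; best_b = b; }
  }
  return IntegerVector::create(best_b, mml[best_b], mmr[best_b]);
}

// Best ungapped anchoring offset of a read against one sequence
// (minimal full-length mismatches; ties -> smallest offset).

// [[Rcpp::export]]
IntegerVector cpp_best_offset(std::string read, std::string seq) {
  const int L = (int)read.size(), n = (int)seq.size();
  if (n < L) return IntegerVector::create(NA_INTEGER, NA_INTEGER);
  int best_off = 0, best_mm = L + 1;
  for (int off = 0; off + L <= n; ++off) {
    int mm = count_mismatches(read, seq, off, best_mm - 1);
    if (mm < best_mm) { best_mm = mm; best_off = off; }
  }
  return IntegerVector::create(best_off, best_mm);
}
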