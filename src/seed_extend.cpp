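#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit base code; -1 for anything not A/C/G/T (case-insensitive).
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'a': return 't';
    case 'C': return 'G'; case 'c': return 'g';
    case 'G': return 'C'; case 'g': return 'c';
    case 'T': return 'A'; case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

struct SeedLoc { int32_t subj; int32_t pos; };

// Ungapped x-drop extension to the right of (qi, sj) exclusive.
// Returns best offset (number of columns taken) and match count at best.
static inline void extend_dir(const std::string& q, const std::string& s,
                              long qi, long sj, int dir, double xdrop,
                              long& best_cols, long& best_matches) {
  double score = 0.0, best = 0.0;
  long cols = 0, matches = 0, bm = 0;
  long i = qi, j = sj;
  while (i >= 0 && j >= 0 && i < (long)q.size() && j < (long)s.size()) {
    bool m = (q[i] == s[j]) ||
             (base_code(q[i]) >= 0 && base_code(q[i]) == base_code(s[j]));
    score += m ? 1.0 : -1.0;
    ++cols; if (m) ++matches;
    if (score > best) { best = score; best_cols = cols; bm = matches; }
    if (best - score > xdrop) break;
    i += dir; j += dir;
  }
  best_matches = bm;
}

// Scan queries against an indexed subject set with exact k-mer seeds and
// ungapped x-drop extension. Coordinates in the output are 0-based
// half-open; query coordinates always refer to the original (plus) query
// orientation; strand -1 means the reverse complement of the query aligned
// to the subject's forward strand.
// [[Rcpp::export(name = ".seed_extend_scan")]]
DataFrame seed_extend_scan(CharacterVector queries, CharacterVector subjects,
                           int k, double min_identity, int min_hit_len,
                           double xdrop, bool both_strands = true) {
  if (k < 4 || k > 31) stop("seed_k must be in [4, 31]");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::vector<std::string> subj(subjects.size());
  for (int i = 0; i < subjects.size(); ++i) subj[i] = as<std::string>(subjects[i]);

  // k-mer index over subjects (forward strand only)
  std::unordered_map<uint64_t, std::vector<SeedLoc>> index;
  for (int si = 0; si < (int)subj.size(); ++si) {
    const std::string& s = subj[si];
    if ((int)s.size() < k) continue;
    uint64_t km = 0; int run = 0;
    for (long j = 0; j < (long)s.size(); ++j) {
      int c = base_code(s[j]);
      if (c < 0) { run = 0; km = 0; continue; }
      km = ((km << 2) | (uint64_t)c) & mask;
      if (++run >= k)
        index[km].push_back(SeedLoc{si, (int32_t)(j - k + 1)});
    }
  }

  std::vector<int> o_query, o_subject, o_strand;
  std::vector<long> o_qs, o_qe, o_ss, o_se, o_len, o_match;
  std::vector<double> o_score;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string qfwd = as<std::string>(queries[qi]);
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::string q = (strand == 0) ? qfwd : revcomp_str(qfwd);
      if ((long)q.size() < k) continue;
      // per (subject, diagonal) rightmost query position already covered
      std::unordered_map<uint64_t, long> covered;
      uint64_t km = 0; int run = 0;
      for (long p = 0; p < (long)q.size(); ++p) {
        int c = base_code(q[p]);
        if (c < 0) { run = 0; km = 0; continue; }
        km = ((km << 2) | (uint64_t)c) & mask;
        if (++run < k) continue;
        long qp = p - k + 1;
        auto it = index.find(km);
        if (it == index.end()) continue;
        for (const SeedLoc& loc : it->second) {
          const std::string& s = subj[loc.subj];
          long sp = loc.pos;
          long diag = qp - sp;
          uint64_t dkey = ((uint64_t)(uint32_t)loc.subj << 33) ^
                          (uint64_t)(diag + (1L << 31));
          auto cv = covered.find(dkey);
          if (cv != covered.end() && qp + k <= cv->second) continue;
          long rc = 0, rm = 0, lc = 0, lm = 0;
          extend_dir(q, s, qp + k, sp + k, +1, xdrop, rc, rm);
          extend_dir(q, s, qp - 1, sp - 1, -1, xdrop, lc, lm);
          long qs = qp - lc, qe = qp + k + rc;       // half-open on q
          long ss = sp - lc, se = sp + k + rc;       // half-open on s
          long len = qe - qs;
          long matches = k + lm + rm;
          covered[dkey] = std::max(cv == covered.end() ? 0L : cv->second, qe);
          if (len < min_hit_len) continue;
          double ident = (double)matches / (double)len;
          if (ident < min_identity) continue;
          long oqs = qs, oqe = qe;
          if (strand == 1) { oqs = (long)q.size() - qe; oqe = (long)q.size() - qs; }
          o_query.push_back(qi + 1);
          o_subject.push_back(loc.subj + 1);
          o_strand.push_back(strand == 0 ? 1 : -1);
          o_qs.push_back(oqs); o_qe.push_back(oqe);
          o_ss.push_back(ss);  o_se.push_back(se);
          o_len.push_back(len); o_match.push_back(matches);
          o_score.push_back((double)matches - (double)(len - matches));
        }
      }
    }
  }

  long n = (long)o_query.size();
  IntegerVector query(n), subject(n), strandv(n);
  NumericVector qs(n), qe(n), ss(n), se(n), len(n), matches(n), score(n), ident(n);
  for (long i = 0; i < n; ++i) {
    query[i] = o_query[i]; subject[i] = o_subject[i]; strandv[i] = o_strand[i];
    qs[i] = o_qs[i]; qe[i] = o_qe[i]; ss[i] = o_ss[i]; se[i] = o_se[i];
    len[i] = o_len[i]; matches[i] = o_match[i]; score[i] = o_score[i];
    ident[i] = (double)o_match[i] / (double)o_len[i];
  }
  return DataFrame::create(
    _["query"] = query, _["subject"] = subject, _["strand"] = strandv,
    _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["length"] = len, _["matches"] = matches, _["identity"] = ident,
    _["score"] = score, _["stringsAsFactors"] = false);
}
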