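#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Unit-cost Levenshtein distance between a and b, capped at cap.
// Returns min(distance, cap + 1); early abandon once every cell of a
// DP row exceeds cap.
static int lv_capped(const char* a, int na, const char* b, int nb, int cap) {
  if (cap < 0) cap = na + nb;
  if (std::abs(na - nb) > cap) return cap + 1;
  std::vector<int> prev(nb + 1), cur(nb + 1);
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    int rowmin = cur[0];
    for (int j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
      if (cur[j] < rowmin) rowmin = cur[j];
    }
    if (rowmin > cap) return cap + 1;
    std::swap(prev, cur);
  }
  return std::min(prev[nb], cap + 1);
}

//' Capped unit-cost Levenshtein distance
//'
//' Edit distance (substitution, insertion and deletion each cost 1)
//' between two strings, capped at `cap`: values larger than `cap` are
//' reported as `cap + 1`, which allows early termination.  `cap = -1`
//' computes the exact distance.
//'
//' @param a,b character strings.
//' @param cap integer cap (>= 0), or -1 for no cap.
//' @return integer distance, at most `cap + 1`.
//' @keywords internal
// [[Rcpp::export]]
int cs_edit_distance(std::string a, std::string b, int cap = -1) {
  return lv_capped(a.c_str(), (int) a.size(), b.c_str(), (int) b.size(), cap);
}

//' Edit distance of every fixed-length window of a read to a pattern
//'
//' For each start position p = 0..(L - window_len) computes the capped
//' Levenshtein distance between read[p, p + window_len) and `pattern`.
//'
//' @param read,pattern character strings.
//' @param window_len window length in bases.
//' @param cap distance cap (distances above it reported as `cap + 1`).
//' @return integer vector of length `max(0, nchar(read) - window_len + 1)`.
//' @keywords internal
// [[Rcpp::export]]
IntegerVector cs_window_distances(std::string read, std::string pattern,
                                  int window_len, int cap) {
  int L = (int) read.size();
  int n = L - window_len + 1;
  if (n < 1) return IntegerVector(0);
  IntegerVector out(n);
  const char* r = read.c_str();
  const char* p = pattern.c_str();
  int np = (int) pattern.size();
  for (int i = 0; i < n; ++i)
    out[i] = lv_capped(r + i, window_len, p, np, cap);
  return out;
}

//' Greedy adapter scan of one read
//'
//' Implements the declared scanning semantics: left-to-right greedy
//' walk; full windows compared to the adapter and its reverse
//' complement at threshold `k`; shortened terminal windows (at least
//' `min_term` bases) compared to adapter prefixes at the scaled
//' threshold `ceil(k * len / w)`; on entering a contiguous qualifying
//' run the hit is placed at the run's leftmost minimum-distance
//' position (exploring at most `w` positions ahead); scanning resumes
//' at the hit end.
//'
//' @param read,adapter,adapter_rc character strings.
//' @param k maximum edit distance for a full window.
//' @param w window length.
//' @param min_term minimum terminal window length.
//' @return integer matrix with columns start, end (0-based half-open),
//'   distance, forward (1 forward / 0 revcomp), tie.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix cs_scan(std::string read, std::string adapter,
                      std::string adapter_rc, int k, int w, int min_term) {
  int L = (int) read.size();
  std::vector<int> h_start, h_end, h_dist, h_fwd, h_tie;
  if (L >= min_term) {
    int n_full = L - w + 1;            // may be <= 0
    int tail_hi = L - min_term;        // last scannable start
    const char* r = read.c_str();
    const char* af = adapter.c_str();
    const char* ar = adapter_rc.c_str();
    int na = (int) adapter.size();

    // distance of the window starting at p (0-based) in both
    // orientations, plus the threshold applying there
    auto probe = [&](int p, int& fd, int& rd, int& thr) {
      if (p < n_full) {
        thr = k;
        fd = lv_capped(r + p, w, af, na, k);
        rd = lv_capped(r + p, w, ar, na, k);
      } else {
        int rem = L - p;
        thr = (int) std::ceil((double) k * rem / w);
        fd = lv_capped(r + p, rem, af, rem, thr);
        rd = lv_capped(r + p, rem, ar, rem, thr);
      }
    };

    int p = 0;
    while (p <= tail_hi) {
      int fd, rd, thr;
      probe(p, fd, rd, thr);
      int d = std::min(fd, rd);
      if (d > thr) { ++p; continue; }
      int best_p = p, best_f = fd, best_r = rd, best_d = d;
      for (int q = p + 1; q <= tail_hi && q < p + w; ++q) {
        int fq, rq, tq;
        probe(q, fq, rq, tq);
        int dq = std::min(fq, rq);
        if (dq > tq) break;
        if (dq < best_d) { best_p = q; best_f = fq; best_r = rq; best_d = dq; }
      }
      int end = (best_p < n_full) ? best_p + w : L;
      h_start.push_back(best_p);
      h_end.push_back(end);
      h_dist.push_back(best_d);
      h_fwd.push_back(best_f <= best_r ? 1 : 0);
      h_tie.push_back(best_f == best_r ? 1 : 0);
      p = end;
    }
  }
  int n = (int) h_start.size();
  IntegerMatrix out(n, 5);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = h_start[i]; out(i, 1) = h_end[i]; out(i, 2) = h_dist[i];
    out(i, 3) = h_fwd[i]; out(i, 4) = h_tie[i];
  }
  colnames(out) = CharacterVector::create("start", "end", "distance",
                                          "forward", "tie");
  return out;
}
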