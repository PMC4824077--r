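// Seed-and-extend alignment of 5'-tagged reads against a small gene region,
// with optional single splicing at annotated donor/acceptor sites.
//
// Each splice combination is materialised as a "layout" (concatenated
// gene-forward sequence). For a read of length m and edit budget
// e = floor(max_edit_frac * m), e+1 non-overlapping k-mer chunks with
// k = floor(m / (e+1)) are looked up in a per-layout k-mer index; by the
// pigeonhole principle every placement with <= e edits leaves at least one
// chunk exact, so the seeded search is equivalent to exhaustive search
// within the budget. Candidate diagonals are merged into windows and a
// reversed semi-global DP yields, for every candidate start s, the minimal
// edit distance of the full read aligned to the layout starting exactly at
// s (free 3' end). All optimal placements are enumerated; placements that
// differ after splice normalisation make the read "ambiguous".

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <set>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base2code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static void build_index(const std::string &seq, int k, KmerIndex &idx) {
  const int n = (int)seq.size();
  if (n < k) return;
  uint64_t key = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base2code(seq[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid >= k) idx[key].push_back(i - k + 1);
  }
}

struct Placement {
  int layout;   // index into layouts (0 = contiguous) after normalisation
  int tss_idx;  // 1-based gene-forward index of the TSS base
  int start;    // 0-based start in the ORIGINAL layout
  int orig_layout;
};

// anchored-start traceback: read global, layout consumed from 'start',
// free end. The canonical path prefers diagonal, then deletion, then
// insertion (walking backward from the smallest optimal end column), which
// makes the first-matched-base TSS and the edit breakdown deterministic.
struct TraceOut {
  int nmis, nins, ndel, ref_len;
  int first_match_off;  // ref offset (from start) of the first matched base
  int min_edit_dist;    // min |edit ref offset - first_match_off|
};

static TraceOut traceback(const std::string &read, const std::string &lay,
                          int start, int emax) {
  const int m = (int)read.size();
  const int w = std::min((int)lay.size() - start, m + emax);
  std::vector<int> D((m + 1) * (w + 1));
  const int W = w + 1;
  for (int j = 0; j <= w; ++j) D[j] = j;
  for (int i = 1; i <= m; ++i) {
    D[i * W] = i;
    const char rc = read[i - 1];
    for (int j = 1; j <= w; ++j) {
      int sub = D[(i - 1) * W + j - 1] + (rc != lay[start + j - 1]);
      int up = D[(i - 1) * W + j] + 1;       // insertion (read base unmatched)
      int left = D[i * W + j - 1] + 1;        // deletion (ref base skipped)
      D[i * W + j] = std::min(sub, std::min(up, left));
    }
  }
  int jbest = 0, best = D[m * W];
  for (int j = 1; j <= w; ++j) if (D[m * W + j] < best) { best = D[m * W + j]; jbest = j; }
  TraceOut out = {0, 0, 0, jbest, 0, INT_MAX};
  std::vector<int> edit_offs;
  int i = m, j = jbest;
  int fmo = -1;
  while (i > 0 || j > 0) {
    int cur = D[i * W + j];
    if (i > 0 && j > 0 && cur == D[(i - 1) * W + j - 1] + (read[i - 1] != lay[start + j - 1])) {
      if (read[i - 1] != lay[start + j - 1]) {
        out.nmis++; edit_offs.push_back(j - 1);
      } else {
        fmo = j - 1;  // final assignment = earliest match in forward order
      }
      --i; --j;
    } else if (j > 0 && cur == D[i * W + j - 1] + 1) {
      out.ndel++; edit_offs.push_back(j - 1);
      --j;
    } else {
      out.nins++; edit_offs.push_back(j);
      --i;
    }
  }
  out.first_match_off = (fmo >= 0) ? fmo : 0;
  for (size_t t = 0; t < edit_offs.size(); ++t) {
    int d = edit_offs[t] - out.first_match_off;
    if (d < 0) d = -d;
    if (d < out.min_edit_dist) out.min_edit_dist = d;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_align_batch(CharacterVector seqs, CharacterVector layout_seqs,
                          IntegerVector layout_junction,
                          IntegerVector layout_delta,
                          double max_edit_frac, int min_len) {
  const int n = seqs.size();
  const int nlay = layout_seqs.size();
  std::vector<std::string> lays(nlay);
  for (int l = 0; l < nlay; ++l) lays[l] = as<std::string>(layout_seqs[l]);

  // lazily built indexes: per layout, per k
  std::vector<std::map<int, KmerIndex> > indexes(nlay);

  IntegerVector status(n), tss_idx(n), layout_out(n), edits(n),
      nmis(n), nins(n), ndel(n), ref_len(n), min_edit_off(n);

  for (int r = 0; r < n; ++r) {
    const std::string read = as<std::string>(seqs[r]);
    const int m = (int)read.size();
    status[r] = 0; tss_idx[r] = NA_INTEGER; layout_out[r] = NA_INTEGER;
    edits[r] = NA_INTEGER; nmis[r] = NA_INTEGER; nins[r] = NA_INTEGER;
    ndel[r] = NA_INTEGER; ref_len[r] = NA_INTEGER; min_edit_off[r] = NA_INTEGER;

    if (m < min_len) { status[r] = 1; continue; }
    const int emax = (int)std::floor(max_edit_frac * m);
    int k = m / (emax + 1);
    if (k > 16) k = 16;
    if (k < 1) k = 1;

    // chunk k-mers of the read
    std::vector<uint64_t> chunk_keys;
    std::vector<int> chunk_off;
    for (int c = 0; c <= emax; ++c) {
      int off = c * k;
      if (off + k > m) break;
      uint64_t key = 0; bool ok = true;
      for (int t = 0; t < k; ++t) {
        int b = base2code(read[off + t]);
        if (b < 0) { ok = false; break; }
        key = (key << 2) | (uint64_t)b;
      }
      if (ok) { chunk_keys.push_back(key); chunk_off.push_back(off); }
    }

    int best = emax + 1;
    // candidate starts per layout with their anchored distances
    std::vector<std::vector<std::pair<int, int> > > cand(nlay); // (start, dist)

    for (int l = 0; l < nlay; ++l) {
      const std::string &lay = lays[l];
      const int Llay = (int)lay.size();
      if (indexes[l].find(k) == indexes[l].end()) {
        build_index(lay, k, indexes[l][k]);
      }
      KmerIndex &idx = indexes[l][k];
      std::set<int> diags;
      for (size_t c = 0; c < chunk_keys.size(); ++c) {
        KmerIndex::const_iterator it = idx.find(chunk_keys[c]);
        if (it == idx.end()) continue;
        const std::vector<int> &hits = it->second;
        for (size_t h = 0; h < hits.size(); ++h) {
          int d = hits[h] - chunk_off[c];
          if (d >= -emax && d < Llay) diags.insert(d);
        }
      }
      if (diags.empty()) continue;

      // merge diagonals whose +-emax start ranges overlap
      std::vector<int> dv(diags.begin(), diags.end());
      size_t i0 = 0;
      while (i0 < dv.size()) {
        size_t i1 = i0;
        while (i1 + 1 < dv.size() && dv[i1 + 1] - dv[i1] <= 2 * emax) ++i1;
        int lo = std::max(0, dv[i0] - emax);
        int hi = std::min(Llay - 1, dv[i1] + emax);
        if (hi >= lo) {
          // window of layout covering every alignment starting in [lo, hi]
          int wend = std::min(Llay - 1, hi + m + emax - 1);
          int wl = wend - lo + 1;
          // reversed semi-global DP: row i over reversed read, free prefix
          // in reversed window; final row gives anchored-start distances
          std::vector<int> prev(wl + 1), cur(wl + 1);
          for (int j = 0; j <= wl; ++j) prev[j] = 0;
          for (int i = 1; i <= m; ++i) {
            cur[0] = i;
            const char rc = read[m - i];
            int rowmin = cur[0];
            for (int j = 1; j <= wl; ++j) {
              int sub = prev[j - 1] + (rc != lay[wend - (j - 1)]);
              int up = prev[j] + 1;
              int left = cur[j - 1] + 1;
              int v = std::min(sub, std::min(up, left));
              cur[j] = v;
              if (v < rowmin) rowmin = v;
            }
            std::swap(prev, cur);
            if (rowmin > emax) { prev[0] = -1; break; } // band exceeded
          }
          if (prev[0] != -1) {
            for (int j = 1; j <= wl; ++j) {
              int s = wend - (j - 1);
              if (s < lo || s > hi) continue;
              int v = prev[j];
              if (v <= emax) {
                cand[l].push_back(std::make_pair(s, v));
                if (v < best) best = v;
              }
            }
          }
        }
        i0 = i1 + 1;
      }
    }

    if (best > emax) { status[r] = 2; continue; }

    // enumerate optimal placements; the TSS of each is the first MATCHED
    // reference base of its canonical traceback, which collapses the
    // boundary-edit shift variants (leading insertions vs leading
    // mismatches) onto one call; spliced placements that do not cross the
    // junction are normalised onto the contiguous layout
    std::vector<Placement> opt;
    std::vector<TraceOut> traces;
    for (int l = 0; l < nlay; ++l) {
      for (size_t c = 0; c < cand[l].size(); ++c) {
        if (cand[l][c].second != best) continue;
        Placement p;
        p.orig_layout = l;
        p.start = cand[l][c].first;
        TraceOut t = traceback(read, lays[l], p.start, emax);
        int q1 = p.start + t.first_match_off + 1;  // 1-based layout pos of TSS
        int ref_end1 = p.start + t.ref_len;        // 1-based last consumed pos
        int junc = layout_junction[l];
        bool crossing = junc >= 0 && p.start + 1 <= junc && ref_end1 > junc;
        p.layout = crossing ? l : 0;
        p.tss_idx = (junc < 0 || q1 <= junc) ? q1 : q1 + layout_delta[l];
        opt.push_back(p);
        traces.push_back(t);
      }
    }
    std::set<std::pair<int, int> > distinct;
    for (size_t t = 0; t < opt.size(); ++t) {
      distinct.insert(std::make_pair(opt[t].tss_idx, opt[t].layout));
    }
    if (distinct.size() > 1) { status[r] = 3; continue; }

    const Placement &p = opt[0];
    const TraceOut &t = traces[0];
    status[r] = 0;
    tss_idx[r] = p.tss_idx;
    layout_out[r] = p.layout;
    edits[r] = best;
    nmis[r] = t.nmis; nins[r] = t.nins; ndel[r] = t.ndel;
    ref_len[r] = t.ref_len;
    min_edit_off[r] = (t.min_edit_dist == INT_MAX) ? -1 : t.min_edit_dist;
  }

  return DataFrame::create(
    _["status"] = status, _["tss_idx"] = tss_idx, _["layout"] = layout_out,
    _["edits"] = edits, _["n_mismatch"] = nmis, _["n_insertion"] = nins,
    _["n_deletion"] = ndel, _["aligned_ref_len"] = ref_len,
    _["min_edit_offset"] = min_edit_off);
}
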