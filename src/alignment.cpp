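#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh). A gap of length g costs
// gap_open + g * gap_extend (both <= 0), so a linear gap model is
// gap_open = 0. Returns the single best-scoring local alignment with an
// explicit column map (query/subject position per alignment column, -1 at
// gaps) so intervals can be projected between coordinate systems.

static inline double score_pair(char a, char b, double match, double mismatch) {
  return a == b ? match : mismatch;
}

// [[Rcpp::export(rng = false)]]
List sw_align_cpp(std::string q, std::string s,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  const double gopen = gap_open + gap_extend; // cost of first gapped column
  std::vector<double> H((m + 1) * (n + 1), 0.0);
  std::vector<double> E((m + 1) * (n + 1), R_NegInf);
  std::vector<double> F((m + 1) * (n + 1), R_NegInf);
  // trace: 0 stop, 1 diag, 2 E (gap in query, consume subject),
  //        3 F (gap in subject, consume query)
  std::vector<uint8_t> trH((m + 1) * (n + 1), 0);
  std::vector<uint8_t> trE((m + 1) * (n + 1), 0); // 1 = opened from H
  std::vector<uint8_t> trF((m + 1) * (n + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int id = i * (n + 1) + j;
      const int up = (i - 1) * (n + 1) + j, lf = id - 1, dg = up - 1;
      double e_open = H[lf] + gopen, e_ext = E[lf] + gap_extend;
      E[id] = e_open >= e_ext ? e_open : e_ext;
      trE[id] = e_open >= e_ext ? 1 : 0;
      double f_open = H[up] + gopen, f_ext = F[up] + gap_extend;
      F[id] = f_open >= f_ext ? f_open : f_ext;
      trF[id] = f_open >= f_ext ? 1 : 0;
      double diag = H[dg] + score_pair(q[i - 1], s[j - 1], match, mismatch);
      double h = 0.0; uint8_t t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[id] > h) { h = E[id]; t = 2; }
      if (F[id] > h) { h = F[id]; t = 3; }
      H[id] = h; trH[id] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> qmap, smap;
  int i = bi, j = bj;
  if (best > 0) {
    uint8_t layer = 0; // 0 = H
    while (i > 0 && j > 0) {
      const int id = i * (n + 1) + j;
      if (layer == 0) {
        uint8_t t = trH[id];
        if (t == 0) break;
        if (t == 1) { qmap.push_back(i - 1); smap.push_back(j - 1); --i; --j; }
        else if (t == 2) layer = 2;
        else layer = 3;
      } else if (layer == 2) { // gap in query, subject char consumed
        qmap.push_back(-1); smap.push_back(j - 1);
        if (trE[id] == 1) layer = 0;
        --j;
      } else { // gap in subject, query char consumed
        qmap.push_back(i - 1); smap.push_back(-1);
        if (trF[id] == 1) layer = 0;
        --i;
      }
    }
    std::reverse(qmap.begin(), qmap.end());
    std::reverse(smap.begin(), smap.end());
  }

  IntegerVector qm(qmap.size()), sm(smap.size());
  for (size_t k = 0; k < qmap.size(); ++k) {
    qm[k] = qmap[k] == -1 ? NA_INTEGER : qmap[k];
    sm[k] = smap[k] == -1 ? NA_INTEGER : smap[k];
  }
  int q_begin = best > 0 ? i : 0, q_end = best > 0 ? bi : 0;
  int s_begin = best > 0 ? j : 0, s_end = best > 0 ? bj : 0;
  return List::create(_["score"] = best,
                      _["q_begin"] = q_begin, _["q_end"] = q_end,
                      _["s_begin"] = s_begin, _["s_end"] = s_end,
                      _["qmap"] = qm, _["smap"] = sm);
}

// ---- k-mer seeded ungapped read mapper -------------------------------------

static inline int base2bits(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) { case 'A': c = 'T'; break; case 'C': c = 'G'; break;
                 case 'G': c = 'C'; break; case 'T': c = 'A'; break; }
  }
  return r;
}

struct Seed { int contig; int pos; };

// Placement candidates come from exact hits of the read's first and last
// k-mer (both strands); each candidate is verified by full-length ungapped
// mismatch counting. Ties at the best mismatch count on different contigs
// mark the read ambiguous; ties within one contig resolve to the leftmost
// position, plus strand first.
// [[Rcpp::export(rng = false)]]
DataFrame map_reads_cpp(CharacterVector read_ids, CharacterVector read_seqs,
                        CharacterVector contig_ids, CharacterVector contig_seqs,
                        int k, int max_mismatch) {
  const int nc = contig_seqs.size(), nr = read_seqs.size();
  std::vector<std::string> contigs(nc);
  for (int c = 0; c < nc; ++c) contigs[c] = as<std::string>(contig_seqs[c]);

  std::unordered_map<uint64_t, std::vector<Seed>> index;
  for (int c = 0; c < nc; ++c) {
    const std::string& seq = contigs[c];
    if ((int)seq.size() < k) continue;
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (int p = 0; p < (int)seq.size(); ++p) {
      int b = base2bits(seq[p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) index[key].push_back({c, p - k + 1});
    }
  }

  auto kmer_key = [&](const std::string& s, int pos, bool& ok) {
    uint64_t key = 0; ok = true;
    for (int p = pos; p < pos + k; ++p) {
      int b = base2bits(s[p]);
      if (b < 0) { ok = false; return (uint64_t)0; }
      key = (key << 2) | (uint64_t)b;
    }
    return key;
  };

  CharacterVector out_contig(nr), out_strand(nr), out_status(nr);
  IntegerVector out_start(nr), out_mm(nr);

  for (int r = 0; r < nr; ++r) {
    const std::string fwd = as<std::string>(read_seqs[r]);
    const int L = fwd.size();
    int best_mm = max_mismatch + 1;
    int hit_contig = -1, hit_start = -1; char hit_strand = '+';
    bool ambiguous = false;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string seq = strand == 0 ? fwd : revcomp(fwd);
      if (L < k) continue;
      // candidate starts from the two terminal k-mers
      std::vector<std::pair<int,int>> cands;
      for (int which = 0; which < 2; ++which) {
        int off = which == 0 ? 0 : L - k;
        bool ok; uint64_t key = kmer_key(seq, off, ok);
        if (!ok) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (const Seed& sd : it->second) {
          int start = sd.pos - off;
          if (start < 0 || start + L > (int)contigs[sd.contig].size()) continue;
          cands.push_back({sd.contig, start});
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (auto& cd : cands) {
        const std::string& cs = contigs[cd.first];
        int mm = 0;
        for (int p = 0; p < L && mm <= max_mismatch; ++p)
          if (cs[cd.second + p] != seq[p]) ++mm;
        if (mm > max_mismatch) continue;
        if (mm < best_mm) {
          best_mm = mm; hit_contig = cd.first; hit_start = cd.second;
          hit_strand = strand == 0 ? '+' : '-'; ambiguous = false;
        } else if (mm == best_mm && hit_contig >= 0) {
          if (cd.first != hit_contig) ambiguous = true;
          else if (cd.second != hit_start || (strand == 1 && hit_strand == '+')) {
            // same contig: keep leftmost, plus strand first — already held
            if (cd.second < hit_start) { hit_start = cd.second;
              hit_strand = strand == 0 ? '+' : '-'; }
          }
        }
      }
    }
    if (hit_contig < 0) {
      out_status[r] = "unmapped"; out_contig[r] = NA_STRING;
      out_start[r] = NA_INTEGER; out_strand[r] = NA_STRING; out_mm[r] = NA_INTEGER;
    } else if (ambiguous) {
      out_status[r] = "ambiguous"; out_contig[r] = NA_STRING;
      out_start[r] = NA_INTEGER; out_strand[r] = NA_STRING; out_mm[r] = NA_INTEGER;
    } else {
      out_status[r] = "mapped";
      out_contig[r] = contig_ids[hit_contig];
      out_start[r] = hit_start;
      out_strand[r] = std::string(1, hit_strand);
      out_mm[r] = best_mm;
    }
  }
  return DataFrame::create(_["read_id"] = read_ids, _["contig_id"] = out_contig,
                           _["start"] = out_start, _["strand"] = out_strand,
                           _["mismatches"] = out_mm, _["status"] = out_status,
                           _["stringsAsFactors"] = false);
}
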