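// Seed-and-extend template scan.
//
// The template is traversed at one-nucleotide intervals; each position's
// k-mer is looked up in the primer half-word hash (pigeonhole split: one
// mismatch per k-mer tolerated) and every candidate posting is verified by
// gap-free extension of the full primer footprint under the weighted
// mismatch rules.  For primers too short for the pigeonhole guarantee to
// cover the whole-primer mismatch budget (floor(L/k) <= maxMismatches),
// every position is verified directly instead, so the reported hit set is
// exactly the exhaustive-scan semantics for every input.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int charMask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'M': return 3;  case 'R': return 5;  case 'W': return 9;
    case 'S': return 6;  case 'Y': return 10; case 'K': return 12;
    case 'V': return 7;  case 'H': return 11; case 'D': return 13;
    case 'B': return 14; case 'N': return 15;
    default:  return 15; // templates are pre-normalised; never reached
  }
}

static inline int maskComp(int m) {
  int r = 0;
  if (m & 1) r |= 8;
  if (m & 8) r |= 1;
  if (m & 2) r |= 4;
  if (m & 4) r |= 2;
  return r;
}

static inline bool isConcrete(int m) {
  return m == 1 || m == 2 || m == 4 || m == 8;
}

// stable guanine mismatch on duplex-opposed masks: pair contains G, no C
static inline bool stableG(int a, int b) {
  if (!isConcrete(a) || !isConcrete(b)) return false;
  if ((a & maskComp(b)) != 0) return false; // Watson-Crick pair
  if (a != 4 && b != 4) return false;
  if (a == 2 || b == 2) return false;
  return true;
}

struct Hit {
  int primer;      // 1-based primer index
  char strand;     // '+' or '-'
  int start0;      // 0-based template start of the footprint
  int nmm;         // raw mismatch count
  double wmm;      // weighted mismatches
  int n3;          // mismatches inside the 3' window
  std::string pos; // 1-based primer-relative mismatch offsets, comma-sep
};

// Verify the full footprint of oriented primer `q` at template start s.
// strandPlus: TRUE when q is the primer as given (3' end at the right).
static bool verifyAt(const std::vector<int>& tm, int s,
                     const std::vector<int>& q, bool strandPlus,
                     double maxMM, int w3, int n3max, bool probeMode,
                     Hit& out) {
  const int L = (int)q.size();
  double wmm = 0.0;
  int nmm = 0, n3 = 0;
  std::vector<int> mmpos;
  for (int j = 0; j < L; ++j) {
    int qm = q[j];
    int tmk = tm[s + j];
    // primer-relative position from the 5' end (0-based)
    int ppos = strandPlus ? j : (L - 1 - j);
    // in probe mode the 3' window has no special role at all
    bool in3 = !probeMode && (ppos >= L - w3);
    if (qm & tmk) {
      if (tmk == 15) wmm += 0.5; // template N: matches everything at half weight
    } else {
      nmm += 1;
      mmpos.push_back(ppos + 1);
      if (in3) {
        n3 += 1;
        wmm += 1.0;
        if (n3 > n3max) return false;
      } else {
        // duplex-opposed bases: plus {q, comp(t)}, minus {comp(q), t}
        bool st = strandPlus ? stableG(qm, maskComp(tmk))
                             : stableG(maskComp(qm), tmk);
        wmm += (st && !in3) ? 0.5 : 1.0;
      }
    }
    if (wmm > maxMM + 1e-9) return false;
  }
  out.nmm = nmm;
  out.wmm = wmm;
  out.n3 = n3;
  std::sort(mmpos.begin(), mmpos.end());
  std::string p;
  for (size_t i = 0; i < mmpos.size(); ++i) {
    if (i) p += ",";
    p += std::to_string(mmpos[i]);
  }
  out.pos = p;
  return true;
}

// [[Rcpp::export(name = ".scanCore")]]
DataFrame scanCore(std::string tmpl,
                   CharacterVector primersPlus,
                   CharacterVector primersMinus,
                   int k, int half1,
                   CharacterVector postKey,
                   IntegerVector postPrimer,
                   IntegerVector postOffset,
                   IntegerVector postOrient,  // 0 = '+', 1 = '-'
                   double maxMismatches,
                   int threePrimeWindow,
                   int number3Errors,
                   bool probeMode,
                   int reportLimit,
                   LogicalVector useIndex) {
  const int n = (int)tmpl.size();
  const int nP = primersPlus.size();

  // encode template
  std::vector<int> tm(n);
  for (int i = 0; i < n; ++i) tm[i] = charMask(tmpl[i]);

  // encode oriented primers: [primer][orient 0='+',1='-']
  std::vector<std::vector<int> > enc(2 * nP);
  std::vector<int> plen(nP);
  for (int i = 0; i < nP; ++i) {
    std::string sp = as<std::string>(primersPlus[i]);
    std::string sm = as<std::string>(primersMinus[i]);
    plen[i] = (int)sp.size();
    enc[2 * i].resize(sp.size());
    enc[2 * i + 1].resize(sm.size());
    for (size_t j = 0; j < sp.size(); ++j) enc[2 * i][j] = charMask(sp[j]);
    for (size_t j = 0; j < sm.size(); ++j) enc[2 * i + 1][j] = charMask(sm[j]);
  }

  std::vector<Hit> hits;
  std::unordered_set<long long> checked; // (primer,orient,start) triples seen

  auto tryStart = [&](int pi, int ori, int s) {
    if (s < 0 || s >= reportLimit) return;
    if (s + plen[pi] > n) return;
    long long key = ((long long)(pi * 2 + ori)) * (n + 1) + s;
    if (!checked.insert(key).second) return;
    Hit h;
    h.primer = pi + 1;
    h.strand = ori == 0 ? '+' : '-';
    h.start0 = s;
    // oriented comparison: '-' compares rc(primer) against plus text,
    // with the primer's 3' end at the left of the window
    if (verifyAt(tm, s, enc[2 * pi + ori], ori == 0, maxMismatches,
                 threePrimeWindow, number3Errors, probeMode, h))
      hits.push_back(h);
  };

  // ---- direct path: primers without the pigeonhole guarantee ----
  for (int pi = 0; pi < nP; ++pi) {
    if (useIndex[pi]) continue;
    for (int ori = 0; ori < 2; ++ori)
      for (int s = 0; s + plen[pi] <= n && s < reportLimit; ++s)
        tryStart(pi, ori, s);
  }

  // ---- index path ----
  bool anyIndexed = false;
  for (int pi = 0; pi < nP; ++pi) if (useIndex[pi]) anyIndexed = true;
  if (anyIndexed && n >= k) {
    // hash of half-word keys -> postings (only for indexed primers)
    std::unordered_multimap<std::string, int> map;
    const int nPost = postKey.size();
    map.reserve(nPost * 2);
    for (int r = 0; r < nPost; ++r) {
      if (!useIndex[postPrimer[r] - 1]) continue;
      map.insert(std::make_pair(as<std::string>(postKey[r]), r));
    }
    const int h2len = k - half1;

    // expand a template half at position p (length len) over degeneracy
    auto expandHalf = [&](int p, int len, std::vector<std::string>& out) {
      out.clear();
      out.push_back(std::string());
      static const char* baseChar = "ACGT";
      for (int j = 0; j < len; ++j) {
        int m = tm[p + j];
        std::vector<std::string> next;
        for (int b = 0; b < 4; ++b) {
          if (!(m & (1 << b))) continue;
          for (size_t e = 0; e < out.size(); ++e)
            next.push_back(out[e] + baseChar[b]);
        }
        if (next.size() > 4096) { out.clear(); return; } // degeneracy guard
        out.swap(next);
      }
    };

    std::vector<std::string> ex;
    for (int t = 0; t + k <= n; ++t) {
      for (int h = 0; h < 2; ++h) {
        int p0 = h == 0 ? t : t + half1;
        int len = h == 0 ? half1 : h2len;
        expandHalf(p0, len, ex);
        for (size_t e = 0; e < ex.size(); ++e) {
          std::string key = (h == 0 ? "1:" : "2:") + ex[e];
          auto range = map.equal_range(key);
          for (auto it = range.first; it != range.second; ++it) {
            int r = it->second;
            int pi = postPrimer[r] - 1;
            // posting offset is within the ORIENTED primer
            tryStart(pi, postOrient[r], t - postOffset[r]);
          }
        }
      }
    }
  }

  const int m = (int)hits.size();
  IntegerVector primer(m), start0(m), nmm(m), n3(m);
  NumericVector wmm(m);
  CharacterVector strand(m), mmpos(m);
  for (int i = 0; i < m; ++i) {
    primer[i] = hits[i].primer;
    strand[i] = std::string(1, hits[i].strand);
    start0[i] = hits[i].start0;
    nmm[i] = hits[i].nmm;
    wmm[i] = hits[i].wmm;
    n3[i] = hits[i].n3;
    mmpos[i] = hits[i].pos;
  }
  return DataFrame::create(_["primer"] = primer, _["strand"] = strand,
                           _["start0"] = start0, _["nMismatches"] = nmm,
                           _["weightedMismatches"] = wmm,
                           _["n3Prime"] = n3,
                           _["mismatchPositions"] = mmpos,
                           _["stringsAsFactors"] = false);
}
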