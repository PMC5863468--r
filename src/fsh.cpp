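#include <Rcpp.h>
#include <cstdint>
#include <cstdlib>
#include <string>
#include <vector>
using namespace Rcpp;

// 2-bit nucleotide encoding: A=00, C=01, G=10, T=11; -1 marks unencodable.
static inline int code2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Maximal runs of encodable symbols; hashing never crosses a run boundary,
// so no emitted window ever covers an ambiguous base (even at a don't-care).
static std::vector<std::pair<size_t, size_t> > acgt_segments(const std::string &x) {
  std::vector<std::pair<size_t, size_t> > segs;
  size_t n = x.size(), i = 0;
  while (i < n) {
    while (i < n && code2(x[i]) < 0) ++i;
    size_t a = i;
    while (i < n && code2(x[i]) >= 0) ++i;
    if (i > a) segs.push_back(std::make_pair(a, i));
  }
  return segs;
}

static inline uint64_t naive_word(const std::string &x, size_t i,
                                  const std::vector<int> &shape) {
  uint64_t h = 0;
  for (size_t r = 0; r < shape.size(); ++r) {
    h |= (uint64_t)code2(x[i + shape[r]]) << (2 * r);
  }
  return h;
}

// [[Rcpp::export]]
int encode_symbol_cpp(std::string c) {
  if (c.size() != 1) return -1;
  return code2(c[0]);
}

// [[Rcpp::export]]
std::string hash_naive_at_cpp(std::string x, int i, IntegerVector shape, int span) {
  if (i < 0 || (size_t)(i + span) > x.size())
    stop("position %d out of range for sequence of length %d and span %d",
         i, (int)x.size(), span);
  std::vector<int> sh(shape.begin(), shape.end());
  for (size_t r = 0; r < sh.size(); ++r) {
    char c = x[i + sh[r]];
    if (code2(c) < 0)
      stop("unencodable symbol '%c' at matched position %d", c, i + sh[r]);
  }
  return std::to_string(naive_word(x, (size_t)i, sh));
}

// [[Rcpp::export]]
List hash_naive_cpp(std::string x, IntegerVector shape, int span) {
  std::vector<int> sh(shape.begin(), shape.end());
  std::vector<int> pos;
  std::vector<std::string> hv;
  std::vector<std::pair<size_t, size_t> > segs = acgt_segments(x);
  for (size_t s = 0; s < segs.size(); ++s) {
    size_t a = segs[s].first, b = segs[s].second;
    if (b - a < (size_t)span) continue;
    for (size_t i = a; i + span <= b; ++i) {
      pos.push_back((int)i);
      hv.push_back(std::to_string(naive_word(x, i, sh)));
    }
  }
  double total = (double)sh.size() * (double)pos.size();
  return List::create(_["position"] = wrap(pos), _["hash"] = wrap(hv),
                      _["encoded"] = total);
}

// Incremental single-seed hashing. plan_j/keep/missing are indexed by the
// lookback window w = 1..span-1 (entry w-1): the chosen previous offset j,
// the kept seed positions C_j, and the positions shape \ C_j to re-encode.
// [[Rcpp::export]]
List hash_fsh_cpp(std::string x, IntegerVector shape, IntegerVector m, int span,
                  IntegerVector plan_j, List keep, List missing) {
  std::vector<int> sh(shape.begin(), shape.end());
  int W = (int)sh.size();
  int nw = span - 1;
  std::vector<uint64_t> mask(nw > 0 ? nw : 0, 0);
  std::vector<int> shiftb(nw > 0 ? nw : 0, 0);
  for (int w = 0; w < nw; ++w) {
    IntegerVector kp = keep[w];
    uint64_t mk = 0;
    for (int t = 0; t < kp.size(); ++t) mk |= (uint64_t)3 << (2 * m[kp[t]]);
    mask[w] = mk;
    shiftb[w] = 2 * m[plan_j[w]];
  }
  std::vector<int> pos;
  std::vector<std::string> hv;
  double inserted = 0;
  std::vector<uint64_t> ring(span > 1 ? span : 1);
  std::vector<std::pair<size_t, size_t> > segs = acgt_segments(x);
  for (size_t s = 0; s < segs.size(); ++s) {
    size_t a = segs[s].first, b = segs[s].second;
    if (b - a < (size_t)span) continue;
    size_t npos = b - a - span + 1;
    for (size_t il = 0; il < npos; ++il) {
      uint64_t h;
      if (il == 0 || span == 1) {
        h = naive_word(x, a + il, sh);
        inserted += W;
      } else {
        int w = (int)std::min(il, (size_t)(span - 1));
        int j = plan_j[w - 1];
        h = (ring[(il - j) % span] >> shiftb[w - 1]) & mask[w - 1];
        IntegerVector ms = missing[w - 1];
        for (int t = 0; t < ms.size(); ++t) {
          int k = ms[t];
          h |= (uint64_t)code2(x[a + il + k]) << (2 * m[k]);
        }
        inserted += ms.size();
      }
      ring[il % span] = h;
      pos.push_back((int)(a + il));
      hv.push_back(std::to_string(h));
    }
  }
  return List::create(_["position"] = wrap(pos), _["hash"] = wrap(hv),
                      _["encoded"] = inserted);
}

// Simultaneous hashing of several seeds with one shared span. Plans are per
// target seed y and window w: source seed plan_z (1-based), offset plan_j,
// kept target positions keep[[y]][[w]], and positions to re-encode.
// [[Rcpp::export]]
List hash_multi_cpp(std::string x, List shapes, List ms, int span,
                    IntegerMatrix plan_z, IntegerMatrix plan_j,
                    List keep, List missing) {
  int ns = shapes.size();
  int nw = span - 1;
  std::vector<std::vector<int> > sh(ns);
  std::vector<std::vector<int> > mv(ns);
  for (int y = 0; y < ns; ++y) {
    IntegerVector s = shapes[y];
    sh[y].assign(s.begin(), s.end());
    IntegerVector m = ms[y];
    mv[y].assign(m.begin(), m.end());
  }
  std::vector<std::vector<uint64_t> > mask(ns, std::vector<uint64_t>(nw > 0 ? nw : 0, 0));
  std::vector<std::vector<int> > shiftb(ns, std::vector<int>(nw > 0 ? nw : 0, 0));
  for (int y = 0; y < ns; ++y) {
    List ky = keep[y];
    for (int w = 0; w < nw; ++w) {
      IntegerVector kp = ky[w];
      uint64_t mk = 0;
      for (int t = 0; t < kp.size(); ++t) mk |= (uint64_t)3 << (2 * mv[y][kp[t]]);
      mask[y][w] = mk;
      int z = plan_z(y, w) - 1;
      shiftb[y][w] = 2 * mv[z][plan_j(y, w)];
    }
  }
  std::vector<std::vector<int> > pos(ns);
  std::vector<std::vector<std::string> > hv(ns);
  std::vector<double> inserted(ns, 0.0);
  std::vector<std::vector<uint64_t> > ring(ns, std::vector<uint64_t>(span > 1 ? span : 1));
  std::vector<std::pair<size_t, size_t> > segs = acgt_segments(x);
  for (size_t s = 0; s < segs.size(); ++s) {
    size_t a = segs[s].first, b = segs[s].second;
    if (b - a < (size_t)span) continue;
    size_t npos = b - a - span + 1;
    for (size_t il = 0; il < npos; ++il) {
      for (int y = 0; y < ns; ++y) {
        uint64_t h;
        if (il == 0 || span == 1) {
          h = naive_word(x, a + il, sh[y]);
          inserted[y] += sh[y].size();
        } else {
          int w = (int)std::min(il, (size_t)(span - 1));
          int z = plan_z(y, w - 1) - 1;
          int j = plan_j(y, w - 1);
          h = (ring[z][(il - j) % span] >> shiftb[y][w - 1]) & mask[y][w - 1];
          List my = missing[y];
          IntegerVector msv = my[w - 1];
          for (int t = 0; t < msv.size(); ++t) {
            int k = msv[t];
            h |= (uint64_t)code2(x[a + il + k]) << (2 * mv[y][k]);
          }
          inserted[y] += msv.size();
        }
        ring[y][il % span] = h;
        pos[y].push_back((int)(a + il));
        hv[y].push_back(std::to_string(h));
      }
    }
  }
  List out(ns);
  for (int y = 0; y < ns; ++y) {
    out[y] = List::create(_["position"] = wrap(pos[y]), _["hash"] = wrap(hv[y]),
                          _["encoded"] = inserted[y]);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector dec_to_bits_cpp(CharacterVector dec, int weight) {
  int nb = 2 * weight;
  CharacterVector out(dec.size());
  for (int i = 0; i < dec.size(); ++i) {
    if (CharacterVector::is_na(dec[i])) { out[i] = NA_STRING; continue; }
    const char *p = CHAR(STRING_ELT(dec, i));
    uint64_t v = 0;
    for (; *p >= '0' && *p <= '9'; ++p) v = v * 10 + (uint64_t)(*p - '0');
    std::string b(nb, '0');
    for (int t = 0; t < nb; ++t)
      if ((v >> t) & 1) b[nb - 1 - t] = '1';
    out[i] = b;
  }
  return out;
}
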