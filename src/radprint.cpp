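#include <Rcpp.h>
using namespace Rcpp;

// Pairwise Hamming neighbour search over equal-length sequences.
// Returns all unordered pairs (i, j), i < j, with Hamming distance <= max_d.
// Early exit once a pair exceeds max_d keeps the scan cheap for the
// well-separated sequences typical of RAD tags.
// [[Rcpp::export(name = ".hamming_neighbors")]]
DataFrame hamming_neighbors(CharacterVector seqs, int max_d) {
  const int n = seqs.size();
  std::vector<const char*> ptr(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    ptr[i] = CHAR(STRING_ELT(seqs, i));
    len[i] = LENGTH(STRING_ELT(seqs, i));
  }
  std::vector<int> ii, jj, dd;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (len[i] != len[j]) stop("sequences must have equal length");
      int d = 0;
      const char *a = ptr[i], *b = ptr[j];
      for (int k = 0; k < len[i]; ++k) {
        if (a[k] != b[k] && ++d > max_d) break;
      }
      if (d <= max_d) { ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(d); }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["d"] = dd);
}

// Cross-set Hamming neighbour search: pairs (i in x, j in y) with d <= max_d.
// [[Rcpp::export(name = ".hamming_neighbors_xy")]]
DataFrame hamming_neighbors_xy(CharacterVector x, CharacterVector y, int max_d) {
  const int nx = x.size(), ny = y.size();
  std::vector<const char*> px(nx), py(ny);
  std::vector<int> lx(nx), ly(ny);
  for (int i = 0; i < nx; ++i) { px[i] = CHAR(STRING_ELT(x, i)); lx[i] = LENGTH(STRING_ELT(x, i)); }
  for (int j = 0; j < ny; ++j) { py[j] = CHAR(STRING_ELT(y, j)); ly[j] = LENGTH(STRING_ELT(y, j)); }
  std::vector<int> ii, jj, dd;
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      if (lx[i] != ly[j]) stop("sequences must have equal length");
      int d = 0;
      const char *a = px[i], *b = py[j];
      for (int k = 0; k < lx[i]; ++k) {
        if (a[k] != b[k] && ++d > max_d) break;
      }
      if (d <= max_d) { ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(d); }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["d"] = dd);
}

// Quality-weighted distance for candidate pairs. For mismatching positions k,
// adds p_i[k] * p_j[k] where p = 1 - 10^(-q/10), the probability that the
// base call is correct given its (median) Phred quality.
// [[Rcpp::export(name = ".weighted_dist_pairs")]]
NumericVector weighted_dist_pairs(CharacterVector seqs, NumericMatrix qmat,
                                  IntegerVector i, IntegerVector j) {
  const int np = i.size();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const int a = i[p] - 1, b = j[p] - 1;
    const char *sa = CHAR(STRING_ELT(seqs, a)), *sb = CHAR(STRING_ELT(seqs, b));
    const int L = LENGTH(STRING_ELT(seqs, a));
    if (LENGTH(STRING_ELT(seqs, b)) != L) stop("sequences must have equal length");
    double w = 0.0;
    for (int k = 0; k < L; ++k) {
      if (sa[k] != sb[k]) {
        double pa = 1.0 - std::pow(10.0, -qmat(a, k) / 10.0);
        double pb = 1.0 - std::pow(10.0, -qmat(b, k) / 10.0);
        w += pa * pb;
      }
    }
    out[p] = w;
  }
  return out;
}

// Decode Phred quality strings into an integer matrix (reads x positions),
// subtracting `offset` and capping at `cap`.
// [[Rcpp::export(name = ".qual_to_matrix")]]
IntegerMatrix qual_to_matrix(CharacterVector q, int offset, int cap) {
  const int n = q.size();
  if (n == 0) return IntegerMatrix(0, 0);
  const int L = LENGTH(STRING_ELT(q, 0));
  IntegerMatrix out(n, L);
  for (int i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(q, i);
    if (LENGTH(s) != L) stop("quality strings must have equal length");
    const char *c = CHAR(s);
    for (int k = 0; k < L; ++k) {
      int v = (int)(unsigned char)c[k] - offset;
      if (v < 0) stop("negative quality after offset subtraction; wrong phred offset?");
      out(i, k) = v > cap ? cap : v;
    }
  }
  return out;
}

// Per-position median of quality rows within groups. `group` is a 1-based
// group index per row; returns a (#groups x L) numeric matrix of medians
// (average of the two central values for even group sizes).
// [[Rcpp::export(name = ".group_col_medians")]]
NumericMatrix group_col_medians(IntegerMatrix qmat, IntegerVector group, int ngroups) {
  const int n = qmat.nrow(), L = qmat.ncol();
  std::vector< std::vector<int> > members(ngroups);
  for (int i = 0; i < n; ++i) members[group[i] - 1].push_back(i);
  NumericMatrix out(ngroups, L);
  std::vector<int> buf;
  for (int g = 0; g < ngroups; ++g) {
    const std::vector<int> &m = members[g];
    const int k = m.size();
    if (k == 0) stop("empty group");
    buf.resize(k);
    for (int col = 0; col < L; ++col) {
      for (int r = 0; r < k; ++r) buf[r] = qmat(m[r], col);
      std::sort(buf.begin(), buf.end());
      out(g, col) = (k % 2 == 1) ? (double)buf[k / 2]
                                 : (buf[k / 2 - 1] + buf[k / 2]) / 2.0;
    }
  }
  return out;
}

// Substitute bases in-place: for each event e, set position pos[e] (1-based)
// of sequence read[e] (1-based) to base[e]. Used by the read simulator to
// inject sequencing errors.
// [[Rcpp::export(name = ".mutate_bases")]]
CharacterVector mutate_bases(CharacterVector seqs, IntegerVector read,
                             IntegerVector pos, CharacterVector base) {
  CharacterVector out = clone(seqs);
  for (int e = 0; e < read.size(); ++e) {
    const int i = read[e] - 1;
    std::string s = as<std::string>(out[i]);
    const int k = pos[e] - 1;
    if (k < 0 || k >= (int)s.size()) stop("mutation position out of range");
    s[k] = CHAR(STRING_ELT(base, e))[0];
    out[i] = s;
  }
  return out;
}
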