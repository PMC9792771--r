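// Alignment and read-processing kernels.
//
// Conventions shared with the R layer:
//  * coordinates are 0-based, half-open; a cut coordinate c sits between
//    template positions c-1 and c;
//  * a gap of length L costs gap_open + L * gap_extend;
//  * identity = matches / alignment columns (gap columns count).

#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

struct AlnResult {
  int score;
  std::string qa; // query with '-' for deletions-from-query
  std::string ra; // reference with '-' for insertions-into-query
};

// Gotoh three-state global alignment with full traceback.
// States: 0 = M (diagonal), 1 = X (gap in query, consumes ref),
//         2 = Y (gap in ref, consumes query).
static AlnResult gotoh1(const std::string& q, const std::string& r,
                        int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)q.size(), m = (int)r.size();
  AlnResult res;

  if (n == 0 && m == 0) { res.score = 0; return res; }
  if (n == 0) {
    res.score = -(gap_open + m * gap_extend);
    res.qa.assign(m, '-'); res.ra = r;
    return res;
  }
  if (m == 0) {
    res.score = -(gap_open + n * gap_extend);
    res.qa = q; res.ra.assign(n, '-');
    return res;
  }

  const int W = m + 1;
  // rolling score rows; full traceback kept as packed 2-bit-per-state bytes
  // (drift from the NEG sentinel stays far from overflow: path length times
  // the largest step is ~1e5 against |NEG| ~ 5e8, so no guards are needed)
  std::vector<int> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);
  std::vector<unsigned char> tb((size_t)(n + 1) * W);
  // tb byte layout: bits 0-1 = prev state entering M, 2-3 entering X,
  // 4-5 entering Y

  Mp[0] = 0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Yp[j] = NEG;
    Xp[j] = -(gap_open + j * gap_extend);
    tb[j] = (unsigned char)(((j == 1) ? 0 : 1) << 2);
  }
  const int go = gap_open + gap_extend, ge = gap_extend;

  for (int i = 1; i <= n; ++i) {
    const char qi = q[i - 1];
    unsigned char* tbrow = &tb[(size_t)i * W];
    Mc[0] = NEG; Xc[0] = NEG;
    Yc[0] = -(gap_open + i * gap_extend);
    tbrow[0] = (unsigned char)(((i == 1) ? 0 : 2) << 4);
    int Mdiag = Mp[0], Xdiag = Xp[0], Ydiag = Yp[0];
    for (int j = 1; j <= m; ++j) {
      const int s = (qi == r[j - 1]) ? match : mismatch;
      unsigned char t;

      int best = Mdiag; t = 0;
      if (Xdiag > best) { best = Xdiag; t = 1; }
      if (Ydiag > best) { best = Ydiag; t = 2; }
      const int mij = best + s;
      unsigned char tbv = t;

      // X: gap in query, consumes r[j-1] (left neighbours, current row)
      int op = Mc[j - 1]; t = 0;
      if (Yc[j - 1] > op) { op = Yc[j - 1]; t = 2; }
      const int vop = op - go, vex = Xc[j - 1] - ge;
      int xij;
      if (vex > vop) { xij = vex; tbv |= (unsigned char)(1 << 2); }
      else { xij = vop; tbv |= (unsigned char)(t << 2); }

      // Y: gap in ref, consumes q[i-1] (upper neighbours, previous row)
      int op2 = Mp[j]; t = 0;
      if (Xp[j] > op2) { op2 = Xp[j]; t = 1; }
      const int wop = op2 - go, wex = Yp[j] - ge;
      int yij;
      if (wex > wop) { yij = wex; tbv |= (unsigned char)(2 << 4); }
      else { yij = wop; tbv |= (unsigned char)(t << 4); }

      Mdiag = Mp[j]; Xdiag = Xp[j]; Ydiag = Yp[j];
      Mc[j] = mij; Xc[j] = xij; Yc[j] = yij;
      tbrow[j] = tbv;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  int state = 0, sc = Mp[m];
  if (Xp[m] > sc) { sc = Xp[m]; state = 1; }
  if (Yp[m] > sc) { sc = Yp[m]; state = 2; }
  res.score = sc;

  std::string qa, ra;
  qa.reserve(n + m); ra.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const unsigned char b = tb[(size_t)i * W + j];
    if (state == 0) {
      qa.push_back(q[i - 1]); ra.push_back(r[j - 1]);
      --i; --j; state = b & 3;
    } else if (state == 1) {
      qa.push_back('-'); ra.push_back(r[j - 1]);
      --j; state = (b >> 2) & 3;
    } else {
      qa.push_back(q[i - 1]); ra.push_back('-');
      --i; state = (b >> 4) & 3;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ra.begin(), ra.end());
  res.qa = qa; res.ra = ra;
  return res;
}

// [[Rcpp::export]]
List gotoh_batch_cpp(CharacterVector query, std::string ref, int match,
                     int mismatch, int gap_open, int gap_extend) {
  const int n = query.size();
  IntegerVector score(n);
  CharacterVector qa(n), ra(n);
  for (int k = 0; k < n; ++k) {
    AlnResult a = gotoh1(as<std::string>(query[k]), ref, match, mismatch,
                         gap_open, gap_extend);
    score[k] = a.score;
    qa[k] = a.qa;
    ra[k] = a.ra;
  }
  return List::create(_["score"] = score, _["query_aln"] = qa,
                      _["template_aln"] = ra);
}

struct Event {
  bool insertion;   // else deletion of template bases
  int len;
  int pmin, pmax;   // reachable template coordinate range after
                    // left/right-normalization: for deletions the range of
                    // start positions, for insertions the range of insertion
                    // points (between pos-1 and pos)
};

static void collect_events(const std::string& qa, const std::string& ra,
                           std::vector<Event>& ev, std::string& R,
                           std::string& Q, std::vector<int>& mism_tpos,
                           int& matches, int& columns) {
  const int L = (int)qa.size();
  R.clear(); Q.clear(); mism_tpos.clear(); ev.clear();
  matches = 0; columns = L;
  for (int k = 0; k < L; ++k) {
    if (ra[k] != '-') R.push_back(ra[k]);
    if (qa[k] != '-') Q.push_back(qa[k]);
  }
  int tpos = 0, k = 0;
  while (k < L) {
    if (qa[k] == '-') {            // deletion of template [tpos, tpos+len)
      int len = 0;
      while (k < L && qa[k] == '-') { ++len; ++k; ++tpos; }
      Event e; e.insertion = false; e.len = len;
      int a = tpos - len;
      int amin = a, amax = a;
      while (amin > 0 && R[amin - 1] == R[amin - 1 + len]) --amin;
      while (amax + len < (int)R.size() && R[amax] == R[amax + len]) ++amax;
      e.pmin = amin; e.pmax = amax;
      ev.push_back(e);
    } else if (ra[k] == '-') {     // insertion at template point tpos
      std::string ins;
      while (k < L && ra[k] == '-') { ins.push_back(qa[k]); ++k; }
      Event e; e.insertion = true; e.len = (int)ins.size();
      int p = tpos;
      std::string s = ins;
      int pmin = p;
      while (pmin > 0 && s[s.size() - 1] == R[pmin - 1]) {
        s = s.substr(s.size() - 1) + s.substr(0, s.size() - 1);
        --pmin;
      }
      s = ins;
      int pmax = p;
      while (pmax < (int)R.size() && s[0] == R[pmax]) {
        s = s.substr(1) + s.substr(0, 1);
        ++pmax;
      }
      e.pmin = pmin; e.pmax = pmax;
      ev.push_back(e);
    } else {
      if (qa[k] == ra[k]) ++matches; else mism_tpos.push_back(tpos);
      ++k; ++tpos;
    }
  }
}

// Per-alignment window profile against a set of cut coordinates.
// [[Rcpp::export]]
List aln_profile_cpp(CharacterVector qa, CharacterVector ra,
                     IntegerVector cuts, int window) {
  const int n = qa.size(), nc = cuts.size();
  IntegerVector matches(n), columns(n);
  IntegerMatrix indel(n, nc), nev(n, nc), subs(n, nc);
  std::vector<Event> ev; std::string R, Q; std::vector<int> mm;
  for (int k = 0; k < n; ++k) {
    int mat, col;
    collect_events(as<std::string>(qa[k]), as<std::string>(ra[k]), ev, R, Q,
                   mm, mat, col);
    matches[k] = mat; columns[k] = col;
    for (int ci = 0; ci < nc; ++ci) {
      const int c = cuts[ci];
      const int wlo = c - window, whi_pos = c + window - 1, whi_pt = c + window;
      int net = 0, cnt = 0, sb = 0;
      for (size_t e = 0; e < ev.size(); ++e) {
        bool hit;
        if (ev[e].insertion) {
          hit = (ev[e].pmax >= wlo) && (ev[e].pmin <= whi_pt);
        } else {
          // reachable deleted positions cover [pmin, pmax + len - 1]
          hit = (ev[e].pmax + ev[e].len - 1 >= wlo) && (ev[e].pmin <= whi_pos);
        }
        if (hit) { ++cnt; net += ev[e].insertion ? ev[e].len : -ev[e].len; }
      }
      for (size_t s = 0; s < mm.size(); ++s)
        if (mm[s] >= wlo && mm[s] <= whi_pos) ++sb;
      indel(k, ci) = net; nev(k, ci) = cnt; subs(k, ci) = sb;
    }
  }
  return List::create(_["matches"] = matches, _["columns"] = columns,
                      _["indel"] = indel, _["events"] = nev, _["subs"] = subs);
}

// Flank/middle decomposition of read-vs-wild-type alignments for the
// split (soft-clip / splice-junction) classifier.
// [[Rcpp::export]]
List split_stats_cpp(CharacterVector qa, CharacterVector ra, int cut1,
                     int cut2, int window) {
  const int n = qa.size();
  const int seglen = cut2 - cut1;
  IntegerVector lmatch(n), lcols(n), rmatch(n), rcols(n);
  LogicalVector junction_del(n);
  CharacterVector middle(n);
  std::vector<Event> ev; std::string R, Q; std::vector<int> mm;
  for (int k = 0; k < n; ++k) {
    const std::string a = as<std::string>(qa[k]);
    const std::string b = as<std::string>(ra[k]);
    int mat, col;
    collect_events(a, b, ev, R, Q, mm, mat, col);
    bool jd = false;
    for (size_t e = 0; e < ev.size(); ++e)
      if (!ev[e].insertion && ev[e].len == seglen &&
          ev[e].pmin <= cut1 && ev[e].pmax >= cut1)
        jd = true;
    junction_del[k] = jd;

    int lm = 0, rm = 0;
    int tpos = 0, qpos = 0;
    int left_end = -1, right_start = (int)Q.size();
    for (size_t c = 0; c < a.size(); ++c) {
      const bool hasq = a[c] != '-', hast = b[c] != '-';
      if (hasq && hast) {
        if (a[c] == b[c]) {
          if (tpos < cut1) ++lm; else if (tpos >= cut2) ++rm;
        }
        if (tpos < cut1 && qpos > left_end) left_end = qpos;
        if (tpos >= cut2 && qpos < right_start) right_start = qpos;
      }
      if (hasq) ++qpos;
      if (hast) ++tpos;
    }
    lmatch[k] = lm; lcols[k] = cut1;
    rmatch[k] = rm; rcols[k] = (int)R.size() - cut2;
    if (right_start > left_end + 1)
      middle[k] = Q.substr(left_end + 1, right_start - left_end - 1);
    else
      middle[k] = "";
  }
  return List::create(_["left_match"] = lmatch, _["left_cols"] = lcols,
                      _["right_match"] = rmatch, _["right_cols"] = rcols,
                      _["junction_deletion"] = junction_del,
                      _["middle"] = middle);
}

// Ungapped comparison of equal-length reads against one template.
// mism = -1 flags a length mismatch.
// [[Rcpp::export]]
List hamming_profile_cpp(CharacterVector reads, std::string ref,
                         IntegerVector cuts, int window) {
  const int n = reads.size(), nc = cuts.size(), m = (int)ref.size();
  IntegerVector mism(n);
  IntegerMatrix subs(n, nc);
  for (int k = 0; k < n; ++k) {
    const std::string s = as<std::string>(reads[k]);
    if ((int)s.size() != m) { mism[k] = -1; continue; }
    int d = 0;
    for (int i = 0; i < m; ++i) {
      if (s[i] != ref[i]) {
        ++d;
        for (int ci = 0; ci < nc; ++ci)
          if (i >= cuts[ci] - window && i <= cuts[ci] + window - 1)
            ++subs(k, ci);
      }
    }
    mism[k] = d;
  }
  return List::create(_["mism"] = mism, _["subs"] = subs);
}

// Best ungapped overlap merge of oriented read pairs (r2 already
// reverse-complemented). Disagreements go to the higher-quality base,
// ties to r1.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector r2rc,
                     CharacterVector q1, CharacterVector q2rc,
                     int min_overlap, double max_mm_frac) {
  const int n = r1.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector merged(n);
  for (int k = 0; k < n; ++k) {
    const std::string a = as<std::string>(r1[k]);
    const std::string b = as<std::string>(r2rc[k]);
    const std::string qa = as<std::string>(q1[k]);
    const std::string qb = as<std::string>(q2rc[k]);
    const int n1 = (int)a.size(), n2 = (int)b.size();
    int best_o = -1, best_score = INT_MIN;
    for (int o = 0; o + min_overlap <= n1; ++o) {
      const int ov = std::min(n1 - o, n2);
      if (ov < min_overlap) break;
      int mmv = 0;
      const int allowed = (int)(ov * max_mm_frac);
      bool ok = true;
      for (int i = 0; i < ov; ++i) {
        if (a[o + i] != b[i] && ++mmv > allowed) { ok = false; break; }
      }
      if (!ok) continue;
      const int score = (ov - mmv) - mmv;
      if (score > best_score) { best_score = score; best_o = o; }
      // a perfect overlap cannot be beaten: later offsets have ov' <= ov
      if (mmv == 0 && score == ov) break;
    }
    if (best_o < 0) { merged[k] = false; mseq[k] = NA_STRING; mqual[k] = NA_STRING; continue; }
    const int o = best_o, ov = std::min(n1 - o, n2);
    std::string s = a.substr(0, o), qs = qa.substr(0, o);
    for (int i = 0; i < ov; ++i) {
      const char ca = a[o + i], cb = b[i];
      const char pa = qa[o + i], pb = qb[i];
      if (ca == cb) { s.push_back(ca); qs.push_back(std::max(pa, pb)); }
      else if (pb > pa) { s.push_back(cb); qs.push_back(pb); }
      else { s.push_back(ca); qs.push_back(pa); }
    }
    if (n1 - o > n2) { s += a.substr(o + ov); qs += qa.substr(o + ov); }
    else if (ov < n2) { s += b.substr(ov); qs += qb.substr(ov); }
    merged[k] = true; mseq[k] = s; mqual[k] = qs;
  }
  return List::create(_["merged"] = merged, _["seq"] = mseq, _["qual"] = mqual);
}

// [[Rcpp::export]]
CharacterVector reverse_strings_cpp(CharacterVector x) {
  const int n = x.size();
  CharacterVector out(n);
  for (int k = 0; k < n; ++k) {
    if (x[k] == NA_STRING) { out[k] = NA_STRING; continue; }
    std::string s = as<std::string>(x[k]);
    std::reverse(s.begin(), s.end());
    out[k] = s;
  }
  return out;
}
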