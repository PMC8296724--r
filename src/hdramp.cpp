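#include <Rcpp.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// N-compatibility: two bases conflict iff both are non-N and differ.
static inline bool compat(char a, char b) {
  return a == 'N' || b == 'N' || a == b;
}

static bool nc_equal_str(const char* a, int la, const char* b, int lb) {
  if (la != lb) return false;
  for (int i = 0; i < la; ++i) if (!compat(a[i], b[i])) return false;
  return true;
}

// [[Rcpp::export(name = ".nc_equal_cpp")]]
LogicalVector nc_equal_cpp(CharacterVector seqs, std::string ref) {
  int n = seqs.size();
  LogicalVector out(n);
  const char* r = ref.c_str();
  int lr = ref.size();
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    out[i] = nc_equal_str(s, std::strlen(s), r, lr);
  }
  return out;
}

// All 1-based start positions where `needle` occurs N-compatibly in `hay`.
static std::vector<int> nc_find(const char* hay, int lh, const char* nd, int ln) {
  std::vector<int> hits;
  for (int o = 0; o + ln <= lh; ++o) {
    bool ok = true;
    for (int j = 0; j < ln; ++j) {
      if (!compat(hay[o + j], nd[j])) { ok = false; break; }
    }
    if (ok) hits.push_back(o + 1);
  }
  return hits;
}

// [[Rcpp::export(name = ".nc_find_cpp")]]
IntegerVector nc_find_cpp(std::string hay, std::string needle) {
  std::vector<int> hits = nc_find(hay.c_str(), hay.size(),
                                  needle.c_str(), needle.size());
  return wrap(hits);
}

// Classification cascade over a vector of variant sequences.
// hdr_ext = edited amplicon from the window start to the amplicon end, so
// hdr_window = hdr_ext[1..window_len] and junction checks can run past the
// window end on length-shifted variants. core starts at core_start (1-based)
// within hdr_ext.
// Returns label codes 1=perfect_hdr, 2=wild_type, 3=erroneous_hdr, 4=other
// plus the 5'/3' junction-perfection flags (perfect/erroneous only).
// [[Rcpp::export(name = ".classify_cpp")]]
List classify_cpp(CharacterVector seqs, std::string hdr_window,
                  std::string wt_window, std::string core, int core_start,
                  std::string hdr_ext) {
  int n = seqs.size();
  IntegerVector label(n);
  LogicalVector p5(n), p3(n);
  const char* hw = hdr_window.c_str(); int lhw = hdr_window.size();
  const char* ww = wt_window.c_str();  int lww = wt_window.size();
  const char* cr = core.c_str();       int lcr = core.size();
  const char* ext = hdr_ext.c_str();   int lext = hdr_ext.size();
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int ls = std::strlen(s);
    bool f5 = false, f3 = false;
    std::vector<int> occ = nc_find(s, ls, cr, lcr);
    // Junction flags: some core occurrence whose flank reproduces the edited
    // reference, in register on the 5' side and contiguously on the 3' side.
    for (size_t k = 0; k < occ.size(); ++k) {
      int st = occ[k];                 // 1-based in variant
      int en = st + lcr - 1;
      if (!f5 && nc_equal_str(s, en, ext, (en <= lext) ? en : -1)) f5 = true;
      int tail = ls - st + 1;
      if (!f3 && core_start + tail - 1 <= lext) {
        bool ok = true;
        for (int j = 0; j < tail; ++j) {
          if (!compat(s[st - 1 + j], ext[core_start - 1 + j])) { ok = false; break; }
        }
        if (ok) f3 = true;
      }
      if (f5 && f3) break;
    }
    if (nc_equal_str(s, ls, hw, lhw)) {
      label[i] = 1; p5[i] = f5; p3[i] = f3;
    } else if (nc_equal_str(s, ls, ww, lww)) {
      label[i] = 2;                     // wild type: side flags undefined
    } else if (!occ.empty()) {
      label[i] = 3; p5[i] = f5; p3[i] = f3;
    } else {
      label[i] = 4;
    }
  }
  return List::create(_["label"] = label, _["perfect_5p"] = p5,
                      _["perfect_3p"] = p3);
}

// Greedy N-tolerant variant merging. Input must be pre-sorted (descending
// read count, then lexicographic). A variant joins the first existing
// cluster whose consensus it does not conflict with at any non-N position
// and from which it differs at <= max_n_diff N-vs-base positions; cluster
// consensus positions are filled in as members contribute non-N bases.
// Cluster-level passes then repeat the same rule between cluster consensi
// until no merge applies. Returns 1-based cluster ids per variant.
// [[Rcpp::export(name = ".nmerge_cpp")]]
IntegerVector nmerge_cpp(CharacterVector seqs, int max_n_diff) {
  int n = seqs.size();
  IntegerVector assign(n);
  if (n == 0) return assign;
  int len = std::strlen(CHAR(STRING_ELT(seqs, 0)));
  std::vector<std::string> cons;          // cluster consensus strings
  std::vector<std::vector<int> > members;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if ((int) std::strlen(s) != len)
      stop("variants must have equal windowed length");
    int placed = -1;
    for (size_t c = 0; c < cons.size(); ++c) {
      const std::string& cc = cons[c];
      int ndiff = 0;
      bool ok = true;
      for (int j = 0; j < len; ++j) {
        char a = s[j], b = cc[j];
        if (a == b) continue;
        if (a == 'N' || b == 'N') {
          if (++ndiff > max_n_diff) { ok = false; break; }
        } else { ok = false; break; }
      }
      if (ok) { placed = (int) c; break; }
    }
    if (placed < 0) {
      cons.push_back(std::string(s, len));
      members.push_back(std::vector<int>(1, i));
    } else {
      std::string& cc = cons[placed];
      for (int j = 0; j < len; ++j) if (cc[j] == 'N' && s[j] != 'N') cc[j] = s[j];
      members[placed].push_back(i);
    }
  }
  // Transitive closure between clusters.
  bool merged = true;
  while (merged) {
    merged = false;
    for (size_t a = 0; a < cons.size() && !merged; ++a) {
      if (members[a].empty()) continue;
      for (size_t b = a + 1; b < cons.size(); ++b) {
        if (members[b].empty()) continue;
        int ndiff = 0;
        bool ok = true;
        for (int j = 0; j < len; ++j) {
          char x = cons[a][j], y = cons[b][j];
          if (x == y) continue;
          if (x == 'N' || y == 'N') {
            if (++ndiff > max_n_diff) { ok = false; break; }
          } else { ok = false; break; }
        }
        if (ok) {
          for (int j = 0; j < len; ++j)
            if (cons[a][j] == 'N' && cons[b][j] != 'N') cons[a][j] = cons[b][j];
          members[a].insert(members[a].end(), members[b].begin(), members[b].end());
          members[b].clear();
          merged = true;
          break;
        }
      }
    }
  }
  int cid = 0;
  for (size_t c = 0; c < cons.size(); ++c) {
    if (members[c].empty()) continue;
    ++cid;
    for (size_t k = 0; k < members[c].size(); ++k) assign[members[c][k]] = cid;
  }
  return assign;
}

// [[Rcpp::export(name = ".rev_str_cpp")]]
CharacterVector rev_str_cpp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    std::string r(s);
    std::reverse(r.begin(), r.end());
    out[i] = r;
  }
  return out;
}

// Convert bases whose Phred score is below q_thresh to N; report N counts.
// [[Rcpp::export(name = ".mask_cpp")]]
List mask_cpp(CharacterVector seqs, CharacterVector quals, int q_thresh) {
  int n = seqs.size();
  CharacterVector mseq(n);
  IntegerVector ncount(n);
  char cut = (char) (q_thresh + 33);
  for (int i = 0; i < n; ++i) {
    std::string s(CHAR(STRING_ELT(seqs, i)));
    const char* q = CHAR(STRING_ELT(quals, i));
    if (s.size() != std::strlen(q)) stop("sequence/quality length mismatch");
    int nc = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      if (q[j] < cut) { s[j] = 'N'; }
      if (s[j] == 'N') ++nc;
    }
    mseq[i] = s;
    ncount[i] = nc;
  }
  return List::create(_["seq"] = mseq, _["n_count"] = ncount);
}

// Ungapped overlap merging of a read pair. fwd and rev_rc are the forward
// read and the reverse-complemented reverse read; quals are Phred+33 strings
// in the same orientation. Candidate placements put the reverse read's start
// at 0-based offset o in forward coordinates (o >= 0: the amplicon is
// assumed at least one read long). The placement maximising matching bases
// wins, ties going to the longer overlap and then the smaller offset;
// acceptance requires overlap >= min_overlap and
// mismatches <= max_mismatch_frac * overlap. Disagreements resolve to the
// higher-quality base (forward on quality ties); merged quality is the
// per-position maximum.
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector fwd, CharacterVector fq,
                     CharacterVector rev_rc, CharacterVector rq,
                     int min_overlap, double max_mismatch_frac) {
  int n = fwd.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector ok(n);
  for (int i = 0; i < n; ++i) {
    const char* F = CHAR(STRING_ELT(fwd, i));
    const char* R = CHAR(STRING_ELT(rev_rc, i));
    const char* FQ = CHAR(STRING_ELT(fq, i));
    const char* RQ = CHAR(STRING_ELT(rq, i));
    int fl = std::strlen(F), rl = std::strlen(R);
    int best_o = -1, best_match = -1, best_len = -1;
    int omax = fl - min_overlap;
    for (int o = 0; o <= omax; ++o) {
      int ov = std::min(fl - o, rl);
      if (ov < min_overlap) break;
      int mm = 0;
      bool beatable = true;
      for (int j = 0; j < ov; ++j) {
        if (F[o + j] != R[j]) {
          ++mm;
          // matches so far + everything left cannot beat the incumbent
          if ((j + 1 - mm) + (ov - j - 1) <= best_match) { beatable = false; break; }
        }
      }
      if (!beatable) continue;
      int match = ov - mm;
      if (match > best_match || (match == best_match && ov > best_len)) {
        best_match = match; best_len = ov; best_o = o;
      }
    }
    bool accepted = best_o >= 0 &&
      (best_len - best_match) <= max_mismatch_frac * best_len + 1e-9;
    if (!accepted) { ok[i] = false; mseq[i] = NA_STRING; mqual[i] = NA_STRING; continue; }
    int o = best_o;
    int ov = std::min(fl - o, rl);
    int total = std::max(fl, o + rl);
    std::string seq(total, 'N'), qual(total, '!');
    for (int j = 0; j < o; ++j) { seq[j] = F[j]; qual[j] = FQ[j]; }
    for (int j = 0; j < ov; ++j) {
      char fb = F[o + j], rb = R[j];
      char fqc = FQ[o + j], rqc = RQ[j];
      if (fb == rb) {
        seq[o + j] = fb;
      } else {
        seq[o + j] = (rqc > fqc) ? rb : fb;   // forward wins quality ties
      }
      qual[o + j] = std::max(fqc, rqc);
    }
    for (int j = ov; j < rl; ++j) { seq[o + j] = R[j]; qual[o + j] = RQ[j]; }
    for (int j = o + rl; j < fl; ++j) { seq[j] = F[j]; qual[j] = FQ[j]; }
    ok[i] = true;
    mseq[i] = seq;
    mqual[i] = qual;
  }
  return List::create(_["ok"] = ok, _["seq"] = mseq, _["qual"] = mqual);
}
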