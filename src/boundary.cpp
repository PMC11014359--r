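#include <Rcpp.h>
using namespace Rcpp;

// Per-read scans used by the read-parsing and tail-calling stages.
// All comparisons are substitution-only (no indels); 'N' never matches.

static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

// Tail/template boundary in an R2 payload (tail-first orientation).
//
// payload[t] aligned to ref_rc[d] starts the templated span; we scan t
// upward (minimal NTA first, so terminal reference-matching As stay
// templated) and end-trim d from 0 so alignments ending at the annotated
// 3' terminus win. Accepts the first (t, d) whose aligned span has
// mismatch rate <= max_rate over span >= min_anchor.
//
// Returns a list of two integer vectors: nta_len (NA when the templated
// region is never reached within the payload) and end_trim.
// [[Rcpp::export]]
List boundary_scan_cpp(CharacterVector payloads, std::string ref_rc,
                       double max_rate, int min_anchor, int max_end_trim) {
  int n = payloads.size();
  int ref_len = ref_rc.size();
  IntegerVector nta_len(n, NA_INTEGER);
  IntegerVector end_trim(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (payloads[i] == NA_STRING) continue;
    std::string p = as<std::string>(payloads[i]);
    int len = p.size();
    bool found = false;
    for (int t = 0; t + min_anchor <= len && !found; ++t) {
      for (int d = 0; d <= max_end_trim && !found; ++d) {
        int span = std::min(len - t, ref_len - d);
        if (span < min_anchor) continue;
        int allowed = (int)std::floor(max_rate * span);
        int mm = 0;
        for (int k = 0; k < span; ++k) {
          if (!base_match(p[t + k], ref_rc[d + k])) {
            if (++mm > allowed) break;
          }
        }
        if (mm <= allowed) {
          nta_len[i] = t;
          end_trim[i] = d;
          found = true;
        }
      }
    }
  }
  return List::create(_["nta_len"] = nta_len, _["end_trim"] = end_trim);
}

// Positional prefix comparison: seq[k] vs ref[k] over span = min(lengths).
// [[Rcpp::export]]
List prefix_mismatch_cpp(CharacterVector seqs, std::string ref) {
  int n = seqs.size();
  int ref_len = ref.size();
  IntegerVector mm(n, NA_INTEGER);
  IntegerVector span(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) continue;
    std::string s = as<std::string>(seqs[i]);
    int sp = std::min((int)s.size(), ref_len);
    int m = 0;
    for (int k = 0; k < sp; ++k) {
      if (!base_match(s[k], ref[k])) ++m;
    }
    mm[i] = m;
    span[i] = sp;
  }
  return List::create(_["mm"] = mm, _["span"] = span);
}

// First start position (1-based, >= from) where `motif` matches with at
// most max_mm substitutions; truncated motifs at the read end must keep
// at least min_overlap bases. NA when absent.
// [[Rcpp::export]]
IntegerVector find_motif_cpp(CharacterVector seqs, std::string motif,
                             int from, int max_mm, int min_overlap) {
  int n = seqs.size();
  int mlen = motif.size();
  IntegerVector pos(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) continue;
    std::string s = as<std::string>(seqs[i]);
    int len = s.size();
    for (int st = from - 1; st < len; ++st) {
      int span = std::min(mlen, len - st);
      if (span < min_overlap) break;
      int m = 0;
      bool ok = true;
      for (int k = 0; k < span; ++k) {
        if (!base_match(s[st + k], motif[k])) {
          if (++m > max_mm) { ok = false; break; }
        }
      }
      if (ok) { pos[i] = st + 1; break; }
    }
  }
  return pos;
}

// Hamming distance of each sequence to a single target of equal length
// (NA when lengths differ).
// [[Rcpp::export]]
IntegerVector hamming_to_cpp(CharacterVector seqs, std::string target) {
  int n = seqs.size();
  int tlen = target.size();
  IntegerVector d(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) continue;
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() != tlen) continue;
    int m = 0;
    for (int k = 0; k < tlen; ++k) {
      if (!base_match(s[k], target[k])) ++m;
    }
    d[i] = m;
  }
  return d;
}
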