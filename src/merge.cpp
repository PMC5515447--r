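#include <Rcpp.h>
using namespace Rcpp;

// Overlap-merge of read pairs. The reverse read arrives already
// reverse-complemented (rvc); its quality string is still in sequencer
// orientation and is indexed back-to-front. For each pair the largest
// overlap whose mismatch fraction is within max_mm_frac is taken; within
// the overlap the higher-quality base wins (tie: forward), consensus
// quality is the maximum of the two.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector fwd, CharacterVector fq,
                     CharacterVector rvc, CharacterVector rq,
                     int min_overlap, double max_mm_frac) {
  int n = fwd.size();
  CharacterVector out_b(n), out_q(n);
  IntegerVector out_ov(n);
  std::string merged, mq;
  for (int i = 0; i < n; ++i) {
    const char *f = CHAR(STRING_ELT(fwd, i));
    const char *qf = CHAR(STRING_ELT(fq, i));
    const char *r = CHAR(STRING_ELT(rvc, i));
    const char *qr0 = CHAR(STRING_ELT(rq, i));
    int lf = LENGTH(STRING_ELT(fwd, i));
    int lr = LENGTH(STRING_ELT(rvc, i));
    int best = -1;
    for (int ov = std::min(lf, lr); ov >= min_overlap; --ov) {
      int allowed = (int)std::floor(max_mm_frac * ov);
      int mm = 0;
      const char *fs = f + (lf - ov);
      for (int j = 0; j < ov; ++j) {
        if (fs[j] != r[j] && ++mm > allowed) break;
      }
      if (mm <= allowed) { best = ov; break; }
    }
    out_ov[i] = best > 0 ? best : 0;
    if (best < 0) {
      out_b[i] = "";
      out_q[i] = "";
      continue;
    }
    int ov = best, lm = lf + lr - ov;
    merged.assign(lm, 'N');
    mq.assign(lm, '!');
    for (int j = 0; j < lf - ov; ++j) { merged[j] = f[j]; mq[j] = qf[j]; }
    for (int j = 0; j < ov; ++j) {
      char fb = f[lf - ov + j], rb = r[j];
      char fqc = qf[lf - ov + j];
      char rqc = qr0[lr - 1 - j];  // reverse-orientation quality
      int k = lf - ov + j;
      if (fb == rb) {
        merged[k] = fb;
        mq[k] = fqc >= rqc ? fqc : rqc;
      } else if (rqc > fqc) {
        merged[k] = rb;
        mq[k] = rqc;
      } else {
        merged[k] = fb;
        mq[k] = fqc;
      }
    }
    for (int j = ov; j < lr; ++j) {
      merged[lf - ov + j] = r[j];
      mq[lf - ov + j] = qr0[lr - 1 - j];
    }
    out_b[i] = merged;
    out_q[i] = mq;
  }
  return List::create(_["bases"] = out_b, _["quals"] = out_q,
                      _["overlap"] = out_ov);
}

// 3' adapter read-through trimming: the longest read suffix matching a
// prefix of any adapter with >= min_match bases and <= max_mismatch
// mismatches is removed. Also removes a full-adapter match that starts
// mid-read and runs to the end (suffix longer than the adapter is handled
// by matching the adapter body). Returns the kept length of each read.
// [[Rcpp::export]]
IntegerVector trim_suffix_cpp(CharacterVector reads, CharacterVector adapters,
                              int min_match, int max_mismatch) {
  int n = reads.size(), na = adapters.size();
  IntegerVector keep(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(reads, i));
    int L = LENGTH(STRING_ELT(reads, i));
    int cut = L;  // first trimmed position (0-based); L = keep all
    for (int a = 0; a < na; ++a) {
      const char *ad = CHAR(STRING_ELT(adapters, a));
      int la = LENGTH(STRING_ELT(adapters, a));
      // candidate start positions of the adapter within the read, earliest
      // (longest match) first
      for (int st = 0; st <= L - min_match; ++st) {
        int m = std::min(L - st, la);
        int mm = 0;
        bool ok = true;
        for (int j = 0; j < m; ++j) {
          if (s[st + j] != ad[j] && ++mm > max_mismatch) { ok = false; break; }
        }
        if (ok && m >= min_match && st < cut) { cut = st; break; }
      }
    }
    keep[i] = cut;
  }
  return keep;
}
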