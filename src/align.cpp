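#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Exhaustive ungapped k-mismatch alignment of short reads against a set of
// reference sequences, both strands. Brute-force Hamming scan with early exit
// once the mismatch budget is exceeded; guaranteed to report every placement.
//
// Returns parallel vectors describing each alignment plus the mismatch
// offsets (0-based, in alignment/genome orientation) flattened into one
// vector with per-alignment start indices.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export(name = ".align_reads_cpp")]]
List align_reads_cpp(CharacterVector genome, CharacterVector reads, int k) {
  const int nseq = genome.size();
  const int nreads = reads.size();
  if (k < 0) stop("k must be >= 0");

  std::vector<std::string> seqs(nseq);
  for (int s = 0; s < nseq; ++s) seqs[s] = as<std::string>(genome[s]);

  std::vector<int> out_read, out_seq, out_pos, out_nm, out_mmstart;
  std::vector<int> out_strand;            // 1 = forward, -1 = reverse
  std::vector<int> mmflat;                // flattened mismatch offsets
  std::vector<int> mmbuf;
  mmbuf.reserve(k + 1);

  for (int r = 0; r < nreads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int L = (int)fwd.size();
    if (L == 0) stop("empty read");
    std::string rev(L, 'N');
    for (int i = 0; i < L; ++i) rev[L - 1 - i] = comp_base(fwd[i]);

    for (int s = 0; s < nseq; ++s) {
      const std::string &g = seqs[s];
      const int glen = (int)g.size();
      if (L > glen) continue;
      const char *gp = g.data();
      for (int strand = 0; strand < 2; ++strand) {
        // aligned-orientation read: forward read on +, reverse complement on -
        const char *rp = (strand == 0) ? fwd.data() : rev.data();
        for (int pos = 0; pos + L <= glen; ++pos) {
          int mm = 0;
          mmbuf.clear();
          const char *gq = gp + pos;
          for (int i = 0; i < L; ++i) {
            // 'N' on either side counts as a mismatch
            if (rp[i] != gq[i] || rp[i] == 'N') {
              if (++mm > k) break;
              mmbuf.push_back(i);
            }
          }
          if (mm <= k) {
            out_read.push_back(r + 1);
            out_seq.push_back(s + 1);
            out_pos.push_back(pos);
            out_strand.push_back(strand == 0 ? 1 : -1);
            out_nm.push_back(mm);
            out_mmstart.push_back((int)mmflat.size());
            for (size_t j = 0; j < mmbuf.size(); ++j) mmflat.push_back(mmbuf[j]);
          }
        }
      }
    }
  }

  return List::create(
    _["read"] = wrap(out_read), _["seq"] = wrap(out_seq),
    _["pos0"] = wrap(out_pos), _["strand"] = wrap(out_strand),
    _["nm"] = wrap(out_nm), _["mm_start"] = wrap(out_mmstart),
    _["mm_flat"] = wrap(mmflat));
}

// Hamming mismatch offsets of `query` placed at 0-based `pos` on `ref`.
// [[Rcpp::export(name = ".mismatch_offsets_cpp")]]
List mismatch_offsets_cpp(CharacterVector ref, IntegerVector seqidx,
                          IntegerVector pos0, CharacterVector query) {
  const int n = query.size();
  List out(n);
  std::vector<std::string> seqs(ref.size());
  for (int s = 0; s < (int)ref.size(); ++s) seqs[s] = as<std::string>(ref[s]);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(query[i]);
    const std::string &g = seqs[seqidx[i] - 1];
    const int L = (int)q.size();
    if (pos0[i] < 0 || pos0[i] + L > (int)g.size())
      stop("alignment out of sequence bounds");
    std::vector<int> mm;
    for (int j = 0; j < L; ++j)
      if (q[j] != g[pos0[i] + j] || q[j] == 'N') mm.push_back(j);
    out[i] = wrap(mm);
  }
  return out;
}
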