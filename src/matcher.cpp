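#include <Rcpp.h>
using namespace Rcpp;

// Ungapped short-read matcher with <=1 mismatch, Bowtie "-v"-style semantics:
// no indels, every placement scored by Hamming distance. A read base 'N'
// counts as a mismatch at its position regardless of the reference base.

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// Hamming distance of read r (length k) against target t at offset off,
// bailing out once max_mm is exceeded. Returns max_mm + 1 on bail-out.
static inline int hamming_at(const char* t, const char* r, int k, int max_mm) {
  int mm = 0;
  for (int i = 0; i < k; ++i) {
    if (t[i] != r[i] || r[i] == 'N') {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

// All placements of one read on one target, both orientations if requested.
// strand: 1 = sense, 2 = antisense (reverse complement of the read matches
// the target window). Rows sorted by (mismatches, start, sense-first).
// [[Rcpp::export]]
DataFrame cpp_match_all(std::string read, std::string target, int max_mm,
                        bool antisense) {
  const int k = (int) read.size();
  const int L = (int) target.size();
  std::vector<int> starts, mms, strands;
  if (k >= 1 && k <= L) {
    std::string rc = antisense ? revcomp(read) : std::string();
    const char* t = target.c_str();
    for (int off = 0; off + k <= L; ++off) {
      int mm = hamming_at(t + off, read.c_str(), k, max_mm);
      if (mm <= max_mm) {
        starts.push_back(off); mms.push_back(mm); strands.push_back(1);
      }
      if (antisense) {
        int mm2 = hamming_at(t + off, rc.c_str(), k, max_mm);
        if (mm2 <= max_mm) {
          starts.push_back(off); mms.push_back(mm2); strands.push_back(2);
        }
      }
    }
  }
  const int n = (int) starts.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (mms[a] != mms[b]) return mms[a] < mms[b];
    if (starts[a] != starts[b]) return starts[a] < starts[b];
    return strands[a] < strands[b];
  });
  IntegerVector o_start(n), o_mm(n), o_strand(n);
  for (int i = 0; i < n; ++i) {
    o_start[i] = starts[ord[i]];
    o_mm[i] = mms[ord[i]];
    o_strand[i] = strands[ord[i]];
  }
  return DataFrame::create(_["start"] = o_start, _["strand"] = o_strand,
                           _["mismatches"] = o_mm);
}

// Sequential-exclusion annotation of many reads against an ordered category
// hierarchy. Targets arrive flattened in scan order: categories in priority
// order and, within a category, targets in lexicographic (byte) name order.
// Winner policy within the first category holding any hit: fewest
// mismatches, then scan order of targets, then smallest start, then sense
// before antisense. Because the scan visits candidates in exactly that
// order among equal-mismatch hits, the first 0-mismatch hit is final and
// the first 1-mismatch hit is the fallback winner.
// [[Rcpp::export]]
List cpp_annotate(CharacterVector reads, CharacterVector targets,
                  IntegerVector target_cat, LogicalVector target_antisense,
                  int max_mm) {
  const int n_reads = reads.size();
  const int n_tgt = targets.size();
  std::vector<std::string> tg(n_tgt);
  for (int j = 0; j < n_tgt; ++j) tg[j] = as<std::string>(targets[j]);

  IntegerVector out_cat(n_reads, NA_INTEGER), out_tgt(n_reads, NA_INTEGER),
      out_start(n_reads, NA_INTEGER), out_strand(n_reads, NA_INTEGER),
      out_mm(n_reads, NA_INTEGER);

  for (int i = 0; i < n_reads; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int k = (int) rd.size();
    std::string rc = revcomp(rd);
    int cur_cat = -1;
    // best hit within the current category
    int b_tgt = -1, b_start = -1, b_strand = 0, b_mm = max_mm + 1;
    bool assigned = false;
    for (int j = 0; j < n_tgt && !assigned; ++j) {
      int cat = target_cat[j];
      if (cat != cur_cat) {
        if (b_tgt >= 0) { assigned = true; break; }  // hit in previous category
        cur_cat = cat;
      }
      const int L = (int) tg[j].size();
      if (k > L || k < 1) continue;
      const char* t = tg[j].c_str();
      bool anti = target_antisense[j];
      for (int off = 0; off + k <= L; ++off) {
        int mm = hamming_at(t + off, rd.c_str(), k, b_mm - 1);
        if (mm < b_mm && mm <= max_mm) {
          b_tgt = j; b_start = off; b_strand = 1; b_mm = mm;
          if (mm == 0) break;
        }
        if (anti) {
          int mm2 = hamming_at(t + off, rc.c_str(), k, b_mm - 1);
          if (mm2 < b_mm && mm2 <= max_mm) {
            b_tgt = j; b_start = off; b_strand = 2; b_mm = mm2;
            if (mm2 == 0) break;
          }
        }
      }
      if (b_mm == 0) assigned = true;  // first exact hit is final in tie order
    }
    if (b_tgt >= 0) {
      out_cat[i] = target_cat[b_tgt];
      out_tgt[i] = b_tgt + 1;  // 1-based into the flattened target vector
      out_start[i] = b_start;
      out_strand[i] = b_strand;
      out_mm[i] = b_mm;
    }
  }
  return List::create(_["cat"] = out_cat, _["target"] = out_tgt,
                      _["start"] = out_start, _["strand"] = out_strand,
                      _["mismatches"] = out_mm);
}
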