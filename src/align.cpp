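#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps: a gap of length L costs
// gap_open + L * gap_extend.  Read is the pattern, ref the subject; both plain
// ACGT strings (any other character never matches).  Best cell ties resolve to
// the first cell in row-major scan order so results are deterministic.
//
// Returns score plus 0-based half-open coordinates of the aligned region in
// read and ref, a CIGAR-like op string over the aligned region using
// M (match), X (mismatch), I (insertion in read), D (deletion from ref),
// and the match / aligned-column counts used for percent identity.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string read, std::string ref,
              int match = 10, int mismatch = -20,
              int gap_open = 20, int gap_extend = 5) {
  const int m = (int) read.size(), n = (int) ref.size();
  if (m == 0 || n == 0) stop("empty sequence in alignment");
  const int NEG = INT_MIN / 4;
  const int gi = gap_open + gap_extend;  // cost of opening a length-1 gap

  // H, E, F as rolling rows; full byte traceback matrices.
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<int> Fcur(n + 1, NEG), Fprev(n + 1, NEG);
  // tb codes for H: 0 stop, 1 diag, 2 from E (D op), 3 from F (I op)
  std::vector<unsigned char> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((size_t)(m + 1) * (n + 1), 0); // 1 = extend
  std::vector<unsigned char> tbF((size_t)(m + 1) * (n + 1), 0); // 1 = extend

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Ecur[0] = NEG; Hcur[0] = 0; Fcur[0] = NEG;
    const int rc = base_code(read[i - 1]);
    for (int j = 1; j <= n; ++j) {
      const size_t at = (size_t) i * (n + 1) + j;
      // E: gap consuming ref (deletion from ref relative to read)
      int e_open = Hcur[j - 1] - gi, e_ext = Ecur[j - 1] - gap_extend;
      Ecur[j] = e_open >= e_ext ? e_open : e_ext;
      tbE[at] = e_open >= e_ext ? 0 : 1;
      // F: gap consuming read (insertion in read)
      int f_open = Hprev[j] - gi, f_ext = Fprev[j] - gap_extend;
      Fcur[j] = f_open >= f_ext ? 0 + f_open : f_ext;
      tbF[at] = f_open >= f_ext ? 0 : 1;
      const int s = (rc >= 0 && rc == base_code(ref[j - 1])) ? match : mismatch;
      int h = 0; unsigned char tb = 0;
      const int diag = Hprev[j - 1] + s;
      if (diag > h) { h = diag; tb = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; tb = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; tb = 3; }
      Hcur[j] = h; tbH[at] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  // traceback from (bi, bj)
  std::string ops; ops.reserve(m + 16);
  int i = bi, j = bj, n_match = 0;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    const size_t at = (size_t) i * (n + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[at];
      if (tb == 0) break;
      if (tb == 1) {
        const bool is_m = base_code(read[i - 1]) >= 0 &&
          base_code(read[i - 1]) == base_code(ref[j - 1]);
        ops.push_back(is_m ? 'M' : 'X');
        if (is_m) ++n_match;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {           // E: D op, consumes ref
      ops.push_back('D');
      unsigned char tb = tbE[at];
      --j;
      if (tb == 0) state = 0;          // gap was opened here
    } else {                           // F: I op, consumes read
      ops.push_back('I');
      unsigned char tb = tbF[at];
      --i;
      if (tb == 0) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode ops into a CIGAR-like string keeping M/X distinct
  std::string cigar;
  int run = 0; char cur = 0;
  for (char c : ops) {
    if (c == cur) { ++run; }
    else {
      if (run > 0) { cigar += std::to_string(run); cigar.push_back(cur); }
      cur = c; run = 1;
    }
  }
  if (run > 0) { cigar += std::to_string(run); cigar.push_back(cur); }

  return List::create(
    _["score"] = best,
    _["read_start"] = i, _["read_end"] = bi,
    _["ref_start"] = j, _["ref_end"] = bj,
    _["cigar"] = cigar,
    _["n_match"] = n_match,
    _["n_cols"] = (int) ops.size());
}

// Tally per-sample allele counts (A, C, G, T, gap) over reference positions
// from aligned reads.  Insertions in reads do not occupy a reference column;
// they are returned separately.  Coordinates are 0-based; `offset` maps each
// transcript to its slot in a concatenated coordinate space.
// [[Rcpp::export(name = ".pileup_tally")]]
List pileup_tally(IntegerVector tx, IntegerVector start, IntegerVector sample,
                  CharacterVector cigar, CharacterVector qseq,
                  IntegerVector offset, int total_len, int n_samples) {
  const int n = tx.size();
  // counts[(gpos * n_samples + s) * 5 + allele]
  std::vector<int> counts((size_t) total_len * n_samples * 5, 0);
  std::vector<int> ins_pos, ins_sample, ins_len;
  for (int a = 0; a < n; ++a) {
    const int s = sample[a] - 1;
    int rpos = offset[tx[a] - 1] + start[a];   // global ref position
    const char *cg = CHAR(STRING_ELT(cigar, a));
    const char *q  = CHAR(STRING_ELT(qseq, a));
    int qi = 0, len = 0;
    for (const char *p = cg; *p; ++p) {
      if (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); continue; }
      const char op = *p;
      if (op == 'M' || op == 'X') {
        for (int t = 0; t < len; ++t) {
          int b = base_code(q[qi + t]);
          if (b >= 0) {
            size_t at = ((size_t)(rpos + t) * n_samples + s) * 5 + b;
            if (rpos + t >= 0 && rpos + t < total_len) ++counts[at];
          }
        }
        rpos += len; qi += len;
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t) {
          if (rpos + t >= 0 && rpos + t < total_len) {
            size_t at = ((size_t)(rpos + t) * n_samples + s) * 5 + 4;
            ++counts[at];
          }
        }
        rpos += len;
      } else if (op == 'I') {
        ins_pos.push_back(rpos); ins_sample.push_back(s + 1);
        ins_len.push_back(len);
        qi += len;
      } else if (op == 'S') {
        qi += len;
      } else {
        stop("unknown cigar op '%c'", op);
      }
      len = 0;
    }
  }
  // emit non-empty columns only
  std::vector<int> out_pos, out_sample, out_a, out_c, out_g, out_t, out_gap;
  for (int g = 0; g < total_len; ++g) {
    for (int s = 0; s < n_samples; ++s) {
      const size_t at = ((size_t) g * n_samples + s) * 5;
      int tot = counts[at] + counts[at + 1] + counts[at + 2] +
                counts[at + 3] + counts[at + 4];
      if (tot > 0) {
        out_pos.push_back(g); out_sample.push_back(s + 1);
        out_a.push_back(counts[at]); out_c.push_back(counts[at + 1]);
        out_g.push_back(counts[at + 2]); out_t.push_back(counts[at + 3]);
        out_gap.push_back(counts[at + 4]);
      }
    }
  }
  return List::create(
    _["gpos"] = wrap(out_pos), _["sample"] = wrap(out_sample),
    _["A"] = wrap(out_a), _["C"] = wrap(out_c), _["G"] = wrap(out_g),
    _["T"] = wrap(out_t), _["gap"] = wrap(out_gap),
    _["ins_gpos"] = wrap(ins_pos), _["ins_sample"] = wrap(ins_sample),
    _["ins_len"] = wrap(ins_len));
}
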