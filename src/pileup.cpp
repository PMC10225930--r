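#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// Flag bits excluded from all tallies: unmapped, secondary, duplicate,
// supplementary.  Duplicate removal honors the aligner/Picard flag.
static inline bool excluded_flag(int flag) {
  return (flag & 4) || (flag & 256) || (flag & 1024) || (flag & 2048);
}

static inline int base_index(char b) {
  switch (b) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N and anything else
  }
}

struct CigarWalker {
  // Iterates aligned (reference-consuming, read-consuming) positions of one
  // read.  Soft clips consume read bases only, so they shift the offset used
  // for raw-read-end distances; insertions consume read, deletions/skips
  // consume reference.
  const std::string &cig;
  size_t ci;
  int ref_pos;   // 1-based reference coordinate of next aligned base
  int read_pos;  // 0-based offset in SEQ (soft clips included)
  int op_len;
  char op;
  CigarWalker(const std::string &cigar, int pos)
    : cig(cigar), ci(0), ref_pos(pos), read_pos(0), op_len(0), op('\0') {}
  bool next_op() {
    if (ci >= cig.size()) return false;
    int len = 0;
    while (ci < cig.size() && isdigit(cig[ci])) {
      len = len * 10 + (cig[ci] - '0');
      ++ci;
    }
    if (ci >= cig.size()) stop("malformed CIGAR: ", cig);
    op = cig[ci++];
    op_len = len;
    return true;
  }
};

// [[Rcpp::export(name = ".pileup_engine")]]
List pileup_engine(IntegerVector pos, IntegerVector flag, IntegerVector mapq,
                   CharacterVector cigar, CharacterVector seq,
                   CharacterVector qual, std::string ref, int region_start,
                   int region_end, int q_base, int q_map) {
  const int n = pos.size();
  const int width = region_end - region_start + 1;
  if (width <= 0) stop("empty region");

  // raw and filtered per-base counts + filtered ref-base strand counts
  IntegerMatrix counts(width, 12);
  std::vector<int> mm_pos, mm_bq, mm_mq, mm_dist;
  std::vector<char> mm_base;
  std::vector<int> mm_rev;

  int last_pos = -1;
  for (int i = 0; i < n; ++i) {
    if (excluded_flag(flag[i])) continue;
    if (pos[i] < last_pos)
      stop("alignments are not coordinate-sorted; sort the input first");
    last_pos = pos[i];
    const std::string s = as<std::string>(seq[i]);
    const std::string q = as<std::string>(qual[i]);
    const std::string cg = as<std::string>(cigar[i]);
    const int L = (int)s.size();
    const bool rev = (flag[i] & 16) != 0;
    CigarWalker w(cg, pos[i]);
    while (w.next_op()) {
      switch (w.op) {
      case 'M': case '=': case 'X': {
        for (int k = 0; k < w.op_len; ++k) {
          const int rp = w.ref_pos + k;
          const int qp = w.read_pos + k;
          if (rp < region_start || rp > region_end) continue;
          if (rp < 1 || rp > (int)ref.size())
            stop("alignment extends beyond reference sequence");
          const int row = rp - region_start;
          const char rb = s[qp];
          const int bi = base_index(rb);
          const int bq = (int)q[qp] - 33;
          counts(row, bi) += 1;
          const bool pass = bq >= q_base && mapq[i] >= q_map;
          if (pass) counts(row, 5 + bi) += 1;
          const char refb = (char)toupper(ref[rp - 1]);
          const char rdb = (char)toupper(rb);
          if (pass && rdb == refb)
            counts(row, rev ? 11 : 10) += 1;
          if (rdb != refb && rdb != 'N' && refb != 'N') {
            const int dist = std::min(qp, L - 1 - qp);
            mm_pos.push_back(rp);
            mm_base.push_back(rdb);
            mm_bq.push_back(bq);
            mm_mq.push_back(mapq[i]);
            mm_dist.push_back(dist);
            mm_rev.push_back(rev ? 1 : 0);
          }
        }
        w.ref_pos += w.op_len;
        w.read_pos += w.op_len;
        break;
      }
      case 'I': case 'S':
        w.read_pos += w.op_len;
        break;
      case 'D': case 'N':
        w.ref_pos += w.op_len;
        break;
      case 'H': case 'P':
        break;
      default:
        stop("unsupported CIGAR op: ", std::string(1, w.op));
      }
    }
  }

  CharacterVector mmb(mm_base.size());
  for (size_t i = 0; i < mm_base.size(); ++i)
    mmb[i] = std::string(1, mm_base[i]);
  return List::create(
      _["counts"] = counts,
      _["mm_pos"] = wrap(mm_pos), _["mm_base"] = mmb,
      _["mm_bq"] = wrap(mm_bq), _["mm_mq"] = wrap(mm_mq),
      _["mm_dist"] = wrap(mm_dist), _["mm_rev"] = wrap(mm_rev));
}

// Per-read gene-level editing aggregation: a read enters the denominator if
// it covers at least one listed site with base quality > q_base, mapping
// quality > q_map and the site >= min_end bp from both raw read ends; it
// enters the numerator if additionally it carries the edited base at such a
// site.  Thresholds are strict (>) to match "higher than" read filters.
// [[Rcpp::export(name = ".gene_editing_reads")]]
IntegerVector gene_editing_reads(IntegerVector pos, IntegerVector flag,
                                 IntegerVector mapq, CharacterVector cigar,
                                 CharacterVector seq, CharacterVector qual,
                                 IntegerVector site_pos,
                                 CharacterVector site_alt, int q_base,
                                 int q_map, int min_end) {
  const int n = pos.size();
  const int ns = site_pos.size();
  std::vector<char> alt(ns);
  for (int j = 0; j < ns; ++j)
    alt[j] = (char)toupper(as<std::string>(site_alt[j])[0]);

  int denom = 0, numer = 0;
  for (int i = 0; i < n; ++i) {
    if (excluded_flag(flag[i])) continue;
    if (mapq[i] <= q_map) continue;
    const std::string s = as<std::string>(seq[i]);
    const std::string q = as<std::string>(qual[i]);
    const std::string cg = as<std::string>(cigar[i]);
    const int L = (int)s.size();
    bool covers = false, edited = false;
    CigarWalker w(cg, pos[i]);
    while (w.next_op()) {
      if (w.op == 'M' || w.op == '=' || w.op == 'X') {
        for (int j = 0; j < ns; ++j) {
          const int sp = site_pos[j];
          if (sp >= w.ref_pos && sp < w.ref_pos + w.op_len) {
            const int qp = w.read_pos + (sp - w.ref_pos);
            const int bq = (int)q[qp] - 33;
            const int dist = std::min(qp, L - 1 - qp);
            if (bq > q_base && dist >= min_end) {
              covers = true;
              if ((char)toupper(s[qp]) == alt[j]) edited = true;
            }
          }
        }
        w.ref_pos += w.op_len;
        w.read_pos += w.op_len;
      } else if (w.op == 'I' || w.op == 'S') {
        w.read_pos += w.op_len;
      } else if (w.op == 'D' || w.op == 'N') {
        w.ref_pos += w.op_len;
      }
    }
    if (covers) {
      ++denom;
      if (edited) ++numer;
    }
  }
  return IntegerVector::create(_["filtered_reads"] = denom,
                               _["edited_reads"] = numer);
}
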