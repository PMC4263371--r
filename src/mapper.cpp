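#include <Rcpp.h>
#include <cstdint>
#include <fstream>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

struct Candidate {
  int gene;
  int start;   // 0-based offset on the reference
  bool rc;     // read mapped as its reverse complement
};

// Exact-k-mer seeded, ungapped Hamming-distance mapper for substitution-only
// short reads against a small set of ORF references.  Reads whose best
// alignment exceeds max_mm_frac * read_len mismatches, or whose best
// alignment is not unique, are discarded.  Returns per-gene 5 x L count
// matrices (rows A, C, G, T, other).
// [[Rcpp::export]]
List cpp_map_fastq(const std::string& fastq_path, CharacterVector gene_ids,
                   CharacterVector gene_seqs, int kmer, int step,
                   double max_mm_frac) {
  const int ng = gene_seqs.size();
  if (ng == 0) stop("empty reference set");
  if (kmer < 4 || kmer > 31) stop("kmer must be in 4..31");
  std::vector<std::string> refs(ng);
  for (int g = 0; g < ng; ++g) refs[g] = as<std::string>(gene_seqs[g]);

  // k-mer index over the forward strand of every reference
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  const uint64_t mask = (((uint64_t)1) << (2 * kmer)) - 1;
  size_t total_len = 0;
  for (int g = 0; g < ng; ++g) {
    const std::string& s = refs[g];
    total_len += s.size();
    if ((int)s.size() < kmer) continue;
    uint64_t h = 0;
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      const int c = base_code(s[i]);
      if (c < 0) {
        run = 0;
        h = 0;
        continue;
      }
      h = ((h << 2) | (uint64_t)c) & mask;
      ++run;
      if (run >= kmer) index[h].push_back(std::make_pair(g, i - kmer + 1));
    }
  }
  index.max_load_factor(0.7f);

  // per-gene interleaved counts: 5 * L (A, C, G, T, other per position)
  std::vector<std::vector<int> > counts(ng);
  for (int g = 0; g < ng; ++g)
    counts[g].assign(5 * refs[g].size(), 0);

  std::ifstream in(fastq_path.c_str());
  if (!in) stop("cannot open FASTQ file");

  long n_total = 0, n_mapped = 0, n_ambiguous = 0, n_unmapped = 0;
  std::string header, seq, plus, qual, rcseq;
  std::vector<Candidate> cands;
  cands.reserve(8);

  while (std::getline(in, header)) {
    if (!std::getline(in, seq)) stop("truncated FASTQ record");
    if (!std::getline(in, plus)) stop("truncated FASTQ record");
    if (!std::getline(in, qual)) stop("truncated FASTQ record");
    ++n_total;
    const int len = (int)seq.size();
    for (int i = 0; i < len; ++i) {
      const char c = seq[i];
      if (c >= 'a' && c <= 'z') seq[i] = c - 32;
    }
    rcseq.resize(len);
    for (int i = 0; i < len; ++i) rcseq[i] = comp_base(seq[len - 1 - i]);

    cands.clear();
    const int max_mm = (int)(max_mm_frac * len);
    for (int ori = 0; ori < 2; ++ori) {
      const std::string& r = (ori == 0) ? seq : rcseq;
      if (len < kmer) break;
      // seed offsets every `step` bases plus one flush with the read end
      for (int o = 0, done = 0; !done; o += step) {
        if (o >= len - kmer) {
          o = len - kmer;
          done = 1;
        }
        uint64_t h = 0;
        bool ok = true;
        for (int j = 0; j < kmer; ++j) {
          const int c = base_code(r[o + j]);
          if (c < 0) {
            ok = false;
            break;
          }
          h = ((h << 2) | (uint64_t)c) & mask;
        }
        if (!ok) continue;
        std::unordered_map<uint64_t,
                           std::vector<std::pair<int, int> > >::const_iterator
            it = index.find(h);
        if (it == index.end()) continue;
        const std::vector<std::pair<int, int> >& hits = it->second;
        for (size_t hix = 0; hix < hits.size(); ++hix) {
          const int g = hits[hix].first;
          const int start = hits[hix].second - o;
          if (start < 0 || start + len > (int)refs[g].size()) continue;
          bool seen = false;
          for (size_t ci = 0; ci < cands.size(); ++ci) {
            if (cands[ci].gene == g && cands[ci].start == start &&
                cands[ci].rc == (ori == 1)) {
              seen = true;
              break;
            }
          }
          if (!seen) {
            Candidate cd;
            cd.gene = g;
            cd.start = start;
            cd.rc = (ori == 1);
            cands.push_back(cd);
          }
        }
      }
    }

    int best_d = len + 1, best_ix = -1, n_best = 0;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      const std::string& r = cands[ci].rc ? rcseq : seq;
      const std::string& ref = refs[cands[ci].gene];
      const int start = cands[ci].start;
      int d = 0;
      for (int j = 0; j < len; ++j) {
        if (r[j] != ref[start + j]) {
          ++d;
          if (d > best_d) break;
        }
      }
      if (d < best_d) {
        best_d = d;
        best_ix = (int)ci;
        n_best = 1;
      } else if (d == best_d) {
        ++n_best;
      }
    }

    if (best_ix < 0 || best_d > max_mm) {
      ++n_unmapped;
      continue;
    }
    if (n_best > 1) {
      ++n_ambiguous;
      continue;
    }
    ++n_mapped;
    const Candidate& cd = cands[best_ix];
    const std::string& r = cd.rc ? rcseq : seq;
    std::vector<int>& cnt = counts[cd.gene];
    for (int j = 0; j < len; ++j) {
      int c = base_code(r[j]);
      if (c < 0) c = 4;
      ++cnt[5 * (cd.start + j) + c];
    }
  }
  in.close();

  List mats(ng);
  CharacterVector rn = CharacterVector::create("A", "C", "G", "T", "other");
  for (int g = 0; g < ng; ++g) {
    const int L = (int)refs[g].size();
    IntegerMatrix m(5, L);
    for (int p = 0; p < L; ++p)
      for (int b = 0; b < 5; ++b) m(b, p) = counts[g][5 * p + b];
    m.attr("dimnames") = List::create(rn, R_NilValue);
    mats[g] = m;
  }
  mats.attr("names") = gene_ids;
  return List::create(_["counts"] = mats, _["n_total"] = (double)n_total,
                      _["n_mapped"] = (double)n_mapped,
                      _["n_ambiguous"] = (double)n_ambiguous,
                      _["n_unmapped"] = (double)n_unmapped);
}
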