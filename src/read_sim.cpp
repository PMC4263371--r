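#include <Rcpp.h>
#include <fstream>
#include <string>

using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Draw 1x read_len substrings uniformly over [0, L - read_len] from a colony
// plasmid sequence, plant per-base substitution sequencing errors, and append
// 4-line FASTQ records (constant Phred-33 'I' quality) to `path`.
//
// All randomness goes through R's RNG so set.seed() gives byte-identical
// output.
// [[Rcpp::export]]
int cpp_sim_reads(const std::string& seq, int n_reads, int read_len,
                  double err_rate, const std::string& id_prefix,
                  const std::string& path, bool append) {
  const int L = (int)seq.size();
  if (L < read_len) stop("sequence shorter than read length");
  if (n_reads < 0) stop("negative read count");
  std::ofstream out(path.c_str(),
                    append ? (std::ios::out | std::ios::app) : std::ios::out);
  if (!out) stop("cannot open FASTQ output file");
  const std::string qual(read_len, 'I');
  std::string buf;
  buf.reserve(1 << 20);
  std::string read;
  const int nstart = L - read_len + 1;
  for (int i = 0; i < n_reads; ++i) {
    int start = (int)(unif_rand() * nstart);
    if (start >= nstart) start = nstart - 1;
    read.assign(seq, start, read_len);
    if (err_rate > 0) {
      int nerr = (int)R::rbinom((double)read_len, err_rate);
      for (int e = 0; e < nerr; ++e) {
        int pos = (int)(unif_rand() * read_len);
        if (pos >= read_len) pos = read_len - 1;
        const char cur = read[pos];
        char sub = cur;
        while (sub == cur) sub = BASES[(int)(unif_rand() * 4) & 3];
        read[pos] = sub;
      }
    }
    buf += '@';
    buf += id_prefix;
    buf += '_';
    buf += std::to_string(i + 1);
    buf += '\n';
    buf += read;
    buf += "\n+\n";
    buf += qual;
    buf += '\n';
    if (buf.size() > (1u << 20) - 1024u) {
      out << buf;
      buf.clear();
    }
  }
  out << buf;
  out.close();
  if (!out) stop("error writing FASTQ output");
  return n_reads;
}
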