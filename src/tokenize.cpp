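#include <Rcpp.h>
using namespace Rcpp;

// Lexicographic k-mer codes (A<C<G<T), 1-based so that 0 stays reserved.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// [[Rcpp::export]]
List cpp_tokenize(CharacterVector seqs, int k, int stride = 1) {
  if (k < 1) stop("k must be >= 1");
  if (stride < 1) stop("stride must be >= 1");
  int n = seqs.size();
  List out(n);
  for (int s = 0; s < n; ++s) {
    std::string str = as<std::string>(seqs[s]);
    int L = (int) str.size();
    if (k > L)
      stop("k (%d) exceeds sequence length (%d) for sequence %d", k, L, s + 1);
    // validate alphabet up front so the error names the offending position
    std::vector<int> codes(L);
    for (int i = 0; i < L; ++i) {
      int c = base_code(str[i]);
      if (c < 0)
        stop("non-ACGT character '%c' at position %d of sequence %d",
             str[i], i + 1, s + 1);
      codes[i] = c;
    }
    int n_win = (L - k) / stride + 1;
    IntegerVector toks(n_win);
    for (int w = 0; w < n_win; ++w) {
      int start = w * stride;
      long code = 0;
      for (int j = 0; j < k; ++j) code = code * 4 + codes[start + j];
      toks[w] = (int) code + 1;  // 1 .. 4^k
    }
    out[s] = toks;
  }
  return out;
}
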