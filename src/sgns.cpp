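// Skip-gram with negative sampling over k-mer sentences, with optional
// FastText-style character n-gram subword vectors. Single-threaded and
// deterministic for a fixed seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sigmoid_d(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// sentences: list of 0-based token id vectors
// subwords: list of length V, each a 0-based id vector into the subword
//   table (may be empty; the word's own vector is always used)
// [[Rcpp::export]]
arma::mat cpp_sgns_train(List sentences, int V, int dim, int window,
                         int epochs, int negative, int min_count,
                         double lr0, List subwords, int n_sub,
                         int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // corpus counts
  std::vector<long> cnt(V, 0);
  long total_positions = 0;
  const int S = sentences.size();
  std::vector<std::vector<int>> corpus(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector sv = sentences[s];
    corpus[s].assign(sv.begin(), sv.end());
    for (int w : corpus[s]) {
      if (w < 0 || w >= V) stop("token id out of range");
      ++cnt[w];
    }
  }
  // drop rare words (min_count) from training sentences
  if (min_count > 1) {
    for (auto& sent : corpus) {
      std::vector<int> kept;
      for (int w : sent) if (cnt[w] >= min_count) kept.push_back(w);
      sent.swap(kept);
    }
  }
  for (auto& sent : corpus) total_positions += (long)sent.size();
  if (total_positions == 0) stop("empty corpus after min_count filtering");

  // unigram^0.75 negative-sampling table
  const int TBL = 1 << 20;
  std::vector<int> table(TBL);
  {
    std::vector<double> p(V, 0.0);
    double z = 0.0;
    for (int w = 0; w < V; ++w)
      if (cnt[w] >= min_count && cnt[w] > 0) {
        p[w] = std::pow((double)cnt[w], 0.75);
        z += p[w];
      }
    double acc = 0.0;
    int w = -1;
    for (int i = 0; i < TBL; ++i) {
      double target = (i + 0.5) / TBL * z;
      while (acc < target && w < V - 1) {
        ++w;
        acc += p[w];
      }
      table[i] = std::max(w, 0);
    }
  }

  // input (word + subword) and output vectors
  arma::mat in_w(dim, V), in_s;
  arma::mat out(dim, V, arma::fill::zeros);
  for (arma::uword i = 0; i < in_w.n_elem; ++i)
    in_w(i) = (unif(rng) - 0.5) / dim;
  if (n_sub > 0) {
    in_s.set_size(dim, n_sub);
    for (arma::uword i = 0; i < in_s.n_elem; ++i)
      in_s(i) = (unif(rng) - 0.5) / dim;
  }
  std::vector<std::vector<int>> sub(V);
  for (int w = 0; w < V; ++w) {
    IntegerVector s = subwords[w];
    sub[w].assign(s.begin(), s.end());
  }

  arma::vec h(dim), gh(dim);
  const long total_work = total_positions * (long)epochs;
  long done = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (auto& sent : corpus) {
      const int L = (int)sent.size();
      for (int pos = 0; pos < L; ++pos, ++done) {
        double lr = lr0 * std::max(1e-4, 1.0 - (double)done / total_work);
        int w = sent[pos];
        int win = 1 + (int)(unif(rng) * window);
        if (win > window) win = window;
        const int n_in = 1 + (int)sub[w].size();
        // hidden = average of the word's input vectors
        h = in_w.col(w);
        for (int g : sub[w]) h += in_s.col(g);
        h /= n_in;
        gh.zeros();
        bool any = false;
        for (int off = -win; off <= win; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= L) continue;
          int c = sent[cpos];
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = c;
              label = 1.0;
            } else {
              target = table[(int)(unif(rng) * TBL) % TBL];
              if (target == c) continue;
              label = 0.0;
            }
            double f = sigmoid_d(arma::dot(out.col(target), h));
            double g = (label - f) * lr;
            gh += g * out.col(target);
            out.col(target) += g * h;
          }
          any = true;
        }
        if (any) {
          gh /= n_in;
          in_w.col(w) += gh;
          for (int g : sub[w]) in_s.col(g) += gh;
        }
      }
    }
  }

  // final word embeddings: average of input vectors; zero rows for k-mers
  // never seen in the corpus so unseen tokens stay inert downstream
  arma::mat W(V, dim, arma::fill::zeros);
  for (int w = 0; w < V; ++w) {
    if (cnt[w] < std::max(min_count, 1)) continue;
    arma::vec v = in_w.col(w);
    for (int g : sub[w]) v += in_s.col(g);
    v /= (1 + (int)sub[w].size());
    W.row(w) = v.t();
  }
  return W;
}
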