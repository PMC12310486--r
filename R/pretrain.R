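#' Skip-gram pretraining configuration
#'
#' Controls the FastText-style skip-gram-with-negative-sampling pretrainer
#' for k-mer embeddings. Negative sampling approximates the full softmax over
#' the vocabulary; subword character n-grams over the k-letter tokens add
#' FastText's subword modeling (set `subword_ngrams = "off"` for plain
#' skip-gram).
#'
#' @param dim embedding dimension (default 64).
#' @param window context radius in tokens (default 5).
#' @param epochs passes over the corpus (default 10).
#' @param negative negative samples per positive pair (default 5).
#' @param min_count minimum corpus frequency for a token to be trained
#'   (default 1).
#' @param subword_ngrams `c(min, max)` character n-gram lengths over the
#'   boundary-marked token, or `"off"`.
#' @param lr initial learning rate, decayed linearly (default 0.025).
#' @param seed integer seed.
#' @param workers training threads; only 1 is supported (training is
#'   deterministic).
#' @return A `skipgram_config` list.
#' @export
skipgram_config <- function(dim = 64L, window = 5L, epochs = 10L,
                            negative = 5L, min_count = 1L,
                            subword_ngrams = c(3L, 5L), lr = 0.025,
                            seed = 1L, workers = 1L) {
  stopifnot(dim >= 1, window >= 1, epochs >= 1, negative >= 0,
            min_count >= 1, lr > 0)
  if (!identical(subword_ngrams, "off")) {
    stopifnot(length(subword_ngrams) == 2L,
              subword_ngrams[1] >= 1, subword_ngrams[1] <= subword_ngrams[2])
    subword_ngrams <- as.integer(subword_ngrams)
  }
  if (workers != 1L)
    stop("only single-threaded training is supported", call. = FALSE)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 min_count = as.integer(min_count),
                 subword_ngrams = subword_ngrams, lr = lr,
                 seed = as.integer(seed), workers = 1L),
            class = "skipgram_config")
}

#' Build the pretraining corpus of k-mer sentences
#'
#' Each miRNA contributes one sentence (its full token sequence); each mRNA is
#' first reversed, then fragmented into overlapping 200-400 nt windows, each
#' fragment contributing one sentence. Records too short to yield a single
#' k-mer are skipped with a warning.
#'
#' @param records list of normalized `seq_record`.
#' @param k k-mer length.
#' @param frag list of fragmentation settings: `min_len`, `max_len`,
#'   `overlap`, `seed` (see [fragment_mrna()]).
#' @return list of character vectors (token sentences), deterministic given
#'   input order and the fragment seed.
#' @export
build_corpus <- function(records, k = 6L,
                         frag = list(min_len = 200L, max_len = 400L,
                                     overlap = 100L, seed = 1L)) {
  sentences <- list()
  skipped <- 0L
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (nchar(rec$residues) < k) {
      skipped <- skipped + 1L
      next
    }
    if (rec$role == "miRNA") {
      sentences[[length(sentences) + 1L]] <- tokenize_kmers(rec$residues, k)
    } else {
      rev_rec <- reverse_orientation(rec)
      fs <- fragment_mrna(rev_rec, frag$min_len, frag$max_len, frag$overlap,
                          seed = frag$seed + i)
      for (res in fs$fragments$residues) {
        if (nchar(res) < k) next
        sentences[[length(sentences) + 1L]] <- tokenize_kmers(res, k)
      }
    }
  }
  if (skipped > 0L)
    warning(skipped, " record(s) shorter than k = ", k, " skipped")
  sentences
}

# Character n-grams of a boundary-marked token, fastText-style.
token_ngrams <- function(token, nmin, nmax) {
  w <- paste0("<", token, ">")
  L <- nchar(w)
  out <- character(0)
  for (n in nmin:nmax) {
    if (n > L) next
    out <- c(out, substring(w, seq_len(L - n + 1L), seq_len(L - n + 1L) + n - 1L))
  }
  out
}

#' Pretrain k-mer embeddings on a corpus
#'
#' Skip-gram with negative sampling (the standard estimator of the softmax
#' co-occurrence objective), optionally with FastText subword vectors.
#' Rows for k-mers absent from the corpus are zero, so unseen tokens stay
#' inert downstream. Deterministic for a fixed seed.
#'
#' @param corpus list of token sentences from [build_corpus()].
#' @param cfg a [skipgram_config()].
#' @param vocab a `kmer_vocabulary` matching the corpus tokens.
#' @return A `kmer_embedding`: list with `vocabulary`, `weights`
#'   (`4^k x dim`, rownames = tokens), and `cfg`.
#' @export
train_embeddings <- function(corpus, cfg = skipgram_config(),
                             vocab = build_vocabulary(6L)) {
  stopifnot(inherits(cfg, "skipgram_config"),
            inherits(vocab, "kmer_vocabulary"))
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  sentences <- lapply(corpus, function(s) kmer_index(vocab, s))
  V <- length(vocab$tokens)
  if (identical(cfg$subword_ngrams, "off")) {
    subwords <- rep(list(integer(0)), V)
    n_sub <- 0L
  } else {
    grams <- lapply(vocab$tokens, token_ngrams,
                    nmin = cfg$subword_ngrams[1], nmax = cfg$subword_ngrams[2])
    sub_vocab <- sort(unique(unlist(grams)))
    subwords <- lapply(grams, function(g)
      match(g, sub_vocab) - 1L)
    n_sub <- length(sub_vocab)
  }
  W <- cpp_sgns_train(sentences, V, cfg$dim, cfg$window, cfg$epochs,
                      cfg$negative, cfg$min_count, cfg$lr, subwords, n_sub,
                      cfg$seed)
  rownames(W) <- vocab$tokens
  if (any(!is.finite(W))) stop("non-finite embedding entries", call. = FALSE)
  structure(list(vocabulary = vocab, weights = W, cfg = cfg),
            class = "kmer_embedding")
}

#' Save / load the embedding matrix as TSV
#'
#' One row per k-mer (vocabulary order): token then `dim` numeric columns.
#' Loading validates the declared `k` and `dim` against the table shape.
#'
#' @param emb a `kmer_embedding`.
#' @param path file path.
#' @return `write_embedding_tsv`: the path, invisibly;
#'   `read_embedding_tsv`: a `kmer_embedding`.
#' @export
write_embedding_tsv <- function(emb, path) {
  stopifnot(inherits(emb, "kmer_embedding"))
  df <- data.frame(token = rownames(emb$weights), emb$weights,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @param k,dim expected k-mer length and embedding dimension.
#' @export
read_embedding_tsv <- function(path, k = 6L, dim = 64L) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  vocab <- build_vocabulary(k)
  if (nrow(df) != length(vocab$tokens) || ncol(df) != dim + 1L)
    stop("embedding table is ", nrow(df), " x ", ncol(df) - 1L,
         ", expected ", length(vocab$tokens), " x ", dim, call. = FALSE)
  if (!identical(df[[1]], vocab$tokens))
    stop("token column does not match the lexicographic vocabulary",
         call. = FALSE)
  W <- as.matrix(df[, -1])
  dimnames(W) <- list(vocab$tokens, NULL)
  structure(list(vocabulary = vocab, weights = W,
                 cfg = skipgram_config(dim = dim)),
            class = "kmer_embedding")
}
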