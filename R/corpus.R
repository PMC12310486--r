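#' @useDynLib mirtarnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never clobber user-level
# reproducibility.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Normalize a raw sequence into an RNA-alphabet record
#'
#' Uppercases, strips whitespace, and maps T to U so that DNA-alphabet FASTA
#' (e.g. transcript databases) and RNA-alphabet FASTA are interchangeable.
#' Ambiguity codes (N, R, Y, ...) are rejected rather than imputed: the k-mer
#' vocabulary is defined over \{A,C,G,U\} only.
#'
#' @param id sequence identifier.
#' @param raw character scalar; residues over A/C/G/U/T, any case, possibly
#'   with whitespace or line breaks.
#' @param role one of `"miRNA"` or `"mRNA"`.
#' @return A `seq_record`: list with `id`, `residues`, `role`.
#' @export
normalize_sequence <- function(id, raw, role = c("miRNA", "mRNA")) {
  role <- match.arg(role)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("`raw` must be a non-empty character scalar", call. = FALSE)
  res <- gsub("[[:space:]]", "", raw)
  if (!nzchar(res))
    stop("sequence '", id, "' is empty after whitespace removal", call. = FALSE)
  res <- toupper(res)
  res <- chartr("T", "U", res)
  bad <- regexpr("[^ACGU]", res)
  if (bad > 0L) {
    stop("sequence '", id, "' has invalid residue '",
         substr(res, bad, bad), "' at position ", bad, call. = FALSE)
  }
  structure(list(id = id, residues = res, role = role), class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<%s> %s (%d nt)\n", x$role, x$id, nchar(x$residues)))
  invisible(x)
}

#' Reverse the orientation of an mRNA record
#'
#' Character-wise reversal (5'->3' becomes 3'->5') with no complementation:
#' the antisense-aware preprocessing exposes the mRNA to the encoder in the
#' orientation in which a miRNA pairs with it, while complementarity itself is
#' left for the model to learn.
#'
#' @param rec a `seq_record` with role `"mRNA"`.
#' @return The record with `residues` reversed; id preserved.
#' @export
reverse_orientation <- function(rec) {
  stopifnot(inherits(rec, "seq_record"))
  if (rec$role != "mRNA")
    stop("reverse_orientation() applies to mRNA records only", call. = FALSE)
  rec$residues <- paste(rev(strsplit(rec$residues, "", fixed = TRUE)[[1]]),
                        collapse = "")
  rec
}

#' Fragment an mRNA into overlapping windows
#'
#' Splits a (typically long) mRNA into fragments whose lengths are drawn
#' uniformly from `[min_len, max_len]` with a seeded generator; consecutive
#' fragments overlap by `overlap` positions so that potential binding sites
#' are never split. A sequence shorter than `min_len` yields a single
#' fragment covering the whole sequence. The final fragment is truncated at
#' the sequence end; because each new window starts `overlap` positions
#' before the previous end, a truncated final window is always longer than
#' the overlap and always contributes new sequence.
#'
#' @param rec a `seq_record`.
#' @param min_len,max_len fragment length bounds (nt).
#' @param overlap overlap between consecutive fragments (nt), `0 <= overlap <
#'   min_len`.
#' @param seed integer seed for the fragment-length draws.
#' @return A `fragment_set`: list with `parent_id` and a data.frame
#'   `fragments` (`start` 0-based inclusive, `end` 0-based exclusive,
#'   `residues`).
#' @export
fragment_mrna <- function(rec, min_len = 200L, max_len = 400L,
                          overlap = 100L, seed = 1L) {
  stopifnot(inherits(rec, "seq_record"))
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  overlap <- as.integer(overlap)
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  if (overlap < 0L || overlap >= min_len)
    stop("need 0 <= overlap < min_len", call. = FALSE)
  L <- nchar(rec$residues)
  if (L < 1L) stop("empty sequence", call. = FALSE)

  if (L < min_len) {
    frags <- data.frame(start = 0L, end = L,
                        residues = rec$residues, stringsAsFactors = FALSE)
  } else {
    starts <- integer(0); ends <- integer(0)
    s <- 0L
    with_seed(seed, {
      while (s < L) {
        len <- sample.int(max_len - min_len + 1L, 1L) + min_len - 1L
        e <- min(s + len, L)
        starts <- c(starts, s); ends <- c(ends, e)
        if (e >= L) break
        s <- e - overlap
      }
    })
    frags <- data.frame(
      start = starts, end = ends,
      residues = substring(rec$residues, starts + 1L, ends),
      stringsAsFactors = FALSE)
  }
  structure(list(parent_id = rec$id, fragments = frags),
            class = "fragment_set")
}

#' Write fragment coordinates as BED-like TSV
#'
#' Three columns (parent id, 0-based start, exclusive end), no header.
#' @param fs a `fragment_set` or list of them.
#' @param path output path.
#' @export
write_fragments_tsv <- function(fs, path) {
  if (inherits(fs, "fragment_set")) fs <- list(fs)
  df <- do.call(rbind, lapply(fs, function(f)
    data.frame(parent = f$parent_id, start = f$fragments$start,
               end = f$fragments$end)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tokenize a sequence into overlapping k-mers
#'
#' Returns the `L - k + 1` substrings of length `k` in order.
#'
#' @param residues character scalar over \{A,C,G,U\}.
#' @param k k-mer length (default 6).
#' @return character vector of tokens.
#' @export
tokenize_kmers <- function(residues, k = 6L) {
  k <- as.integer(k)
  L <- nchar(residues)
  if (L < k)
    stop("sequence of length ", L, " too short to tokenize with k = ", k,
         call. = FALSE)
  substring(residues, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

#' Build the complete k-mer vocabulary
#'
#' All `4^k` strings over A < C < G < U in lexicographic order, with a
#' bijective token -> 0-based index map.
#'
#' @param k k-mer length (default 6 gives the 4096-token vocabulary).
#' @return A `kmer_vocabulary`: list with `k`, `tokens`, and an environment
#'   `index` usable via [kmer_index()].
#' @export
build_vocabulary <- function(k = 6L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  grid <- do.call(expand.grid,
                  c(rev(replicate(k, RNA_ALPHABET, simplify = FALSE)),
                    list(stringsAsFactors = FALSE)))
  tokens <- do.call(paste0, rev(grid))
  structure(list(k = k, tokens = tokens), class = "kmer_vocabulary")
}

#' Map k-mer tokens to 0-based vocabulary indices
#'
#' Computed arithmetically from the lexicographic layout (A=0, C=1, G=2, U=3),
#' so lookup is O(k) per token with no hash table.
#'
#' @param vocab a `kmer_vocabulary`.
#' @param tokens character vector of k-mers.
#' @return integer vector of 0-based indices.
#' @export
kmer_index <- function(vocab, tokens) {
  stopifnot(inherits(vocab, "kmer_vocabulary"))
  k <- vocab$k
  if (any(nchar(tokens) != k)) stop("token length != k", call. = FALSE)
  digits <- chartr("ACGU", "0123", tokens)
  if (any(grepl("[^0-3]", digits))) stop("non-ACGU token", call. = FALSE)
  idx <- integer(length(tokens))
  for (i in seq_len(k)) {
    idx <- idx * 4L + as.integer(substr(digits, i, i))
  }
  idx
}

#' Read a FASTA file into normalized sequence records
#'
#' The first whitespace-delimited token of each header is the id; residues are
#' normalized via [normalize_sequence()].
#'
#' @param path FASTA file (multi-line records allowed).
#' @param role role assigned to every record in the file.
#' @return list of `seq_record`.
#' @export
read_fasta_records <- function(path, role = c("miRNA", "mRNA")) {
  role <- match.arg(role)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  recs <- Map(function(id, s) normalize_sequence(id, s, role),
              ids, as.character(set))
  unname(recs)
}

#' Write sequence records as FASTA
#' @param records list of `seq_record`.
#' @param path output path.
#' @export
write_fasta_records <- function(records, path) {
  set <- Biostrings::BStringSet(
    vapply(records, function(r) r$residues, ""))
  names(set) <- vapply(records, function(r) r$id, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an interaction pair list from TSV
#'
#' Two or three tab-separated columns: miRNA id, mRNA id, optional 0/1 label.
#' @param path TSV path (no header).
#' @return data.frame with columns `mirna`, `mrna`, and `label` if present.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 2L) names(df) <- c("mirna", "mrna")
  else if (ncol(df) >= 3L) {
    df <- df[, 1:3]
    names(df) <- c("mirna", "mrna", "label")
  } else stop("pair TSV needs >= 2 columns", call. = FALSE)
  df
}

#' Write an interaction pair list as TSV
#' @param pairs data.frame with `mirna`, `mrna`, optionally `label` and
#'   further columns.
#' @param path output path.
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
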