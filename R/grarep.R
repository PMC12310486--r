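#' Build a bipartite miRNA-mRNA interaction graph
#'
#' Nodes are ordered miRNAs (sorted) then mRNAs (sorted); `S` is the symmetric
#' 0/1 adjacency matrix in that order, with zero diagonal. Duplicate pairs
#' collapse (set semantics); edges connect miRNA to mRNA only.
#'
#' @param pairs data.frame with columns `mirna` and `mrna` (positive edges).
#' @return An `interaction_graph`: list with `nodes` (data.frame `id`,
#'   `role`) and adjacency matrix `S`.
#' @export
build_graph <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("mirna", "mrna") %in% names(pairs)))
  if (!nrow(pairs)) stop("no edges", call. = FALSE)
  mir <- sort(unique(as.character(pairs$mirna)))
  mr <- sort(unique(as.character(pairs$mrna)))
  clash <- intersect(mir, mr)
  if (length(clash))
    stop("ids used as both miRNA and mRNA: ",
         paste(clash, collapse = ", "), call. = FALSE)
  ids <- c(mir, mr)
  n <- length(ids)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(pairs$mirna, ids)
  j <- match(pairs$mrna, ids)
  S[cbind(i, j)] <- 1
  S[cbind(j, i)] <- 1
  structure(list(
    nodes = data.frame(id = ids,
                       role = rep(c("miRNA", "mRNA"),
                                  c(length(mir), length(mr))),
                       stringsAsFactors = FALSE),
    S = S), class = "interaction_graph")
}

#' GraRep configuration
#'
#' @param K maximum transition step (orders of the random walk to factorise).
#' @param d dimension per step; the concatenated embedding has `K * d`
#'   columns (defaults 4 and 16, giving 64-dimensional node features).
#' @param beta log-shift factor; `NULL` means the standard `1/N` chosen at
#'   embed time.
#' @param eps numeric guard inside the logarithm.
#' @param normalize_gamma divide each k-step probability by its column sum
#'   before the log (the PPMI-style normalisation of the original GraRep
#'   formulation); `FALSE` takes the log of the raw k-step probability.
#' @return A `grarep_config` list.
#' @export
grarep_config <- function(K = 4L, d = 16L, beta = NULL, eps = 1e-9,
                          normalize_gamma = TRUE) {
  stopifnot(K >= 1, d >= 1, is.null(beta) || beta > 0, eps > 0)
  structure(list(K = as.integer(K), d = as.integer(d), beta = beta,
                 eps = eps, normalize_gamma = isTRUE(normalize_gamma)),
            class = "grarep_config")
}

#' Random-walk transition matrix of an interaction graph
#'
#' `A = D^-1 S`: each non-isolated row of the adjacency matrix divided by its
#' degree. Rows of isolated nodes stay all-zero (with a warning) rather than
#' becoming NaN.
#'
#' @param graph an `interaction_graph`.
#' @return row-stochastic (on non-isolated rows) matrix.
#' @export
transition_matrix <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  deg <- rowSums(graph$S)
  if (any(deg == 0))
    warning(sum(deg == 0), " isolated node(s); transition rows left zero")
  A <- graph$S / pmax(deg, 1)
  A[deg == 0, ] <- 0
  A
}

#' Log-shifted k-step probability matrix
#'
#' From the k-th power of the transition matrix `A`, computes
#' `X^k[i,j] = log(A^k[i,j] / Gamma_j + eps) - log(beta)` where `Gamma_j` is
#' the column sum of `A^k` (skipped when `normalize_gamma` is off), then sets
#' negative entries to zero. All-zero columns stay zero thanks to the `eps`
#' guard.
#'
#' @param A transition matrix.
#' @param k step count (`A` is raised to the k-th power by repeated
#'   multiplication).
#' @param cfg a [grarep_config()]; `beta = NULL` resolves to `1/nrow(A)`.
#' @return matrix `X^k`, non-negative.
#' @export
kstep_log_matrix <- function(A, k, cfg = grarep_config()) {
  stopifnot(k >= 1, k <= cfg$K)
  beta <- if (is.null(cfg$beta)) 1 / nrow(A) else cfg$beta
  Ak <- A
  if (k > 1) for (i in 2:k) Ak <- Ak %*% A
  P <- Ak
  if (cfg$normalize_gamma) {
    gam <- colSums(Ak)
    zero <- gam == 0
    P <- sweep(Ak, 2L, pmax(gam, cfg$eps), "/")
    P[, zero] <- 0
  }
  X <- log(P + cfg$eps) - log(beta)
  X[X < 0] <- 0
  X
}

#' k-step representation via truncated SVD
#'
#' `W^k = U_d diag(sigma_1..sigma_d)^{1/2}` from the SVD of `X^k`.
#' Deterministic sign convention: each left singular vector is flipped so that
#' its largest-magnitude entry (first such entry on ties) is positive.
#'
#' @param Xk non-negative matrix from [kstep_log_matrix()].
#' @param d number of singular triplets kept (`d <= nrow(Xk)`).
#' @return `nrow(Xk) x d` matrix.
#' @export
kstep_representation <- function(Xk, d) {
  if (!all(is.finite(Xk))) stop("non-finite entries in X^k", call. = FALSE)
  stopifnot(d >= 1, d <= nrow(Xk))
  sv <- svd(Xk, nu = d, nv = 0)
  U <- sv$u
  for (j in seq_len(d)) {
    m <- which.max(abs(U[, j]))
    if (U[m, j] < 0) U[, j] <- -U[, j]
  }
  U %*% diag(sqrt(sv$d[seq_len(d)]), d, d)
}

#' GraRep node embedding of an interaction graph
#'
#' Concatenates the k-step representations for k = 1..K into the final node
#' feature matrix `W` of shape `N x (K*d)`. Multi-order factorisation captures
#' both direct miRNA-mRNA links (k = 1) and indirect relationships through
#' intermediate nodes (k > 1).
#'
#' @param graph an `interaction_graph`.
#' @param cfg a [grarep_config()].
#' @return A `node_embedding`: list with `nodes` (as in the graph) and matrix
#'   `W` (rownames = node ids).
#' @export
grarep_embed <- function(graph, cfg = grarep_config()) {
  stopifnot(inherits(graph, "interaction_graph"),
            inherits(cfg, "grarep_config"))
  A <- transition_matrix(graph)
  blocks <- lapply(seq_len(cfg$K), function(k)
    kstep_representation(kstep_log_matrix(A, k, cfg), cfg$d))
  W <- do.call(cbind, blocks)
  rownames(W) <- graph$nodes$id
  structure(list(nodes = graph$nodes, W = W, cfg = cfg),
            class = "node_embedding")
}

#' Look up node features, with a zero-vector fallback
#'
#' Nodes absent from the (training) graph are transductively cold: they
#' receive zero vectors, with a warning naming how many were missing.
#'
#' @param emb a `node_embedding`.
#' @param ids node ids to fetch.
#' @return matrix `length(ids) x ncol(W)`.
#' @export
node_features <- function(emb, ids) {
  stopifnot(inherits(emb, "node_embedding"))
  out <- matrix(0, length(ids), ncol(emb$W))
  hit <- match(ids, rownames(emb$W))
  ok <- !is.na(hit)
  if (any(!ok))
    warning(sum(!ok), " node(s) absent from the embedded graph; zero vectors")
  out[ok, ] <- emb$W[hit[ok], , drop = FALSE]
  rownames(out) <- ids
  out
}

#' Write node embeddings as TSV (id, role, feature columns)
#' @param emb a `node_embedding`.
#' @param path output path.
#' @export
write_node_embedding_tsv <- function(emb, path) {
  df <- data.frame(id = emb$nodes$id, role = emb$nodes$role,
                   emb$W, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
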