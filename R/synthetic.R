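#' Specification for the synthetic miRNA-mRNA fixture
#'
#' Describes a seeded random corpus of short miRNAs and long mRNAs plus a
#' balanced set of labeled pairs with a planted seed-complementarity signal:
#' for each positive pair, the Watson-Crick reverse complement of the miRNA
#' seed region (positions 2-8) is written into the mRNA at a random position.
#' This mirrors the biological seed-match mechanism that makes miRNA-target
#' pairs learnable from sequence, at a scale trainable in minutes on one CPU.
#'
#' @param n_mirna,n_mrna number of miRNA / mRNA sequences (defaults 40 / 120).
#' @param mirna_len miRNA length in nt (default 22).
#' @param mrna_len_range length range for mRNAs, sampled uniformly (default
#'   200-800 nt).
#' @param seed_region 1-based inclusive positions of the miRNA seed
#'   (default 2-8).
#' @param n_pos number of positive pairs (default 600; an equal number of
#'   negatives is sampled, giving a balanced set).
#' @param noise_rate probability that a pair's label is flipped (default 0).
#' @param seed integer seed; fully determines the fixture.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_mirna = 40L, n_mrna = 120L, mirna_len = 22L,
                           mrna_len_range = c(200L, 800L),
                           seed_region = c(2L, 8L), n_pos = 600L,
                           noise_rate = 0, seed = 1L) {
  stopifnot(n_mirna >= 1, n_mrna >= 1, mirna_len >= seed_region[2],
            seed_region[1] >= 1, seed_region[1] <= seed_region[2],
            mrna_len_range[1] <= mrna_len_range[2],
            noise_rate >= 0, noise_rate <= 1)
  structure(list(n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
                 mirna_len = as.integer(mirna_len),
                 mrna_len_range = as.integer(mrna_len_range),
                 seed_region = as.integer(seed_region),
                 n_pos = as.integer(n_pos),
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

random_residues <- function(n) {
  paste(sample(RNA_ALPHABET, n, replace = TRUE), collapse = "")
}

#' Generate the synthetic sequence set
#'
#' miRNA ids are `mir001, mir002, ...`; mRNA ids `gene001, ...`. Residues are
#' i.i.d. uniform over \{A,C,G,U\}; mRNA lengths uniform over the configured
#' range. Bit-reproducible for a fixed spec.
#'
#' @param spec a [synthetic_spec()].
#' @return list of `seq_record` (miRNAs first, then mRNAs).
#' @export
generate_sequences <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    mirnas <- lapply(seq_len(spec$n_mirna), function(i)
      normalize_sequence(sprintf("mir%03d", i),
                         random_residues(spec$mirna_len), "miRNA"))
    mrnas <- lapply(seq_len(spec$n_mrna), function(i) {
      L <- sample(spec$mrna_len_range[1]:spec$mrna_len_range[2], 1L)
      normalize_sequence(sprintf("gene%03d", i), random_residues(L), "mRNA")
    })
    c(mirnas, mrnas)
  })
}

#' Reverse complement of an RNA string (A<->U, C<->G)
#' @param x character scalar over \{A,C,G,U\}.
#' @return character scalar.
#' @export
reverse_complement <- function(x) {
  paste(rev(strsplit(chartr("AUCG", "UAGC", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' Plant interactions into the synthetic sequence set
#'
#' Samples `n_pos` distinct miRNA-mRNA pairs as positives and, for each, writes
#' the reverse complement of the miRNA seed region into the paired mRNA at a
#' random position (overwriting in place, never overlapping a previously
#' planted site in the same mRNA). An equal number of distinct unplanted pairs
#' becomes the negatives. Labels are then flipped independently with
#' probability `noise_rate`.
#'
#' @param spec a [synthetic_spec()].
#' @param records output of [generate_sequences()] for the same spec.
#' @return list with `records` (mRNAs now carrying planted motifs) and
#'   `pairs`, a data.frame (`mirna`, `mrna`, `label`).
#' @export
plant_interactions <- function(spec, records) {
  stopifnot(inherits(spec, "synthetic_spec"))
  roles <- vapply(records, function(r) r$role, "")
  mir_ids <- vapply(records[roles == "miRNA"], function(r) r$id, "")
  mrna_idx <- which(roles == "mRNA")
  mrna_ids <- vapply(records[mrna_idx], function(r) r$id, "")
  n_cells <- length(mir_ids) * length(mrna_ids)
  if (2L * spec$n_pos > n_cells)
    stop("grid too small for ", spec$n_pos, " positives + negatives",
         call. = FALSE)

  with_seed(spec$seed + 1L, {
    cells <- sample.int(n_cells, 2L * spec$n_pos)
    mi_of <- ((cells - 1L) %% length(mir_ids)) + 1L
    m_of <- ((cells - 1L) %/% length(mir_ids)) + 1L
    pos <- seq_len(spec$n_pos)

    occupied <- vector("list", length(mrna_ids))  # planted intervals per mRNA
    for (p in pos) {
      mi <- records[[which(roles == "miRNA")[mi_of[p]]]]
      ri <- mrna_idx[m_of[p]]
      seed_seq <- substr(mi$residues, spec$seed_region[1], spec$seed_region[2])
      motif <- reverse_complement(seed_seq)
      w <- nchar(motif)
      L <- nchar(records[[ri]]$residues)
      if (L < w) stop("mRNA shorter than motif", call. = FALSE)
      repeat {
        at <- sample.int(L - w + 1L, 1L)  # 1-based start
        clash <- any(vapply(occupied[[m_of[p]]], function(iv)
          at <= iv[2] && iv[1] <= at + w - 1L, TRUE))
        if (!clash) break
      }
      substr(records[[ri]]$residues, at, at + w - 1L) <- motif
      occupied[[m_of[p]]] <- c(occupied[[m_of[p]]], list(c(at, at + w - 1L)))
    }

    label <- rep(c(1L, 0L), each = spec$n_pos)
    if (spec$noise_rate > 0) {
      flip <- stats::runif(length(label)) < spec$noise_rate
      label[flip] <- 1L - label[flip]
    }
    pairs <- data.frame(mirna = mir_ids[mi_of], mrna = mrna_ids[m_of],
                        label = label, stringsAsFactors = FALSE)
  })
  list(records = records, pairs = pairs)
}

#' Generate the complete synthetic fixture
#'
#' Convenience wrapper: [generate_sequences()] then [plant_interactions()].
#' @param spec a [synthetic_spec()]; default spec if missing.
#' @return list with `records`, `pairs`, `spec`.
#' @export
generate_fixture <- function(spec = synthetic_spec()) {
  records <- generate_sequences(spec)
  out <- plant_interactions(spec, records)
  out$spec <- spec
  out
}
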