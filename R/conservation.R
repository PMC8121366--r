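#' Pairwise p-distance matrix of an alignment
#'
#' Distance between two aligned sequences = 1 - (fraction of identical
#' residues over columns where neither sequence has a gap). Pairs sharing
#' no comparable column get distance 1 with a warning. This simple
#' alignment-based distance stands in for aligner-internal distances when
#' only the final alignment is available.
#'
#' @param x A `lobe_msa` with at least two sequences.
#' @return Symmetric numeric matrix with sequence ids as dimnames.
#' @export
distance_matrix <- function(x) {
  if (nrow(x) < 2) abort("at least two sequences required")
  m <- msa_char_matrix(x)
  n <- nrow(m)
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(x$id, x$id))
  warned <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        d[i, j] <- d[j, i] <- 1
        warned <- TRUE
      } else {
        d[i, j] <- d[j, i] <- 1 - sum(m[i, comp] == m[j, comp]) / nc
      }
    }
  }
  if (warned)
    warn("sequence pair(s) share no comparable columns; distance set to 1")
  d
}

#' Greedy redundancy pruning of an alignment
#'
#' Removes near-duplicate sequences until `target_n` remain: pair distances
#' are sorted in ascending order (ties broken by the lexicographic id
#' pair), and starting from the smallest distance one member of each pair
#' whose members both survive is removed. The member removed is the one
#' with the smaller mean distance to all other surviving sequences (so
#' outliers are kept and the surviving set spreads as evenly as possible
#' over sequence space); on a tie the later input sequence is removed.
#' The output preserves the original row order of the survivors.
#'
#' @param x A `lobe_msa`.
#' @param target_n Number of sequences to keep (`2 <= target_n <= nrow(x)`).
#' @return The pruned `lobe_msa`.
#' @export
prune_redundancy <- function(x, target_n) {
  n <- nrow(x)
  if (target_n < 2 || target_n > n)
    abort(sprintf("target_n must be in [2, %d], got %s", n, target_n))
  if (target_n == n) return(x)
  d <- distance_matrix(x)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  id1 <- pmin(x$id[pairs[, 1]], x$id[pairs[, 2]])
  id2 <- pmax(x$id[pairs[, 1]], x$id[pairs[, 2]])
  ord <- order(d[pairs], id1, id2)
  pairs <- pairs[ord, , drop = FALSE]
  alive <- rep(TRUE, n)
  n_alive <- n
  for (k in seq_len(nrow(pairs))) {
    if (n_alive <= target_n) break
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!alive[i] || !alive[j]) next
    mean_to_rest <- function(s) {
      others <- alive; others[s] <- FALSE
      mean(d[s, others])
    }
    mi <- mean_to_rest(i); mj <- mean_to_rest(j)
    drop <- if (mi < mj) i else if (mj < mi) j else max(i, j)
    alive[drop] <- FALSE
    n_alive <- n_alive - 1
  }
  msa(x$id[alive], x$seq[alive])
}

#' Per-column residue frequencies
#'
#' Frequencies of the 20 standard amino acids per alignment column, with
#' gaps and ambiguity codes (X/B/Z and any other non-standard symbol)
#' excluded and the remaining counts renormalized. Suitable as a
#' position-frequency table for sequence-logo rendering.
#'
#' @param x A `lobe_msa`.
#' @return Tibble with `column`, `gap_fraction`, `n_effective` and one
#'   column per residue (A..Y); frequency rows sum to 1 where
#'   `n_effective > 0`.
#' @export
residue_frequencies <- function(x) {
  m <- msa_char_matrix(x)
  L <- ncol(m)
  freq <- matrix(0, L, 20, dimnames = list(NULL, .aa_standard))
  gap_fraction <- numeric(L)
  n_eff <- integer(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    gap_fraction[j] <- mean(col == "-")
    std <- col[col %in% .aa_standard]
    n_eff[j] <- length(std)
    if (n_eff[j] > 0)
      freq[j, ] <- tabulate(match(std, .aa_standard), 20) / n_eff[j]
  }
  out <- as_tibble(freq)
  out <- bind_cols(tibble(column = seq_len(L), gap_fraction = gap_fraction,
                          n_effective = n_eff), out)
  out
}

#' Per-column sequence entropy (log base 20)
#'
#' Sequence variability per alignment column as the Shannon entropy of the
#' 20-residue frequency distribution taken to base 20, so that `S` lies in
#' `[0, 1]`: 0 for a fully conserved column, 1 for a column with all 20
#' residues equally frequent (`S = -sum(p_i * log20(p_i))`, with
#' `0 * log 0 = 0`). Gaps and ambiguity codes are excluded and frequencies
#' renormalized; columns whose gap fraction exceeds `gap_max` are flagged
#' (but still computed), and columns with no standard residue at all get
#' `S = NA` and `undefined = TRUE`.
#'
#' @param x A `lobe_msa` with at least two sequences.
#' @param gap_max Gap-fraction flagging threshold (default 0.5).
#' @return An `entropy_profile` tibble: `column`, `gap_fraction`,
#'   `n_effective`, `entropy`, `gap_flagged`, `undefined`; the per-column
#'   frequency matrix is carried in attribute `frequencies`.
#' @export
column_entropy <- function(x, gap_max = 0.5) {
  if (nrow(x) < 2) abort("at least two sequences required")
  fr <- residue_frequencies(x)
  fmat <- as.matrix(fr[, .aa_standard])
  plogp <- fmat * log(fmat, base = 20)
  plogp[!is.finite(plogp)] <- 0
  S <- -rowSums(plogp)
  S[fr$n_effective == 0] <- NA_real_
  out <- tibble(
    column = fr$column, gap_fraction = fr$gap_fraction,
    n_effective = fr$n_effective, entropy = S,
    gap_flagged = fr$gap_fraction > gap_max,
    undefined = fr$n_effective == 0
  )
  structure(out, frequencies = fmat, gap_max = gap_max,
            class = c("entropy_profile", class(tibble())))
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("<entropy profile: %d columns, mean S %.3f, %d gap-flagged>\n",
              nrow(x), mean(x$entropy, na.rm = TRUE), sum(x$gap_flagged)))
  NextMethod()
}

#' Map column entropies onto a structure
#'
#' Transfers the per-column entropy of an alignment onto the residues of a
#' structure chain via a reference sequence in the alignment: the ungapped
#' reference is globally aligned to the chain sequence, and every structure
#' residue aligned to a reference position inherits the entropy of that
#' position's alignment column (written to the B-factor column by
#' [write_structure_with_scores()], the conventional way of colouring a
#' model by conservation). Residues without a counterpart get `sentinel`.
#'
#' @param structure A `lobe_structure`.
#' @param profile An `entropy_profile` from [column_entropy()].
#' @param x The `lobe_msa` the profile was computed from.
#' @param reference_id Id of the reference row in the alignment.
#' @param chain Chain id (default: first chain).
#' @param min_identity Minimum fractional identity (over aligned non-gap
#'   columns) between reference and chain sequence (default 0.8).
#' @param sentinel Score for unmatched residues (default 0).
#' @return List with `structure` (B-factors replaced by entropies),
#'   `scores` (per-residue tibble) and `alignment` (the reference-to-chain
#'   alignment).
#' @export
map_entropy_to_structure <- function(structure, profile, x, reference_id,
                                     chain = NULL, min_identity = 0.8,
                                     sentinel = 0) {
  if (!reference_id %in% x$id)
    abort(paste0("reference id '", reference_id, "' not in alignment"))
  chain <- chain %||% structure_chains(structure)[1]
  ref_row <- x$seq[x$id == reference_id]
  ref_chars <- strsplit(ref_row, "")[[1]]
  ref_cols <- which(ref_chars != "-")          # alignment column per position
  ref_seq <- paste(ref_chars[ref_cols], collapse = "")
  ch_seq <- chain_sequence(structure, chain)
  aln <- global_align(ref_seq, ch_seq)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  ident <- sum(ca[both] == cb[both]) / max(1, sum(both))
  if (ident < min_identity)
    abort(sprintf(
      "reference/chain identity %.1f%% below threshold %.1f%%\n%s\n%s",
      100 * ident, 100 * min_identity, aln$aligned_a, aln$aligned_b))
  ia <- cumsum(ca != "-"); ib <- cumsum(cb != "-")
  res <- filter(residue_table(structure), .data$chain == !!chain)
  score <- rep(sentinel, nrow(res))
  hit <- which(both)
  # structure residue ib[k] <- entropy of alignment column of ref position ia[k]
  ent <- profile$entropy[ref_cols[ia[hit]]]
  ent[is.na(ent)] <- sentinel
  score[ib[hit]] <- ent
  scores <- tibble(chain = res$chain, resno = res$resno, insert = res$insert,
                   resname = res$resname, score = score)
  at <- as_tibble(structure)
  key_at <- paste(at$chain, at$resno, at$insert)
  key_sc <- paste(scores$chain, scores$resno, scores$insert)
  idx <- match(key_at, key_sc)
  at$bfactor <- ifelse(is.na(idx), sentinel,
                       round(clamp(scores$score[idx], 0, 999.99), 2))
  list(structure = restore_structure(at, structure), scores = scores,
       alignment = aln)
}

#' Write an entropy profile as TSV
#'
#' Columns: alignment column, gap fraction, number of standard residues,
#' entropy, flags, and the three most frequent residues as `res:freq`.
#'
#' @param profile An `entropy_profile`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_entropy_tsv <- function(profile, path) {
  fmat <- attr(profile, "frequencies")
  top3 <- apply(fmat, 1, function(p) {
    o <- order(p, decreasing = TRUE)[1:3]
    paste(sprintf("%s:%.3f", .aa_standard[o], p[o]), collapse = ",")
  })
  df <- mutate(as_tibble(profile), top_residues = top3)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Write a position-frequency matrix (minimal MEME-like text)
#'
#' Tab-separated: a header naming the 20 residue columns, then one row of
#' frequencies per alignment column.
#'
#' @param x A `lobe_msa` (frequencies are computed) or the tibble returned
#'   by [residue_frequencies()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_pfm <- function(x, path) {
  fr <- if (inherits(x, "lobe_msa")) residue_frequencies(x) else as_tibble(x)
  readr::write_tsv(fr[, c("column", .aa_standard)], path)
  invisible(path)
}
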