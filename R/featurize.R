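# Featurization of TMD sequences and correlation-based feature selection.

#' Split a TMD into contiguous subsequences
#'
#' Divides a sequence into \code{n_chunks} contiguous, non-overlapping,
#' exhaustive chunks whose lengths differ by at most one, with the longer
#' chunks first (remainder-first convention). For TMD lengths 25 and 26 this
#' places the scanned positions 6, 9, 13, 17 and 21 into subsequences 2, 3,
#' 5, 6 and 7 of nine.
#'
#' @param sequence A single sequence string.
#' @param n_chunks Number of chunks (default 9).
#' @return Character vector of \code{n_chunks} subsequences.
#' @examples
#' nchar(split_tmd(strrep("L", 26)))  # 3 3 3 3 3 3 3 3 2
#' @export
split_tmd <- function(sequence, n_chunks = 9L) {
  L <- nchar(sequence)
  if (L < n_chunks)
    stop("sequence of length ", L, " cannot form ", n_chunks,
         " non-empty chunks")
  sizes <- chunk_sizes(L, n_chunks)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  substring(sequence, starts, ends)
}

chunk_sizes <- function(L, n_chunks = 9L) {
  base <- L %/% n_chunks
  rem <- L %% n_chunks
  c(rep(base + 1L, rem), rep(base, n_chunks - rem))
}

#' Which subsequence a position falls in
#' @param position 1-based residue position.
#' @param L Sequence length.
#' @param n_chunks Number of chunks.
#' @return 1-based chunk number.
#' @export
position_chunk <- function(position, L, n_chunks = 9L) {
  ends <- cumsum(chunk_sizes(L, n_chunks))
  vapply(position, function(p) which(p <= ends)[1L], integer(1L))
}

#' Construct a feature specification
#'
#' A feature spec is the ordered list of (slot, index accession) pairs the
#' regressor consumes. Under \code{version = "v1"} a slot is a mutated
#' position and the feature is the scaled index value of the residue at that
#' position; under \code{"v2"} a slot is a subsequence number (of 9) and the
#' feature is the mean scaled value over that subsequence's residues.
#'
#' @param slots Integer vector of slot ids (positions or chunk numbers).
#' @param accessions Character vector, same length, of index accessions.
#' @param version \code{"v1"} or \code{"v2"}.
#' @param n_chunks Number of subsequences for v2 (default 9).
#' @return A \code{feature_spec}.
#' @export
feature_spec <- function(slots, accessions, version = c("v1", "v2"),
                         n_chunks = 9L) {
  version <- match.arg(version)
  stopifnot(length(slots) == length(accessions))
  o <- order(slots, accessions)
  slots <- as.integer(slots[o]); accessions <- accessions[o]
  if (anyDuplicated(paste(slots, accessions)))
    stop("duplicate (slot, index) pairs in feature spec")
  structure(list(version = version, slots = slots, accessions = accessions,
                 n_chunks = n_chunks),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("Feature spec (%s): %d features over %s %s\n", x$version,
              length(x$slots),
              if (x$version == "v1") "positions" else "subsequences",
              paste(sort(unique(x$slots)), collapse = ", ")))
  invisible(x)
}

#' Featurize sequences under a feature spec
#'
#' @param sequences Character vector of sequences.
#' @param spec A \code{feature_spec}.
#' @param indices A \code{scaled_index_list} containing every accession in
#'   the spec.
#' @return Numeric matrix, one row per sequence, one column per feature (in
#'   spec order), values in [0, 1]. Non-canonical residues are imputed at
#'   mid-scale with a warning.
#' @export
featurize <- function(sequences, spec, indices) {
  stopifnot(inherits(spec, "feature_spec"))
  missing_idx <- setdiff(unique(spec$accessions), names(indices))
  if (length(missing_idx))
    stop("indices absent from table: ", paste(missing_idx, collapse = ", "))
  n <- length(sequences)
  X <- matrix(NA_real_, n, length(spec$slots),
              dimnames = list(NULL, paste0(spec$accessions, "@", spec$slots)))
  for (i in seq_len(n)) {
    s <- sequences[i]
    if (spec$version == "v1") {
      if (nchar(s) < max(spec$slots))
        stop("sequence ", i, " shorter than slot position ", max(spec$slots))
      aa <- strsplit(s, "")[[1L]]
      for (j in seq_along(spec$slots))
        X[i, j] <- index_values(indices[[spec$accessions[j]]],
                                aa[spec$slots[j]])
    } else {
      chunks <- split_tmd(s, spec$n_chunks)
      for (j in seq_along(spec$slots))
        X[i, j] <- mean(index_values(indices[[spec$accessions[j]]],
                                     chunks[spec$slots[j]]))
    }
  }
  X
}

#' Select position-specific features by Pearson correlation
#'
#' For every candidate (slot, index) pair, the scaled feature values of the
#' variants substituted within that slot (plus the reference variant) are
#' correlated with their measured affinities; a pair is retained iff
#' \code{|r| > r_min} and the two-sided t-distribution P-value is
#' \code{< p_max}, both strict. By default only the training split enters
#' the correlations, so the held-out evaluation is leakage-free.
#'
#' @param dataset A \code{conmem_dataset} with inferred substitution
#'   positions.
#' @param indices A \code{scaled_index_list} of candidate indices.
#' @param r_min Exclusive lower bound on |r| (default 0.7).
#' @param p_max Exclusive upper bound on the P-value (default 0.01).
#' @param version Featurization scheme; v2 maps positions to subsequences.
#' @param select_on Use the training split only (default) or all variants.
#' @return A \code{feature_spec}; its \code{"selection"} attribute records
#'   the full correlation table (slot, accession, r, p, n, selected).
#' @export
select_features <- function(dataset, indices, r_min = 0.7, p_max = 0.01,
                            version = c("v1", "v2"),
                            select_on = c("train", "all")) {
  version <- match.arg(version)
  select_on <- match.arg(select_on)
  stopifnot(r_min > 0, r_min < 1, p_max > 0, p_max < 1)
  d <- as.data.frame(dataset)
  if (select_on == "train") d <- d[d$split == "train", , drop = FALSE]
  positions <- attr(dataset, "positions")
  if (is.null(positions))
    positions <- sort(unique(stats::na.omit(d$position)))
  L <- attr(dataset, "tmd_length") %||% unique(nchar(d$sequence))[1L]

  if (version == "v1") {
    slot_of <- stats::setNames(positions, positions)
    slots <- positions
  } else {
    slots <- sort(unique(position_chunk(positions, L)))
    slot_of <- stats::setNames(position_chunk(positions, L), positions)
  }

  rows <- list()
  for (slot in slots) {
    in_slot <- is.na(d$position) |
      (!is.na(d$position) & slot_of[as.character(d$position)] == slot)
    sub <- d[in_slot, , drop = FALSE]
    if (nrow(sub) < 3L) next
    for (acc in names(indices)) {
      sp <- feature_spec(slot, acc, version)
      x <- featurize(sub$sequence, sp, indices)[, 1L]
      if (stats::sd(x) == 0 || stats::sd(sub$affinity) == 0) next
      ct <- stats::cor.test(x, sub$affinity, method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        slot = slot, accession = acc, r = unname(ct$estimate),
        p = ct$p.value, n = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no evaluable (slot, index) pairs in dataset")
  tab$selected <- abs(tab$r) > r_min & tab$p < p_max
  if (!any(tab$selected))
    stop("no features passed selection (|r| > ", r_min, ", P < ", p_max,
         "); cannot train")
  keep <- tab[tab$selected, , drop = FALSE]
  spec <- feature_spec(keep$slot, keep$accession, version)
  attr(spec, "selection") <- tab[order(tab$slot, tab$accession), ]
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
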