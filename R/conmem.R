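# ConMem-style substitution-scan binding datasets: TSV I/O and a synthetic
# generator with a planted, property-linear affinity function.

#' Default ConMem-like TMD backbone
#'
#' A consensus-like 26-residue scaffold: a Leu/Ile/Val/Phe-rich 24-residue
#' hydrophobic core with Val at the central position 13, flanked by Pro
#' (position 1) and Lys (position 26). Substitution scans replace single core
#' residues; affinities are expressed relative to this reference.
#'
#' @param tmd_length Total length (default 26). Other lengths give a poly-Leu
#'   core with Val at the central position, same P/K flanks.
#' @return A single character string.
#' @export
conmem_backbone <- function(tmd_length = 26L) {
  if (tmd_length == 26L)
    return("PLLIFLLVLLILVLLFLILLVLLILK")
  stopifnot(tmd_length >= 9L)
  core <- rep("L", tmd_length - 2L)
  core[ceiling((tmd_length - 2L) / 2L)] <- "V"
  paste0("P", paste(core, collapse = ""), "K")
}

#' Default planted affinity components for the synthetic generator
#'
#' The planted ground truth is linear in scaled residue properties: binding
#' increases with side-chain polarity (Grantham scale) and hydrophilicity
#' (Hopp-Woods scale) at every scanned position. Two correlated property
#' components mirror the biology being emulated -- polar and charged
#' residues in a TMD promote chaperone engagement, and many correlated
#' polarity-type indices track the measured affinities -- and the weights
#' are sized so the strongest binders reach roughly four times the
#' reference, matching the measured dynamic range of the substitution scan.
#'
#' @param positions Scanned positions (1-based within the TMD).
#' @return List of components, each \code{list(accession, weight, positions)}.
#' @export
planted_default <- function(positions = c(6L, 9L, 13L, 17L, 21L)) {
  list(
    list(accession = "GRAR740102", weight = 2.2, positions = positions),
    list(accession = "HOPT810101", weight = 0.5, positions = positions)
  )
}

#' Planted affinity of sequences under a property-linear ground truth
#'
#' Affinity = 1 + sum over components and positions of
#' weight * (scaled value of the residue - scaled value of the backbone
#' residue). The backbone sequence itself therefore has affinity exactly 1.
#'
#' @param sequences Character vector of TMD sequences.
#' @param backbone Reference sequence.
#' @param planted Component list as from \code{\link{planted_default}}.
#' @param indices A \code{scaled_index_list} containing every planted accession.
#' @return Numeric vector of noiseless affinities.
#' @export
planted_affinity <- function(sequences, backbone = conmem_backbone(),
                             planted = planted_default(),
                             indices = aaindex_core()) {
  ref <- strsplit(backbone, "")[[1L]]
  vapply(sequences, function(s) {
    aa <- strsplit(s, "")[[1L]]
    delta <- 0
    for (comp in planted) {
      idx <- indices[[comp$accession]]
      if (is.null(idx)) stop("planted index not in table: ", comp$accession)
      for (p in comp$positions)
        delta <- delta + comp$weight * (idx$values[[aa[p]]] - idx$values[[ref[p]]])
    }
    1 + delta
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Simulate a ConMem-style binding dataset
#'
#' Generates single-residue substitution variants of a reference TMD with a
#' planted affinity function plus Gaussian noise, shaped like the published
#' substitution scans: all 19 exchanges at the central position plus a panel
#' of eight residues (G, S, Y, P, E, D, K, R) at the remaining scanned
#' positions; further variants are drawn from the unused (position, residue)
#' combinations. The reference variant is always included with affinity
#' exactly 1 (it is the normalizer and carries no noise). Affinities are
#' truncated at 0.
#'
#' Two dataset shapes match the two predictor iterations: \code{version_hint
#' = "v1"} defaults to 59 variants split 44/15 and \code{"v2"} to 77 variants
#' split 57/20.
#'
#' @param n_variants Total variants including the reference.
#' @param n_test Held-out test-set size (train gets the rest).
#' @param positions Scanned positions.
#' @param residue_panel Residues scanned at non-central positions.
#' @param center Central position receiving all 19 exchanges.
#' @param backbone Reference sequence (defines the TMD length).
#' @param planted Planted component list; see \code{\link{planted_default}}.
#' @param indices Scaled index table used by the planted function.
#' @param noise_sd Gaussian noise SD on substituted variants; default
#'   \code{0.1 *} the planted signal range over the generated design.
#' @param seed Integer seed; generation is reproducible from it.
#' @param version_hint \code{"v1"} (position features) or \code{"v2"}
#'   (subsequence features); also sets the default sizes above.
#' @param exhaustive If TRUE, error when \code{n_variants} exceeds the number
#'   of distinct (position, residue) combinations; otherwise extra draws
#'   repeat combinations (with fresh noise).
#' @return A \code{conmem_dataset}: a data.frame with columns
#'   \code{sequence}, \code{affinity}, \code{split}, \code{position},
#'   \code{residue}, plus attributes (\code{tmd_length}, \code{positions},
#'   \code{version_hint}, \code{seed}, \code{noise_sd}, \code{signal_range},
#'   \code{backbone}).
#' @export
simulate_conmem <- function(n_variants = if (version_hint == "v2") 77L else 59L,
                            n_test = if (version_hint == "v2") 20L else 15L,
                            positions = c(6L, 9L, 13L, 17L, 21L),
                            residue_panel = c("G", "S", "Y", "P", "E", "D",
                                              "K", "R"),
                            center = 13L,
                            backbone = conmem_backbone(),
                            planted = planted_default(positions),
                            indices = aaindex_core(),
                            noise_sd = NULL,
                            seed = 1L,
                            version_hint = c("v1", "v2"),
                            exhaustive = FALSE) {
  version_hint <- match.arg(version_hint)
  stopifnot(n_variants >= 1L, n_test < n_variants, is.null(noise_sd) ||
              noise_sd >= 0)
  ref <- strsplit(backbone, "")[[1L]]
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

  combo <- function(p, r) data.frame(position = p, residue = r,
                                     stringsAsFactors = FALSE)
  core <- rbind(
    do.call(rbind, lapply(setdiff(aa20, ref[center]),
                          function(r) combo(center, r))),
    do.call(rbind, unlist(lapply(setdiff(positions, center), function(p) {
      lapply(setdiff(residue_panel, ref[p]), function(r) combo(p, r))
    }), recursive = FALSE))
  )
  all_combos <- do.call(rbind, unlist(lapply(positions, function(p) {
    lapply(setdiff(aa20, ref[p]), function(r) combo(p, r))
  }), recursive = FALSE))
  key <- function(d) paste(d$position, d$residue)
  extra_pool <- all_combos[!(key(all_combos) %in% key(core)), , drop = FALSE]

  n_sub <- n_variants - 1L
  if (exhaustive && n_sub > nrow(all_combos))
    stop("n_variants exceeds the ", nrow(all_combos) + 1L,
         " distinct variants available in exhaustive mode")

  local_seed(seed)
  design <- if (n_sub <= nrow(core)) {
    core[sample.int(nrow(core), n_sub), , drop = FALSE]
  } else {
    extra_n <- n_sub - nrow(core)
    if (extra_n <= nrow(extra_pool)) {
      rbind(core, extra_pool[sample.int(nrow(extra_pool), extra_n), ,
                             drop = FALSE])
    } else {
      rbind(core, extra_pool,
            all_combos[sample.int(nrow(all_combos),
                                  extra_n - nrow(extra_pool), replace = TRUE), ,
                       drop = FALSE])
    }
  }

  mutate1 <- function(p, r) {
    s <- ref; s[p] <- r; paste(s, collapse = "")
  }
  seqs <- mapply(mutate1, design$position, design$residue)
  mu <- planted_affinity(seqs, backbone, planted, indices)
  signal_range <- diff(range(c(1, mu)))
  if (is.null(noise_sd)) noise_sd <- 0.1 * signal_range
  aff <- mu + stats::rnorm(length(mu), 0, noise_sd)
  n_trunc <- sum(aff < 0)
  if (n_trunc > 0)
    message(n_trunc, " simulated affinities truncated at 0")
  aff <- pmax(aff, 0)

  df <- data.frame(
    sequence = c(backbone, seqs),
    affinity = c(1, aff),
    split = "train",
    position = c(NA_integer_, design$position),
    residue = c(NA_character_, design$residue),
    stringsAsFactors = FALSE, row.names = NULL
  )
  df$split[sample.int(nrow(df), n_test)] <- "test"
  structure(df, class = c("conmem_dataset", "data.frame"),
            tmd_length = nchar(backbone), positions = positions,
            version_hint = version_hint, seed = seed, noise_sd = noise_sd,
            signal_range = signal_range, backbone = backbone)
}

#' @export
print.conmem_dataset <- function(x, ...) {
  cat(sprintf(
    "ConMem binding dataset: %d variants (L = %d), %d train / %d test\n",
    nrow(x), attr(x, "tmd_length"), sum(x$split == "train"),
    sum(x$split == "test")))
  if (!is.null(attr(x, "noise_sd")))
    cat(sprintf("  synthetic (seed %s, noise sd %.4g, signal range %.4g)\n",
                attr(x, "seed"), attr(x, "noise_sd"), attr(x, "signal_range")))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Write a ConMem dataset to TSV
#' @param dataset A \code{conmem_dataset}.
#' @param file Output path.
#' @export
write_conmem <- function(dataset, file) {
  utils::write.table(as.data.frame(dataset), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read a ConMem-style binding dataset from TSV
#'
#' Expects columns \code{sequence}, \code{affinity} and optionally
#' \code{split} (train/test). Substitutions are inferred per column relative
#' to the consensus (most frequent residue at each position); if the
#' consensus sequence itself is present its affinity defines the reference
#' and all affinities are renormalized so the reference is exactly 1.
#'
#' @param file Input TSV path.
#' @param normalize Renormalize to the reference variant (default TRUE).
#' @return A \code{conmem_dataset}.
#' @export
read_conmem <- function(file, normalize = TRUE) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("sequence", "affinity") %in% names(df)))
  if (is.null(df$split)) df$split <- "train"
  L <- unique(nchar(df$sequence))
  if (length(L) != 1L)
    stop("ragged sequence lengths: ", paste(L, collapse = ", "))
  if (any(!is.finite(df$affinity)) || any(df$affinity < 0))
    stop("affinities must be finite and non-negative")
  dup <- split(df$affinity, df$sequence)
  conflict <- names(dup)[vapply(dup, function(a) length(unique(a)) > 1L,
                                logical(1L))]
  if (length(conflict))
    stop("duplicate sequences with conflicting affinities: ",
         substr(conflict[1L], 1, 12), "...")

  mat <- do.call(rbind, strsplit(df$sequence, ""))
  consensus <- apply(mat, 2L, function(col)
    names(sort(table(col), decreasing = TRUE))[1L])
  nmis <- rowSums(mat != matrix(consensus, nrow(mat), L, byrow = TRUE))
  pos <- res <- rep(NA, nrow(df))
  one <- which(nmis == 1L)
  pos[one] <- apply(mat[one, , drop = FALSE], 1L, function(r)
    which(r != consensus))
  res[one] <- mat[cbind(one, as.integer(pos[one]))]

  ref_seq <- paste(consensus, collapse = "")
  if (normalize) {
    iref <- which(df$sequence == ref_seq)
    if (length(iref)) {
      df$affinity <- df$affinity / df$affinity[iref[1L]]
    } else {
      warning("consensus reference sequence absent; affinities left as given")
    }
  }
  structure(data.frame(sequence = df$sequence, affinity = df$affinity,
                       split = df$split, position = as.integer(pos),
                       residue = as.character(res), stringsAsFactors = FALSE),
            class = c("conmem_dataset", "data.frame"),
            tmd_length = L, backbone = ref_seq,
            positions = sort(unique(stats::na.omit(as.integer(pos)))))
}

# Set the RNG seed for the calling frame only, restoring the prior state on
# exit so library code does not disturb the user's random stream.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible())
  prev <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  expr <- if (is.null(prev)) {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(prev), envir = globalenv()))
  }
  do.call(on.exit, list(expr, TRUE), envir = envir)
  set.seed(seed)
  invisible()
}
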