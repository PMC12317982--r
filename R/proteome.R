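# Proteome-wide TMD scoring: topology orientation, prediction, 0-100
# normalization, per-protein max aggregation, and group summaries.

# UniProt-style location labels treated as the exo (lumenal/extracellular)
# side of the membrane.
EXO_LABELS <- c("Extracellular", "Lumenal",
                "Mitochondrial matrix", "Peroxisomal matrix",
                "Perinuclear space", "Lumenal, vesicle", "Intragranular",
                "Lumenal, melanosome", "Nuclear", "Vesicular",
                "Mitochondrial intermembrane")

#' Map a subcellular-location label to a membrane side
#'
#' Extracellular/lumenal-type labels (including organellar lumen-equivalents
#' such as the mitochondrial matrix) map to \code{"exo"}; cytoplasm-type
#' labels map to \code{"endo"}. Unknown labels default to \code{"endo"} with
#' a warning.
#'
#' @param label Character vector of location strings.
#' @return Character vector of \code{"exo"} / \code{"endo"}.
#' @export
map_localization <- function(label) {
  vapply(label, function(l) {
    l <- trimws(l)
    if (l %in% EXO_LABELS) return("exo")
    if (grepl("^(Cytoplasm|Cytosol)", l, ignore.case = TRUE)) return("endo")
    warning("unrecognized location label '", l, "'; defaulting to endo")
    "endo"
  }, character(1L), USE.NAMES = FALSE)
}

#' Orient a TMD record so its first residue is on the exo side
#'
#' TMDs are scored in the N-exo convention of the binding assay; a record
#' whose first residue sits on the endo (cytoplasmic) side is reversed.
#' Idempotent. Records without a start-side annotation default to exo with a
#' warning.
#'
#' @param records Data frame with columns \code{protein_id},
#'   \code{tmd_index}, \code{sequence}, \code{start_side} (\code{"exo"},
#'   \code{"endo"}, or NA).
#' @return The data frame with all sequences exo-first and
#'   \code{start_side == "exo"}.
#' @export
orient_tmd <- function(records) {
  if (is.null(records$start_side)) records$start_side <- NA_character_
  missing <- is.na(records$start_side) | records$start_side == ""
  if (any(missing)) {
    warning(sum(missing), " TMD record(s) without topology annotation; ",
            "defaulting to exo-start")
    records$start_side[missing] <- "exo"
  }
  stopifnot(all(records$start_side %in% c("exo", "endo")))
  flip <- records$start_side == "endo"
  records$sequence[flip] <- vapply(records$sequence[flip], function(s)
    paste(rev(strsplit(s, "")[[1L]]), collapse = ""), character(1L),
    USE.NAMES = FALSE)
  records$start_side <- "exo"
  records
}

#' Score all TMDs of a proteome with a fitted predictor
#'
#' Orients every record, predicts its raw affinity, min-max normalizes raw
#' scores to the 0-100 scale over the whole scored set, and aggregates to
#' per-protein scores as the maximum over the protein's TMDs. Records that
#' cannot be featurized (e.g. too short for the feature spec) are excluded
#' with a warning; normalization is monotone, so max-then-normalize equals
#' normalize-then-max.
#'
#' @param model An \code{emc_fit}.
#' @param records Data frame with columns \code{protein_id},
#'   \code{tmd_index}, \code{sequence}, optional \code{start_side},
#'   \code{class_label}.
#' @param normalize Rescale to 0-100 (default TRUE). A degenerate single-
#'   score set maps to 0.
#' @return A \code{scored_proteome}: list with \code{tmd} (per-TMD table:
#'   raw and normalized scores) and \code{protein} (per-protein table:
#'   \code{score}, \code{n_tmds}, optional \code{class_label}).
#' @export
score_proteome <- function(model, records, normalize = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "sequence") %in% names(records)))
  if (is.null(records$tmd_index))
    records$tmd_index <- stats::ave(seq_len(nrow(records)),
                                    records$protein_id, FUN = seq_along)
  records <- orient_tmd(records)
  raw <- suppressWarnings(predict(model, records$sequence))
  drop_n <- sum(is.na(raw))
  if (drop_n > 0L)
    warning(drop_n, " TMD(s) could not be featurized and were excluded")
  records <- records[!is.na(raw), , drop = FALSE]
  raw <- raw[!is.na(raw)]
  if (length(raw) == 0L) stop("no scorable TMDs in input")

  norm <- if (!normalize) raw else {
    rng <- range(raw)
    if (diff(rng) == 0) rep(0, length(raw))
    else (raw - rng[1L]) / diff(rng) * 100
  }
  tmd <- data.frame(protein_id = records$protein_id,
                    tmd_index = records$tmd_index,
                    sequence = records$sequence,
                    raw_score = raw, score = norm,
                    stringsAsFactors = FALSE)
  agg <- function(v, f) as.vector(tapply(v, records$protein_id, f))
  protein <- data.frame(protein_id = sort(unique(records$protein_id)),
                        score = agg(norm, max),
                        n_tmds = agg(norm, length),
                        stringsAsFactors = FALSE)
  if (!is.null(records$class_label)) {
    lab <- tapply(records$class_label, records$protein_id,
                  function(x) x[1L])
    protein$class_label <- as.vector(lab)
  }
  structure(list(tmd = tmd, protein = protein, normalized = normalize),
            class = "scored_proteome")
}

#' @export
print.scored_proteome <- function(x, ...) {
  cat(sprintf("Scored proteome: %d TMDs in %d proteins (%s scores)\n",
              nrow(x$tmd), nrow(x$protein),
              if (x$normalized) "0-100 normalized" else "raw"))
  print(utils::head(x$protein))
  invisible(x)
}

#' Summarize protein scores by group
#'
#' @param scored A \code{scored_proteome}.
#' @param by \code{"pass"} (single-pass vs multipass, from \code{n_tmds}),
#'   \code{"n_tmds"}, or \code{"class_label"}.
#' @param frequencies Also report each group's share of its proteins.
#' @return Data frame with \code{group}, \code{n}, \code{mean}, \code{sd}
#'   (and \code{share} if requested) of per-protein scores.
#' @export
summarize_groups <- function(scored, by = c("pass", "n_tmds", "class_label"),
                             frequencies = FALSE) {
  by <- match.arg(by)
  p <- scored$protein
  g <- switch(by,
              pass = ifelse(p$n_tmds > 1L, "multipass", "single-pass"),
              n_tmds = as.character(p$n_tmds),
              class_label = {
                if (is.null(p$class_label))
                  stop("no class labels in scored proteome")
                p$class_label
              })
  out <- do.call(rbind, lapply(split(p$score, g), function(v)
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_)))
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (frequencies) out$share <- out$n / sum(out$n)
  out[order(out$group), , drop = FALSE]
}

#' Read a TMD table from TSV
#'
#' Columns: \code{protein_id}, \code{sequence}, optional \code{tmd_index},
#' \code{start_side}, \code{location}, \code{class_label}. A
#' \code{location} column is mapped to \code{start_side} via
#' \code{\link{map_localization}} when \code{start_side} is absent.
#'
#' @param file TSV path.
#' @return Data frame of TMD records.
#' @export
read_tmd_table <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  stopifnot(all(c("protein_id", "sequence") %in% names(df)))
  if (is.null(df$start_side) && !is.null(df$location))
    df$start_side <- map_localization(df$location)
  df
}

#' Write per-TMD and per-protein score tables as TSV
#'
#' @param scored A \code{scored_proteome}.
#' @param tmd_file,protein_file Output paths (either may be NULL to skip).
#' @export
write_scores <- function(scored, tmd_file = NULL, protein_file = NULL) {
  if (!is.null(tmd_file))
    utils::write.table(scored$tmd, tmd_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(protein_file))
    utils::write.table(scored$protein, protein_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(scored)
}
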