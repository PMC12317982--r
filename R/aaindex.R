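# Canonical residue order of the AAindex1 I-line matrix (row 1 then row 2).
AA_ILINE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
# Alphabetical order used for TSV export columns.
AA_ALPHA <- sort(AA_ILINE)

#' Parse an AAindex1 flat file
#'
#' Reads zero or more AAindex1 records (\code{H}, \code{D}, \code{I} lines,
#' \code{//} terminators) and returns one entry per record. Only single-residue
#' indices (AAindex1) are supported; the two value rows of the \code{I} block
#' follow the database's residue order (A R N D C Q E G H I / L K M F P S T W
#' Y V). \code{NA} values are tolerated and flag the entry as incomplete.
#'
#' @param file Path to an AAindex1-format file, or a character vector of lines
#'   via \code{text}.
#' @param text Optional character scalar/vector holding the flat-file content
#'   directly (overrides \code{file}).
#' @return An object of class \code{"aaindex_table"}: a named list of entries,
#'   each a list with \code{accession}, \code{description}, \code{values}
#'   (named numeric over the 20 canonical residues) and \code{has_missing}.
#' @examples
#' tab <- read_aaindex(system.file("extdata", "aaindex_core.txt",
#'                                 package = "emcbind"))
#' tab[["KYTJ820101"]]$values[c("I", "R")]
#' @export
read_aaindex <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(file, warn = FALSE)
  }
  entries <- list()
  rec <- character()
  for (ln in lines) {
    if (identical(trimws(ln), "//")) {
      if (length(rec) > 0L) {
        e <- parse_aaindex_record(rec)
        if (e$accession %in% names(entries))
          stop("duplicate AAindex accession: ", e$accession)
        entries[[e$accession]] <- e
      }
      rec <- character()
    } else if (nzchar(trimws(ln))) {
      rec <- c(rec, ln)
    }
  }
  if (length(rec) > 0L && any(grepl("^H ", rec)))
    stop("AAindex record not terminated by '//': ",
         sub("^H\\s+", "", grep("^H ", rec, value = TRUE)[1L]))
  structure(entries, class = "aaindex_table")
}

parse_aaindex_record <- function(rec) {
  hline <- grep("^H\\s", rec)
  if (length(hline) != 1L)
    stop("malformed AAindex record: expected exactly one H line")
  accession <- trimws(sub("^H\\s+", "", rec[hline]))
  dlines <- grep("^D\\s", rec)
  description <- if (length(dlines)) {
    paste(trimws(sub("^D\\s+", "", rec[dlines])), collapse = " ")
  } else ""
  iline <- grep("^I\\s", rec)
  if (length(iline) != 1L)
    stop("malformed AAindex record '", accession, "': missing I line")
  if (length(rec) < iline + 2L)
    stop("malformed AAindex record '", accession,
         "': expected two value rows after the I line")
  vals <- unlist(lapply(rec[(iline + 1L):(iline + 2L)], function(l) {
    strsplit(trimws(l), "\\s+")[[1L]]
  }), use.names = FALSE)
  if (length(vals) != 20L)
    stop("malformed AAindex record '", accession, "': expected 20 values, got ",
         length(vals))
  num <- suppressWarnings(as.numeric(ifelse(vals %in% c("NA", "-"), NA, vals)))
  bad <- is.na(num) & !(vals %in% c("NA", "-"))
  if (any(bad))
    stop("malformed AAindex record '", accession, "': non-numeric value '",
         vals[bad][1L], "'")
  names(num) <- AA_ILINE
  list(accession = accession, description = description,
       values = num, has_missing = anyNA(num))
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat("AAindex table:", length(x), "entries\n")
  for (e in x) {
    cat(sprintf("  %-12s %s%s\n", e$accession,
                substr(e$description, 1, 60),
                if (e$has_missing) " [missing values]" else ""))
  }
  invisible(x)
}

#' Write an AAindex table back to the AAindex1 flat format
#'
#' @param table An \code{aaindex_table}.
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
write_aaindex <- function(table, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (e in table) {
    writeLines(c(paste("H", e$accession), paste("D", e$description),
                 paste("I ", paste(sprintf("%s/%s", AA_ILINE[1:10],
                                           AA_ILINE[11:20]), collapse = "  "))),
               con)
    fmt <- function(v) paste(ifelse(is.na(v), "NA", sprintf("%.6f", v)),
                             collapse = " ")
    writeLines(c(fmt(e$values[1:10]), fmt(e$values[11:20]), "//"), con)
  }
  invisible(file)
}

#' Min-max scale a property index to the 0-1 range
#'
#' Affine rescaling of the 20 residue values so the minimum maps to 0 and the
#' maximum to 1. Indices with missing values, or constant indices (max equal
#' to min, for which the map is undefined), are rejected.
#'
#' @param entry A single \code{aaindex_table} entry.
#' @return An object of class \code{"scaled_index"} with \code{accession},
#'   \code{values} (in [0, 1]), \code{scale_min} and \code{scale_max}.
#' @export
scale_index <- function(entry) {
  v <- entry$values
  if (isTRUE(entry$has_missing) || anyNA(v))
    stop("index '", entry$accession, "' has missing values; cannot scale")
  mn <- min(v); mx <- max(v)
  if (mx == mn)
    stop("index '", entry$accession, "' is constant; min-max scaling undefined")
  structure(list(accession = entry$accession,
                 values = (v - mn) / (mx - mn),
                 scale_min = mn, scale_max = mx),
            class = "scaled_index")
}

#' Scale every usable index in a table
#'
#' Applies \code{\link{scale_index}} to each entry, silently dropping entries
#' that are constant or have missing values (they carry no usable signal for
#' feature selection); dropped accessions are reported via \code{message}.
#'
#' @param table An \code{aaindex_table}.
#' @return Named list of \code{scaled_index} objects,
#'   class \code{"scaled_index_list"}.
#' @export
scale_aaindex <- function(table) {
  out <- list()
  dropped <- character()
  for (e in table) {
    s <- tryCatch(scale_index(e), error = function(err) NULL)
    if (is.null(s)) dropped <- c(dropped, e$accession) else out[[e$accession]] <- s
  }
  if (length(dropped))
    message("dropped unusable indices: ", paste(dropped, collapse = ", "))
  structure(out, class = "scaled_index_list")
}

#' Bundled amino-acid property indices
#'
#' Loads the package's bundled table of 20 widely used published property
#' scales (hydropathy, hydrophilicity, polarity, charge, volume, secondary-
#' structure propensities, ...), already min-max scaled. This is the default
#' feature pool for \code{\link{emc_fit}}; a full AAindex download can be
#' substituted via \code{\link{read_aaindex}} + \code{\link{scale_aaindex}}.
#'
#' @param scaled Logical; return scaled indices (default) or the raw table.
#' @return A \code{scaled_index_list} (or \code{aaindex_table} if
#'   \code{scaled = FALSE}).
#' @export
aaindex_core <- function(scaled = TRUE) {
  tab <- read_aaindex(system.file("extdata", "aaindex_core.txt",
                                  package = "emcbind", mustWork = TRUE))
  if (scaled) scale_aaindex(tab) else tab
}

#' Look up scaled values for a residue string
#'
#' Non-canonical residues (X, B, Z, U, ...) have no tabulated property value
#' and are imputed at mid-scale (0.5) with a warning.
#'
#' @param index A \code{scaled_index}.
#' @param residues Character vector of single-letter residues, or a single
#'   sequence string.
#' @return Numeric vector of scaled values in [0, 1], one per residue.
#' @export
index_values <- function(index, residues) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1L]]
  v <- index$values[residues]
  if (anyNA(v)) {
    warning("non-canonical residue(s) ",
            paste(unique(residues[is.na(v)]), collapse = ","),
            " imputed at mid-scale (0.5) for index ", index$accession)
    v[is.na(v)] <- 0.5
  }
  unname(v)
}

#' Export a scaled index table as TSV
#'
#' One row per index, columns \code{accession} then the 20 canonical residues
#' in alphabetical order.
#'
#' @param scaled A \code{scaled_index_list}.
#' @param file Output path.
#' @export
write_scaled_tsv <- function(scaled, file) {
  m <- t(vapply(scaled, function(s) s$values[AA_ALPHA], numeric(20L)))
  colnames(m) <- AA_ALPHA
  df <- data.frame(accession = names(scaled), m, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
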