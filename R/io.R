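# Readers/writers for the pipeline's TSV contracts and table validation.

#' Write a count matrix as TSV
#'
#' First column `gene_id`, remaining columns `t=<hours>`.  Replicates are
#' conventionally written as separate files suffixed `_rep<k>`.
#'
#' @param counts Count matrix with gene rownames and `t=` column names.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV
#'
#' @param path Path to a TSV written by [write_counts_tsv()] (or any file
#'   honoring the same header contract).
#' @return Integer matrix with a `times` attribute.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id")
    stop("first column of ", path, " must be gene_id", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  attr(m, "times") <- parse_time_header(colnames(m))
  m
}

#' Write single-cell tracks as TSV
#'
#' Columns: `cell_id`, `parent_id`, `frame`, `time_h`, `area`,
#' `fluor_total` (optional), `arrested`.
#'
#' @param tree A `lineage_tree`.
#' @param path Output path.
#' @export
write_tracks_tsv <- function(tree, path) {
  keep <- intersect(c("cell_id", "parent_id", "frame", "time_h", "area",
                      "fluor_total", "arrested"), names(tree$tracks))
  utils::write.table(tree$tracks[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read single-cell tracks TSV into a lineage tree
#'
#' @param path Path to a tracks TSV.
#' @return A `lineage_tree` (validated; see [lineage_tree()]).
#' @export
read_tracks_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  df$parent_id <- as.character(df$parent_id)
  df$cell_id <- as.character(df$cell_id)
  lineage_tree(df)
}

#' Write mutant calls as TSV
#' @param calls Calls data frame.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an annotation table
#'
#' Expects columns `gene_id`, `essential` (logical), and optionally
#' `groups` (comma-separated category labels).
#'
#' @param path Path to a TSV.
#' @return Annotation data frame.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "essential") %in% names(df)))
    stop("annotation must have gene_id and essential columns",
         call. = FALSE)
  df$essential <- as.logical(df$essential)
  df
}

#' Validate pipeline tables
#'
#' Schema, monotone-time, and invariant checks for the pipeline's input
#' tables.  Returns machine-readable diagnostics (zero rows for
#' well-formed inputs) rather than stopping at the first problem.
#'
#' @param paths Named list/vector of paths; recognized names are
#'   `counts` (one or more count TSVs), `tracks`, and `annotation`.
#' @return Data frame of diagnostics: `table`, `row`, `column`, `issue`.
#' @export
validate_tables <- function(paths) {
  diags <- list()
  note <- function(tab, row, col, issue)
    diags[[length(diags) + 1L]] <<- data.frame(
      table = tab, row = row, column = col, issue = issue,
      stringsAsFactors = FALSE)
  for (p in paths[names(paths) == "counts"]) {
    df <- tryCatch(utils::read.table(p, sep = "\t", header = TRUE,
                                     check.names = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) { note(p, NA, NA, "unreadable"); next }
    if (names(df)[1] != "gene_id") {
      note(p, 0, 1, "first column must be gene_id"); next
    }
    tm <- tryCatch(parse_time_header(names(df)[-1]),
                   error = function(e) NULL)
    if (is.null(tm)) {
      note(p, 0, NA, "count columns must be named t=<hours>")
    } else {
      if (any(diff(tm) <= 0))
        note(p, 0, which(diff(tm) <= 0)[1] + 2,
             "timepoints not strictly increasing")
      if (tm[1] != 0) note(p, 0, 2, "t = 0 column missing")
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      note(p, bad[1, 1], bad[1, 2] + 1,
           "counts must be non-negative integers")
  }
  if ("tracks" %in% names(paths)) {
    p <- paths[["tracks"]]
    df <- tryCatch(utils::read.table(p, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE,
                                     na.strings = c("NA", "")),
                   error = function(e) NULL)
    if (is.null(df)) {
      note(p, NA, NA, "unreadable")
    } else {
      req <- c("cell_id", "parent_id", "frame", "time_h", "area")
      miss <- setdiff(req, names(df))
      if (length(miss) > 0) {
        note(p, 0, NA, paste("missing columns:",
                             paste(miss, collapse = ", ")))
      } else {
        bad <- which(!is.finite(df$area) | df$area <= 0)
        if (length(bad) > 0)
          note(p, bad[1], which(names(df) == "area"),
               "non-positive area")
        for (cc in split(seq_len(nrow(df)), df$cell_id)) {
          tt <- df$time_h[cc]
          if (any(diff(tt) <= 0)) {
            note(p, cc[which(diff(tt) <= 0)[1] + 1],
                 which(names(df) == "time_h"),
                 "times not strictly increasing within cell")
            break
          }
        }
      }
    }
  }
  if ("annotation" %in% names(paths)) {
    p <- paths[["annotation"]]
    df <- tryCatch(utils::read.table(p, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE),
                   error = function(e) NULL)
    if (is.null(df)) note(p, NA, NA, "unreadable")
    else if (!all(c("gene_id", "essential") %in% names(df)))
      note(p, 0, NA, "annotation needs gene_id and essential columns")
  }
  if (length(diags) == 0)
    return(data.frame(table = character(), row = integer(),
                      column = integer(), issue = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, diags)
  rownames(out) <- NULL
  out
}
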