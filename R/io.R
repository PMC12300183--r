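# Tab-delimited input/output with validation.
#
# All tables are plain UTF-8 TSV with a header row; missing values are
# empty cells on disk.  Search-engine exports are tabular, so no vendor or
# XML formats are parsed here.

PSM_ID_COLUMNS <- c("protein_id", "peptide_id", "run_id")

#' Validate a channel design table
#'
#' @param design data.frame with columns channel_id, strain, replicate,
#'   role.  Strains are HT, LT or REF; roles are "reduced",
#'   "oxidized-complement", "abundance" or "reference".
#' @param type "any", "redox" (requires exactly one reduced and one
#'   oxidized-complement channel per (strain, replicate)) or "abundance".
#' @return the design, invisibly, after validation.
#' @export
validate_channel_design <- function(design, type = c("any", "redox", "abundance")) {
  type <- match.arg(type)
  req <- c("channel_id", "strain", "replicate", "role")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stopf("channel design lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(design$channel_id))
    stopf("channel design has duplicated channel_id values")
  bad <- setdiff(design$strain, c("HT", "LT", "REF"))
  if (length(bad)) stopf("unknown strain label(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(design$role,
                 c("reduced", "oxidized-complement", "abundance", "reference"))
  if (length(bad)) stopf("unknown role(s): %s", paste(bad, collapse = ", "))
  if (type == "redox") {
    samp <- design[design$strain %in% c("HT", "LT"), ]
    if (!nrow(samp)) stopf("not a redox design: no HT/LT channels")
    key <- paste(samp$strain, samp$replicate)
    for (k in unique(key)) {
      roles <- samp$role[key == k]
      if (sum(roles == "reduced") != 1 || sum(roles == "oxidized-complement") != 1)
        stopf("not a redox design: sample %s needs exactly one reduced and one oxidized-complement channel", k)
    }
  }
  if (type == "abundance" && !any(design$role == "abundance"))
    stopf("not an abundance design: no channels with role 'abundance'")
  invisible(design)
}

#' Read a PSM-level reporter-intensity table
#'
#' Expects a tab-delimited file with header columns protein_id,
#' peptide_id, run_id, plus one numeric intensity column per design
#' channel.  Empty cells become missing values; negative intensities are
#' rejected with the offending row and column named.
#'
#' @param path file path.
#' @param design channel design the intensity columns must match.
#' @return data.frame with the identifier columns and the design's
#'   channels, in design order.
#' @export
read_psm_table <- function(path, design) {
  validate_channel_design(design)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = c("", "NA"),
                           colClasses = "character")
  miss <- setdiff(PSM_ID_COLUMNS, names(raw))
  if (length(miss))
    stopf("PSM table '%s' lacks required column(s): %s",
          path, paste(miss, collapse = ", "))
  miss <- setdiff(design$channel_id, names(raw))
  if (length(miss))
    stopf("PSM table '%s' lacks design channel column(s): %s",
          path, paste(miss, collapse = ", "))
  out <- raw[c(PSM_ID_COLUMNS, design$channel_id)]
  for (ch in design$channel_id) {
    v <- suppressWarnings(as.numeric(out[[ch]]))
    bad <- which(!is.na(out[[ch]]) & is.na(v))
    if (length(bad))
      stopf("PSM table '%s': non-numeric intensity at row %d, column '%s'",
            path, bad[1], ch)
    neg <- which(v < 0)
    if (length(neg))
      stopf("PSM table '%s': negative intensity at row %d, column '%s'",
            path, neg[1], ch)
    out[[ch]] <- v
  }
  out
}

#' Read a protein annotation table
#'
#' Tab-delimited with columns protein_id and terms (semicolon-separated
#' term labels; empty = unannotated).  Duplicate protein rows are merged
#' by term union with a warning.
#'
#' @param path file path.
#' @return named list protein_id -> unique character vector of terms,
#'   class `annotation_catalog`.
#' @export
read_annotations <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           na.strings = character(0),
                           colClasses = "character")
  miss <- setdiff(c("protein_id", "terms"), names(raw))
  if (length(miss))
    stopf("annotation table '%s' lacks column(s): %s",
          path, paste(miss, collapse = ", "))
  split_terms <- function(x) {
    t <- strsplit(x, ";", fixed = TRUE)[[1]]
    unique(trimws(t[nzchar(trimws(t))]))
  }
  terms <- lapply(raw$terms, split_terms)
  names(terms) <- raw$protein_id
  dup <- unique(raw$protein_id[duplicated(raw$protein_id)])
  if (length(dup)) {
    warning(sprintf("annotation table '%s': %d duplicated protein id(s) merged by term union",
                    path, length(dup)), call. = FALSE)
    merged <- lapply(dup, function(p)
      unique(unlist(terms[names(terms) == p], use.names = FALSE)))
    keep <- !duplicated(names(terms))
    terms <- terms[keep]
    terms[dup] <- merged
  }
  class(terms) <- "annotation_catalog"
  terms
}

#' Write a single result table as TSV
#'
#' Floats are serialized with 9 significant digits, missing values as
#' empty cells; an existing file is only overwritten with `force = TRUE`.
#'
#' @param x data.frame (or matrix, written with a leading id column).
#' @param path output path.
#' @param force overwrite an existing file.
#' @param id_column name of the leading column when `x` is a matrix with
#'   row names.
#' @return the path, invisibly.
#' @export
write_tsv_table <- function(x, path, force = FALSE, id_column = "protein_id") {
  if (file.exists(path) && !force)
    stopf("refusing to overwrite '%s' (use force = TRUE)", path)
  if (is.matrix(x)) {
    x <- data.frame(rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
    names(x)[1] <- id_column
  }
  out <- x
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.9g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a TSV written by [write_tsv_table()]
#'
#' @param path file path.
#' @return data.frame with column types re-inferred, empty cells as NA.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "")
}

#' Write a named list of result tables to a directory
#'
#' @param tables named list of data.frames/matrices; each is written as
#'   `<name>.tsv`.
#' @param out_dir output directory (created if needed).
#' @param force overwrite existing files.
#' @return named character vector of file paths.
#' @export
write_results <- function(tables, out_dir, force = FALSE) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  paths <- vapply(names(tables), function(nm) {
    write_tsv_table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                    force = force)
  }, character(1))
  paths
}
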