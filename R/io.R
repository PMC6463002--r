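#' @importFrom tibble tibble as_tibble
#' @importFrom utils read.delim write.table
NULL

MISSING_MARKERS_IN <- c("NA", "null", "")
MISSING_MARKER_OUT <- "NA"

#' Read a PSI event-by-sample table
#'
#' Reads a tab-separated PSI table in the TCGASpliceSeq-style dialect:
#' metadata columns `as_id`, `symbol`, `splice_type`, `exons`, followed
#' by one column per sample. Sample tumor/normal labels come from a
#' companion annotation table (see [read_sample_annotation()]).
#'
#' @param path Path to the PSI TSV.
#' @param sample_groups Either a data frame with columns `sample_id`,
#'   `group`, or a named character vector mapping sample id to group.
#' @param missing_markers Strings treated as missing on input.
#' @return A validated [psi_matrix()].
#' @export
read_psi_table <- function(path, sample_groups,
                           missing_markers = MISSING_MARKERS_IN) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL)
  meta_cols <- c("as_id", "symbol", "splice_type", "exons")
  if (ncol(raw) < 5 || !identical(names(raw)[1:4], meta_cols)) {
    abort(paste0("malformed PSI header: expected columns ",
                 paste(meta_cols, collapse = ", "),
                 " followed by sample columns"))
  }
  sample_cols <- names(raw)[-(1:4)]
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_cols))
  for (j in seq_along(sample_cols)) {
    cell <- raw[[sample_cols[j]]]
    is_missing <- cell %in% missing_markers
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("non-numeric PSI cell '%s' at row %d, column '%s'",
                    cell[i], i, sample_cols[j]))
    }
    out_of_range <- !is_missing & (num < 0 | num > 1)
    if (any(out_of_range)) {
      i <- which(out_of_range)[1]
      abort(sprintf("PSI value %s outside [0, 1] at row %d, column '%s'",
                    cell[i], i, sample_cols[j]))
    }
    num[is_missing] <- NA_real_
    vals[, j] <- num
  }
  if (is.data.frame(sample_groups)) {
    grp <- setNames(sample_groups$group, sample_groups$sample_id)
  } else {
    grp <- sample_groups
  }
  if (!all(sample_cols %in% names(grp))) {
    abort("every PSI sample column needs a tumor/normal annotation")
  }
  psi_matrix(
    vals,
    events = tibble(event_id = raw$as_id, gene_symbol = raw$symbol,
                    splice_class = raw$splice_type,
                    exon_descriptor = raw$exons),
    samples = tibble(sample_id = sample_cols,
                     group = unname(grp[sample_cols]))
  )
}

#' Write a PSI matrix to the tab-separated dialect read by [read_psi_table()]
#'
#' Values are written with a fixed format (`%.17g`) so that
#' `read_psi_table(write_psi_table(m))` round-trips exactly; missing
#' entries are written as `NA`.
#'
#' @param m A `psi_matrix`.
#' @param path Output TSV path.
#' @param annotation_path Optional path for the companion
#'   `sample_id  group` annotation TSV.
#' @return `path`, invisibly.
#' @export
write_psi_table <- function(m, path, annotation_path = NULL) {
  chr <- matrix(sprintf("%.17g", m$values), nrow = nrow(m$values))
  chr[is.na(m$values)] <- MISSING_MARKER_OUT
  df <- data.frame(
    as_id = m$events$event_id, symbol = m$events$gene_symbol,
    splice_type = m$events$splice_class, exons = m$events$exon_descriptor,
    chr, check.names = FALSE, stringsAsFactors = FALSE
  )
  names(df)[-(1:4)] <- m$samples$sample_id
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    write.table(as.data.frame(m$samples), annotation_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a tumor/normal sample annotation table
#'
#' @param path TSV with columns `sample_id`, `group`.
#' @return A tibble with those columns.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("sample_id", "group") %in% names(df))) {
    abort("sample annotation must have columns sample_id, group")
  }
  if (!all(df$group %in% c("tumor", "normal"))) {
    abort("sample group labels must be 'tumor' or 'normal'")
  }
  as_tibble(df[c("sample_id", "group")])
}

#' Read a clinical endpoint table
#'
#' Expects a TSV with columns `sample_id`, `os_time`, `os_event`,
#' `pfi_time`, `pfi_event`: overall-survival and progression-free
#' interval times in days with 0/1 status flags.
#'
#' @param path Clinical TSV path.
#' @return A validated tibble.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- read.delim(path, header = TRUE, sep = "\t")
  validate_clinical(as_tibble(df))
}

validate_clinical <- function(df) {
  need <- c("sample_id", "os_time", "os_event", "pfi_time", "pfi_event")
  if (!all(need %in% names(df))) {
    abort(paste0("clinical table must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in clinical table")
  tm <- c(df$os_time, df$pfi_time)
  if (any(is.na(tm)) || any(tm < 0)) abort("survival times must be nonnegative")
  for (col in c("os_event", "pfi_event")) {
    v <- df[[col]]
    if (is.logical(v)) v <- as.integer(v)
    if (!all(v %in% c(0L, 1L))) abort(paste0(col, " must be 0/1"))
    df[[col]] <- as.integer(v)
  }
  df$os_time <- as.numeric(df$os_time)
  df$pfi_time <- as.numeric(df$pfi_time)
  df[need]
}

#' Read gene sets in GMT format
#'
#' One set per line: term id, description, then member gene symbols,
#' tab-separated. Symbols are uppercased.
#'
#' @param path GMT file path.
#' @return A named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(paste0("GMT line with no genes: ", substr(ln, 1, 40)))
    }
    genes <- unique(toupper(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) abort(paste0("empty gene set: ", parts[1]))
    if (parts[1] %in% names(sets)) abort(paste0("duplicate term id: ", parts[1]))
    s <- genes
    attr(s, "description") <- parts[2]
    sets[[parts[1]]] <- s
  }
  if (length(sets) == 0) abort("no gene sets in GMT file")
  sets
}
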