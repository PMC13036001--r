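#' Read / write FASTA files of amino-acid sequences
#'
#' Thin wrappers around Biostrings that add the package's conventions:
#' duplicate record ids are an error (naming the offending id), lowercase
#' residues are upconverted with a warning, and records round-trip
#' losslessly.
#'
#' @param path file path
#' @return `read_fasta`: a named character vector of sequences (names are
#'   record ids); empty file gives an empty vector
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- names(set)
  # first whitespace-delimited word is the id, as in standard FASTA headers
  ids <- sub("\\s.*$", "", ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    warning("FASTA contains lowercase residues; converting to uppercase")
    seqs <- toupper(seqs)
  }
  setNames(seqs, ids)
}

#' @rdname read_fasta
#' @param records named character vector of sequences
#' @export
write_fasta <- function(path, records) {
  stopifnot(is.character(records))
  if (is.null(names(records)) && length(records))
    stop("records must be named (names become FASTA ids)")
  set <- Biostrings::AAStringSet(records)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write paired heavy-light tables
#'
#' Delimited tables (TSV by default, CSV for `.csv` paths) with header
#' columns `heavy_id`, `heavy`, `light` and optionally `light_v`, `light_j`.
#' `light` may be absent on read (generation input).  Records with the wrong
#' field count raise a parse error naming the line.  Sequences are
#' upconverted from lowercase with a warning; content validation (alphabet,
#' anchors) is left to [curate_pairs()].
#'
#' @param path file path
#' @return `read_paired_table`: a data.frame with columns `id`, `heavy`,
#'   and when present `light`, `light_v`, `light_j`
#' @export
read_paired_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (!length(nf)) {
    return(data.frame(id = character(), heavy = character(),
                      light = character(), stringsAsFactors = FALSE))
  }
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 bad[1], nf[1], nf[bad[1]]))
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = TRUE)
  need <- c("heavy_id", "heavy")
  if (!all(need %in% names(df)))
    stop("paired table must have columns heavy_id and heavy")
  out <- data.frame(id = df$heavy_id, heavy = df$heavy,
                    stringsAsFactors = FALSE)
  for (col in c("light", "light_v", "light_j"))
    if (col %in% names(df)) out[[col]] <- df[[col]]
  for (col in intersect(c("heavy", "light"), names(out))) {
    if (any(grepl("[a-z]", out[[col]]))) {
      warning(sprintf("column '%s' contains lowercase residues; converting", col))
      out[[col]] <- toupper(out[[col]])
    }
  }
  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup))
    stop("duplicate pair id(s): ", paste(dup, collapse = ", "))
  out
}

#' @rdname read_paired_table
#' @param pairs data.frame with columns `id`, `heavy` and optionally
#'   `light`, `light_v`, `light_j`
#' @export
write_paired_table <- function(path, pairs) {
  stopifnot(is.data.frame(pairs), all(c("id", "heavy") %in% names(pairs)))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- pairs[, intersect(c("id", "heavy", "light", "light_v", "light_j"),
                           names(pairs)), drop = FALSE]
  names(out)[names(out) == "id"] <- "heavy_id"
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
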