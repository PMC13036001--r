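#' Region-definition table for a numbering scheme
#'
#' Loads the versioned scheme table shipped with the package (IMGT-style or
#' Kabat-style region conventions for the numbering-lite annotator):
#' the window of allowed first-conserved-cysteine positions, the fixed FR2,
#' FR3 and FR4 lengths, and the allowed CDR length ranges.
#'
#' @param scheme `"imgt"` or `"kabat"` (case-insensitive)
#' @return named list of scheme constants
#' @export
scheme_table <- function(scheme = c("imgt", "kabat")) {
  scheme <- tolower(scheme[1])
  scheme <- match.arg(scheme, c("imgt", "kabat"))
  if (is.null(.lcgen_env$schemes)) {
    path <- system.file("extdata", "scheme_tables.json", package = "lcgen")
    .lcgen_env$schemes <- jsonlite::fromJSON(path)
  }
  .lcgen_env$schemes[[scheme]]
}

REGION_NAMES <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

new_region_annotation <- function(scheme, starts, ends, len) {
  b <- cbind(start = as.integer(starts), end = as.integer(ends))
  rownames(b) <- REGION_NAMES
  structure(list(scheme = scheme, boundaries = b, length = as.integer(len)),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  b <- x$boundaries
  cat(sprintf("region_annotation (%s, length %d): %s\n", x$scheme, x$length,
              paste(sprintf("%s[%d-%d]", rownames(b), b[, 1], b[, 2]),
                    collapse = " ")))
  invisible(x)
}

#' Annotate framework and CDR regions of a variable-domain sequence
#'
#' A numbering-lite stand-in for external antibody numbering tools, exact on
#' indel-free sequences.  Anchors: FR1 ends at the first cysteine found
#' within the scheme's allowed window (positions 21-26); FR3 ends at the
#' first cysteine at least `cdr1_min + fr2_len + cdr2_min + fr3_len`
#' positions later; FR2 starts at the conserved tryptophan directly after
#' CDR1 and has the scheme's fixed length; FR4 has fixed length and must
#' begin with phenylalanine (light J) or tryptophan (heavy J).  All derived
#' CDR lengths must fall within the scheme's ranges.
#'
#' Coordinates are 1-based closed intervals that tile `[1, nchar(seq)]`.
#'
#' @param seq amino-acid sequence (uppercase)
#' @param scheme `"imgt"` or `"kabat"`
#' @param germline_hint optional `region_annotation` of the germline the
#'   sequence derives from; used directly (after re-validating the cysteine
#'   anchors) when its length matches, as for indel-free synthetic data
#' @return a `region_annotation`, or `NULL` if the sequence cannot be
#'   annotated (missing/misplaced anchors or out-of-range region lengths);
#'   batch callers should treat `NULL` as "flagged invalid"
#' @export
annotate_regions <- function(seq, scheme = "imgt", germline_hint = NULL) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) return(NULL)
  tab <- scheme_table(scheme)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)

  if (!is.null(germline_hint) && inherits(germline_hint, "region_annotation") &&
      germline_hint$length == L) {
    b <- germline_hint$boundaries
    if (chars[b["FR1", "end"]] == "C" && chars[b["FR3", "end"]] == "C")
      return(new_region_annotation(scheme, b[, "start"], b[, "end"], L))
  }

  win <- tab$c1_window
  min_total <- win[1] + tab$cdr1_range[1] + tab$fr2_len + tab$cdr2_range[1] +
    tab$fr3_len + tab$cdr3_range[1] + tab$fr4_len
  if (L < min_total) return(NULL)

  cand <- seq.int(win[1], min(win[2], L))
  c1 <- cand[chars[cand] == "C"][1]
  if (is.na(c1)) return(NULL)

  min_gap <- tab$cdr1_range[1] + tab$fr2_len + tab$cdr2_range[1] + tab$fr3_len
  later <- which(chars == "C")
  later <- later[later >= c1 + min_gap]
  if (!length(later)) return(NULL)
  c2 <- later[1]
  fr3_start <- c2 - tab$fr3_len + 1L

  # conserved tryptophan = FR2 start, directly after CDR1
  w_cand <- c1 + 1L + seq.int(tab$cdr1_range[1], tab$cdr1_range[2])
  w_cand <- w_cand[w_cand <= L & chars[w_cand] == "W"]
  w <- NA_integer_
  for (wc in w_cand) {
    cdr2_len <- fr3_start - (wc + tab$fr2_len)
    if (cdr2_len >= tab$cdr2_range[1] && cdr2_len <= tab$cdr2_range[2]) {
      w <- wc
      break
    }
  }
  if (is.na(w)) return(NULL)

  fr4_start <- L - tab$fr4_len + 1L
  if (fr4_start <= c2 + 1L) return(NULL)
  if (!(chars[fr4_start] %in% tab$fr4_first)) return(NULL)
  cdr3_len <- fr4_start - 1L - c2
  if (cdr3_len < tab$cdr3_range[1] || cdr3_len > tab$cdr3_range[2]) return(NULL)

  starts <- c(1L, c1 + 1L, w, w + tab$fr2_len, fr3_start, c2 + 1L, fr4_start)
  ends <- c(c1, w - 1L, w + tab$fr2_len - 1L, fr3_start - 1L, c2, fr4_start - 1L, L)
  new_region_annotation(scheme, starts, ends, L)
}

#' Extract the per-region subsequences of an annotated sequence
#'
#' @param seq the annotated sequence
#' @param annotation its `region_annotation`
#' @return named character vector (FR1, CDR1, ..., FR4)
#' @export
region_sequences <- function(seq, annotation) {
  stopifnot(inherits(annotation, "region_annotation"),
            nchar(seq) == annotation$length)
  b <- annotation$boundaries
  setNames(substring(seq, b[, "start"], b[, "end"]), rownames(b))
}

#' Serialise a region annotation as JSON
#'
#' Named 1-based closed intervals, suitable for user-facing reports.
#'
#' @param annotation a `region_annotation`
#' @return a JSON string
#' @export
annotation_to_json <- function(annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  b <- annotation$boundaries
  obj <- list(scheme = annotation$scheme, length = annotation$length,
              regions = lapply(seq_len(nrow(b)), function(i)
                list(start = b[i, 1], end = b[i, 2])))
  names(obj$regions) <- rownames(b)
  jsonlite::toJSON(obj, auto_unbox = TRUE)
}
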