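#' Nearest-germline assignment and identity
#'
#' Best V germline by ungapped identity over the V-encoded span (FR1 through
#' the second conserved cysteine, truncated to the shorter of query span and
#' germline), best J germline likewise over the trailing J-encoded span.
#' Ties resolve to the first germline in id order.
#'
#' @param seq chain sequence
#' @param germline_set a [light_germline_set()] / [heavy_germline_set()]
#' @param annotation optional precomputed [annotate_regions()] result
#' @return list with `best_v_id`, `best_j_id`, `v_identity`, `j_identity`,
#'   `mean_identity`, or `NULL` if the sequence cannot be annotated
#' @export
nearest_germline <- function(seq, germline_set, annotation = NULL) {
  if (is.null(annotation)) annotation <- annotate_regions(seq)
  if (is.null(annotation)) return(NULL)
  if (!length(germline_set$v)) stop("empty germline set")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  v_end <- annotation$boundaries["FR3", "end"]

  ident_prefix <- function(germ) {
    g <- strsplit(germ, "", fixed = TRUE)[[1]]
    m <- min(v_end, length(g))
    sum(chars[seq_len(m)] == g[seq_len(m)]) / m
  }
  ident_suffix <- function(germ) {
    g <- strsplit(germ, "", fixed = TRUE)[[1]]
    m <- min(length(g), length(chars))
    sum(chars[length(chars) - m + seq_len(m)] ==
          g[length(g) - m + seq_len(m)]) / m
  }
  vid <- vapply(germline_set$v, function(r) ident_prefix(r$seq), 0)
  jid <- vapply(germline_set$j, function(r) ident_suffix(r$seq), 0)
  bv <- which.max(vid)
  bj <- which.max(jid)
  list(best_v_id = germline_set$v[[bv]]$id,
       best_j_id = germline_set$j[[bj]]$id,
       v_identity = vid[bv], j_identity = jid[bj],
       mean_identity = (vid[bv] + jid[bj]) / 2)
}

#' Per-region mutation counts against a germline chain
#'
#' Position-wise mismatches within each annotated region.  The V-encoded
#' regions (FR1, CDR1, FR2, CDR2, FR3) are reported as `v_regions`; CDR3 and
#' FR4 are junction-ambiguous (partly not germline-encoded) and reported
#' separately.  The region counts always partition the Hamming distance
#' over the full compared span.
#'
#' @param seq chain sequence
#' @param germline same-length germline chain (e.g. the generator's
#'   pre-mutation ground truth)
#' @param annotation a [annotate_regions()] result for `seq`
#' @return list with `counts` (named 7-vector), `v_total`, `junction_total`
#' @export
count_region_mutations <- function(seq, germline, annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  if (nchar(seq) != nchar(germline) || nchar(seq) != annotation$length)
    stop("sequence and germline spans differ in length (indels unsupported)")
  a <- strsplit(seq, "", fixed = TRUE)[[1]]
  b <- strsplit(germline, "", fixed = TRUE)[[1]]
  bd <- annotation$boundaries
  counts <- vapply(rownames(bd), function(rg) {
    i <- bd[rg, "start"]:bd[rg, "end"]
    sum(a[i] != b[i])
  }, 0L)
  list(counts = counts,
       v_total = sum(counts[c("FR1", "CDR1", "FR2", "CDR2", "FR3")]),
       junction_total = sum(counts[c("CDR3", "FR4")]))
}

#' Heavy/light co-evolution correlation
#'
#' For each pair, the mean V/J germline identity of each chain (via
#' [nearest_germline()]); returns the Pearson correlation between the heavy
#' and light identities with the p-value from the exact t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` against a t distribution with `n - 2`
#' degrees of freedom.
#'
#' @param pairs data.frame with `heavy` and `light` columns
#' @param heavy_germlines,light_germlines germline sets for the two chains
#' @return list with `r`, `p_value`, `n` (pairs with both chains assigned),
#'   and the per-pair identity vectors `heavy_identity`, `light_identity`
#' @export
coevolution_correlation <- function(pairs, heavy_germlines, light_germlines) {
  hi <- numeric(0); li <- numeric(0)
  for (i in seq_len(nrow(pairs))) {
    ah <- nearest_germline(pairs$heavy[i], heavy_germlines)
    al <- nearest_germline(pairs$light[i], light_germlines)
    if (is.null(ah) || is.null(al)) next
    hi <- c(hi, ah$mean_identity)
    li <- c(li, al$mean_identity)
  }
  n <- length(hi)
  if (n < 3) stop("need at least 3 assignable pairs")
  if (stats::sd(hi) == 0 || stats::sd(li) == 0)
    stop("zero variance in germline identities; correlation undefined")
  r <- cor(hi, li)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p_value = p, n = n, heavy_identity = hi, light_identity = li)
}

#' Maximum identity of generated sequences to a reference set
#'
#' Brute-force novelty scan: for each generated sequence, the maximum over
#' the reference of ungapped identity computed over the overlapping prefix
#' span `[1, min(length)]`; exact full-length matches are flagged.
#'
#' @param generated,reference character vectors of sequences
#' @return data.frame with `sequence`, `max_identity`, `nearest`,
#'   `exact_match`
#' @export
novelty_scan <- function(generated, reference) {
  stopifnot(length(reference) > 0)
  ref_chars <- strsplit(reference, "", fixed = TRUE)
  out <- lapply(generated, function(g) {
    gc <- strsplit(g, "", fixed = TRUE)[[1]]
    best <- -1; nearest <- NA_integer_
    for (j in seq_along(ref_chars)) {
      rc <- ref_chars[[j]]
      m <- min(length(gc), length(rc))
      id <- sum(gc[seq_len(m)] == rc[seq_len(m)]) / m
      if (id > best) { best <- id; nearest <- j }
    }
    data.frame(sequence = g, max_identity = best,
               nearest = reference[nearest],
               exact_match = g %in% reference,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
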