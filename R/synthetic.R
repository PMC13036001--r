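#' Build the default synthetic paired-repertoire model
#'
#' Constructs a desk-scale stand-in for a paired human Fv repertoire with the
#' statistical structure the generation model is meant to exploit:
#'
#' * 8 heavy and 6 light germline V families (4 kappa-like, 2 lambda-like),
#'   each light family carrying a unique 10-residue leading signature whose
#'   first two residues identify the type (`DI...` kappa-like, `QS...`
#'   lambda-like), two V genes per light family;
#' * indel-free framework templates with the conserved anchor residues
#'   (cysteine at position 23, tryptophan at FR2 start, cysteine at FR3 end,
#'   phenylalanine/tryptophan at FR4 start) at scheme-consistent positions;
#' * J segments contributing the last three CDR3 residues plus FR4;
#' * a non-uniform heavy-family x light-family pairing matrix with one
#'   dominant partner (probability 0.6) per heavy family;
#' * somatic-hypermutation statistics: a per-antibody maturation intensity
#'   `lambda ~ Gamma(shape 2, scale 3.5)` shared by both chains, with
#'   per-chain Poisson mutation counts at rates 1.2 (heavy) and 0.8 (light),
#'   which induces the natural positive correlation between heavy and light
#'   mutation loads.
#'
#' Framework and CDR templates avoid cysteine and tryptophan outside the
#' anchors so that anchor-based annotation is exact on unmutated chains.
#'
#' @param seed integer seed; the same seed always yields the identical
#'   repertoire
#' @return an object of class `synthetic_repertoire`
#' @export
build_default_repertoire <- function(seed = 104L) {
  with_preserved_rng(seed, {
    safe <- setdiff(AA_ALPHABET, c("C", "W"))
    rand_res <- function(n) paste(sample(safe, n, replace = TRUE), collapse = "")

    make_light_family <- function(fam, type, sig2, weight) {
      repeat {
        sig <- paste0(sig2, rand_res(8))
        if (!(sig %in% .lcgen_tmp_sigs)) break
      }
      .lcgen_tmp_sigs <<- c(.lcgen_tmp_sigs, sig)
      cdr1_len <- sample(6:8, 1)
      fr1 <- paste0(sig, rand_res(12), "C")
      cdr1 <- rand_res(cdr1_len)
      fr2 <- paste0("W", rand_res(16))
      cdr2 <- rand_res(3)
      fr3 <- paste0(rand_res(35), "C")
      base <- list(fr1 = fr1, cdr1 = cdr1, fr2 = fr2, cdr2 = cdr2, fr3 = fr3)
      genes <- list()
      for (g in 1:2) {
        parts <- base
        if (g == 2) {
          # second allele-like gene: a few template substitutions outside
          # the signature and anchors
          v <- strsplit(paste0(parts$fr1, parts$cdr1, parts$fr2, parts$cdr2,
                               parts$fr3), "")[[1]]
          anch <- c(23L, 23L + cdr1_len + 1L, length(v))
          pos <- sample(setdiff(11:(length(v) - 1L), anch), 4)
          for (p in pos) v[p] <- sample(setdiff(safe, v[p]), 1)
          vs <- paste(v, collapse = "")
          parts$fr1 <- substr(vs, 1, 23)
          parts$cdr1 <- substr(vs, 24, 23 + cdr1_len)
          parts$fr2 <- substr(vs, 24 + cdr1_len, 40 + cdr1_len)
          parts$cdr2 <- substr(vs, 41 + cdr1_len, 43 + cdr1_len)
          parts$fr3 <- substr(vs, 44 + cdr1_len, 79 + cdr1_len)
        }
        genes[[g]] <- c(parts, list(
          id = sprintf("%s-%d", fam, g), family = fam, type = type,
          cdr1_len = cdr1_len,
          seq = paste0(parts$fr1, parts$cdr1, parts$fr2, parts$cdr2, parts$fr3),
          weight = weight * c(0.6, 0.4)[g]))
      }
      genes
    }

    .lcgen_tmp_sigs <- character()
    fam_weights <- c(4, 3, 2, 1, 2, 1)
    light_v <- list()
    for (i in 1:4)
      light_v <- c(light_v, make_light_family(sprintf("SYN-KV%d", i), "kappa",
                                              "DI", fam_weights[i]))
    for (i in 1:2)
      light_v <- c(light_v, make_light_family(sprintf("SYN-LV%d", i), "lambda",
                                              "QS", fam_weights[4 + i]))

    heavy_v <- lapply(1:8, function(i) {
      cdr1_len <- 8L
      parts <- list(fr1 = paste0(rand_res(22), "C"), cdr1 = rand_res(cdr1_len),
                    fr2 = paste0("W", rand_res(16)), cdr2 = rand_res(7),
                    fr3 = paste0(rand_res(35), "C"))
      c(parts, list(id = sprintf("SYN-HV%d-1", i), family = sprintf("SYN-HF%d", i),
                    type = "heavy", cdr1_len = cdr1_len,
                    seq = paste0(parts$fr1, parts$cdr1, parts$fr2, parts$cdr2,
                                 parts$fr3),
                    weight = 1))
    })

    light_j <- lapply(1:3, function(i)
      list(id = sprintf("SYN-LJ%d", i), seq = paste0(rand_res(3), "F", rand_res(9))))
    heavy_j <- lapply(1:2, function(i)
      list(id = sprintf("SYN-HJ%d", i), seq = paste0(rand_res(3), "W", rand_res(9))))

    hf <- vapply(heavy_v, `[[`, "", "family")
    lf <- unique(vapply(light_v, `[[`, "", "family"))
    pairing <- matrix(0.4 / (length(lf) - 1), nrow = length(hf), ncol = length(lf),
                      dimnames = list(hf, lf))
    for (i in seq_along(hf)) pairing[i, ((i - 1) %% length(lf)) + 1] <- 0.6

    rep <- structure(list(
      heavy_v = heavy_v, light_v = light_v,
      heavy_j = heavy_j, light_j = light_j,
      pairing = pairing,
      shm = list(gamma_shape = 2, gamma_scale = 3.5,
                 rate_heavy = 1.2, rate_light = 0.8),
      cdr3_len = list(heavy = c(11L, 15L), light = c(8L, 11L)),
      j_cdr3 = 3L, fr4_len = 10L,
      seed = as.integer(seed)
    ), class = "synthetic_repertoire")

    # exemplar full-length chains with stored ground-truth boundaries
    add_exemplars <- function(vlist, jlist, min_cdr3) {
      fill <- paste(rep("G", min_cdr3 - rep$j_cdr3), collapse = "")
      lapply(vlist, function(v) {
        v$exemplar <- paste0(v$seq, fill, jlist[[1]]$seq)
        v$exemplar_annotation <- annotate_regions(v$exemplar, "imgt")
        if (is.null(v$exemplar_annotation))
          stop("internal error: germline exemplar failed annotation")
        v
      })
    }
    rep$light_v <- add_exemplars(rep$light_v, rep$light_j, rep$cdr3_len$light[1])
    rep$heavy_v <- add_exemplars(rep$heavy_v, rep$heavy_j, rep$cdr3_len$heavy[1])
    rep
  })
}

#' @export
print.synthetic_repertoire <- function(x, ...) {
  cat(sprintf(
    "synthetic_repertoire: %d heavy V genes (%d families), %d light V genes (%d families), seed %d\n",
    length(x$heavy_v), nrow(x$pairing), length(x$light_v), ncol(x$pairing),
    x$seed))
  invisible(x)
}

# chain assembly + somatic hypermutation for one chain
mutate_chain <- function(germ, n_mut, anchors, safe19 = AA_ALPHABET) {
  chars <- strsplit(germ, "", fixed = TRUE)[[1]]
  avail <- setdiff(seq_along(chars), anchors)
  n_mut <- min(n_mut, length(avail))
  pos <- if (n_mut > 0) sort(sample(avail, n_mut)) else integer()
  for (p in pos) chars[p] <- sample(setdiff(safe19, chars[p]), 1)
  list(seq = paste(chars, collapse = ""), positions = pos)
}

#' Sample one paired antibody from a synthetic repertoire
#'
#' Draws a heavy germline uniformly, the light family from the heavy family's
#' pairing-preference row, a shared maturation intensity
#' `lambda ~ Gamma(shape, scale)`, per-chain Poisson mutation counts
#' `Poisson(lambda * rate)`, uniform non-anchor mutation positions with
#' uniform substitutions over the 19 alternative residues, and a CDR3
#' junction of random length and composition.  Uses R's current RNG stream.
#'
#' @param repertoire a [build_default_repertoire()] object
#' @return a list with the pair (`heavy`, `light`) and full ground truth:
#'   germline ids, pre-mutation chains (`heavy_germ`, `light_germ`), planted
#'   mutation positions, and the maturation intensity `lambda`
#' @export
sample_pair <- function(repertoire) {
  r <- repertoire
  hv <- r$heavy_v[[sample(length(r$heavy_v), 1)]]
  lfam <- sample(colnames(r$pairing), 1, prob = r$pairing[hv$family, ])
  lgenes <- r$light_v[vapply(r$light_v, `[[`, "", "family") == lfam]
  lv <- lgenes[[sample(length(lgenes), 1)]]
  hj <- r$heavy_j[[sample(length(r$heavy_j), 1)]]
  lj <- r$light_j[[sample(length(r$light_j), 1)]]
  safe <- setdiff(AA_ALPHABET, c("C", "W"))

  assemble <- function(v, j, cdr3_rng) {
    cdr3_len <- sample(seq.int(cdr3_rng[1], cdr3_rng[2]), 1)
    junction <- paste(sample(safe, cdr3_len - r$j_cdr3, replace = TRUE),
                      collapse = "")
    germ <- paste0(v$seq, junction, j$seq)
    vlen <- nchar(v$seq)
    anchors <- c(23L, 23L + v$cdr1_len + 1L, vlen,
                 nchar(germ) - r$fr4_len + 1L)
    list(germ = germ, anchors = anchors)
  }
  h <- assemble(hv, hj, r$cdr3_len$heavy)
  l <- assemble(lv, lj, r$cdr3_len$light)

  lambda <- rgamma(1, shape = r$shm$gamma_shape, scale = r$shm$gamma_scale)
  nh <- rpois(1, lambda * r$shm$rate_heavy)
  nl <- rpois(1, lambda * r$shm$rate_light)
  # redraw mutation placement until both chains remain annotatable, so that
  # generated repertoires pass curation by construction (a substitution can
  # otherwise plant a spurious cysteine/tryptophan that confuses the
  # anchor heuristic; ~2-3% of draws)
  repeat {
    hm <- mutate_chain(h$germ, nh, h$anchors)
    if (!is.null(annotate_regions(hm$seq, "imgt"))) break
  }
  repeat {
    lm <- mutate_chain(l$germ, nl, l$anchors)
    if (!is.null(annotate_regions(lm$seq, "imgt"))) break
  }

  list(heavy = hm$seq, light = lm$seq,
       heavy_v = hv$id, heavy_j = hj$id,
       light_v = lv$id, light_j = lj$id,
       light_family = lfam, heavy_family = hv$family, light_type = lv$type,
       heavy_germ = h$germ, light_germ = l$germ,
       heavy_mut_pos = hm$positions, light_mut_pos = lm$positions,
       lambda = lambda)
}

#' Generate a synthetic paired dataset with ground truth
#'
#' @param n number of pairs (>= 1)
#' @param seed integer seed; the full dataset is reproducible per seed
#' @param repertoire repertoire to sample from (the default reference
#'   repertoire if `NULL`)
#' @return an object of class `synthetic_dataset`: `pairs` (data.frame with
#'   `id`, `heavy`, `light`, `light_v`, `light_j`), `truth` (data.frame with
#'   the germline ids, pre-mutation chains, comma-separated planted mutation
#'   positions, per-chain mutation counts and `lambda`), and the
#'   `repertoire`
#' @export
make_dataset <- function(n, seed = 1L, repertoire = NULL) {
  stopifnot(n >= 1)
  if (is.null(repertoire)) repertoire <- build_default_repertoire()
  samples <- with_preserved_rng(seed,
    lapply(seq_len(n), function(i) sample_pair(repertoire)))
  ids <- sprintf("synpair%05d", seq_len(n))
  pairs <- data.frame(
    id = ids,
    heavy = vapply(samples, `[[`, "", "heavy"),
    light = vapply(samples, `[[`, "", "light"),
    light_v = vapply(samples, `[[`, "", "light_v"),
    light_j = vapply(samples, `[[`, "", "light_j"),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    id = ids,
    heavy_v = vapply(samples, `[[`, "", "heavy_v"),
    heavy_j = vapply(samples, `[[`, "", "heavy_j"),
    light_v = vapply(samples, `[[`, "", "light_v"),
    light_j = vapply(samples, `[[`, "", "light_j"),
    heavy_family = vapply(samples, `[[`, "", "heavy_family"),
    light_family = vapply(samples, `[[`, "", "light_family"),
    light_type = vapply(samples, `[[`, "", "light_type"),
    heavy_germ = vapply(samples, `[[`, "", "heavy_germ"),
    light_germ = vapply(samples, `[[`, "", "light_germ"),
    heavy_mut_pos = vapply(samples, function(s)
      paste(s$heavy_mut_pos, collapse = ","), ""),
    light_mut_pos = vapply(samples, function(s)
      paste(s$light_mut_pos, collapse = ","), ""),
    n_mut_heavy = vapply(samples, function(s) length(s$heavy_mut_pos), 0L),
    n_mut_light = vapply(samples, function(s) length(s$light_mut_pos), 0L),
    lambda = vapply(samples, `[[`, 0, "lambda"),
    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, truth = truth, repertoire = repertoire),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d pairs (mean mutations heavy %.1f, light %.1f)\n",
              nrow(x$pairs), mean(x$truth$n_mut_heavy), mean(x$truth$n_mut_light)))
  invisible(x)
}

#' Export a synthetic dataset as paired table + ground-truth sidecar
#'
#' The paired table contains only what curation is allowed to see (ids and
#' sequences plus germline labels); the ground truth goes to a separate
#' sidecar file.
#'
#' @param dataset a [make_dataset()] result
#' @param pairs_path path for the paired table (TSV/CSV by extension)
#' @param truth_path optional path for the ground-truth sidecar (TSV)
#' @export
export_dataset <- function(dataset, pairs_path, truth_path = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  write_paired_table(pairs_path, dataset$pairs)
  if (!is.null(truth_path))
    utils::write.table(dataset$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(pairs_path)
}

#' Germline sets for assignment, reversion and scoring
#'
#' Extract the V and J germline records of one chain from a repertoire, in
#' id order (which also defines tie-breaking for nearest-germline
#' assignment).
#'
#' @param repertoire a `synthetic_repertoire`
#' @return list with elements `v` and `j`, each a list of records with at
#'   least `id` and `seq`
#' @export
light_germline_set <- function(repertoire) {
  v <- repertoire$light_v[order(vapply(repertoire$light_v, `[[`, "", "id"))]
  j <- repertoire$light_j[order(vapply(repertoire$light_j, `[[`, "", "id"))]
  list(v = v, j = j, fr4_len = repertoire$fr4_len, j_cdr3 = repertoire$j_cdr3)
}

#' @rdname light_germline_set
#' @export
heavy_germline_set <- function(repertoire) {
  v <- repertoire$heavy_v[order(vapply(repertoire$heavy_v, `[[`, "", "id"))]
  j <- repertoire$heavy_j[order(vapply(repertoire$heavy_j, `[[`, "", "id"))]
  list(v = v, j = j, fr4_len = repertoire$fr4_len, j_cdr3 = repertoire$j_cdr3)
}

#' Germline leading-residue frequency table
#'
#' One row per light V gene with its 2-residue (type-level) and 10-residue
#' (family/gene-level) leading signatures and a positive frequency weight;
#' the lookup table behind germline-restricted seeding.
#'
#' @param repertoire a `synthetic_repertoire`
#' @return data.frame with columns `id`, `type`, `family`, `leading2`,
#'   `leading10`, `weight`
#' @export
germline_frequency_table <- function(repertoire) {
  lv <- repertoire$light_v
  data.frame(
    id = vapply(lv, `[[`, "", "id"),
    type = vapply(lv, `[[`, "", "type"),
    family = vapply(lv, `[[`, "", "family"),
    leading2 = vapply(lv, function(v) substr(v$seq, 1, 2), ""),
    leading10 = vapply(lv, function(v) substr(v$seq, 1, 10), ""),
    weight = vapply(lv, `[[`, 0, "weight"),
    stringsAsFactors = FALSE)
}

#' Germline CDR reference for chain-type inference
#'
#' The kappa-like and lambda-like germline CDR1/CDR2 sequences, used to
#' infer the light-chain type from user-provided CDRs by BLOSUM62 alignment.
#'
#' @param repertoire a `synthetic_repertoire`
#' @return list `kappa`/`lambda`, each with character vectors `cdr1`, `cdr2`
#' @export
germline_cdr_reference <- function(repertoire) {
  out <- list()
  for (tp in c("kappa", "lambda")) {
    recs <- repertoire$light_v[vapply(repertoire$light_v, `[[`, "", "type") == tp]
    out[[tp]] <- list(cdr1 = unique(vapply(recs, `[[`, "", "cdr1")),
                      cdr2 = unique(vapply(recs, `[[`, "", "cdr2")))
  }
  out
}
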