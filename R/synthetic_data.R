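#' Describe a synthetic pseudo-species
#'
#' A profile specifies how to simulate promoter-like sequences: an i.i.d.
#' A/C/G/T background with controllable GC content and one or more positional
#' motifs (fixed pattern, fixed offset, per-position mutation probability)
#' standing in for real promoter elements such as the TATA box.
#'
#' @param name Species tag.
#' @param length Sequence length (default 1000).
#' @param motifs List of motifs, each a list with `pattern` (ACGT string),
#'   `offset` (0-based start) and `mutation_rate` in `[0, 0.5]`.
#' @param background_gc Background GC fraction in (0, 1);
#'   `P(G) = P(C) = background_gc / 2`.
#' @return A `species_profile` object.
#' @export
species_profile <- function(name, length = 1000, motifs = list(),
                            background_gc = 0.45) {
  stopifnot(is.character(name), length >= 1,
            background_gc > 0, background_gc < 1)
  for (m in motifs) {
    stopifnot(all(c("pattern", "offset", "mutation_rate") %in% names(m)))
    if (!grepl("^[ACGT]+$", m$pattern)) stop("motif pattern must be ACGT")
    if (m$mutation_rate < 0 || m$mutation_rate > 0.5)
      stop("mutation_rate must be in [0, 0.5]")
    if (m$offset < 0 || m$offset + nchar(m$pattern) > length)
      stop("motif '", m$pattern, "' does not fit at offset ", m$offset)
  }
  structure(list(name = name, length = as.integer(length), motifs = motifs,
                 background_gc = background_gc),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s: length %d, GC %.2f, %d motif(s)\n",
              x$name, x$length, x$background_gc, length(x$motifs)))
  for (m in x$motifs)
    cat(sprintf("  %s @ %d (mutation %.2f)\n", m$pattern, m$offset,
                m$mutation_rate))
  invisible(x)
}

#' Three default pseudo-species profiles
#'
#' Emulates the study design of comparing promoters from three divergent
#' organisms: each profile carries a distinct 10-mer motif at a distinct
#' offset upstream of a nominal +1 position (placed at 70% of the sequence,
#' mirroring a -700/+300 window) and a distinct background GC content, so
#' within-species classification is learnable while cross-species transfer
#' degrades by construction.
#'
#' @param length Sequence length (default 250; use 1000 for full-scale runs).
#' @param mutation_rate Per-position motif mutation probability (default
#'   0.10).
#' @return Named list of three `species_profile` objects.
#' @export
default_profiles <- function(length = 250, mutation_rate = 0.10) {
  tss <- round(0.7 * length)
  stopifnot(tss >= 70)  # motifs must fit upstream
  mk <- function(name, pattern, offset, gc)
    species_profile(name, length,
                    motifs = list(list(pattern = pattern, offset = offset,
                                       mutation_rate = mutation_rate)),
                    background_gc = gc)
  list(
    yeastlike = mk("yeastlike", "TATATAAAGG", tss - 30L, 0.38),
    plantlike = mk("plantlike", "CCAATCAGGT", tss - 60L, 0.45),
    humanlike = mk("humanlike", "GGGCGGGACT", tss - 45L, 0.52))
}

#' Simulate promoter-like sequences from a profile
#'
#' Background bases are drawn i.i.d. with `P(G) = P(C) = background_gc/2`;
#' each motif is written at its offset and then mutated per position (to one
#' of the three other bases) with the profile's mutation probability.
#' Deterministic under `seed`.
#'
#' @param profile A [species_profile()].
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @return A tibble of `n` records (species tag set, label 1).
#' @export
generate_promoters <- function(profile, n, seed = 1) {
  stopifnot(inherits(profile, "species_profile"), n > 0)
  L <- profile$length
  gc <- profile$background_gc
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  withr::with_seed(seed, {
    mat <- matrix(sample(BASES, n * L, replace = TRUE, prob = prob),
                  nrow = n, ncol = L)
    for (m in profile$motifs) {
      pat <- strsplit(m$pattern, "")[[1]]
      for (j in seq_along(pat)) {
        col <- m$offset + j
        mat[, col] <- pat[j]
        if (m$mutation_rate > 0) {
          hit <- runif(n) < m$mutation_rate
          if (any(hit))
            mat[hit, col] <- vapply(
              which(hit),
              function(i) sample(setdiff(BASES, pat[j]), 1),
              character(1))
        }
      }
    }
    bases <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
    seq_records(sprintf("%s_prom_%06d", profile$name, seq_len(n)), bases,
                species = profile$name, label = 1L)
  })
}

#' Motif-presence rule classifier
#'
#' Labels a record positive when every motif of the profile matches at its
#' offset with at most `max_mismatch` mismatches. This trivial scan is the
#' independent learnability oracle for the synthetic fixtures: it bounds from
#' below what a trained model should achieve.
#'
#' @param records A tibble of records.
#' @param profile A [species_profile()] with at least one motif.
#' @param max_mismatch Allowed mismatches per motif (default 3).
#' @return Integer vector of predicted 0/1 labels.
#' @export
motif_scan_classify <- function(records, profile, max_mismatch = 3) {
  records <- check_records(records)
  if (length(profile$motifs) == 0) stop("profile has no motifs to scan for")
  hits <- rep(TRUE, nrow(records))
  for (m in profile$motifs) {
    len <- nchar(m$pattern)
    sub <- substring(records$bases, m$offset + 1L, m$offset + len)
    pat <- strsplit(m$pattern, "")[[1]]
    mm <- rowSums(
      matrix(unlist(strsplit(sub, "")), ncol = len, byrow = TRUE) !=
        matrix(pat, nrow = nrow(records), ncol = len, byrow = TRUE))
    hits <- hits & (mm <= max_mismatch)
  }
  as.integer(hits)
}

#' Generate the full synthetic study fixture
#'
#' For each default pseudo-species: `n_per_class` promoters plus their paired
#' shuffled negatives (a balanced binary dataset of `2 * n_per_class`
#' records) and a motif-free, composition-matched random background pool for
#' background testing. Byte-identical under a fixed seed.
#'
#' @param n_per_class Promoters per species (default 1000).
#' @param length Sequence length (default 250; use 1000 for full-scale runs).
#' @param seed Integer master seed.
#' @param n_background Background pool size per species (default 600).
#' @param shuffle_mode Negative-set shuffle mode (default mononucleotide).
#' @param mutation_rate Motif mutation probability (default 0.10).
#' @return Named list per species, each with `dataset` (labelled records),
#'   `background` (records) and `profile`.
#' @export
generate_full_fixture <- function(n_per_class = 1000, length = 250, seed = 1,
                                  n_background = 600,
                                  shuffle_mode = c("mononucleotide",
                                                   "dinucleotide"),
                                  mutation_rate = 0.10) {
  shuffle_mode <- match.arg(shuffle_mode)
  profiles <- default_profiles(length, mutation_rate)
  out <- list()
  for (i in seq_along(profiles)) {
    pf <- profiles[[i]]
    pos <- generate_promoters(pf, n_per_class, seed = seed + 10000L * i)
    dataset <- build_binary_dataset(pos, mode = shuffle_mode,
                                    seed = seed + 10000L * i + 5000L)
    bg_profile <- species_profile(pf$name, pf$length, motifs = list(),
                                  background_gc = pf$background_gc)
    background <- generate_promoters(bg_profile, n_background,
                                     seed = seed + 10000L * i + 9000L)
    background$label <- 0L
    background$id <- sprintf("%s_bg_%06d", pf$name, seq_len(n_background))
    out[[pf$name]] <- list(dataset = dataset, background = background,
                           profile = pf)
  }
  structure(out, class = "promoter_fixture")
}
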