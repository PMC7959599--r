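#' Shuffle a sequence, preserving its composition
#'
#' Builds the synthetic background class. `"mononucleotide"` applies a
#' uniform random permutation of the characters, preserving single-nucleotide
#' counts. `"dinucleotide"` draws a random Eulerian path on the dinucleotide
#' transition multigraph (Altschul-Erickson style), additionally preserving
#' all 16 dinucleotide counts and the first and last character. Both destroy
#' positional signal while matching composition, which forces classifiers to
#' learn arrangement rather than base content.
#'
#' @param bases A single ACGT string (length >= 2; >= 3 for dinucleotide
#'   mode).
#' @param mode `"mononucleotide"` (default) or `"dinucleotide"`.
#' @param seed Integer seed; deterministic for fixed inputs.
#' @return A shuffled string of the same length.
#' @examples
#' shuffle_sequence("ACGTACGT", seed = 1)
#' @export
shuffle_sequence <- function(bases, mode = c("mononucleotide", "dinucleotide"),
                             seed = 1) {
  mode <- match.arg(mode)
  stopifnot(length(bases) == 1, is.character(bases))
  if (!grepl("^[ACGT]+$", bases)) stop("non-ACGT character in sequence")
  L <- nchar(bases)
  if (mode == "mononucleotide") {
    if (L < 2) stop("sequence too short to shuffle (need length >= 2)")
    chars <- strsplit(bases, "")[[1]]
    return(withr::with_seed(seed, paste(sample(chars), collapse = "")))
  }
  if (L < 3) stop("dinucleotide shuffle needs length >= 3")
  withr::with_seed(seed, dinucleotide_shuffle(bases))
}

# Altschul-Erickson dinucleotide shuffle: pick a random "last out-edge" for
# every non-terminal vertex such that the last edges form an arborescence
# into the terminal character, shuffle the remaining out-edges, then walk the
# Eulerian path. Preserves all dinucleotide counts and the end characters.
dinucleotide_shuffle <- function(bases) {
  chars <- strsplit(bases, "")[[1]]
  n <- length(chars)
  from <- chars[-n]
  to <- chars[-1]
  verts <- unique(chars)
  out <- lapply(setNames(verts, verts), function(v) to[from == v])
  last <- chars[n]
  nonterm <- setdiff(verts[vapply(out, length, 1L) > 0], last)
  for (try in 1:1000) {
    last_edge <- vapply(nonterm, function(v) {
      e <- out[[v]]
      e[sample.int(length(e), 1)]
    }, character(1))
    reaches <- vapply(nonterm, function(v) {
      for (step in seq_len(length(verts) + 1)) {
        if (v == last) return(TRUE)
        if (!v %in% names(last_edge)) return(FALSE)
        v <- last_edge[[v]]
      }
      FALSE
    }, logical(1))
    if (all(reaches)) break
    if (try == 1000) stop("failed to sample a connected edge ordering")
  }
  ordered <- lapply(setNames(verts, verts), function(v) {
    e <- out[[v]]
    if (v %in% names(last_edge)) {
      drop <- match(last_edge[[v]], e)
      e <- e[-drop]
      c(if (length(e) > 1) sample(e) else e, last_edge[[v]])
    } else {
      if (length(e) > 1) sample(e) else e
    }
  })
  pos <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- chars[1]
  v <- chars[1]
  for (i in 2:n) {
    nxt <- ordered[[v]][pos[[v]]]
    pos[[v]] <- pos[[v]] + 1L
    res[i] <- nxt
    v <- nxt
  }
  paste(res, collapse = "")
}

#' Build a balanced promoter / shuffled-background dataset
#'
#' Pairs every promoter (label 1) with one shuffled counterpart (label 0),
#' giving an exactly 1:1 dataset in which each negative matches its positive
#' in length and nucleotide composition. Per-record seeds are derived from
#' `seed` plus the record index, so the result is order-independent and
#' reproducible.
#'
#' @param promoters A tibble of cleaned promoter records.
#' @param mode Shuffle mode, see [shuffle_sequence()].
#' @param seed Integer master seed.
#' @return A tibble of `2n` records: the promoters (label 1) followed by
#'   their shuffled negatives (label 0, ids suffixed `_shuffled`).
#' @export
build_binary_dataset <- function(promoters,
                                 mode = c("mononucleotide", "dinucleotide"),
                                 seed = 1) {
  mode <- match.arg(mode)
  promoters <- check_records(promoters, require_acgt = TRUE)
  if (nrow(promoters) == 0) stop("empty promoter set")
  pos <- promoters
  pos$label <- 1L
  shuffled <- vapply(seq_len(nrow(pos)), function(i) {
    shuffle_sequence(pos$bases[i], mode = mode, seed = seed + i)
  }, character(1))
  neg <- seq_records(paste0(pos$id, "_shuffled"), shuffled,
                     species = pos$species, label = 0L)
  dplyr::bind_rows(pos, neg)
}
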