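#' Overlapping k-mers of a sequence
#'
#' Enumerates windows `bases[i..i+k)` for `i = 0, stride, 2*stride, ...`
#' (default stride 1, the package's feature-extraction convention), giving
#' `floor((L - k)/stride) + 1` k-mers.
#'
#' @param bases A single ACGT string.
#' @param k k-mer length, `1 <= k <= nchar(bases)`.
#' @param stride Step between window starts (default 1).
#' @return Character vector of k-mers.
#' @examples
#' kmerize("ACGT", 2)
#' @export
kmerize <- function(bases, k, stride = 1) {
  stopifnot(length(bases) == 1, is.character(bases))
  L <- nchar(bases)
  if (k < 1 || k > L) stop("k must satisfy 1 <= k <= sequence length (", L, ")")
  if (!grepl("^[ACGT]+$", bases)) stop("non-ACGT character in sequence")
  starts <- seq.int(1L, L - k + 1L, by = stride)
  substring(bases, starts, starts + k - 1L)
}

# all 4^k k-mers in lexicographic order (A < C < G < T); index i corresponds
# to the integer code produced by cpp_tokenize
all_kmers <- function(k) {
  g <- expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE)
  do.call(paste0, g[, seq.int(k, 1L), drop = FALSE])
}

# lexicographic codes (1 .. 4^k) for every window of every sequence
tokenize_codes <- function(bases, k, stride = 1) {
  cpp_tokenize(bases, as.integer(k), as.integer(stride))
}

#' Fit a frequency-ranked k-mer vocabulary
#'
#' Counts every overlapping k-mer (stride 1) across the corpus and assigns
#' integer indices by descending count starting at 1; ties are broken
#' lexicographically so vocabularies are platform-independent. Index 0 is
#' reserved and never assigned: it marks out-of-vocabulary k-mers in data
#' encoded later. Fit the vocabulary on the training split only to avoid
#' leaking test-set composition.
#'
#' @param corpus Character vector of ACGT sequences (non-empty).
#' @param k k-mer length.
#' @return A `kmer_vocab` object: `k`, a tibble `table` with columns `kmer`,
#'   `count`, `index`, and an internal code-to-index lookup.
#' @examples
#' fit_vocabulary(c("AAC", "ACA"), k = 1)$table
#' @export
fit_vocabulary <- function(corpus, k) {
  if (length(corpus) == 0) stop("empty corpus")
  stopifnot(is.character(corpus), k >= 1)
  if (any(nchar(corpus) < k)) stop("every corpus sequence must be >= k long")
  codes <- tokenize_codes(corpus, k)
  counts <- tabulate(unlist(codes), nbins = 4^k)
  kmers <- all_kmers(k)
  present <- which(counts > 0)
  ord <- present[order(-counts[present], kmers[present])]
  table <- tibble::tibble(kmer = kmers[ord], count = counts[ord],
                          index = seq_along(ord))
  code_to_index <- integer(4^k)
  code_to_index[ord] <- seq_along(ord)
  structure(list(k = as.integer(k), table = table,
                 code_to_index = code_to_index,
                 n_tokens = sum(counts)),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab> k=%d, %d k-mers, %d tokens counted\n",
              x$k, nrow(x$table), x$n_tokens))
  print(head(x$table, 5))
  invisible(x)
}

#' Frequency-based tokenization of one sequence
#'
#' Maps each overlapping k-mer to its vocabulary index; k-mers absent from
#' the vocabulary get the reserved index 0. The result has length
#' `L - k + 1`.
#'
#' @param bases A single ACGT string of length `>= vocab$k`.
#' @param vocab A [fit_vocabulary()] object.
#' @return Integer vector of tokens in `[0, V]`.
#' @examples
#' v <- fit_vocabulary(c("AAC"), k = 1)
#' fbt_encode("AAC", v)
#' @export
fbt_encode <- function(bases, vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  codes <- tokenize_codes(bases, vocab$k)[[1]]
  vocab$code_to_index[codes]
}

#' One-hot encode a sequence over all 4^k k-mer channels
#'
#' Each column is the indicator of one overlapping k-mer under lexicographic
#' channel order (A < C < G < T per position), giving a binary matrix of
#' shape `4^k x (L - k + 1)`: a 1,000-nt sequence yields 4 x 1000 at k = 1
#' and 16 x 999 at k = 2.
#'
#' @param bases A single ACGT string.
#' @param k k-mer length.
#' @return Integer 0/1 matrix with k-mers as rownames; every column sums to 1.
#' @examples
#' onehot_encode("AC", 1)
#' @export
onehot_encode <- function(bases, k) {
  codes <- tokenize_codes(bases, k)[[1]]
  m <- matrix(0L, nrow = 4^k, ncol = length(codes),
              dimnames = list(all_kmers(k), NULL))
  m[cbind(codes, seq_along(codes))] <- 1L
  m
}

#' Reconstruct the sequence behind a one-hot matrix
#'
#' Inverts [onehot_encode()]: each column must be a valid indicator and
#' consecutive k-mer windows must agree on their overlap, otherwise an error
#' is raised. The result has length `ncol(matrix) + k - 1`.
#'
#' @param matrix A one-hot matrix as produced by [onehot_encode()].
#' @return The source ACGT string.
#' @export
onehot_decode <- function(matrix) {
  if (!all(matrix %in% c(0L, 1L)) || !all(colSums(matrix) == 1))
    stop("matrix columns must be 0/1 indicators summing to 1")
  k <- as.integer(round(log(nrow(matrix), base = 4)))
  if (4^k != nrow(matrix)) stop("row count is not a power of 4")
  kmers <- all_kmers(k)[apply(matrix, 2, which.max)]
  if (length(kmers) > 1 && k > 1) {
    lead <- substring(kmers[-length(kmers)], 2L, k)
    lag <- substring(kmers[-1], 1L, k - 1L)
    bad <- which(lead != lag)
    if (length(bad))
      stop("inconsistent overlapping windows at column ", bad[1], ": '",
           kmers[bad[1]], "' vs '", kmers[bad[1] + 1], "'")
  }
  paste0(kmers[1], paste(substring(kmers[-1], k, k), collapse = ""))
}

#' Encode a set of equal-length records for model input
#'
#' Produces the token matrix the three classifiers consume. With
#' `encoder = "fbt"` tokens are vocabulary indices (out-of-vocabulary = 0);
#' with `encoder = "onehot"` tokens are the lexicographic k-mer codes
#' `1..4^k`, which the networks expand internally into the `4^k`-channel
#' indicator representation (one 1 per column, exactly the one-hot matrix).
#'
#' @param records A tibble of records, all sequences the same length.
#' @param k k-mer length.
#' @param encoder `"fbt"` or `"onehot"`.
#' @param vocab A [fit_vocabulary()] object (required for `"fbt"`; fit it on
#'   the training split only).
#' @return An `encoded_promoters` object: integer token matrix
#'   `n x (L - k + 1)` plus the encoding contract (encoder, k, vocabulary
#'   hash) and the records' ids, labels and species.
#' @export
encode_sequences <- function(records, k, encoder = c("fbt", "onehot"),
                             vocab = NULL) {
  encoder <- match.arg(encoder)
  k <- as.integer(k)
  records <- check_records(records, require_acgt = TRUE)
  if (nrow(records) == 0) stop("no records to encode")
  L <- unique(nchar(records$bases))
  if (length(L) != 1)
    stop("all sequences must have equal length; found lengths ",
         paste(sort(L), collapse = ", "))
  codes <- tokenize_codes(records$bases, k)
  tokens <- do.call(rbind, codes)
  if (encoder == "fbt") {
    if (is.null(vocab)) stop("encoder 'fbt' requires a fitted vocabulary")
    stopifnot(inherits(vocab, "kmer_vocab"))
    if (vocab$k != k) stop("vocabulary k (", vocab$k, ") != requested k (", k, ")")
    tokens[] <- vocab$code_to_index[tokens]
    vocab_size <- nrow(vocab$table)
    vhash <- rlang::hash(list("fbt", k, vocab$table$kmer, vocab$table$index))
  } else {
    vocab <- NULL
    vocab_size <- 4L^k
    vhash <- rlang::hash(list("onehot", k))
  }
  structure(list(tokens = tokens, encoder = encoder, k = as.integer(k),
                 source_length = L, vocab = vocab,
                 vocab_size = as.integer(vocab_size), vocab_hash = vhash,
                 ids = records$id, labels = records$label,
                 species = records$species),
            class = "encoded_promoters")
}

#' @export
print.encoded_promoters <- function(x, ...) {
  cat(sprintf("<encoded_promoters> %d sequences, %s k=%d, %d positions, V=%d\n",
              nrow(x$tokens), x$encoder, x$k, ncol(x$tokens), x$vocab_size))
  invisible(x)
}

#' @export
`[.encoded_promoters` <- function(x, i) {
  x$tokens <- x$tokens[i, , drop = FALSE]
  x$ids <- x$ids[i]
  x$labels <- x$labels[i]
  x$species <- x$species[i]
  x
}

#' @export
dim.encoded_promoters <- function(x) dim(x$tokens)

#' Write / read a fitted vocabulary as tab-separated text
#'
#' The header comment line records `k` and the corpus token count; the body
#' has columns `kmer`, `index`, `count`.
#'
#' @param vocab A [fit_vocabulary()] object.
#' @param path File path.
#' @return `write_vocabulary()` returns `path` invisibly; `read_vocabulary()`
#'   returns a `kmer_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d n_tokens=%d", vocab$k, vocab$n_tokens), con)
  write.table(vocab$table[, c("kmer", "index", "count")], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  header <- readLines(path, n = 1)
  k <- as.integer(sub("^# k=(\\d+).*", "\\1", header))
  n_tokens <- as.integer(sub(".*n_tokens=(\\d+).*", "\\1", header))
  tab <- read.table(path, sep = "\t", header = TRUE, skip = 1,
                    colClasses = c("character", "integer", "integer"))
  tab <- tibble::as_tibble(tab)[order(tibble::as_tibble(tab)$index), ]
  kmers <- all_kmers(k)
  code_to_index <- integer(4^k)
  code_to_index[match(tab$kmer, kmers)] <- tab$index
  structure(list(k = k, table = tab[, c("kmer", "count", "index")],
                 code_to_index = code_to_index, n_tokens = n_tokens),
            class = "kmer_vocab")
}
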