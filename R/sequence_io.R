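#' Read sequence records from a FASTA file
#'
#' Headers are split on `|`: the text before the first `|` is the record id
#' (whitespace is allowed inside ids), and subsequent `key=value` fields are
#' parsed into the `label` and `species` columns. Bases are uppercased and
#' entry order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble of records (see [seq_records()]).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1|label=1|species=demo", "acgtACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (length(nonblank) == 0) {
    return(seq_records(character(), character()))
  }
  first <- nonblank[1]
  if (!startsWith(lines[first], ">"))
    stop("not FASTA content: line ", first, " does not start with '>'")
  x <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(x) == 0))
    stop("record with empty sequence: ",
         names(x)[which(Biostrings::width(x) == 0)[1]])
  headers <- names(x)
  parts <- strsplit(headers, "|", fixed = TRUE)
  id <- vapply(parts, `[[`, character(1), 1)
  tag <- function(p, key) {
    hit <- grep(paste0("^", key, "="), p[-1], value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
  }
  label <- vapply(parts, tag, character(1), key = "label")
  species <- vapply(parts, tag, character(1), key = "species")
  seq_records(id, toupper(as.character(x)),
              species = species,
              label = suppressWarnings(as.integer(label)))
}

#' Write sequence records to a FASTA file
#'
#' Non-missing `label` and `species` values are carried in the header as
#' pipe-delimited tags (`>id|label=1|species=tag`), the format [read_fasta()]
#' parses back, so a write/read round trip preserves ids, bases and metadata.
#'
#' @param records A tibble of records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- check_records(records)
  headers <- records$id
  has_label <- !is.na(records$label)
  headers[has_label] <- paste0(headers[has_label], "|label=",
                               records$label[has_label])
  has_sp <- !is.na(records$species)
  headers[has_sp] <- paste0(headers[has_sp], "|species=",
                            records$species[has_sp])
  x <- Biostrings::DNAStringSet(records$bases)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Filter records to clean fixed-length ACGT sequences
#'
#' Drops any record whose sequence has the wrong length or contains a
#' character outside A/C/G/T (e.g. N). No masking or imputation is attempted;
#' counts dropped per reason are reported via [message()].
#'
#' @param records A tibble of records.
#' @param required_length Exact sequence length to keep.
#' @return The filtered tibble (a subset of the input; idempotent).
#' @export
clean_records <- function(records, required_length) {
  records <- check_records(records)
  stopifnot(is.numeric(required_length), required_length > 0)
  bad_alpha <- !grepl("^[ACGT]*$", records$bases)
  bad_len <- nchar(records$bases) != required_length
  keep <- !bad_alpha & !bad_len
  message(sprintf(
    "clean_records: kept %d/%d (%d non-ACGT, %d wrong length)",
    sum(keep), nrow(records), sum(bad_alpha), sum(bad_len & !bad_alpha)))
  records[keep, , drop = FALSE]
}

#' Promoter window around a transcription start site
#'
#' Computes the 0-based half-open genomic interval covering `upstream` bases
#' before and `downstream` bases after the TSS (default \eqn{-700/+300},
#' giving a 1,000 bp window). Offsets are strand-relative: on the minus
#' strand the window mirrors to `[tss - downstream, tss + upstream)` and the
#' extracted sequence should be reverse-complemented (as
#' [extract_promoters()] does).
#'
#' @param tss Integer vector of 0-based TSS positions.
#' @param strand Character vector of `"+"` or `"-"` (recycled).
#' @param upstream,downstream Window extent in bases (defaults 700 and 300).
#' @param chrom Optional chromosome names carried through.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`; every
#'   interval has length `upstream + downstream`.
#' @examples
#' promoter_interval(10000, "+")
#' @export
promoter_interval <- function(tss, strand, upstream = 700, downstream = 300,
                              chrom = NA_character_) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  n <- max(length(tss), length(strand))
  tss <- rep_len(as.integer(tss), n)
  strand <- rep_len(strand, n)
  chrom <- rep_len(as.character(chrom), n)
  start <- ifelse(strand == "+", tss - upstream, tss - downstream)
  end <- ifelse(strand == "+", tss + downstream, tss + upstream)
  if (any(start < 0))
    stop("promoter window extends below coordinate 0 (tss=",
         tss[which(start < 0)[1]], ", strand=", strand[which(start < 0)[1]], ")")
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

#' Extract promoter windows from a genome
#'
#' Computes [promoter_interval()] for each row of a BED-like TSS table and
#' extracts the corresponding sequence from the genome records. The TSS is
#' taken as the strand-aware 5' end of each BED feature; minus-strand windows
#' are reverse-complemented.
#'
#' @param genome A tibble of records (chromosome sequences, `id` = chrom).
#' @param tss_table Data frame with BED columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand` (0-based half-open).
#' @param upstream,downstream Window extent, as in [promoter_interval()].
#' @return A tibble of promoter records (`label = 1`).
#' @export
extract_promoters <- function(genome, tss_table, upstream = 700,
                              downstream = 300) {
  genome <- check_records(genome)
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(tss_table)))
    stop("tss_table must have columns ", paste(need, collapse = ", "))
  tss <- ifelse(tss_table$strand == "+", tss_table$start, tss_table$end - 1L)
  iv <- promoter_interval(tss, tss_table$strand, upstream, downstream,
                          chrom = tss_table$chrom)
  chrom_seq <- setNames(genome$bases, genome$id)
  missing_chrom <- setdiff(unique(iv$chrom), names(chrom_seq))
  if (length(missing_chrom))
    stop("chromosome(s) not in genome: ", paste(missing_chrom, collapse = ", "))
  too_long <- iv$end > nchar(chrom_seq[iv$chrom])
  if (any(too_long))
    stop("promoter window extends past chromosome end for TSS at ",
         iv$chrom[which(too_long)[1]], ":", tss[which(too_long)[1]])
  seqs <- substring(chrom_seq[iv$chrom], iv$start + 1L, iv$end)
  minus <- iv$strand == "-"
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  name <- if ("name" %in% names(tss_table)) as.character(tss_table$name) else
    paste0(iv$chrom, ":", iv$start, "-", iv$end)
  seq_records(name, seqs, label = 1L)
}

#' Read a 6-column BED file of TSS features
#'
#' @param path Path to a BED file (no header).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_tss_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "name", "score",
                                  "strand"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "character", "character"))
  tibble::as_tibble(bed)
}

#' Sample random fixed-length windows from a genome
#'
#' Draws `n` contiguous windows uniformly over all valid (sequence, offset)
#' positions on the forward strand, rejecting windows that contain a
#' non-ACGT character. Used to build the random genomic background test set.
#'
#' @param genome A tibble of records (the source sequences).
#' @param n Number of windows to draw.
#' @param length Window length (default 1000).
#' @param seed Integer seed; output is reproducible bit-for-bit.
#' @param max_tries Rejection budget (default `100 * n`).
#' @return A tibble of `n` records of the requested length.
#' @export
sample_random_subsequences <- function(genome, n, length = 1000, seed = 1,
                                       max_tries = 100 * n) {
  genome <- check_records(genome)
  stopifnot(n > 0, length > 0)
  n_off <- pmax(nchar(genome$bases) - length + 1L, 0L)
  if (sum(n_off) == 0)
    stop("no valid window: every sequence is shorter than ", length)
  out <- character(n)
  got <- 0L
  tries <- 0L
  withr::with_seed(seed, {
    while (got < n) {
      m <- min(n - got, 1000L)
      src <- sample.int(nrow(genome), m, replace = TRUE, prob = n_off)
      off <- floor(runif(m) * n_off[src]) + 1L
      win <- substring(genome$bases[src], off, off + length - 1L)
      ok <- grepl("^[ACGT]+$", win)
      keep <- win[ok]
      take <- head(keep, n - got)
      out[got + seq_along(take)] <- take
      got <- got + length(take)
      tries <- tries + m
      if (tries > max_tries && got < n)
        stop("rejection budget exhausted after ", tries, " draws: the genome",
             " is too dense in non-ACGT (N) characters to sample ", n,
             " clean windows")
    }
  })
  seq_records(sprintf("bg_%06d", seq_len(n)), out)
}
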