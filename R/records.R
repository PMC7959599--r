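#' Construct a tibble of sequence records
#'
#' The basic currency of the package: one row per nucleotide sequence with an
#' identifier, the bases, an optional species tag and an optional class label
#' (binary promoter task: 1 = promoter, 0 = non-promoter; multiclass task:
#' 0-based species index).
#'
#' @param id Character vector of identifiers. Must not contain `|`, which is
#'   reserved as the metadata delimiter in FASTA headers.
#' @param bases Character vector of sequences over A/C/G/T (lowercase is
#'   uppercased).
#' @param species Optional character vector of species tags.
#' @param label Optional integer vector of class labels.
#' @return A tibble with columns `id`, `bases`, `species`, `label`.
#' @examples
#' seq_records(c("p1", "p2"), c("ACGT", "ttga"))
#' @export
seq_records <- function(id, bases, species = NA_character_, label = NA_integer_) {
  stopifnot(is.character(id), is.character(bases), length(id) == length(bases))
  if (any(grepl("|", id, fixed = TRUE)))
    stop("record ids must not contain '|' (reserved header delimiter)")
  bases <- unname(toupper(bases))
  if (any(nchar(bases) == 0)) stop("record with empty sequence")
  tibble::tibble(
    id = unname(id),
    bases = bases,
    species = unname(as.character(species)),
    label = unname(as.integer(label))
  )
}

# shared validation for functions that consume record tibbles
check_records <- function(records, require_acgt = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("id", "bases")
  if (!all(need %in% names(records)))
    stop("records must have columns 'id' and 'bases'")
  if (!"species" %in% names(records)) records$species <- NA_character_
  if (!"label" %in% names(records)) records$label <- NA_integer_
  if (require_acgt && nrow(records) > 0 &&
      !all(grepl("^[ACGT]+$", records$bases)))
    stop("records contain non-ACGT characters; run clean_records() first")
  tibble::as_tibble(records)
}
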