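#' Coerce a data frame to a validated barcode alignment
#'
#' A barcode alignment is a tibble with one row per specimen and columns
#' `specimen_id`, `species`, and `sequence` (aligned, equal-length DNA over
#' the alphabet A/C/G/T/N/-). The reading frame of the first complete codon
#' is carried as the `frame_offset` attribute (0, 1 or 2).
#'
#' @param x A data frame with columns `specimen_id`, `species`, `sequence`.
#' @param frame_offset Integer 0-2, column index (0-based) of the first
#'   complete codon.
#' @return A tibble of class `barcode_alignment`.
#' @export
#' @examples
#' aln <- as_barcode_alignment(tibble::tibble(
#'   specimen_id = c("s1", "s2"),
#'   species = c("A", "B"),
#'   sequence = c("ATGACG", "ATAACG")
#' ))
#' alignment_length(aln)
as_barcode_alignment <- function(x, frame_offset = 0L) {
  if (!is.data.frame(x)) {
    abort_hrmelt("alignment must be a data frame", "input_error")
  }
  need <- c("specimen_id", "species", "sequence")
  if (!all(need %in% names(x))) {
    abort_hrmelt(
      paste0("alignment needs columns: ", paste(need, collapse = ", ")),
      "input_error"
    )
  }
  aln <- as_tibble(x)[need]
  aln$specimen_id <- as.character(aln$specimen_id)
  aln$species <- as.character(aln$species)
  aln$sequence <- toupper(as.character(aln$sequence))
  if (nrow(aln) == 0) {
    abort_hrmelt("alignment must contain at least one record", "input_error")
  }
  if (anyDuplicated(aln$specimen_id)) {
    abort_hrmelt("specimen_id values must be unique", "input_error")
  }
  lens <- nchar(aln$sequence)
  if (length(unique(lens)) != 1) {
    abort_hrmelt(
      sprintf(
        "aligned sequences must have equal length (found lengths %s)",
        paste(sort(unique(lens)), collapse = ", ")
      ),
      "alignment_error"
    )
  }
  bad <- str_detect(aln$sequence, "[^ACGTN-]")
  if (any(bad)) {
    abort_hrmelt(
      sprintf(
        "non-ACGTN- character in sequence(s): %s",
        paste(head(aln$specimen_id[bad], 5), collapse = ", ")
      ),
      "alphabet_error"
    )
  }
  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) {
    abort_hrmelt("frame_offset must be 0, 1 or 2", "config_error")
  }
  attr(aln, "frame_offset") <- frame_offset
  class(aln) <- c("barcode_alignment", class(aln))
  aln
}

#' @rdname as_barcode_alignment
#' @export
alignment_length <- function(x) nchar(x$sequence[[1]])

#' @rdname as_barcode_alignment
#' @export
frame_offset <- function(x) {
  fo <- attr(x, "frame_offset", exact = TRUE)
  if (is.null(fo)) 0L else fo
}

#' Read a species-labelled alignment from FASTA
#'
#' The species label is parsed from each FASTA header as the text after the
#' last occurrence of `delimiter` (default `"|"`); headers without the
#' delimiter get the label `"unknown"`.
#'
#' @param path Path to an aligned FASTA file.
#' @param delimiter Single character separating specimen id from species
#'   label in the header.
#' @inheritParams as_barcode_alignment
#' @return A `barcode_alignment` tibble.
#' @export
read_alignment <- function(path, delimiter = "|", frame_offset = 0L) {
  if (!file.exists(path)) {
    abort_hrmelt(sprintf("file not found: %s", path), "input_error")
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort_hrmelt(sprintf("could not parse FASTA: %s", conditionMessage(e)),
        "input_error",
        parent = e
      )
    }
  )
  if (length(set) == 0) {
    abort_hrmelt("empty FASTA file", "input_error")
  }
  headers <- names(set)
  has_delim <- str_detect(headers, fixed(delimiter))
  species <- ifelse(
    has_delim,
    vapply(
      str_split(headers, fixed(delimiter)),
      function(p) p[[length(p)]], character(1)
    ),
    "unknown"
  )
  ids <- ifelse(
    has_delim,
    vapply(
      str_split(headers, fixed(delimiter)),
      function(p) paste(p[-length(p)], collapse = delimiter), character(1)
    ),
    headers
  )
  as_barcode_alignment(
    tibble(
      specimen_id = ids,
      species = species,
      sequence = as.character(set)
    ),
    frame_offset = frame_offset
  )
}

#' Write a barcode alignment to FASTA
#'
#' Headers are written as `specimen_id|species` (with the configured
#' delimiter), so [read_alignment()] round-trips the labelling.
#'
#' @param aln A `barcode_alignment`.
#' @param path Output FASTA path.
#' @param delimiter Header delimiter, as in [read_alignment()].
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, delimiter = "|") {
  aln <- as_barcode_alignment(aln, frame_offset(aln))
  set <- Biostrings::BStringSet(aln$sequence)
  names(set) <- paste(aln$specimen_id, aln$species, sep = delimiter)
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}

.codon_tables <- function(code_table) {
  switch(code_table,
    standard = Biostrings::getGeneticCode("SGC0"),
    invertebrate_mito = Biostrings::getGeneticCode("SGC4"),
    abort_hrmelt(
      sprintf(
        "unknown code_table '%s' (use \"standard\" or \"invertebrate_mito\")",
        code_table
      ),
      "config_error"
    )
  )
}

#' Translate a nucleotide sequence codon by codon
#'
#' One amino-acid letter per complete codon starting at `frame_offset`.
#' Codons containing `N` or a gap translate to `"X"`. The default genetic
#' code is the standard code (NCBI table 1): a third-position A/G transition
#' in an AT-starting codon then reads Ile vs Met, the substitution type a
#' COI mini-barcode diagnostic can hinge on. Under the invertebrate
#' mitochondrial code (table 5, `"invertebrate_mito"`) both ATA and ATG read
#' Met, so that distinction disappears; selecting table 5 raises a warning
#' to flag it.
#'
#' @param sequence A DNA string (may contain N and `-`).
#' @param frame_offset Offset (0-2) of the first complete codon.
#' @param code_table `"standard"` (table 1) or `"invertebrate_mito"`
#'   (table 5).
#' @return A single amino-acid string, one letter per complete codon.
#' @export
#' @examples
#' translate_codons("ATAATG") # "IM" under the standard code
translate_codons <- function(sequence, frame_offset = 0L,
                             code_table = "standard") {
  code <- .codon_tables(code_table)
  if (identical(code_table, "invertebrate_mito")) {
    rlang::warn(
      paste(
        "invertebrate mitochondrial code (table 5): ATA translates to Met,",
        "so ATA/ATG third-position transitions are silent under this table"
      ),
      class = "hrmelt_code_table_warning",
      .frequency = "once",
      .frequency_id = "hrmelt_invert_mito"
    )
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n - frame_offset < 3) {
    abort_hrmelt("sequence has no complete codon after frame_offset",
      "input_error")
  }
  n_codons <- (n - frame_offset) %/% 3
  starts <- frame_offset + 3 * (seq_len(n_codons) - 1) + 1
  codons <- substring(sequence, starts, starts + 2)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Collapse an alignment to haplotypes
#'
#' One haplotype per distinct sequence x species pair, ordered by
#' descending count then lexicographic sequence; ids `H1`, `H2`, ... follow
#' that order. The haplotypes partition the specimens: each `specimen_id`
#' appears in exactly one `members` list.
#'
#' @param aln A `barcode_alignment`.
#' @return A tibble with columns `haplotype_id`, `species`, `sequence`,
#'   `count`, and list-column `members`.
#' @export
collapse_haplotypes <- function(aln) {
  aln <- as_barcode_alignment(aln, frame_offset(aln))
  haps <- aln |>
    group_by(.data$species, .data$sequence) |>
    summarise(
      count = n(),
      members = list(.data$specimen_id),
      .groups = "drop"
    ) |>
    arrange(desc(.data$count), .data$sequence) |>
    mutate(haplotype_id = paste0("H", row_number())) |>
    select("haplotype_id", "species", "sequence", "count", "members")
  haps
}
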