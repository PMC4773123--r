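#' Read a FASTQ file into a tibble of reads
#'
#' Strict 4-line-record parser: yields reads in file order, preserves read
#' ids verbatim (without the leading `@`), and normalizes sequences to the
#' internal RNA alphabet. An empty file gives an empty tibble, not an error.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  empty <- tibble(read_id = character(), sequence = character(),
                  quality = character())
  if (n == 0) return(empty)
  if (n %% 4 != 0) {
    seedmir_abort(
      sprintf("truncated FASTQ record at record %d in '%s'",
              n %/% 4 + 1, path), "fastq_parse")
  }
  ids <- lines[seq(1, n, by = 4)]
  seqs <- lines[seq(2, n, by = 4)]
  plus <- lines[seq(3, n, by = 4)]
  quals <- lines[seq(4, n, by = 4)]
  bad_head <- !startsWith(ids, "@") | !startsWith(plus, "+")
  if (any(bad_head)) {
    seedmir_abort(sprintf("malformed FASTQ record %d in '%s'",
                          which(bad_head)[1], path), "fastq_parse")
  }
  mismatch <- nchar(seqs) != nchar(quals)
  if (any(mismatch)) {
    seedmir_abort(
      sprintf("sequence/quality length mismatch at record %d in '%s'",
              which(mismatch)[1], path), "fastq_parse")
  }
  tibble(read_id = sub("^@", "", ids),
         sequence = normalize_sequence(seqs),
         quality = quals)
}

#' Write reads to FASTQ
#'
#' @param reads tibble with `read_id`, `sequence` and optionally `quality`
#'   (constant maximal quality is written when absent).
#' @param path output path.
#' @param alphabet `"rna"` writes sequences as stored; `"dna"` maps U to T
#'   (the alphabet a sequencer emits).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  s <- reads$sequence
  if (alphabet == "dna") s <- rna_to_dna(s)
  q <- reads$quality %||% strrep("I", nchar(s))
  out <- character(4L * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$read_id)
  out[seq(2, length(out), 4)] <- s
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- q
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path path to an uncompressed FASTA file.
#' @return tibble with columns `header` (full header line after `>`) and
#'   `sequence` (normalized RNA).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    return(tibble(header = character(), sequence = character()))
  }
  tibble(header = names(ss),
         sequence = normalize_sequence(as.character(ss)))
}

#' Write sequences to FASTA
#'
#' @param x tibble holding header and sequence columns.
#' @param path output path.
#' @param header_col,seq_col column names to use.
#' @param alphabet `"rna"` or `"dna"` (U mapped to T).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, header_col = "header", seq_col = "sequence",
                        alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  s <- x[[seq_col]]
  if (alphabet == "dna") s <- rna_to_dna(s)
  writeLines(paste0(">", x[[header_col]], "\n", s), path)
  invisible(path)
}

#' Load a mature miRNA or ncRNA reference library
#'
#' Parses miRBase-style headers (`>ath-miR166a`, optionally followed by an
#' accession and description) into reference entries with species code,
#' member name, family, RNA class and arm. Headers without a species-dash
#' prefix must be resolvable through `species_map`. Duplicate
#' (species, name, sequence) triples collapse to one entry with a warning.
#'
#' @param path FASTA file of mature sequences.
#' @param species_map optional named character vector mapping unprefixed
#'   header names to species codes.
#' @param class_map optional named character vector mapping header names to
#'   RNA classes (`miRNA`, `rRNA`, `tRNA`, `snRNA`, `snoRNA`, `other_ncRNA`).
#'   Names containing a structural-RNA class string are classified from the
#'   name itself when no map entry exists; everything else defaults to
#'   `default_class`.
#' @param default_class class assigned when nothing else applies.
#' @return tibble of reference entries with columns `accession`,
#'   `species_code`, `name`, `family`, `rna_class`, `sequence`, `arm`.
#' @export
load_reference <- function(path, species_map = NULL, class_map = NULL,
                           default_class = "miRNA") {
  fa <- read_fasta(path)
  token <- stringr::word(fa$header, 1)
  desc <- trimws(sub("^\\S+\\s*", "", fa$header))

  prefixed <- grepl("^[A-Za-z]{3,4}-", token)
  species <- ifelse(prefixed, tolower(sub("-.*$", "", token)), NA_character_)
  name <- ifelse(prefixed, sub("^[A-Za-z]{3,4}-", "", token), token)
  if (!is.null(species_map)) {
    hit <- !prefixed & token %in% names(species_map)
    species[hit] <- unname(species_map[token[hit]])
  }
  if (anyNA(species)) {
    seedmir_abort(
      sprintf("cannot resolve a species code for header '%s'",
              fa$header[which(is.na(species))[1]]),
      "reference_format")
  }

  rna_class <- rep(default_class, nrow(fa))
  from_name <- stringr::str_match(name, "(snoRNA|snRNA|rRNA|tRNA)")[, 2]
  rna_class[!is.na(from_name)] <- from_name[!is.na(from_name)]
  if (!is.null(class_map)) {
    hit <- token %in% names(class_map)
    rna_class[hit] <- unname(class_map[token[hit]])
  }

  accession <- ifelse(nzchar(desc), stringr::word(desc, 1), token)
  out <- tibble(
    accession = accession,
    species_code = species,
    name = name,
    family = ifelse(rna_class == "miRNA", derive_family(name), NA_character_),
    rna_class = rna_class,
    sequence = fa$sequence,
    arm = arm_from_name(name))

  dup <- duplicated(out[c("species_code", "name", "sequence")])
  if (any(dup)) {
    warn(sprintf("collapsed %d duplicate reference entr%s in '%s'",
                 sum(dup), if (sum(dup) == 1) "y" else "ies", path))
    out <- out[!dup, ]
  }
  out
}

#' Write a reference tibble back to FASTA
#'
#' Headers are `species_code-name`; loading the result with
#' [load_reference()] reproduces the entry list.
#'
#' @param reference reference tibble as returned by [load_reference()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  x <- tibble(header = paste0(reference$species_code, "-", reference$name,
                              " ", reference$accession),
              sequence = reference$sequence)
  write_fasta(x, path)
}
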