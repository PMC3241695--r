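#' @importFrom Biostrings DNAString DNAStringSet readBStringSet writeXStringSet
#'   reverseComplement matchPattern translate subseq GENETIC_CODE
#' @importFrom IRanges IRanges start end width
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Normalize a raw nucleotide string to the internal DNA alphabet
#'
#' Uppercases the input, maps U to T, and records whether any U was seen.
#' The internal alphabet is DNA (`A`, `C`, `G`, `T`, plus the ambiguity code
#' `N`, which is retained in sequences but excluded from composition counts).
#'
#' @param raw Character scalar, a nucleotide sequence over
#'   `A,C,G,T,U,N` (case-insensitive).
#' @return A list with elements `sequence` (normalized string) and
#'   `alphabet` (`"DNA"` or `"RNA"`; `"RNA"` if any `U`/`u` occurred).
#' @examples
#' normalize_alphabet("acgu")  # "ACGT", RNA
#' @export
normalize_alphabet <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L)
    stop("sequence must be a non-empty character scalar", call. = FALSE)
  up <- toupper(raw)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U", "N"))
  if (length(bad) > 0L)
    stop(sprintf("illegal character '%s' at offset %d", chars[bad[1L]], bad[1L]),
         call. = FALSE)
  has_u <- any(chars == "U")
  list(sequence = gsub("U", "T", up, fixed = TRUE),
       alphabet = if (has_u) "RNA" else "DNA")
}

#' Construct a genome record
#'
#' A genome record holds one normalized nucleotide sequence together with its
#' identifier and the alphabet of the original input. All downstream
#' coordinates are 1-based inclusive on the forward strand.
#'
#' @param id Character scalar identifier.
#' @param sequence Raw nucleotide string; normalized via [normalize_alphabet()].
#' @param description Optional free-text description.
#' @return An object of class `genome_record` with fields `id`, `description`,
#'   `sequence` (over `A,C,G,T,N`), `original_alphabet`.
#' @export
genome_record <- function(id, sequence, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  norm <- normalize_alphabet(sequence)
  structure(
    list(id = id, description = description,
         sequence = norm$sequence, original_alphabet = norm$alphabet),
    class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%d nt, input alphabet %s)\n",
              x$id, nchar(x$sequence), x$original_alphabet))
  invisible(x)
}

#' Read a (multi-record) FASTA file into genome records
#'
#' Sequences are normalized to the internal DNA alphabet (U mapped to T and
#' tagged as RNA input). Record order is preserved; duplicate identifiers are
#' an error.
#'
#' @param path Path to a FASTA file.
#' @return A list of [genome_record()] objects, named by id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L)
    stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(first, ">"))
    stop("malformed FASTA header at line 1 (expected '>'): ", path,
         call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  recs <- lapply(seq_along(set), function(i) {
    norm <- tryCatch(normalize_alphabet(as.character(set[[i]])),
                     error = function(e)
                       stop(sprintf("record '%s': %s", ids[i], conditionMessage(e)),
                            call. = FALSE))
    structure(list(id = ids[i], description = desc[i],
                   sequence = norm$sequence,
                   original_alphabet = norm$alphabet),
              class = "genome_record")
  })
  names(recs) <- ids
  recs
}

#' Write genome records to a FASTA file
#'
#' @param records A list of [genome_record()] objects (or a single record).
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_record")) records <- list(records)
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# internal: 1-based inclusive span; length 0 allowed (end = start - 1)
span <- function(start, end) {
  stopifnot(end >= start - 1L)
  list(start = as.integer(start), end = as.integer(end),
       length = as.integer(end - start + 1L))
}

#' Write a GFF3 annotation for a di-cistronic architecture
#'
#' Emits the five genome segments (`five_prime_UTR`, two `CDS`,
#' `intergenic_region`, `three_prime_UTR`) and, optionally, motif hits as
#' child features of their CDS (`sequence_motif`, with amino-acid positions
#' converted to nucleotide coordinates on the genome). Zero-length segments
#' are omitted. Coordinates are 1-based inclusive per GFF3.
#'
#' @param record A [genome_record()].
#' @param arch A `dicistronic_architecture` from [detect_dicistronic()].
#' @param hits Optional data frame of motif hits (as from [scan_motifs()])
#'   with an `orf` column (1 or 2) naming the polyprotein each hit lies on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(record, arch, hits = NULL, path) {
  stopifnot(inherits(record, "genome_record"),
            inherits(arch, "dicistronic_architecture"))
  glen <- nchar(record$sequence)
  if (arch$genome_length != glen)
    stop("architecture genome_length does not match record length",
         call. = FALSE)
  seg <- list(
    list(type = "five_prime_UTR", s = arch$utr5),
    list(type = "CDS", s = span(arch$orf1$start, arch$orf1$end)),
    list(type = "intergenic_region", s = arch$igr),
    list(type = "CDS", s = span(arch$orf2$start, arch$orf2$end)),
    list(type = "three_prime_UTR", s = arch$utr3))
  keep <- vapply(seg, function(x) x$s$length > 0L, TRUE)
  seg <- seg[keep]
  starts <- vapply(seg, function(x) x$s$start, 1L)
  ends <- vapply(seg, function(x) x$s$end, 1L)
  if (any(starts < 1L) || any(ends > glen))
    stop("segment coordinates exceed sequence bounds", call. = FALSE)
  types <- vapply(seg, `[[`, "", "type")
  ids <- character(length(seg))
  ids[types == "CDS"] <- c("ORF1", "ORF2")[seq_len(sum(types == "CDS"))]
  ids[ids == ""] <- tolower(types[ids == ""])
  gr <- GenomicRanges::GRanges(
    seqnames = record$id,
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = "+")
  S4Vectors::mcols(gr)$type <- types
  S4Vectors::mcols(gr)$ID <- ids
  S4Vectors::mcols(gr)$source <- "dicistro"
  S4Vectors::mcols(gr)$phase <- ifelse(types == "CDS", 0L, NA_integer_)
  if (!is.null(hits) && nrow(hits) > 0L) {
    if (!"orf" %in% names(hits))
      stop("motif hit table must carry an 'orf' column (1 or 2)", call. = FALSE)
    orf_start <- c(arch$orf1$start, arch$orf2$start)[hits$orf]
    nt_start <- orf_start + (hits$aa_start - 1L) * 3L
    nt_end <- nt_start + nchar(hits$match) * 3L - 1L
    if (any(nt_end > glen))
      stop("motif coordinates exceed sequence bounds", call. = FALSE)
    mgr <- GenomicRanges::GRanges(
      seqnames = record$id,
      ranges = IRanges::IRanges(start = nt_start, end = nt_end),
      strand = "+")
    S4Vectors::mcols(mgr)$type <- "sequence_motif"
    S4Vectors::mcols(mgr)$ID <- paste0("motif_", seq_len(nrow(hits)), "_", hits$name)
    S4Vectors::mcols(mgr)$source <- "dicistro"
    S4Vectors::mcols(mgr)$phase <- NA_integer_
    S4Vectors::mcols(mgr)$Parent <- paste0("ORF", hits$orf)
    S4Vectors::mcols(gr)$Parent <- NA_character_
    gr <- c(gr, mgr)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
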