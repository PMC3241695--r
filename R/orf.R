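#' Map start and stop codons per forward reading frame
#'
#' Enumerates, for each of the three forward frames, the 1-based positions of
#' every `ATG` and every stop codon (`TAA`, `TAG`, `TGA`). This is the data
#' behind the classic ORF map plot (half-height start ticks, full-height stop
#' ticks per frame).
#'
#' @param record A [genome_record()] or a plain nucleotide string.
#' @return A list with one element per frame (`frame1`..`frame3`), each a list
#'   with sorted integer vectors `starts` and `stops`.
#' @export
codon_map <- function(record) {
  seq <- as_sequence(record)
  L <- nchar(seq)
  out <- lapply(1:3, function(f) list(starts = integer(), stops = integer()))
  names(out) <- paste0("frame", 1:3)
  if (L < 3L) return(out)
  pos <- seq_len(L - 2L)
  codons <- substring(seq, pos, pos + 2L)
  is_start <- codons == "ATG"
  is_stop <- codons %in% c("TAA", "TAG", "TGA")
  frame <- ((pos - 1L) %% 3L) + 1L
  for (f in 1:3) {
    out[[f]]$starts <- pos[is_start & frame == f]
    out[[f]]$stops <- pos[is_stop & frame == f]
  }
  out
}

# accept either a genome_record or a bare string
as_sequence <- function(x) {
  if (inherits(x, "genome_record")) return(x$sequence)
  if (is.character(x) && length(x) == 1L) return(normalize_alphabet(x)$sequence)
  stop("expected a genome_record or a nucleotide string", call. = FALSE)
}

# ORFs on one strand of a sequence given in its own 5'->3' orientation.
# Rule: within each stop-bounded region of a frame, the 5'-most ATG opens the
# ORF, which runs to (and includes) the terminating stop codon.
orfs_one_strand <- function(seq, min_aa, all_starts = FALSE) {
  L <- nchar(seq)
  res <- list()
  if (L < 6L)
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      nt_length = integer(), aa_length = integer()))
  pos <- seq_len(L - 2L)
  codons <- substring(seq, pos, pos + 2L)
  for (f in 1:3) {
    cpos <- seq.int(f, L - 2L, by = 3L)
    cvec <- codons[cpos]
    stop_idx <- which(cvec %in% c("TAA", "TAG", "TGA"))
    atg_idx <- which(cvec == "ATG")
    prev <- 0L
    for (j in stop_idx) {
      in_region <- atg_idx[atg_idx > prev & atg_idx < j]
      if (length(in_region) > 0L) {
        starts <- if (all_starts) in_region else in_region[1L]
        for (i in starts) {
          aa_len <- j - i
          if (aa_len >= min_aa)
            res[[length(res) + 1L]] <- c(cpos[i], cpos[j] + 2L, f,
                                         (j - i + 1L) * 3L, aa_len)
        }
      }
      prev <- j
    }
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      nt_length = integer(), aa_length = integer()))
  m <- do.call(rbind, res)
  data.frame(start = m[, 1L], end = m[, 2L], frame = m[, 3L],
             nt_length = m[, 4L], aa_length = m[, 5L])
}

#' Find open reading frames
#'
#' Reports every maximal AUG-to-in-frame-stop ORF with at least `min_aa`
#' encoded amino acids. Within each stop-bounded stretch of a reading frame
#' the 5'-most AUG defines the ORF (set `all_starts = TRUE` to also list
#' downstream-AUG alternatives). Reverse-strand ORFs are reported in
#' forward-strand coordinates (`start` is the leftmost base) with
#' `strand == "-"` and the frame of the reverse-complemented sequence.
#'
#' @param record A [genome_record()] or nucleotide string.
#' @param min_aa Minimum encoded protein length in amino acids (default 100,
#'   the "large ORF" candidate threshold).
#' @param strands `"both"` (default) or `"forward"`.
#' @param all_starts If `TRUE`, every AUG in a stop-bounded region opens an
#'   ORF, not only the 5'-most.
#' @return A data frame with columns `start`, `end` (1-based inclusive, the
#'   `end` is the last base of the stop codon), `frame`, `strand`,
#'   `nt_length`, `aa_length`, sorted by descending `nt_length` then
#'   ascending `start`.
#' @export
find_orfs <- function(record, min_aa = 100L, strands = c("both", "forward"),
                      all_starts = FALSE) {
  strands <- match.arg(strands)
  stopifnot(min_aa >= 1L)
  seq <- as_sequence(record)
  L <- nchar(seq)
  fwd <- orfs_one_strand(seq, min_aa, all_starts)
  fwd$strand <- rep("+", nrow(fwd))
  out <- fwd
  if (strands == "both") {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    rev <- orfs_one_strand(rc, min_aa, all_starts)
    if (nrow(rev) > 0L) {
      new_start <- L - rev$end + 1L
      new_end <- L - rev$start + 1L
      rev$start <- new_start
      rev$end <- new_end
      rev$strand <- "-"
      out <- rbind(fwd, rev)
    }
  }
  out <- out[order(-out$nt_length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("start", "end", "frame", "strand", "nt_length", "aa_length")]
}

#' Translate an ORF with the standard genetic code
#'
#' Translates the codons from `start` to `end`, excluding the terminal stop
#' codon. An in-frame stop before the end is an inconsistency error.
#'
#' @param record A [genome_record()] or nucleotide string.
#' @param orf A one-row data frame or list with `start`, `end`, `strand`
#'   (as produced by [find_orfs()]).
#' @return The amino-acid string, of length `(end - start + 1)/3 - 1`.
#' @export
translate_orf <- function(record, orf) {
  seq <- as_sequence(record)
  start <- as.integer(orf$start); end <- as.integer(orf$end)
  if (is.na(start) || is.na(end) || start < 1L || end > nchar(seq) ||
      start >= end)
    stop("ORF coordinates out of bounds", call. = FALSE)
  if ((end - start + 1L) %% 3L != 0L)
    stop("ORF length not divisible by 3", call. = FALSE)
  dna <- Biostrings::DNAString(substr(seq, start, end))
  strand <- if (!is.null(orf$strand)) orf$strand else "+"
  if (identical(strand, "-")) dna <- Biostrings::reverseComplement(dna)
  aa <- as.character(Biostrings::translate(dna, if.fuzzy.codon = "solve",
                                           no.init.codon = TRUE))
  n <- nchar(aa)
  if (substr(aa, n, n) != "*")
    stop("ORF does not end with a stop codon", call. = FALSE)
  body <- substr(aa, 1L, n - 1L)
  if (grepl("*", body, fixed = TRUE))
    stop("internal stop codon before ORF end", call. = FALSE)
  body
}

#' Detect a di-cistronic genome architecture
#'
#' Selects the two longest non-overlapping forward-strand ORFs, orders them
#' 5' to 3' (ORF1 upstream of ORF2), and partitions the genome into
#' 5'UTR / ORF1 / intergenic region / ORF2 / 3'UTR. The presence of any
#' reverse-strand ORF longer than `large_orf_min_nt` is reported as a flag
#' (a di-cistronic positive-strand genome is expected to have none), never
#' as a failure.
#'
#' @param orfs Data frame from [find_orfs()] run on the same record.
#' @param genome_length Genome length in nt.
#' @param large_orf_min_nt Reverse-strand "large ORF" flag threshold (nt).
#' @return An object of class `dicistronic_architecture`: `genome_length`,
#'   spans `utr5`, `igr`, `utr3` (each `start`/`end`/`length`), ORF rows
#'   `orf1`, `orf2`, and `reverse_large_orf` (logical flag).
#' @export
detect_dicistronic <- function(orfs, genome_length, large_orf_min_nt = 300L) {
  genome_length <- as.integer(genome_length)
  fwd <- orfs[orfs$strand == "+", , drop = FALSE]
  fwd <- fwd[order(-fwd$nt_length, fwd$start), , drop = FALSE]
  if (nrow(fwd) < 2L)
    stop("not di-cistronic: fewer than two qualifying forward-strand ORFs",
         call. = FALSE)
  a <- fwd[1L, ]
  rest <- fwd[-1L, , drop = FALSE]
  compatible <- rest$start > a$end | rest$end < a$start
  if (!any(compatible)) {
    cand <- paste(sprintf("%d..%d", rest$start, rest$end), collapse = ", ")
    stop("ambiguous architecture: top ORF ", sprintf("%d..%d", a$start, a$end),
         " overlaps all other candidates (", cand, ")", call. = FALSE)
  }
  b <- rest[which(compatible)[1L], ]
  if (a$start < b$start) { orf1 <- a; orf2 <- b } else { orf1 <- b; orf2 <- a }
  if (orf2$end > genome_length)
    stop("ORF coordinates exceed genome length", call. = FALSE)
  arch <- structure(list(
    genome_length = genome_length,
    utr5 = span(1L, orf1$start - 1L),
    orf1 = as.list(orf1),
    igr = span(orf1$end + 1L, orf2$start - 1L),
    orf2 = as.list(orf2),
    utr3 = span(orf2$end + 1L, genome_length),
    reverse_large_orf = any(orfs$strand == "-" &
                              orfs$nt_length > large_orf_min_nt)),
    class = "dicistronic_architecture")
  total <- arch$utr5$length + orf1$nt_length + arch$igr$length +
    orf2$nt_length + arch$utr3$length
  stopifnot(total == genome_length)
  arch
}

#' @export
print.dicistronic_architecture <- function(x, ...) {
  cat(sprintf("<dicistronic_architecture> genome %d nt\n", x$genome_length))
  cat(sprintf("  5'UTR %d..%d (%d nt)\n", x$utr5$start, x$utr5$end, x$utr5$length))
  cat(sprintf("  ORF1  %d..%d (%d nt, %d aa, frame %d)\n", x$orf1$start,
              x$orf1$end, x$orf1$nt_length, x$orf1$aa_length, x$orf1$frame))
  cat(sprintf("  IGR   %d..%d (%d nt)\n", x$igr$start, x$igr$end, x$igr$length))
  cat(sprintf("  ORF2  %d..%d (%d nt, %d aa, frame %d)\n", x$orf2$start,
              x$orf2$end, x$orf2$nt_length, x$orf2$aa_length, x$orf2$frame))
  cat(sprintf("  3'UTR %d..%d (%d nt)\n", x$utr3$start, x$utr3$end, x$utr3$length))
  if (isTRUE(x$reverse_large_orf))
    cat("  note: large reverse-strand ORF present\n")
  invisible(x)
}

#' Segment accounting for a di-cistronic architecture
#'
#' @param arch A `dicistronic_architecture`.
#' @return A list with per-segment lengths (nt), per-ORF amino-acid lengths,
#'   and `coding_fraction` / `noncoding_fraction` in percent (1 decimal).
#' @export
segment_report <- function(arch) {
  stopifnot(inherits(arch, "dicistronic_architecture"))
  coding_nt <- arch$orf1$nt_length + arch$orf2$nt_length
  glen <- arch$genome_length
  list(
    genome_length = glen,
    utr5_nt = arch$utr5$length,
    orf1_nt = arch$orf1$nt_length,
    igr_nt = arch$igr$length,
    orf2_nt = arch$orf2$nt_length,
    utr3_nt = arch$utr3$length,
    orf1_aa = arch$orf1$aa_length,
    orf2_aa = arch$orf2$aa_length,
    coding_fraction = round(100 * coding_nt / glen, 1L),
    noncoding_fraction = round(100 * (glen - coding_nt) / glen, 1L))
}

# validate a primer string: DNA with IUPAC ambiguity codes allowed
normalize_primer <- function(primer) {
  p <- gsub("U", "T", toupper(gsub("[ -]", "", primer)), fixed = TRUE)
  ok <- strsplit(p, "")[[1L]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok))
    stop("primer contains non-IUPAC character(s): ",
         paste(unique(strsplit(p, "")[[1L]][!ok]), collapse = ","),
         call. = FALSE)
  p
}

#' Place a primer pair in silico and predict the amplicon
#'
#' The sense primer is matched exactly on the forward strand; the antisense
#' primer is matched as its reverse complement. IUPAC degenerate bases in a
#' primer (R, V, ...) match their expansion set; the template is read
#' literally. The principal amplicon runs from the 5'-most sense site to the
#' 3'-most downstream antisense site, length inclusive of both primer
#' footprints. Absent primers give a no-amplicon result, not an error;
#' multiple product combinations are all returned and flagged ambiguous.
#'
#' @param record A [genome_record()] or nucleotide string (the template).
#' @param sense_primer,antisense_primer Primer sequences (>= 10 nt), written
#'   5'->3' as ordered for PCR.
#' @return A list: `found` (logical), `products` (data frame `start`, `end`,
#'   `length`), `amplicon` (the principal product row or `NULL`), and
#'   `ambiguous` (logical).
#' @export
insilico_amplicon <- function(record, sense_primer, antisense_primer) {
  seq <- as_sequence(record)
  fwd <- normalize_primer(sense_primer)
  rev <- normalize_primer(antisense_primer)
  if (nchar(fwd) < 10L || nchar(rev) < 10L)
    stop("primers must be at least 10 nt", call. = FALSE)
  subject <- Biostrings::DNAString(seq)
  s_hits <- Biostrings::matchPattern(Biostrings::DNAString(fwd), subject,
                                     fixed = "subject")
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(rev))
  a_hits <- Biostrings::matchPattern(rc, subject, fixed = "subject")
  none <- list(found = FALSE,
               products = data.frame(start = integer(), end = integer(),
                                     length = integer()),
               amplicon = NULL, ambiguous = FALSE)
  if (length(s_hits) == 0L || length(a_hits) == 0L) return(none)
  s_start <- IRanges::start(s_hits); s_end <- IRanges::end(s_hits)
  a_start <- IRanges::start(a_hits); a_end <- IRanges::end(a_hits)
  prods <- NULL
  for (i in seq_along(s_start)) {
    ok <- a_start > s_end[i]
    if (any(ok))
      prods <- rbind(prods, data.frame(start = s_start[i], end = a_end[ok]))
  }
  if (is.null(prods)) return(none)
  prods$length <- prods$end - prods$start + 1L
  prods <- prods[order(prods$start, prods$end), , drop = FALSE]
  rownames(prods) <- NULL
  principal <- data.frame(start = min(prods$start),
                          end = max(prods$end[prods$start == min(prods$start)]))
  principal$length <- principal$end - principal$start + 1L
  list(found = TRUE, products = prods, amplicon = principal,
       ambiguous = nrow(prods) > 1L)
}
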