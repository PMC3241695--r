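NUC <- c("A", "C", "G", "T")
DINUC <- as.vector(outer(NUC, NUC, function(x, y) paste0(x, y)))
DINUC <- sort(DINUC)  # AA, AC, ..., TT

#' Mono- and dinucleotide composition of a sequence
#'
#' Mononucleotide frequencies are taken over non-N positions; dinucleotide
#' frequencies over overlapping windows of adjacent non-N pairs (linear, not
#' circular). The observed/expected bias ratio of each of the 16
#' dinucleotides is the observed dinucleotide frequency divided by the
#' product of the two constituent mononucleotide frequencies; a ratio below 1
#' marks under-representation (the classic example being CpG suppression in
#' mammalian viruses, and UpA depletion across RNA viruses generally).
#'
#' @param record A [genome_record()] or nucleotide string.
#' @return A `composition_profile`: `mono` (4 frequencies, A,C,G,T), `dinuc`
#'   (16 frequencies, AA..TT), `oe` (16 observed/expected ratios, NA where
#'   the expected frequency is zero), `oe_defined` (logical 16),
#'   `n_mono`, `n_dinuc` (counted positions/windows).
#' @export
composition_profile <- function(record) {
  seq <- as_sequence(record)
  dna <- Biostrings::DNAString(seq)
  mono_counts <- Biostrings::letterFrequency(dna, NUC)
  n_mono <- sum(mono_counts)
  di_counts <- Biostrings::oligonucleotideFrequency(dna, width = 2L)[DINUC]
  n_dinuc <- sum(di_counts)
  if (n_mono < 2L || n_dinuc < 1L)
    stop("insufficient sequence: need at least 2 adjacent non-N bases",
         call. = FALSE)
  mono <- as.numeric(mono_counts) / n_mono
  names(mono) <- NUC
  dinuc <- as.numeric(di_counts) / n_dinuc
  names(dinuc) <- DINUC
  expected <- mono[substr(DINUC, 1L, 1L)] * mono[substr(DINUC, 2L, 2L)]
  defined <- expected > 0
  oe <- ifelse(defined, dinuc / expected, NA_real_)
  names(oe) <- names(defined) <- DINUC
  structure(list(mono = mono, dinuc = dinuc, oe = oe, oe_defined = defined,
                 n_mono = n_mono, n_dinuc = n_dinuc),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat("<composition_profile>\n  mono: ",
      paste(sprintf("%s %.1f%%", NUC, 100 * x$mono), collapse = ", "),
      sprintf("\n  GC %.1f%%, AU %.1f%%", gc_content(x), au_content(x)),
      sprintf("\n  O/E CpG %.2f, UpA %.2f\n", x$oe[["CG"]], x$oe[["TA"]]))
  invisible(x)
}

#' G+C and A+U content in percent
#'
#' @param profile A [composition_profile()].
#' @return Percent, rounded to 1 decimal in reports (returned unrounded).
#' @export
gc_content <- function(profile) {
  stopifnot(inherits(profile, "composition_profile"))
  100 * (profile$mono[["G"]] + profile$mono[["C"]])
}

#' @rdname gc_content
#' @export
au_content <- function(profile) {
  stopifnot(inherits(profile, "composition_profile"))
  100 * (profile$mono[["A"]] + profile$mono[["T"]])
}

#' Assemble the 20-dimensional composition feature vector
#'
#' `mode = "frequencies"` concatenates the 4 mononucleotide and 16
#' dinucleotide frequencies (the feature set used to fit the host
#' discriminant model); `mode = "oe"` concatenates the 4 mononucleotide
#' frequencies and the 16 observed/expected ratios (the representation in
#' which CpG/UpA biases are usually displayed). Ordering is fixed:
#' A,C,G,T then AA,AC,...,TT.
#'
#' @param profile A [composition_profile()].
#' @param mode `"frequencies"` (default) or `"oe"`.
#' @return Named numeric vector of length 20.
#' @export
build_features <- function(profile, mode = c("frequencies", "oe")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "composition_profile"))
  if (mode == "frequencies") {
    c(profile$mono, profile$dinuc)
  } else {
    if (any(!profile$oe_defined))
      stop("O/E undefined for dinucleotide(s): ",
           paste(DINUC[!profile$oe_defined], collapse = ", "), call. = FALSE)
    c(profile$mono, profile$oe)
  }
}

#' Feature matrix for a set of records
#'
#' @param records List of [genome_record()]s.
#' @param mode Passed to [build_features()].
#' @return Numeric matrix, one row per record, rownames = record ids.
#' @export
feature_matrix <- function(records, mode = c("frequencies", "oe")) {
  mode <- match.arg(mode)
  m <- t(vapply(records, function(r) build_features(composition_profile(r), mode),
                numeric(20L)))
  rownames(m) <- vapply(records, `[[`, "", "id")
  m
}
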