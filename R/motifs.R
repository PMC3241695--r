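# Motif patterns are fixed-length, one alternative set per position, written
# with bracket notation: "[QH]CAIGLFVKD" means Q-or-H then the literal rest.
# No gaps or quantifiers: every motif in the shipped catalogue is fixed-length.

#' Parse a motif pattern into per-position alternative sets
#'
#' @param pattern Pattern string, e.g. `"YGDD"` or `"[QH]CAIGLFVKD[QS]"`.
#' @return A list of character vectors, one per position.
#' @export
parse_motif_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars) || j == i + 1L)
        stop("malformed alternative set in pattern: ", pattern, call. = FALSE)
      sets[[length(sets) + 1L]] <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else {
      sets[[length(sets) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  if (length(sets) < 2L)
    stop("motif pattern must span at least 2 positions: ", pattern,
         call. = FALSE)
  sets
}

motif_pattern_length <- function(pattern) length(parse_motif_pattern(pattern))

# all (overlapping) 1-based match positions of a pattern on a protein
match_motif <- function(protein, pattern) {
  sets <- parse_motif_pattern(pattern)
  rx <- paste0("(?=", paste(vapply(sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = ""), ")")
  m <- gregexpr(rx, protein, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

#' Scan a polyprotein for a catalogue of conserved motifs
#'
#' Reports every occurrence of every pattern. A hit whose start equals the
#' catalogue's `expected_position` is marked position-confirmed. Short
#' promiscuous motifs (up to `short_max_len` positions, e.g. PSG, GE, APL)
#' match frequently by chance, so each short hit additionally carries a
#' `proximity_ok` flag: `TRUE` when it lies within `proximity_window` amino
#' acids of a longer motif hit of the same region, which is how such anchors
#' are read in practice; standalone short hits remain listed with
#' `proximity_ok = FALSE`.
#'
#' @param protein Amino-acid string.
#' @param catalogue Data frame with columns `name`, `region`, `pattern` and
#'   optionally `expected_position` (NA allowed); see
#'   [default_motif_catalogue()].
#' @param proximity_window Window (aa) for the short-motif proximity flag.
#' @param short_max_len Pattern length at or below which a motif is treated
#'   as promiscuous.
#' @return Data frame of hits sorted by `aa_start`: `name`, `region`,
#'   `aa_start`, `match`, `expected_position`, `position_confirmed`,
#'   `short_motif`, `proximity_ok`.
#' @export
scan_motifs <- function(protein, catalogue, proximity_window = 50L,
                        short_max_len = 3L) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  empty <- data.frame(name = character(), region = character(),
                      aa_start = integer(), match = character(),
                      expected_position = integer(),
                      position_confirmed = logical(),
                      short_motif = logical(), proximity_ok = logical())
  if (is.null(catalogue) || nrow(catalogue) == 0L) return(empty)
  if (!"expected_position" %in% names(catalogue))
    catalogue$expected_position <- NA_integer_
  rows <- lapply(seq_len(nrow(catalogue)), function(k) {
    pat <- catalogue$pattern[k]
    len <- motif_pattern_length(pat)
    pos <- match_motif(protein, pat)
    if (length(pos) == 0L) return(NULL)
    exp_pos <- as.integer(catalogue$expected_position[k])
    data.frame(name = catalogue$name[k], region = catalogue$region[k],
               aa_start = pos, match = substring(protein, pos, pos + len - 1L),
               expected_position = exp_pos,
               position_confirmed = !is.na(exp_pos) & pos == exp_pos,
               short_motif = len <= short_max_len,
               proximity_ok = NA)
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits)) return(empty)
  hits <- hits[order(hits$aa_start, hits$name), , drop = FALSE]
  anchor <- hits$aa_start[!hits$short_motif]
  hits$proximity_ok <- vapply(seq_len(nrow(hits)), function(i) {
    if (!hits$short_motif[i]) return(TRUE)
    same <- !hits$short_motif & hits$region == hits$region[i]
    any(abs(hits$aa_start[same] - hits$aa_start[i]) <= proximity_window)
  }, TRUE)
  rownames(hits) <- NULL
  hits
}

#' Verify the Hel-(VPg)x-Pro-Pol replication module order
#'
#' Checks that the replication domains appear on the polyprotein in the
#' conserved picorna-like order: every helicase hit upstream of the first VPg
#' hit, which precedes the first protease hit, which precedes the first
#' polymerase hit. Absent regions are skipped and reported. The presence of
#' the picornavirus 2A motif NPGP (region `2A` in the catalogue) is also
#' reported, since its absence is a distinguishing character.
#'
#' Standalone short-motif hits (`short_motif & !proximity_ok`) are chance
#' matches and are excluded from the verdict; the verdict is invariant to
#' the input order of the hit table.
#'
#' @param hits Hit table from [scan_motifs()] for one polyprotein.
#' @return A list: `ordered` (verdict over present regions), `present`,
#'   `absent` (region names among helicase/VPg/protease/polymerase),
#'   `npgp_found`, and `positions` (the compared positions per region).
#' @export
check_module_order <- function(hits) {
  if (all(c("short_motif", "proximity_ok") %in% names(hits)))
    hits <- hits[!(hits$short_motif & !hits$proximity_ok), , drop = FALSE]
  regions <- c("helicase", "VPg", "protease", "polymerase")
  pos <- lapply(regions, function(r) {
    p <- hits$aa_start[hits$region == r]
    if (length(p) == 0L) return(NULL)
    if (r == "helicase") max(p) else min(p)
  })
  names(pos) <- regions
  present <- regions[!vapply(pos, is.null, TRUE)]
  vals <- unlist(pos[present])
  list(ordered = length(vals) <= 1L || all(diff(vals) > 0),
       present = present,
       absent = setdiff(regions, present),
       npgp_found = any(hits$region == "2A"),
       positions = vals)
}

#' Find tandem repeats of a motif unit
#'
#' Reports maximal runs of two or more unit matches whose consecutive start
#' positions differ by the unit length (within `max_gap`). Used for the VPg
#' tandem repeat, two adjacent 11-aa copies on the replicase polyprotein.
#'
#' @param protein Amino-acid string.
#' @param unit Unit pattern (bracket notation allowed), at least 3 positions.
#' @param max_gap Allowed deviation (aa) of consecutive start spacing from
#'   the unit length (default 0: exactly adjacent copies).
#' @return A list of integer vectors, one per run, giving unit start
#'   positions; empty list when no run of >= 2 copies exists.
#' @export
find_tandem_repeat <- function(protein, unit, max_gap = 0L) {
  sets <- parse_motif_pattern(unit)
  if (length(sets) < 3L)
    stop("repeat unit must span at least 3 positions", call. = FALSE)
  u <- length(sets)
  starts <- match_motif(protein, unit)
  runs <- list()
  if (length(starts) == 0L) return(runs)
  cur <- starts[1L]
  for (s in starts[-1L]) {
    gap <- s - cur[length(cur)]
    if (gap >= u - max_gap && gap <= u + max_gap) {
      cur <- c(cur, s)
    } else {
      if (length(cur) >= 2L) runs[[length(runs) + 1L]] <- cur
      cur <- s
    }
  }
  if (length(cur) >= 2L) runs[[length(runs) + 1L]] <- cur
  runs
}

#' Build a cleavage scheme
#'
#' A cleavage scheme is an ordered list of protease cut positions (cut after
#' residue P1, i.e. between `cut_after` and `cut_after + 1`) with the mature
#' peptide names they delimit. Site dipeptide patterns in slash notation
#' (`"ESMQ/DPY"`) are optional annotations checked against the polyprotein
#' when the scheme is applied.
#'
#' @param cut_after Strictly increasing integer vector of P1 positions.
#' @param peptides Character vector of `length(cut_after) + 1` peptide names.
#' @param sites Optional character vector of site patterns (slash notation),
#'   NA allowed.
#' @param tentative Logical vector marking cuts that are provisional.
#' @return A `cleavage_scheme` object.
#' @export
cleavage_scheme <- function(cut_after, peptides, sites = NA_character_,
                            tentative = FALSE) {
  cut_after <- as.integer(cut_after)
  if (length(cut_after) == 0L || any(diff(cut_after) <= 0L) ||
      any(cut_after < 1L))
    stop("cut positions must be strictly increasing positive integers",
         call. = FALSE)
  if (length(peptides) != length(cut_after) + 1L)
    stop("need one peptide name more than cuts", call. = FALSE)
  sites <- rep_len(as.character(sites), length(cut_after))
  tentative <- rep_len(as.logical(tentative), length(cut_after))
  structure(list(cut_after = cut_after, peptides = peptides, sites = sites,
                 tentative = tentative), class = "cleavage_scheme")
}

#' Annotate mature peptides from a cleavage scheme
#'
#' Partitions the polyprotein into contiguous peptides at the scheme's cut
#' positions. When a cut carries a site pattern (e.g. `"RAFGF/SSPPD"`), the
#' residues flanking the cut are compared against it and the result reported
#' in `site_matched` (a mismatch is informative, not an error: schemes are
#' homology-based predictions).
#'
#' @param protein Amino-acid string.
#' @param scheme A [cleavage_scheme()].
#' @return Data frame: `name`, `start`, `end`, `aa_length`, `tentative`,
#'   plus per-cut `site_matched` attached as attribute `"sites"`.
#' @export
annotate_cleavage <- function(protein, scheme) {
  stopifnot(inherits(scheme, "cleavage_scheme"))
  n <- nchar(protein)
  cuts <- scheme$cut_after
  if (any(cuts >= n))
    stop("cut position at or beyond polyprotein end", call. = FALSE)
  bounds <- c(0L, cuts, n)
  tab <- data.frame(
    name = scheme$peptides,
    start = bounds[-length(bounds)] + 1L,
    end = bounds[-1L],
    tentative = c(scheme$tentative, FALSE)[seq_along(scheme$peptides)])
  tab$aa_length <- tab$end - tab$start + 1L
  tab <- tab[, c("name", "start", "end", "aa_length", "tentative")]
  site_ok <- vapply(seq_along(cuts), function(i) {
    pat <- scheme$sites[i]
    if (is.na(pat)) return(NA)
    halves <- strsplit(pat, "/", fixed = TRUE)[[1L]]
    p1 <- nchar(halves[1L])
    from <- cuts[i] - p1 + 1L
    to <- cuts[i] + nchar(halves[2L])
    if (from < 1L || to > n) return(FALSE)
    observed <- substr(protein, from, to)
    identical(observed, paste0(halves[1L], halves[2L]))
  }, NA)
  attr(tab, "sites") <- data.frame(cut_after = cuts, site = scheme$sites,
                                   site_matched = site_ok)
  stopifnot(sum(tab$aa_length) == n)
  tab
}
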