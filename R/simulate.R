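# First-order Markov sequence simulation with prescribed mononucleotide
# frequencies and dinucleotide O/E targets, plus a builder for fully
# specified artificial di-cistronic genomes whose ground-truth annotation
# is known. These are the inputs every pipeline stage is exercised on.

#' Host composition specification
#'
#' Target composition for one simulated host class: mononucleotide
#' frequencies plus dinucleotide observed/expected ratio targets (ratios not
#' listed default to 1, i.e. no bias).
#'
#' @param host Class label (e.g. `"fish"`).
#' @param mono Named numeric length 4 (`A`,`C`,`G`,`T`), summing to 1.
#' @param oe Named numeric of O/E targets for any of the 16 dinucleotides
#'   (`"CG"`, `"TA"`, ...); unlisted pairs are 1.
#' @param length Sequence length to simulate (nt).
#' @param n Class size (number of sequences).
#'
#' @details Requested ratios are projected onto the nearest jointly
#' realizable set before use: a sequence cannot, say, deplete CpG while
#' every other ratio stays exactly 1, because the dinucleotide joint
#' distribution must have the mononucleotide vector as both of its margins
#' (real genomes compensate CpG loss elsewhere). The projection
#' (iterative proportional fitting of `f(x) f(y) rho(xy)` to margins `f`)
#' yields the achievable targets stored in `$oe`; the raw request is kept in
#' `$oe_requested`. A chain built from the projected joint has stationary
#' mononucleotide distribution exactly `f`.
#'
#' @return A `host_composition_spec` with fields `host`, `mono`, `oe`
#'   (realizable O/E targets), `oe_requested`, `length`, `n`.
#' @export
host_composition_spec <- function(host, mono, oe = numeric(), length = 3000L,
                                  n = 1L) {
  stopifnot(is.character(host), length(host) == 1L)
  mono <- mono[NUC]
  if (any(is.na(mono)) || any(mono < 0) || abs(sum(mono) - 1) > 1e-9)
    stop("mono must be named A,C,G,T frequencies summing to 1", call. = FALSE)
  full_oe <- rep(1, 16L)
  names(full_oe) <- DINUC
  if (length(oe) > 0L) {
    bad <- setdiff(names(oe), DINUC)
    if (length(bad) > 0L)
      stop("unknown dinucleotide(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(oe < 0)) stop("O/E targets must be >= 0", call. = FALSE)
    full_oe[names(oe)] <- oe
  }
  stopifnot(length >= 2L, n >= 1L)
  joint <- balance_dinucleotide_joint(mono, full_oe)
  realized <- rep(0, 16L)
  names(realized) <- DINUC
  fx <- mono[substr(DINUC, 1L, 1L)] * mono[substr(DINUC, 2L, 2L)]
  pos <- fx > 0
  # joint rows = first base; row-major flattening matches DINUC order
  realized[pos] <- as.vector(t(joint))[pos] / fx[pos]
  structure(list(host = host, mono = mono, oe = realized,
                 oe_requested = full_oe, length = as.integer(length),
                 n = as.integer(n)),
            class = "host_composition_spec")
}

# Project a requested dinucleotide joint f(x) f(y) rho(xy) onto the set of
# joints with row and column margins f (Sinkhorn / iterative proportional
# fitting). Rows or columns with f = 0 are left out. Errors when a base with
# positive frequency has zero transition mass.
balance_dinucleotide_joint <- function(mono, oe, tol = 1e-13,
                                       max_iter = 10000L) {
  rho <- matrix(oe[DINUC], 4L, 4L, byrow = TRUE, dimnames = list(NUC, NUC))
  Q <- outer(mono, mono) * rho
  act <- mono > 0
  if (any(rowSums(Q)[act] == 0))
    stop("infeasible spec: zero transition mass out of ",
         paste(NUC[act & rowSums(Q) == 0], collapse = ","), call. = FALSE)
  f <- mono[act]
  Qa <- Q[act, act, drop = FALSE]
  for (i in seq_len(max_iter)) {
    rs <- rowSums(Qa)
    if (any(rs == 0))
      stop("infeasible spec: transition mass vanished during balancing",
           call. = FALSE)
    Qa <- Qa * (f / rs)
    cs <- colSums(Qa)
    if (any(cs == 0))
      stop("infeasible spec: no path into base ",
           paste(names(f)[cs == 0], collapse = ","), call. = FALSE)
    Qa <- t(t(Qa) * (f / cs))
    if (max(abs(rowSums(Qa) - f)) < tol && max(abs(colSums(Qa) - f)) < tol)
      break
  }
  Q[act, act] <- Qa
  Q[!act, ] <- 0
  Q[, !act] <- 0
  Q
}

#' Default host composition profiles
#'
#' Four synthetic host classes mirroring the structure of a picorna-like
#' control panel: class sizes (mammal 117, insect 63, plant 167, fish 5) and
#' lengths of at least 3000 nt. The profiles are invented simulation
#' parameters, chosen to reproduce the qualitative biology — CpG suppression
#' in mammal- and plant-infecting viruses, no CpG deficiency in insect and
#' fish viruses, UpA depletion throughout, AU-rich insect genomes — not
#' measurements of any real sequence set.
#'
#' @param length Sequence length per control (default 3000 nt).
#' @param sizes Named class sizes.
#' @return List of [host_composition_spec()]s.
#' @export
default_host_specs <- function(length = 3000L,
                               sizes = c(mammal = 117L, insect = 63L,
                                         plant = 167L, fish = 5L)) {
  profiles <- list(
    mammal = list(mono = c(A = 0.22, C = 0.28, G = 0.26, T = 0.24),
                  oe = c(CG = 0.45, TA = 0.60)),
    insect = list(mono = c(A = 0.31, C = 0.19, G = 0.21, T = 0.29),
                  oe = c(CG = 1.05, TA = 0.70)),
    plant = list(mono = c(A = 0.27, C = 0.24, G = 0.24, T = 0.25),
                 oe = c(CG = 0.55, TA = 0.65)),
    fish = list(mono = c(A = 0.26, C = 0.27, G = 0.21, T = 0.26),
                oe = c(CG = 1.00, TA = 0.85)))
  lapply(names(sizes), function(h) {
    if (!h %in% names(profiles)) stop("no default profile for host ", h,
                                      call. = FALSE)
    host_composition_spec(h, profiles[[h]]$mono, profiles[[h]]$oe,
                          length = length, n = sizes[[h]])
  })
}

#' First-order Markov transition matrix from a composition spec
#'
#' Rows follow `P(y | x) proportional to f(y) * rho(xy)`, with `rho` the
#' spec's realizable (margin-balanced) O/E targets, normalized per row. With
#' all `rho = 1` this is the i.i.d. chain with the target mononucleotide
#' distribution; `rho(xy) < 1` thins the `x -> y` transition. Because the
#' spec's targets are balanced at construction, the chain's stationary
#' mononucleotide distribution equals `f` exactly and its stationary
#' dinucleotide O/E ratios equal the spec's `$oe`; empirical values converge
#' there as sequence length grows (the contract is
#' convergence-in-tolerance, not finite-sample exactness).
#'
#' @param spec A [host_composition_spec()].
#' @return Row-stochastic 4 x 4 matrix (rows = preceding base A,C,G,T).
#' @export
markov_from_profile <- function(spec) {
  stopifnot(inherits(spec, "host_composition_spec"))
  Q <- balance_dinucleotide_joint(spec$mono, spec$oe)
  P <- matrix(0, 4L, 4L, dimnames = list(NUC, NUC))
  act <- spec$mono > 0
  P[act, ] <- Q[act, , drop = FALSE] / rowSums(Q)[act]
  # unreachable zero-frequency states get a formal uniform row
  if (any(!act)) P[!act, ] <- 0.25
  P
}

# stationary distribution of a row-stochastic matrix
stationary_distribution <- function(P) {
  es <- eigen(t(P))
  i <- which.min(abs(es$values - 1))
  v <- Re(es$vectors[, i])
  v <- pmax(v * sign(sum(v)), 0)
  v / sum(v)
}

#' Sample a nucleotide sequence from a Markov chain
#'
#' The first base is drawn from the chain's stationary distribution,
#' subsequent bases from the transition matrix. Deterministic given `seed`.
#'
#' @param matrix Row-stochastic 4 x 4 transition matrix (A,C,G,T order).
#' @param length Sequence length (>= 2).
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (so a caller can seed once for a whole panel).
#' @return Nucleotide string.
#' @export
sample_sequence <- function(matrix, length, seed = NULL) {
  stopifnot(is.matrix(matrix), all(dim(matrix) == 4L), length >= 2L)
  if (any(matrix < 0) || any(abs(rowSums(matrix) - 1) > 1e-8))
    stop("transition matrix must be row-stochastic", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pi0 <- stationary_distribution(matrix)
  cum <- t(apply(matrix, 1L, cumsum))
  u <- stats::runif(length)
  s <- integer(length)
  s[1L] <- 1L + sum(u[1L] > cumsum(pi0)[1:3])
  for (i in 2:length) {
    th <- cum[s[i - 1L], ]
    s[i] <- 1L + (u[i] > th[1L]) + (u[i] > th[2L]) + (u[i] > th[3L])
  }
  paste(NUC[s], collapse = "")
}

# one Markov step from state `prev` (character); returns a base
markov_step <- function(cum, prev) {
  u <- stats::runif(1L)
  th <- cum[prev, ]
  NUC[1L + (u > th[1L]) + (u > th[2L]) + (u > th[3L])]
}

# lexicographically first codon per amino acid (standard code)
first_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split_codons <- split(names(gc), unname(gc))
  vapply(split_codons, function(cs) sort(cs)[1L], "")
}

#' Di-cistronic genome specification
#'
#' Fully determines an artificial genome: the five segment lengths, motif
#' placements on each ORF polyprotein (amino-acid coordinates, position 1 is
#' the initiator Met), the background composition the non-motif sequence is
#' drawn from, and the seed.
#'
#' @param utr5,orf1_nt,igr,orf2_nt,utr3 Segment lengths (nt); ORF lengths
#'   must be multiples of 3 with at least 2 codons (start + stop).
#' @param motifs Optional data frame `orf` (1 or 2), `name`, `pattern`
#'   (bracket notation; the first alternative per position is embedded),
#'   `aa_start` (>= 2; placements must be disjoint and fit inside the ORF).
#' @param background A [host_composition_spec()] (only its composition is
#'   used) or `NULL` for a uniform i.i.d. background.
#' @param seed Integer seed.
#' @return A `genome_spec`.
#' @export
genome_spec <- function(utr5, orf1_nt, igr, orf2_nt, utr3, motifs = NULL,
                        background = NULL, seed = 1L) {
  for (v in c(utr5, igr, utr3)) stopifnot(v >= 0L)
  for (v in c(orf1_nt, orf2_nt))
    if (v < 6L || v %% 3L != 0L)
      stop("ORF lengths must be multiples of 3 with >= 2 codons",
           call. = FALSE)
  if (is.null(background))
    background <- host_composition_spec(
      "uniform", c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  if (!is.null(motifs) && nrow(motifs) > 0L) {
    stopifnot(all(c("orf", "name", "pattern", "aa_start") %in% names(motifs)))
    for (o in 1:2) {
      m <- motifs[motifs$orf == o, , drop = FALSE]
      if (nrow(m) == 0L) next
      aa_len <- c(orf1_nt, orf2_nt)[o] / 3L - 1L
      len <- vapply(m$pattern, motif_pattern_length, 1L)
      if (any(m$aa_start < 2L) || any(m$aa_start + len - 1L > aa_len))
        stop("motif placement outside ORF", o, " body", call. = FALSE)
      m <- m[order(m$aa_start), , drop = FALSE]
      ends <- m$aa_start + len[order(m$aa_start)] - 1L
      if (nrow(m) > 1L && any(m$aa_start[-1L] <= ends[-nrow(m)]))
        stop("overlapping motif placements on ORF", o, call. = FALSE)
    }
  }
  structure(list(utr5 = as.integer(utr5), orf1_nt = as.integer(orf1_nt),
                 igr = as.integer(igr), orf2_nt = as.integer(orf2_nt),
                 utr3 = as.integer(utr3), motifs = motifs,
                 background = background, seed = as.integer(seed)),
            class = "genome_spec")
}

# assemble one ORF: ATG + (aa body with embedded motifs) + TAA; non-motif
# codons drawn from the background chain, stop codons rejected
build_orf_sequence <- function(nt_len, motifs, cum, codon_of, max_tries) {
  n_codons <- nt_len / 3L
  aa_len <- n_codons - 1L
  fixed <- rep(NA_character_, aa_len)
  fixed[1L] <- "M"
  if (!is.null(motifs) && nrow(motifs) > 0L) {
    for (k in seq_len(nrow(motifs))) {
      sets <- parse_motif_pattern(motifs$pattern[k])
      res <- vapply(sets, `[[`, "", 1L)
      fixed[motifs$aa_start[k] + seq_along(res) - 1L] <- res
    }
  }
  codons <- character(n_codons)
  prev <- "A"
  for (i in seq_len(aa_len)) {
    if (!is.na(fixed[i])) {
      codons[i] <- codon_of[[fixed[i]]]
    } else {
      for (t in seq_len(max_tries)) {
        c1 <- markov_step(cum, prev)
        c2 <- markov_step(cum, c1)
        c3 <- markov_step(cum, c2)
        cod <- paste0(c1, c2, c3)
        if (!cod %in% c("TAA", "TAG", "TGA")) break
        if (t == max_tries)
          stop("retry cap exceeded while avoiding stop codons", call. = FALSE)
      }
      codons[i] <- cod
    }
    prev <- substr(codons[i], 3L, 3L)
  }
  codons[n_codons] <- "TAA"
  paste(codons, collapse = "")
}

#' Build an artificial di-cistronic genome with known ground truth
#'
#' Generates a genome realizing a [genome_spec()]: ORFs begin with ATG, end
#' with a stop, contain no internal in-frame stop; motif amino acids are
#' reverse-translated with a fixed deterministic codon choice
#' (lexicographically first codon per residue); all other sequence is drawn
#' from the background Markov chain. The assembled genome is verified by
#' running the ORF detector itself and the noncoding/interior sequence is
#' rejection-resampled until the detected architecture equals the
#' specification exactly (a chance upstream AUG in an ORF's stop-bounded
#' region would otherwise shift the detected start).
#'
#' @param spec A [genome_spec()].
#' @param max_tries Rejection-sampling retry cap (default 10000 across
#'   codon-level stop avoidance, 200 whole-genome re-draws).
#' @return List: `record` (a [genome_record()]), `architecture` (ground-truth
#'   `dicistronic_architecture`), `motif_hits` (data frame `orf`, `name`,
#'   `aa_start`), `spec`.
#' @export
build_dicistronic_genome <- function(spec, max_tries = 10000L) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  P <- markov_from_profile(spec$background)
  cum <- t(apply(P, 1L, cumsum))
  codon_of <- as.list(first_codon_table())
  glen <- spec$utr5 + spec$orf1_nt + spec$igr + spec$orf2_nt + spec$utr3
  orf1_start <- spec$utr5 + 1L
  orf1_end <- spec$utr5 + spec$orf1_nt
  orf2_start <- orf1_end + spec$igr + 1L
  orf2_end <- orf2_start + spec$orf2_nt - 1L
  m1 <- if (is.null(spec$motifs)) NULL else
    spec$motifs[spec$motifs$orf == 1L, , drop = FALSE]
  m2 <- if (is.null(spec$motifs)) NULL else
    spec$motifs[spec$motifs$orf == 2L, , drop = FALSE]
  min_aa <- min(spec$orf1_nt, spec$orf2_nt) / 3L - 1L

  for (attempt in seq_len(200L)) {
    utr5 <- if (spec$utr5 > 0L) sample_sequence(P, max(spec$utr5, 2L)) else ""
    utr5 <- substr(utr5, 1L, spec$utr5)
    orf1 <- build_orf_sequence(spec$orf1_nt, m1, cum, codon_of, max_tries)
    igr <- if (spec$igr > 0L) substr(sample_sequence(P, max(spec$igr, 2L)),
                                     1L, spec$igr) else ""
    orf2 <- build_orf_sequence(spec$orf2_nt, m2, cum, codon_of, max_tries)
    utr3 <- if (spec$utr3 > 0L) substr(sample_sequence(P, max(spec$utr3, 2L)),
                                       1L, spec$utr3) else ""
    genome <- paste0(utr5, orf1, igr, orf2, utr3)
    stopifnot(nchar(genome) == glen)
    ok <- tryCatch({
      arch <- detect_dicistronic(find_orfs(genome, min_aa = min_aa),
                                 genome_length = glen)
      arch$orf1$start == orf1_start && arch$orf1$end == orf1_end &&
        arch$orf2$start == orf2_start && arch$orf2$end == orf2_end
    }, error = function(e) FALSE)
    if (ok) {
      rec <- genome_record(sprintf("synthetic_dicistronic_seed%d", spec$seed),
                           genome, description = "builder-generated genome")
      truth <- structure(list(
        genome_length = glen,
        utr5 = span(1L, spec$utr5),
        orf1 = list(start = orf1_start, end = orf1_end,
                    frame = ((orf1_start - 1L) %% 3L) + 1L, strand = "+",
                    nt_length = spec$orf1_nt,
                    aa_length = spec$orf1_nt / 3L - 1L),
        igr = span(orf1_end + 1L, orf2_start - 1L),
        orf2 = list(start = orf2_start, end = orf2_end,
                    frame = ((orf2_start - 1L) %% 3L) + 1L, strand = "+",
                    nt_length = spec$orf2_nt,
                    aa_length = spec$orf2_nt / 3L - 1L),
        utr3 = span(orf2_end + 1L, glen),
        reverse_large_orf = FALSE), class = "dicistronic_architecture")
      hits <- if (is.null(spec$motifs)) {
        data.frame(orf = integer(), name = character(), aa_start = integer())
      } else {
        spec$motifs[, c("orf", "name", "aa_start")]
      }
      return(list(record = rec, architecture = truth, motif_hits = hits,
                  spec = spec))
    }
  }
  stop("retry cap exceeded: could not realize the genome spec", call. = FALSE)
}

#' Generate a host-labeled control panel
#'
#' Simulates, for each composition spec, `n` sequences of the given length
#' from its Markov chain. The default panel mirrors the structure of a
#' picorna-like host-control set: 352 sequences in classes mammal (117),
#' insect (63), plant (167) and fish (5), each 3000 nt or longer.
#'
#' @param specs List of [host_composition_spec()]s (>= 2), default
#'   [default_host_specs()].
#' @param seed Integer seed (one seeding for the whole panel).
#' @param out_fasta,out_labels Optional output paths (FASTA; TSV with columns
#'   `id`, `host`).
#' @return List: `records` (list of [genome_record()]s) and `labels`
#'   (data frame `id`, `host`).
#' @export
make_control_panel <- function(specs = default_host_specs(), seed = 1L,
                               out_fasta = NULL, out_labels = NULL) {
  if (length(specs) < 2L) stop("need at least 2 specs", call. = FALSE)
  set.seed(seed)
  records <- list()
  labels <- NULL
  for (spec in specs) {
    stopifnot(inherits(spec, "host_composition_spec"))
    if (spec$n < 1L) stop("class size must be >= 1", call. = FALSE)
    P <- markov_from_profile(spec)
    for (i in seq_len(spec$n)) {
      id <- sprintf("%s_%03d", spec$host, i)
      records[[id]] <- genome_record(id, sample_sequence(P, spec$length),
                                     description = paste("host", spec$host))
      labels <- rbind(labels, data.frame(id = id, host = spec$host))
    }
  }
  if (!is.null(out_fasta)) write_fasta(records, out_fasta)
  if (!is.null(out_labels))
    utils::write.table(labels, out_labels, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(records = records, labels = labels)
}

#' Reference-genome-like synthetic specification
#'
#' A [genome_spec()] mimicking the published di-cistronic reference layout:
#' segments 827 / 5451 / 118 / 3030 / 139 nt (genome 9565 nt; ORF1 at
#' 828..6278 encoding 1816 aa, ORF2 at 6397..9426 encoding 1009 aa), with
#' every catalogued replicase motif embedded at its published amino-acid
#' anchor, the two VPg repeat copies at 1116/1127, the 3C/3D junction Q/T at
#' 1317/1318, the capsid cleavage sites RAFGF/SSPPD (339/340) and ESMQ/DPY
#' (665/666), the tentative VP2/VP4 junction Q/T at 262/263, and the capsid
#' alignment motifs at invented positions (no positions were published for
#' them). Background composition is the fish-like default profile.
#'
#' @param seed Integer seed.
#' @return A `genome_spec`.
#' @export
halv_genome_spec <- function(seed = 1L) {
  cat1 <- default_motif_catalogue("orf1")
  cat1 <- cat1[!is.na(cat1$expected_position) & cat1$name != "VPg-unit", ]
  orf1 <- data.frame(orf = 1L, name = cat1$name, pattern = cat1$pattern,
                     aa_start = cat1$expected_position)
  orf1 <- rbind(orf1,
                data.frame(orf = 1L,
                           name = c("VPg-copy1", "VPg-copy2", "3C/3D-site"),
                           pattern = c("QCAIGLFVKDQ", "SCLMNKHSLDQ", "QT"),
                           aa_start = c(1116L, 1127L, 1317L)))
  orf2 <- data.frame(
    orf = 2L,
    name = c("GRLI", "LRIPF", "VP2/VP4-site", "RAFGF/SSPPD-site", "DEM",
             "YWAGSI", "VATPFHAGRLVLAYVP", "GE", "VWD", "DDFSF",
             "ESMQ/DPY-site"),
    pattern = c("GRLI", "LRIPF", "QT", "RAFGFSSPPD", "DEM", "YWAGSI",
                "VATPFHAGRLVLAYVP", "GE", "VWD", "DDFSF", "ESMQDPY"),
    aa_start = c(50L, 120L, 262L, 335L, 400L, 450L, 500L, 518L, 550L, 600L,
                 662L))
  fish <- default_host_specs()[[4L]]
  genome_spec(utr5 = 827L, orf1_nt = 5451L, igr = 118L, orf2_nt = 3030L,
              utr3 = 139L, motifs = rbind(orf1, orf2), background = fish,
              seed = seed)
}
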