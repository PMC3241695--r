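# Independent brute-force oracles and small fixture generators. These stay
# deliberately naive (position-by-position loops) so they cannot share a bug
# with the vectorized implementations they check.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n,
               replace = TRUE), collapse = "")
}

# every ATG extended to its first in-frame stop; then the 5'-most start per
# stop is kept -- the defining ORF rule, derived independently
oracle_orfs_forward <- function(seq, min_aa) {
  L <- nchar(seq)
  hits <- list()
  for (s in seq_len(max(L - 5L, 0L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    p <- s + 3L
    while (p + 2L <= L) {
      cod <- substr(seq, p, p + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        hits[[length(hits) + 1L]] <- c(start = s, end = p + 2L)
        break
      }
      p <- p + 3L
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), end = integer()))
  m <- as.data.frame(do.call(rbind, hits))
  m <- do.call(rbind, lapply(split(m, m$end), function(g)
    g[which.min(g$start), ]))
  m$aa <- (m$end - m$start + 1L) / 3L - 1L
  m <- m[m$aa >= min_aa, c("start", "end")]
  m[order(m$start), , drop = FALSE]
}

# literal character counting of mono/dinucleotide composition
oracle_composition <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  nuc <- c("A", "C", "G", "T")
  keep <- ch %in% nuc
  mono_counts <- vapply(nuc, function(b) sum(ch == b), 1L)
  mono <- mono_counts / sum(mono_counts)
  pairs <- paste0(ch[-length(ch)], ch[-1L])
  valid <- keep[-length(ch)] & keep[-1L]
  pairs <- pairs[valid]
  dn <- sort(as.vector(outer(nuc, nuc, paste0)))
  di_counts <- vapply(dn, function(d) sum(pairs == d), 1L)
  dinuc <- di_counts / sum(di_counts)
  expected <- mono[substr(dn, 1L, 1L)] * mono[substr(dn, 2L, 2L)]
  oe <- ifelse(expected > 0, dinuc / expected, NA_real_)
  list(mono = mono, dinuc = stats::setNames(dinuc, dn),
       oe = stats::setNames(oe, dn))
}

# positionwise alternative-set matcher
oracle_match_motif <- function(protein, pattern) {
  sets <- parse_motif_pattern(pattern)
  n <- nchar(protein)
  k <- length(sets)
  out <- integer()
  for (s in seq_len(max(n - k + 1L, 0L))) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!substr(protein, s + j - 1L, s + j - 1L) %in% sets[[j]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) out <- c(out, s)
  }
  out
}

# dense generalized-eigen CDA oracle: eigen of solve(W + eps I) %*% B
oracle_cda <- function(x, labels, ridge = 1e-6) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  p <- ncol(x)
  centroids <- t(sapply(classes, function(cl)
    colMeans(x[labels == cl, , drop = FALSE])))
  grand <- colMeans(x)
  W <- matrix(0, p, p)
  for (cl in classes) {
    xc <- sweep(x[labels == cl, , drop = FALSE], 2L,
                centroids[classes == cl, ])
    W <- W + t(xc) %*% xc
  }
  counts <- sapply(classes, function(cl) sum(labels == cl))
  dm <- sweep(centroids, 2L, grand)
  B <- t(dm * counts) %*% dm
  eps <- ridge * sum(diag(W)) / p
  es <- eigen(solve(W + diag(eps, p)) %*% B)
  list(values = Re(es$values), vectors = Re(es$vectors), W = W, B = B)
}

# small well-separated 4-class gaussian problem for discriminant tests
random_class_problem <- function(n_per = 15L, p = 6L, k = 4L, sep = 4) {
  centers <- matrix(stats::rnorm(k * p, sd = sep), k, p)
  x <- do.call(rbind, lapply(seq_len(k), function(j)
    sweep(matrix(stats::rnorm(n_per * p), n_per, p), 2L, centers[j, ], `+`)))
  list(x = x, labels = rep(letters[seq_len(k)], each = n_per))
}

halv_arch_fixture <- function() {
  orfs <- data.frame(start = c(828L, 6397L), end = c(6278L, 9426L),
                     frame = c(3L, 1L), strand = "+",
                     nt_length = c(5451L, 3030L),
                     aa_length = c(1816L, 1009L))
  detect_dicistronic(orfs, genome_length = 9565L)
}
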