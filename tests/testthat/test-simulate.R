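test_that("an unbiased spec gives the i.i.d. chain with rows equal to mono", {
  spec <- host_composition_spec("x", c(A = 0.3, C = 0.2, G = 0.2, T = 0.3))
  P <- markov_from_profile(spec)
  expect_equal(P, matrix(rep(spec$mono, each = 4), 4, 4,
                         dimnames = list(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"))),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(P)), rep(1, 4))
})

test_that("a CpG-depleted spec thins the C-to-G transition", {
  spec <- host_composition_spec("x", c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                                oe = c(CG = 0.4))
  P <- markov_from_profile(spec)
  expect_lt(P["C", "G"], 0.25)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  # the spec records the achievable (margin-consistent) target
  expect_lt(spec$oe[["CG"]], 1)
  expect_equal(spec$oe_requested[["CG"]], 0.4)
})

test_that("infeasible composition specs are rejected", {
  oe_zero <- setNames(rep(0, 4), c("CA", "CC", "CG", "CT"))
  expect_error(host_composition_spec(
    "x", c(A = 0.25, C = 0.25, G = 0.25, T = 0.25), oe = oe_zero),
    "infeasible|transition mass")
  expect_error(host_composition_spec("x", c(A = 0.5, C = 0.5, G = 0, T = 0.2)),
               "summing to 1")
})

test_that("the chain's stationary mononucleotide distribution equals the spec", {
  for (spec in default_host_specs()) {
    P <- markov_from_profile(spec)
    pi0 <- dicistro:::stationary_distribution(P)
    expect_equal(unname(pi0), unname(spec$mono), tolerance = 1e-9)
  }
})

test_that("sequence sampling is deterministic and respects absorbing chains", {
  P <- diag(4)
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  s <- sample_sequence(P, 50, seed = 1)
  expect_equal(length(unique(strsplit(s, "")[[1L]])), 1L)

  spec <- host_composition_spec("x", c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  Q <- markov_from_profile(spec)
  expect_identical(sample_sequence(Q, 5000, seed = 42),
                   sample_sequence(Q, 5000, seed = 42))
  expect_false(identical(sample_sequence(Q, 5000, seed = 42),
                         sample_sequence(Q, 5000, seed = 43)))
  expect_error(sample_sequence(matrix(1, 4, 4), 10), "row-stochastic")
})

test_that("uniform i.i.d. sampling hits 25 percent per base at L = 100k", {
  spec <- host_composition_spec("x", c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  s <- sample_sequence(markov_from_profile(spec), 100000, seed = 7)
  p <- composition_profile(s)
  expect_true(all(abs(p$mono - 0.25) <= 0.01))
})

test_that("empirical composition converges to spec targets with length", {
  spec <- default_host_specs()[[1L]]  # mammal: strongest biases
  P <- markov_from_profile(spec)
  tolerances <- c(`3000` = 0.08, `10000` = 0.05, `100000` = 0.02)
  for (L in c(3000L, 10000L, 100000L)) {
    s <- sample_sequence(P, L, seed = 20260200 + L %% 997)
    pr <- composition_profile(s)
    tol <- tolerances[[as.character(L)]]
    expect_lte(mean(abs(pr$oe - spec$oe)), tol)
    expect_lte(max(abs(pr$mono - spec$mono)), tol)
  }
})

test_that("the genome builder realizes minimal and reference layouts", {
  tiny <- build_dicistronic_genome(genome_spec(0, 9, 0, 9, 0, seed = 5))
  expect_equal(nchar(tiny$record$sequence), 18L)
  expect_equal(tiny$architecture$utr5$length, 0L)
  expect_equal(tiny$architecture$orf1$start, 1L)
  expect_equal(tiny$architecture$orf2$end, 18L)

  g <- build_dicistronic_genome(halv_genome_spec(seed = 2))
  expect_equal(nchar(g$record$sequence), 9565L)
  expect_equal(g$architecture$orf1$start, 828L)
  expect_equal(g$architecture$orf1$end, 6278L)
  expect_equal(g$architecture$orf2$start, 6397L)
  expect_equal(g$architecture$orf2$end, 9426L)
  expect_equal(g$architecture$igr$length, 118L)
  # ORFs translate cleanly at the designed lengths
  expect_equal(nchar(translate_orf(g$record, g$architecture$orf1)), 1816L)
  expect_equal(nchar(translate_orf(g$record, g$architecture$orf2)), 1009L)
})

test_that("builder output is byte-identical for identical spec and seed", {
  a <- build_dicistronic_genome(genome_spec(100, 300, 50, 300, 80, seed = 9))
  b <- build_dicistronic_genome(genome_spec(100, 300, 50, 300, 80, seed = 9))
  expect_identical(a$record$sequence, b$record$sequence)
  c <- build_dicistronic_genome(genome_spec(100, 300, 50, 300, 80, seed = 10))
  expect_false(identical(a$record$sequence, c$record$sequence))
})

test_that("invalid genome specs are rejected up front", {
  expect_error(genome_spec(10, 8, 5, 9, 5), "multiples of 3")
  expect_error(genome_spec(10, 3, 5, 9, 5), "2 codons")
  m <- data.frame(orf = 1L, name = "x", pattern = "WWWWW", aa_start = 8L)
  expect_error(genome_spec(0, 27, 0, 9, 0, motifs = m), "outside")
  m2 <- data.frame(orf = 1L, name = c("x", "y"),
                   pattern = c("WWW", "HHH"), aa_start = c(5L, 6L))
  expect_error(genome_spec(0, 60, 0, 9, 0, motifs = m2), "overlap")
})

test_that("detection recovers the builder's architecture on random specs", {
  set.seed(601)
  for (i in 1:12) {
    spec <- genome_spec(utr5 = sample(0:250, 1),
                        orf1_nt = 3L * sample(110:500, 1),
                        igr = sample(0:150, 1),
                        orf2_nt = 3L * sample(110:300, 1),
                        utr3 = sample(0:200, 1), seed = 7000 + i)
    g <- build_dicistronic_genome(spec)
    min_aa <- min(spec$orf1_nt, spec$orf2_nt) / 3L - 1L
    arch <- detect_dicistronic(find_orfs(g$record, min_aa = min_aa),
                               nchar(g$record$sequence))
    expect_equal(arch$orf1$start, g$architecture$orf1$start)
    expect_equal(arch$orf1$end, g$architecture$orf1$end)
    expect_equal(arch$orf2$start, g$architecture$orf2$start)
    expect_equal(arch$orf2$end, g$architecture$orf2$end)
    expect_equal(arch$utr5$length, spec$utr5)
    expect_equal(arch$igr$length, spec$igr)
    expect_equal(arch$utr3$length, spec$utr3)
  }
})

test_that("control panels have the requested class structure on disk", {
  specs <- list(
    host_composition_spec("a", c(A = 0.4, C = 0.2, G = 0.2, T = 0.2),
                          length = 500L, n = 4L),
    host_composition_spec("b", c(A = 0.2, C = 0.3, G = 0.3, T = 0.2),
                          length = 500L, n = 6L))
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  panel <- make_control_panel(specs, seed = 3, out_fasta = fa,
                              out_labels = tsv)
  expect_equal(length(panel$records), 10L)
  expect_equal(table(panel$labels$host), table(c(rep("a", 4), rep("b", 6))))
  back <- read_fasta(fa)
  expect_equal(names(back), panel$labels$id)
  lab <- read.delim(tsv)
  expect_equal(lab$host, panel$labels$host)
  expect_error(make_control_panel(specs[1]), "at least 2")
})

test_that("identical class profiles give chance-level concordance", {
  spec <- host_composition_spec("x", c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                                length = 800L, n = 25L)
  spec2 <- spec
  spec2$host <- "y"
  panel <- make_control_panel(list(spec, spec2), seed = 13)
  x <- feature_matrix(panel$records)
  conc <- concordance(x, panel$labels$host, scheme = "loo")
  expect_gt(conc, 0.2)
  expect_lt(conc, 0.8)
})
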