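test_that("codon map places starts and stops in the right frames", {
  cm <- codon_map("ATGTAA")
  expect_equal(cm$frame1$starts, 1L)
  expect_equal(cm$frame1$stops, 4L)
  expect_equal(cm$frame2$starts, integer())
  expect_equal(cm$frame3$stops, integer())

  # hand enumeration: AATGA has ATG at 2 (frame 2) and TGA at 3 (frame 3)
  cm2 <- codon_map("AATGA")
  expect_equal(cm2$frame2$starts, 2L)
  expect_equal(cm2$frame3$stops, 3L)
  expect_equal(cm2$frame1$starts, integer())
})

test_that("codon map equals a sliding-window brute force on a random 3000-mer", {
  set.seed(201)
  seq <- random_dna(3000)
  cm <- codon_map(seq)
  for (p in seq_len(nchar(seq) - 2L)) {
    cod <- substr(seq, p, p + 2L)
    f <- ((p - 1L) %% 3L) + 1L
    if (cod == "ATG") expect_true(p %in% cm[[f]]$starts)
    if (cod %in% c("TAA", "TAG", "TGA")) expect_true(p %in% cm[[f]]$stops)
  }
  expect_equal(length(cm$frame1$starts) + length(cm$frame2$starts) +
                 length(cm$frame3$starts),
               sum(substring(seq, 1:2998, 3:3000) == "ATG"))
})

test_that("ORF finding follows the 5'-most-AUG rule and handles edge cases", {
  orfs <- find_orfs("ATGAAATAG", min_aa = 1L)
  expect_equal(nrow(orfs[orfs$strand == "+", ]), 1L)
  fwd <- orfs[orfs$strand == "+", ]
  expect_equal(fwd$start, 1L)
  expect_equal(fwd$end, 9L)
  expect_equal(fwd$aa_length, 2L)

  expect_equal(nrow(find_orfs("AAACCCGGGTTTAAACCC", min_aa = 1L,
                              strands = "forward")), 0L)

  # 5'-most AUG: both ATGs share a stop; only the first opens the ORF
  two <- find_orfs("ATGATGAAATAG", min_aa = 1L, strands = "forward")
  expect_equal(two$start, 1L)
  all_s <- find_orfs("ATGATGAAATAG", min_aa = 1L, strands = "forward",
                     all_starts = TRUE)
  expect_equal(sort(all_s$start), c(1L, 4L))
})

test_that("ORF finder equals the brute-force oracle on 200 random sequences", {
  set.seed(202)
  for (i in 1:200) {
    seq <- random_dna(sample(500:1500, 1))
    min_aa <- sample(c(1L, 5L, 20L), 1)
    got <- find_orfs(seq, min_aa = min_aa, strands = "forward")
    want <- oracle_orfs_forward(seq, min_aa)
    got <- got[order(got$start), ]
    expect_equal(got$start, want$start, info = paste("iter", i))
    expect_equal(got$end, want$end, info = paste("iter", i))
    # every reported ORF: length divisible by 3, clean translation
    for (r in seq_len(nrow(got))) {
      expect_equal(got$nt_length[r] %% 3L, 0L)
      aa <- translate_orf(seq, got[r, ])
      expect_equal(nchar(aa), got$aa_length[r])
      expect_false(grepl("*", aa, fixed = TRUE))
    }
  }
})

test_that("reverse-strand ORFs are reported in forward coordinates", {
  # ATGAAATAG on the minus strand
  seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAATAG")))
  orfs <- find_orfs(seq, min_aa = 1L)
  rev <- orfs[orfs$strand == "-", ]
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$start, 1L)
  expect_equal(rev$end, 9L)
  expect_equal(translate_orf(seq, rev), "MK")
})

test_that("translation applies the standard code and flags internal stops", {
  expect_identical(translate_orf("ATGAAATAG",
                                 list(start = 1L, end = 9L, strand = "+")),
                   "MK")
  expect_error(translate_orf("ATGTAAAAATAG",
                             list(start = 1L, end = 12L, strand = "+")),
               "internal stop")
  expect_error(translate_orf("ATGAAATAG",
                             list(start = 1L, end = 8L, strand = "+")),
               "divisible")
  expect_error(translate_orf("ATGAAAAAA",
                             list(start = 1L, end = 9L, strand = "+")),
               "stop codon")
})

test_that("di-cistronic detection recovers the reference architecture", {
  arch <- halv_arch_fixture()
  expect_equal(arch$utr5$start, 1L)
  expect_equal(arch$utr5$end, 827L)
  expect_equal(arch$igr$start, 6279L)
  expect_equal(arch$igr$end, 6396L)
  expect_equal(arch$igr$length, 118L)
  expect_equal(arch$utr3$start, 9427L)
  expect_equal(arch$utr3$end, 9565L)
  expect_equal(arch$utr3$length, 139L)
  expect_false(arch$reverse_large_orf)
})

test_that("detection errors on single-ORF and unresolvable-overlap inputs", {
  one <- data.frame(start = 10L, end = 309L, frame = 1L, strand = "+",
                    nt_length = 300L, aa_length = 99L)
  expect_error(detect_dicistronic(one, 400L), "fewer than two")

  overlapping <- data.frame(start = c(1L, 4L), end = c(600L, 597L),
                            frame = c(1L, 1L), strand = "+",
                            nt_length = c(600L, 594L),
                            aa_length = c(199L, 197L))
  expect_error(detect_dicistronic(overlapping, 700L), "ambiguous")
})

test_that("large reverse-strand ORFs raise the flag, not an error", {
  orfs <- data.frame(start = c(1L, 400L, 50L), end = c(300L, 702L, 450L),
                     frame = 1L, strand = c("+", "+", "-"),
                     nt_length = c(300L, 303L, 401L),
                     aa_length = c(99L, 100L, 133L))
  arch <- detect_dicistronic(orfs, 800L, large_orf_min_nt = 300L)
  expect_true(arch$reverse_large_orf)
  arch2 <- detect_dicistronic(orfs, 800L, large_orf_min_nt = 500L)
  expect_false(arch2$reverse_large_orf)
})

test_that("segment accounting reproduces the published coding fraction", {
  rep <- segment_report(halv_arch_fixture())
  expect_equal(rep$coding_fraction, 88.7)
  expect_equal(rep$noncoding_fraction, 11.3)
  expect_equal(rep$orf1_aa, 1816L)
  expect_equal(rep$orf2_aa, 1009L)
  expect_equal(rep$utr5_nt + rep$orf1_nt + rep$igr_nt + rep$orf2_nt +
                 rep$utr3_nt, rep$genome_length)
})

test_that("a fully coding two-ORF genome reports 100 percent coding", {
  orfs <- data.frame(start = c(1L, 10L), end = c(9L, 18L), frame = 1L,
                     strand = "+", nt_length = 9L, aa_length = 2L)
  rep <- segment_report(detect_dicistronic(orfs, 18L))
  expect_equal(rep$coding_fraction, 100)
  expect_equal(rep$noncoding_fraction, 0)
})

test_that("coding and noncoding fractions sum to 100 over random layouts", {
  set.seed(203)
  for (i in 1:25) {
    u5 <- sample(0:500, 1); o1 <- 3L * sample(10:300, 1)
    ig <- sample(0:200, 1); o2 <- 3L * sample(10:200, 1)
    u3 <- sample(0:300, 1)
    glen <- u5 + o1 + ig + o2 + u3
    orfs <- data.frame(start = c(u5 + 1L, u5 + o1 + ig + 1L),
                       end = c(u5 + o1, u5 + o1 + ig + o2),
                       frame = 1L, strand = "+", nt_length = c(o1, o2),
                       aa_length = c(o1, o2) / 3L - 1L)
    rep <- segment_report(detect_dicistronic(orfs, glen))
    expect_lte(abs(rep$coding_fraction + rep$noncoding_fraction - 100), 0.1)
  }
})

test_that("in-silico PCR recovers designed amplicons", {
  set.seed(204)
  seq <- random_dna(9565)
  fwd <- substr(seq, 3265, 3284)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seq, 3695, 3714))))
  amp <- insilico_amplicon(seq, fwd, rev)
  expect_true(amp$found)
  expect_equal(amp$amplicon$length, 450L)
  expect_equal(amp$amplicon$start, 3265L)
  expect_equal(amp$amplicon$end, 3714L)
})

test_that("absent primers give a no-amplicon result, not an error", {
  set.seed(205)
  seq <- random_dna(500)
  amp <- insilico_amplicon(seq, substr(seq, 10, 29),
                           "CCCCCCCCCCCCCCCCCCCC")
  expect_false(amp$found)
  expect_null(amp$amplicon)
  expect_error(insilico_amplicon(seq, "ATG", "CCCCCCCCCC"), "10 nt")
})

test_that("degenerate IUPAC primer bases match their expansion set", {
  template <- paste0("TTTTTTTTTT", "ACGTACGTAG", "CCGGCCGGCCAATTGG",
                     "CATCATCATC", "TTTTTTTTTT")
  # R matches A/G, V matches A/C/G
  amp <- insilico_amplicon(template, "ACGTACGTRG",
                           as.character(Biostrings::reverseComplement(
                             Biostrings::DNAString("CATCATCATV"))))
  expect_true(amp$found)
  expect_equal(amp$amplicon$start, 11L)
})

test_that("multiple compatible sites are flagged ambiguous", {
  core <- "GGGGGGGGGGGGGGGGGGGG"
  site_f <- "ACACACACAC"
  template <- paste0(site_f, core, site_f, core, "TATATATATA")
  rev_primer <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TATATATATA")))
  amp <- insilico_amplicon(template, site_f, rev_primer)
  expect_true(amp$ambiguous)
  expect_equal(nrow(amp$products), 2L)
  # principal product: 5'-most sense to 3'-most antisense
  expect_equal(amp$amplicon$start, 1L)
  expect_equal(amp$amplicon$end, nchar(template))
})
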