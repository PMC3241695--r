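#!/usr/bin/env Rscript
# Step 2 — genome characterization.
#
# Annotates the synthetic genome from step 1: ORF enumeration, di-cistronic
# architecture, segment accounting (coding fraction), conserved-motif scan
# with the replication-module order verdict, VPg tandem repeat, cleavage of
# both polyproteins into mature peptides, and in-silico placement of the
# diagnostic primer pairs. Expects analysis/01_simulate.R to have run.

suppressPackageStartupMessages(library(dicistro))

stopifnot(file.exists("results/synthetic_genome.fasta"))

run_characterize(list(fasta = "results/synthetic_genome.fasta",
                      out_dir = "results/characterize",
                      orf1_scheme = "halv-orf1",
                      orf2_scheme = "halv-orf2"))

seg <- read.delim("results/characterize/segments.tsv")
message("segments (nt): 5'UTR ", seg$utr5_nt, ", ORF1 ", seg$orf1_nt,
        ", IGR ", seg$igr_nt, ", ORF2 ", seg$orf2_nt, ", 3'UTR ",
        seg$utr3_nt)
message("coding fraction: ", seg$coding_fraction, "% (noncoding ",
        seg$noncoding_fraction, "%); GC ", seg$gc_percent, "%")

ord <- read.delim("results/characterize/module_order.tsv")
message("Hel-(VPg)x-Pro-Pol order: ", ord$ordered,
        "; picornavirus 2A motif NPGP found: ", ord$npgp_found)

# VPg tandem repeat on the replicase polyprotein
rec <- read_fasta("results/synthetic_genome.fasta")[[1L]]
arch <- detect_dicistronic(find_orfs(rec), nchar(rec$sequence))
p1 <- translate_orf(rec, arch$orf1)
cat1 <- default_motif_catalogue("orf1")
runs <- find_tandem_repeat(p1, cat1$pattern[cat1$name == "VPg-unit"])
message("VPg repeat unit starts: ", paste(runs[[1L]], collapse = ", "))

# diagnostic (450 nt) and screening (~1000 nt) primer pairs, lifted from the
# published genome coordinates
rc <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))
s <- rec$sequence
amps <- rbind(
  data.frame(assay = "diagnostic",
             t(unlist(insilico_amplicon(rec, substr(s, 3265, 3284),
                                        rc(substr(s, 3695, 3714)))$amplicon))),
  data.frame(assay = "screening",
             t(unlist(insilico_amplicon(rec, substr(s, 5458, 5475),
                                        rc(substr(s, 6451, 6468)))$amplicon))))
write.table(amps, "results/amplicons.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("amplicons: diagnostic ", amps$length[1L], " nt, screening ",
        amps$length[2L], " nt")
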