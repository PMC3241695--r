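# Shipped motif catalogue and cleavage-scheme presets for the reference
# di-cistronic genome (HalV-type): ORF1 replicase motifs with their published
# amino-acid anchor positions, ORF2 capsid motifs (no anchor positions were
# published for these), and the homology-predicted protease cleavage schemes.

#' Default conserved-motif catalogue
#'
#' ORF1 carries the picorna-like replication motifs with known amino-acid
#' anchor positions on the 1816-aa polyprotein: 2C-like helicase (GKS, YDDF,
#' KATLSEK at 522/575/608), 3C-like protease (GDCG, ILGIHGA at 1253/1270) and
#' 3D-like RNA-dependent RNA polymerase (KDERR, VGINPDSAEW, LGDY, PSG, YGDD,
#' FLKR, APL at 1488..1741). The VPg unit is the 11-aa tandem-repeat motif
#' between helicase and protease; its pattern is the per-position union of
#' the two printed copy readings (the published notation is ambiguous about
#' the exact per-copy sequence, so no single reading is assumed). The
#' picornavirus 2A motif NPGP is included so its absence can be reported.
#' ORF2 capsid motifs (GRLI, LRIPF, FGFSSP, DEM, YWAGSI, VATPFHAGRLVLAYVP,
#' VWD, GE, DDFSF) have no published positions and ship with
#' `expected_position = NA`.
#'
#' @param orf `"orf1"`, `"orf2"`, or `"both"` (default).
#' @return Data frame with columns `name`, `region`, `pattern`,
#'   `expected_position`, `orf`.
#' @export
default_motif_catalogue <- function(orf = c("both", "orf1", "orf2")) {
  orf <- match.arg(orf)
  orf1 <- data.frame(
    name = c("GKS", "YDDF", "KATLSEK",
             "VPg-unit",
             "GDCG", "ILGIHGA",
             "KDERR", "VGINPDSAEW", "LGDY", "PSG", "YGDD", "FLKR", "APL",
             "NPGP"),
    region = c(rep("helicase", 3L), "VPg", rep("protease", 2L),
               rep("polymerase", 7L), "2A"),
    pattern = c("GKS", "YDDF", "KATLSEK",
                "[QHS]C[AL][IM][GN][LK][FH][VS][KL]D[QSL]",
                "GDCG", "ILGIHGA",
                "KDERR", "VGINPDSAEW", "LGDY", "PSG", "YGDD", "FLKR", "APL",
                "NPGP"),
    expected_position = c(522L, 575L, 608L, 1116L, 1253L, 1270L,
                          1488L, 1543L, 1590L, 1634L, 1676L, 1727L, 1741L,
                          NA_integer_),
    orf = 1L)
  orf2 <- data.frame(
    name = c("GRLI", "LRIPF", "FGFSSP", "DEM", "YWAGSI",
             "VATPFHAGRLVLAYVP", "VWD", "GE", "DDFSF"),
    region = "capsid",
    pattern = c("GRLI", "LRIPF", "FGFSSP", "DEM", "YWAGSI",
                "VATPFHAGRLVLAYVP", "VWD", "GE", "DDFSF"),
    expected_position = NA_integer_,
    orf = 2L)
  switch(orf, orf1 = orf1, orf2 = orf2, both = rbind(orf1, orf2))
}

#' Named cleavage-scheme presets
#'
#' `"halv-orf1"`: the single predicted 3C/3D junction Q/T after residue 1317
#' of the 1816-aa replicase polyprotein. `"halv-orf2"`: the capsid
#' polyprotein cuts VP2/VP4 (Q/T after 262, tentative — stated only as
#' "probably between aa260 or aa280"), VP4/VP3 (RAFGF/SSPPD after 339) and
#' VP3/VP1 (ESMQ/DPY after 665). `"halv-orf2-major"`: only the two
#' confidently predicted capsid cuts, leaving VP2+VP4 unsplit.
#'
#' @param name Preset name.
#' @return A [cleavage_scheme()].
#' @export
cleavage_preset <- function(name = c("halv-orf1", "halv-orf2",
                                     "halv-orf2-major")) {
  name <- match.arg(name)
  switch(name,
    "halv-orf1" = cleavage_scheme(
      cut_after = 1317L,
      peptides = c("Hel-VPg-3C", "3D"),
      sites = "Q/T"),
    "halv-orf2" = cleavage_scheme(
      cut_after = c(262L, 339L, 665L),
      peptides = c("VP2", "VP4", "VP3", "VP1"),
      sites = c("Q/T", "RAFGF/SSPPD", "ESMQ/DPY"),
      tentative = c(TRUE, FALSE, FALSE)),
    "halv-orf2-major" = cleavage_scheme(
      cut_after = c(339L, 665L),
      peptides = c("VP2+VP4", "VP3", "VP1"),
      sites = c("RAFGF/SSPPD", "ESMQ/DPY")))
}

#' Read / write a motif catalogue as TSV
#'
#' Columns: `name`, `region`, `pattern`, `expected_position`, `orf`.
#'
#' @param path TSV path.
#' @return For `read_motif_catalogue`, the catalogue data frame.
#' @export
read_motif_catalogue <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "region", "pattern")
  if (!all(need %in% names(tab)))
    stop("catalogue TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"expected_position" %in% names(tab))
    tab$expected_position <- NA_integer_
  tab
}

#' @rdname read_motif_catalogue
#' @param catalogue Catalogue data frame.
#' @export
write_motif_catalogue <- function(catalogue, path) {
  utils::write.table(catalogue, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
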