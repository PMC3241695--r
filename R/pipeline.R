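# One-configuration orchestration of the two workflows: genome
# characterization (annotate -> motif scan -> composition) and NCA host
# prediction (panel -> discriminant model -> query classification).
# Configurations are plain lists, readable from a YAML file; every report
# number is recomputable from the TSV intermediates.

default_run_config <- function() {
  list(min_aa = 100L, large_orf_min_nt = 300L, ridge = 1e-6,
       mode = "frequencies", priors = "equal", scheme = "resubstitution",
       ellipse_level = 0.95, seed = 1L)
}

#' Load a run configuration
#'
#' @param config A named list of options, or a path to a YAML file holding
#'   one. Unset fields take documented defaults; unknown fields error.
#' @return Completed configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- default_run_config()
  known <- c(names(defaults), "fasta", "out_dir", "train_fasta", "labels_tsv",
             "query_fasta", "catalogue_tsv", "orf1_scheme", "orf2_scheme")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, config)
  if (out$min_aa < 1L || out$ridge < 0 || out$ellipse_level <= 0 ||
      out$ellipse_level >= 1)
    stop("config threshold out of range", call. = FALSE)
  out
}

log_msg <- function(con, level, ...) {
  line <- sprintf("[%s] %s", level, paste0(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Characterize di-cistronic genomes end to end
#'
#' For every record in `config$fasta`: detect the di-cistronic architecture,
#' write a GFF3 annotation, translate both ORFs and scan them against the
#' motif catalogue (with the replication-module order verdict), apply the
#' cleavage presets when requested, and profile the nucleotide composition.
#' Outputs under `config$out_dir`: `<id>.gff3` per record, `segments.tsv`,
#' `motifs.tsv`, `module_order.tsv`, `peptides.tsv`, `composition.tsv`,
#' `run.log`. On any stage failure the stage name is reported and partial
#' outputs are removed.
#'
#' @param config List or YAML path; fields `fasta` (input FASTA), `out_dir`,
#'   and optionally `min_aa`, `large_orf_min_nt`, `catalogue_tsv`,
#'   `orf1_scheme`, `orf2_scheme` (preset names, see [cleavage_preset()]).
#' @return Invisibly, a list with the per-record reports.
#' @export
run_characterize <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$fasta) || is.null(config$out_dir))
    stop("config must set 'fasta' and 'out_dir'", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  made <- character()
  logf <- file.path(config$out_dir, "run.log")
  con <- file(logf, open = "wt")
  on.exit(close(con), add = TRUE)
  made <- c(made, logf)
  stage <- "read_fasta"
  result <- tryCatch({
    log_msg(con, "INFO", "characterize: seed ", config$seed,
            ", min_aa ", config$min_aa)
    records <- read_fasta(config$fasta)
    catalogue <- if (!is.null(config$catalogue_tsv))
      read_motif_catalogue(config$catalogue_tsv) else default_motif_catalogue()
    if (!"orf" %in% names(catalogue)) catalogue$orf <- NA_integer_
    segments <- NULL; motif_tab <- NULL; order_tab <- NULL
    peptide_tab <- NULL; comp_tab <- NULL
    reports <- list()
    for (rec in records) {
      stage <- "find_orfs"
      orfs <- find_orfs(rec, min_aa = config$min_aa)
      stage <- "detect_dicistronic"
      arch <- detect_dicistronic(orfs, nchar(rec$sequence),
                                 large_orf_min_nt = config$large_orf_min_nt)
      stage <- "segment_report"
      seg <- segment_report(arch)
      stage <- "composition_profile"
      prof <- composition_profile(rec)
      segments <- rbind(segments, data.frame(
        id = rec$id, as.data.frame(seg),
        gc_percent = round(gc_content(prof), 1L),
        au_percent = round(au_content(prof), 1L)))
      comp_tab <- rbind(comp_tab, data.frame(
        id = rec$id, t(build_features(prof, "frequencies")),
        t(stats::setNames(prof$oe, paste0("oe_", DINUC))),
        check.names = FALSE))
      stage <- "scan_motifs"
      hits_all <- NULL
      order_row <- NULL
      for (o in 1:2) {
        protein <- translate_orf(rec, if (o == 1L) arch$orf1 else arch$orf2)
        cat_o <- catalogue[is.na(catalogue$orf) | catalogue$orf == o, ,
                           drop = FALSE]
        hits <- scan_motifs(protein, cat_o)
        if (nrow(hits) > 0L)
          hits_all <- rbind(hits_all, data.frame(id = rec$id, orf = o, hits))
        if (o == 1L) {
          verdict <- check_module_order(hits)
          order_row <- data.frame(
            id = rec$id, ordered = verdict$ordered,
            present = paste(verdict$present, collapse = ","),
            absent = paste(verdict$absent, collapse = ","),
            npgp_found = verdict$npgp_found)
        }
        stage <- "annotate_cleavage"
        preset <- config[[paste0("orf", o, "_scheme")]]
        if (!is.null(preset)) {
          pep <- annotate_cleavage(protein, cleavage_preset(preset))
          peptide_tab <- rbind(peptide_tab,
                               data.frame(id = rec$id, orf = o, pep))
        }
        stage <- "scan_motifs"
      }
      motif_tab <- rbind(motif_tab, hits_all)
      order_tab <- rbind(order_tab, order_row)
      stage <- "write_annotations"
      gff <- file.path(config$out_dir, paste0(rec$id, ".gff3"))
      seg_hits <- if (is.null(hits_all)) NULL else
        hits_all[!is.na(hits_all$position_confirmed) &
                   hits_all$position_confirmed, , drop = FALSE]
      write_annotations(rec, arch, seg_hits, gff)
      made <- c(made, gff)
      reports[[rec$id]] <- list(architecture = arch, segments = seg,
                                profile = prof)
      log_msg(con, "INFO", rec$id, ": coding ", seg$coding_fraction,
              "%, GC ", round(gc_content(prof), 1L), "%")
    }
    stage <- "write_reports"
    if (is.null(motif_tab))
      motif_tab <- data.frame(id = character(), orf = integer(),
                              name = character(), aa_start = integer())
    made <- c(made,
              write_tsv(segments, file.path(config$out_dir, "segments.tsv")),
              write_tsv(motif_tab, file.path(config$out_dir, "motifs.tsv")),
              write_tsv(order_tab, file.path(config$out_dir, "module_order.tsv")),
              write_tsv(comp_tab, file.path(config$out_dir, "composition.tsv")))
    if (!is.null(peptide_tab))
      made <- c(made,
                write_tsv(peptide_tab, file.path(config$out_dir, "peptides.tsv")))
    reports
  }, error = function(e) {
    unlink(setdiff(made, logf))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

#' Fit the host discriminant model and predict query hosts
#'
#' Trains the canonical discriminant model on a labeled control panel
#' (`train_fasta` + `labels_tsv`), reports eigenvalues and concordance,
#' classifies every query sequence, and emits per-class confidence-ellipse
#' parameters for the canonical-factor pairs (1,2), (1,3), (2,3). Outputs
#' under `out_dir`: `model_summary.tsv`, `training_coordinates.tsv`,
#' `predictions.tsv`, `ellipses.tsv`, `run.log`.
#'
#' @param config List or YAML path; fields `train_fasta`, `labels_tsv`
#'   (TSV: `id`, `host`), `query_fasta`, `out_dir`, and optionally `mode`,
#'   `ridge`, `priors`, `scheme`, `ellipse_level`.
#' @return Invisibly, list: `model`, `concordance`, `predictions`,
#'   `ellipses`.
#' @export
run_nca <- function(config) {
  config <- read_run_config(config)
  for (f in c("train_fasta", "labels_tsv", "query_fasta", "out_dir"))
    if (is.null(config[[f]]))
      stop("config must set '", f, "'", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  con <- file(logf, open = "wt")
  on.exit(close(con), add = TRUE)
  train <- read_fasta(config$train_fasta)
  labels <- utils::read.delim(config$labels_tsv, stringsAsFactors = FALSE)
  if (!all(c("id", "host") %in% names(labels)))
    stop("label TSV must have columns 'id' and 'host'", call. = FALSE)
  orphans_seq <- setdiff(names(train), labels$id)
  orphans_lab <- setdiff(labels$id, names(train))
  if (length(orphans_seq) + length(orphans_lab) > 0L)
    stop("label/sequence id mismatch; unlabeled: [",
         paste(orphans_seq, collapse = ","), "], missing sequence: [",
         paste(orphans_lab, collapse = ","), "]", call. = FALSE)
  labels <- labels[match(names(train), labels$id), ]
  log_msg(con, "INFO", "nca: ", length(train), " training sequences, mode ",
          config$mode, ", priors ", config$priors, ", seed ", config$seed)
  x <- feature_matrix(train, mode = config$mode)
  model <- fit_cda(x, labels$host, ridge = config$ridge,
                   priors = config$priors)
  conc <- concordance(x, labels$host, scheme = config$scheme,
                      ridge = config$ridge, priors = config$priors)
  log_msg(con, "INFO", "concordance (", config$scheme, "): ",
          round(100 * conc, 1L), "%")
  queries <- read_fasta(config$query_fasta)
  qx <- feature_matrix(queries, mode = config$mode)
  pred <- data.frame(id = names(queries), classify(model, qx),
                     check.names = FALSE)
  for (i in seq_len(nrow(pred)))
    log_msg(con, "INFO", "query ", pred$id[i], " -> ", pred$predicted[i])
  z <- canonical_coordinates(model, x)
  coords <- data.frame(id = names(train), host = labels$host, z,
                       check.names = FALSE)
  ncf <- ncol(z)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  pairs <- Filter(function(p) all(p <= ncf), pairs)
  ell <- NULL
  for (p in pairs) {
    for (cl in model$classes) {
      pts <- z[labels$host == cl, p, drop = FALSE]
      if (nrow(pts) < 3L) next
      e <- confidence_ellipse(pts, level = config$ellipse_level)
      ell <- rbind(ell, data.frame(
        cf_x = p[1L], cf_y = p[2L], host = cl,
        center_x = e$center[1L], center_y = e$center[2L],
        axis_major = e$axes[1L], axis_minor = e$axes[2L],
        angle = e$angle, level = e$level, degenerate = e$degenerate))
    }
  }
  summary_tab <- data.frame(
    statistic = c(paste0("eigenvalue_CF", seq_along(model$eigenvalues)),
                  paste0("concordance_", config$scheme)),
    value = c(model$eigenvalues, conc))
  write_tsv(summary_tab, file.path(config$out_dir, "model_summary.tsv"))
  write_tsv(coords, file.path(config$out_dir, "training_coordinates.tsv"))
  write_tsv(pred, file.path(config$out_dir, "predictions.tsv"))
  if (!is.null(ell))
    write_tsv(ell, file.path(config$out_dir, "ellipses.tsv"))
  invisible(list(model = model, concordance = conc, predictions = pred,
                 ellipses = ell))
}
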