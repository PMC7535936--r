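#' Pipeline configuration
#'
#' Bundles inputs and per-stage parameters. Defaults reproduce the
#' published thresholds (E < 10 prefilter, 90% redundancy identity,
#' inflation 1.5, composition-rule minima). Stages without inputs
#' (e.g. no contigs, no annotations) are skipped automatically.
#'
#' @param proteins Protein tibble (`id`, `taxid`, `residues`) or FASTA
#'   path; identifiers must follow `<taxid>|<source>|<uid>`.
#' @param taxonomy A `taxonomy_tbl` or path to a 3-column taxonomy TSV.
#' @param contigs Optional nucleotide tibble (`id`, `taxid`, `bases`)
#'   or FASTA path for the genomic ORF stage.
#' @param stages Named logical vector toggling stages `orf`, `cluster`,
#'   `filter`, `validate`, `enrich`, `ppi`.
#' @param preprocess A [preprocess_config()].
#' @param aligner An [aligner_config()].
#' @param e_cutoff E-value cutoff for clustering input hits.
#' @param mcl An [mcl_config()].
#' @param min_species Minimum species per orthogroup retained after
#'   clustering.
#' @param focal,rule,rule_scale Lineage filter settings (see
#'   [lineage_specific_orthogroups()]).
#' @param profile_min_cols,profile_gap_open,profile_gap_extend,profile_min_score
#'   Profile search settings (see [profile_search()]).
#' @param annotations Optional domain annotation table (tibble/path)
#'   for the enrichment stage.
#' @param annotation_e_cutoff E-value cutoff for annotations.
#' @param ppi_edges,ppi_classes Optional PPI edge list and node-class
#'   table for the network stage.
#' @param ppi_min_score PPI combined-score threshold.
#' @param out_dir Output directory for [write_report()] (created on
#'   demand).
#' @param seed Global seed; per-stage substreams are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(proteins, taxonomy, contigs = NULL,
                            stages = c(orf = TRUE, cluster = TRUE,
                                       filter = TRUE, validate = TRUE,
                                       enrich = TRUE, ppi = TRUE),
                            preprocess = preprocess_config(),
                            aligner = aligner_config(),
                            e_cutoff = 1e-5,
                            mcl = mcl_config(),
                            min_species = 2,
                            focal = "Bilateria", rule = "bilaterian",
                            rule_scale = 1,
                            profile_min_cols = 20, profile_gap_open = 3,
                            profile_gap_extend = 0.3, profile_min_score = 60,
                            annotations = NULL, annotation_e_cutoff = 5e-5,
                            ppi_edges = NULL, ppi_classes = NULL,
                            ppi_min_score = 400,
                            out_dir = NULL, seed = 1) {
  if (is.character(proteins)) proteins <- read_fasta(proteins, "AA")
  if (is.character(taxonomy)) taxonomy <- read_taxonomy_tsv(taxonomy)
  if (is.character(contigs)) contigs <- read_fasta(contigs, "DNA")
  defaults <- c(orf = TRUE, cluster = TRUE, filter = TRUE, validate = TRUE,
                enrich = TRUE, ppi = TRUE)
  defaults[names(stages)] <- stages
  structure(list(proteins = proteins, taxonomy = taxonomy, contigs = contigs,
                 stages = defaults, preprocess = preprocess, aligner = aligner,
                 e_cutoff = e_cutoff, mcl = mcl, min_species = min_species,
                 focal = focal, rule = rule, rule_scale = rule_scale,
                 profile_min_cols = profile_min_cols,
                 profile_gap_open = profile_gap_open,
                 profile_gap_extend = profile_gap_extend,
                 profile_min_score = profile_min_score,
                 annotations = annotations,
                 annotation_e_cutoff = annotation_e_cutoff,
                 ppi_edges = ppi_edges, ppi_classes = ppi_classes,
                 ppi_min_score = ppi_min_score,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the discovery pipeline end-to-end
#'
#' Executes the enabled stages in order: genomic ORF extraction and
#' filtering, all-vs-all similarity and Markov clustering, lineage
#' filtering, profile-based validation, domain enrichment and PPI
#' statistics. Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: list with per-stage counts, the final
#'   lineage-specific orthogroup list, verdicts, statistics and the
#'   orthogroup table.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- list()
  log_stage <- function(...) message("[cladesift] ", ...)
  seqs <- config$proteins

  if (isTRUE(config$stages[["orf"]]) && !is.null(config$contigs)) {
    log_stage("orf: translating ", nrow(config$contigs), " contigs")
    orfs <- six_frame_orfs(config$contigs, config$preprocess)
    taxid_by_ctg <- stats::setNames(config$contigs$taxid, config$contigs$id)
    orf_records <- tibble(
      id = make_seq_id(taxid_by_ctg[orfs$contig], "orf",
                       paste0(orfs$contig, "_", orfs$frame, "_", orfs$start)),
      taxid = unname(taxid_by_ctg[orfs$contig]),
      residues = orfs$residues)
    counts$orf_raw <- nrow(orf_records)
    orf_records <- split_x_runs(orf_records, config$preprocess)
    counts$orf_split <- nrow(orf_records)
    if (nrow(seqs) > 0 && nrow(orf_records) > 0) {
      orf_records <- similarity_prefilter(orf_records, seqs,
                                          config$preprocess, config$aligner)
      orf_records$best_e <- NULL
    }
    counts$orf_prefilter <- nrow(orf_records)
    orf_records <- reduce_redundancy(orf_records, config$preprocess)
    counts$orf_nr <- nrow(orf_records)
    seqs <- bind_rows(seqs, orf_records)
  }
  counts$sequences <- nrow(seqs)

  groups <- NULL
  if (isTRUE(config$stages[["cluster"]])) {
    log_stage("cluster: all-vs-all over ", nrow(seqs), " sequences")
    hits <- all_vs_all_similarity(seqs, config$aligner, config$e_cutoff)
    counts$hits <- nrow(hits)
    edges <- build_orthomcl_graph(hits)
    counts$edges <- nrow(edges)
    groups <- mcl_cluster(edges, config$mcl)
    counts$orthogroups <- n_distinct(groups$og_id)
    groups <- select_orthogroups(groups, config$min_species)
    counts$orthogroups_selected <- n_distinct(groups$og_id)
  }

  candidates <- NULL
  if (isTRUE(config$stages[["filter"]]) && !is.null(groups)) {
    log_stage("filter: lineage rule '", config$rule, "' focal ", config$focal)
    candidates <- lineage_specific_orthogroups(
      groups, config$taxonomy, config$focal, config$rule, config$rule_scale)
    counts$candidates <- nrow(candidates)
  }

  verdicts <- NULL
  final_set <- candidates$og_id %||% character(0)
  if (isTRUE(config$stages[["validate"]]) && !is.null(candidates) &&
      nrow(candidates) > 0) {
    log_stage("validate: profiles for ", n_distinct(groups$og_id), " orthogroups")
    profs <- orthogroup_profiles(groups, seqs)
    hits <- profile_search_all(profs,
                               gap_open = config$profile_gap_open,
                               gap_extend = config$profile_gap_extend,
                               min_cols = config$profile_min_cols,
                               min_score = config$profile_min_score)
    rbh <- reciprocal_best_hits(hits)
    comps <- orthogroup_composition(groups, config$taxonomy)
    verdicts <- correct_lineage_set(candidates$og_id, rbh, comps,
                                    focal = config$focal)
    final_set <- verdicts$og_id[verdicts$status == "retained"]
    counts$removed_ancient <- sum(verdicts$status == "removed_ancient")
  }
  counts$final <- length(final_set)

  stats_tbl <- list()
  if (isTRUE(config$stages[["enrich"]]) && !is.null(config$annotations)) {
    log_stage("enrich: domain classes")
    ann <- load_domain_annotations(config$annotations,
                                   config$annotation_e_cutoff)
    classes <- count_domain_classes(ann)
    counts$tf_proteins <- classes$n_tf
    counts$polyzf_proteins <- classes$n_polyzf
  }
  if (isTRUE(config$stages[["ppi"]]) && !is.null(config$ppi_edges)) {
    log_stage("ppi: network statistics")
    net <- load_ppi_edges(config$ppi_edges, config$ppi_classes,
                          config$ppi_min_score)
    counts$ppi_nodes <- nrow(net$nodes)
    counts$ppi_edges <- nrow(net$edges)
    stats_tbl$class_mixing <- interaction_class_test(net)$result
  }

  structure(list(counts = counts,
                 orthogroups = groups,
                 candidates = candidates,
                 verdicts = verdicts,
                 final_set = sort(final_set),
                 statistics = bind_rows(stats_tbl),
                 seed = config$seed,
                 version = as.character(utils::packageVersion("cladesift"))),
            class = "run_report")
}

# Build one profile per orthogroup from member sequences.
orthogroup_profiles <- function(groups, seqs, alpha = 1.0) {
  seq_of <- stats::setNames(seqs$residues, seqs$id)
  ogs <- split(groups$member_id, groups$og_id)
  profs <- imap(ogs, function(members, og) {
    members <- members[members %in% names(seq_of)]
    if (length(members) == 0) return(NULL)
    msa <- build_msa(tibble(id = members, residues = unname(seq_of[members])),
                     og_id = og)
    build_profile(msa, alpha = alpha)
  })
  profs[!map_lgl(profs, is.null)]
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> final lineage-specific orthogroups: ",
      length(x$final_set), "\n", sep = "")
  for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes `report.json` (counts, final set, statistics, seed),
#' `final_orthogroups.tsv`, and `groups.txt` in the classic groups
#' dialect. Stage counts are validated to reconcile before writing.
#'
#' @param report A `run_report`.
#' @param path Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (!is.null(report$verdicts)) {
    reconciled <- report$counts$final + (report$counts$removed_ancient %||% 0)
    if (!is.null(report$counts$candidates) &&
        reconciled != report$counts$candidates) {
      abort("stage counts do not reconcile: candidates != final + removed")
    }
  }
  js <- file.path(path, "report.json")
  jsonlite::write_json(
    list(counts = report$counts, final_set = report$final_set,
         statistics = if (nrow(report$statistics %||% tibble()) > 0) {
           report$statistics[, c("method", "statistic", "p_value")]
         } else NULL,
         seed = report$seed, version = report$version),
    js, auto_unbox = TRUE, digits = NA, null = "null")
  tsv <- file.path(path, "final_orthogroups.tsv")
  utils::write.table(tibble(og_id = report$final_set), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gf <- NULL
  if (!is.null(report$orthogroups)) {
    gf <- file.path(path, "groups.txt")
    write_groups_file(report$orthogroups, gf)
  }
  invisible(c(js, tsv, gf))
}
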