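# Orchestration: simulate -> quantify -> normalize -> rollup -> diff ->
# network -> enrich as a configured, logged, resumable run with a
# manifest (parameter hashes, file checksums, wall times).

#' Run configuration
#'
#' Nested configuration for a full pipeline run.
#'
#' @param sim a [sim_config()].
#' @param network a [network_config()].
#' @param quantifier_k quantifier ions per peptide.
#' @param min_fragments minimum nonzero quantifier ions per injection.
#' @param reference_level calibration dilution level.
#' @param reference_k calibration peptides.
#' @param covariates residualization covariates.
#' @param comparisons pairwise comparisons for volcano tables.
#' @param macro_clusters macro-cluster count for enrichment co-clustering.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), network = network_config(),
                       quantifier_k = 5, min_fragments = 3,
                       reference_level = 3, reference_k = 4,
                       covariates = c("age_death", "sex", "pmi"),
                       comparisons = c("AsymAD/CTL", "AD/CTL", "PD/CTL"),
                       macro_clusters = 6) {
  structure(list(sim = sim, network = network, quantifier_k = quantifier_k,
                 min_fragments = min_fragments,
                 reference_level = reference_level,
                 reference_k = reference_k, covariates = covariates,
                 comparisons = comparisons,
                 macro_clusters = macro_clusters), class = "run_config")
}

#' Write an entities x samples matrix as CSV
#' @param m matrix (abundance matrix accepted).
#' @param path output path.
#' @param id_col name of the row-identifier column.
#' @export
write_matrix_csv <- function(m, path, id_col = "entity") {
  df <- data.frame(rownames(m), unclass_matrix(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an entities x samples CSV into a matrix
#' @param path CSV path written by [write_matrix_csv()].
#' @return numeric matrix with row names from the first column.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

.hash_obj <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

.hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(unname(h), basename(paths))
}

.check_inputs <- function(paths, manifest) {
  known <- list()
  for (st in manifest$stages) known[names(st$outputs)] <- st$outputs
  for (p in paths) {
    if (!file.exists(p)) integrity_error(sprintf("missing input file: %s", p))
    b <- basename(p)
    if (!is.null(known[[b]]) && unname(tools::md5sum(p)) != known[[b]])
      integrity_error(sprintf(
        "input file %s does not match the checksum recorded upstream", p))
  }
}

#' Run the full analysis pipeline
#'
#' Executes the seven stages (simulate, quantify, normalize, rollup, diff,
#' network, enrich) in order, writing each stage's outputs plus a
#' `manifest.json` recording parameter hashes, input/output checksums and
#' wall times. A rerun skips stages whose parameters and inputs are
#' unchanged and whose outputs are intact; a corrupted intermediate file
#' raises a file-integrity error naming the file.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param force rerun every stage regardless of the manifest.
#' @param quiet suppress progress messages.
#' @param through last stage to execute ("simulate", "quantify",
#'   "normalize", "rollup", "diff", "network" or "enrich").
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir, force = FALSE,
                         quiet = FALSE, through = "enrich") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  man_path <- pth("manifest.json")
  manifest <- if (file.exists(man_path) && !force)
    jsonlite::read_json(man_path) else list(stages = list())
  say <- function(...) if (!quiet) message(sprintf(...))

  stage_defs <- list(
    simulate = list(
      params = config$sim, inputs = character(),
      outputs = c("cohort.csv", "targets.csv", "transitions.csv",
                  "reference.csv", "truth.json"),
      fun = function() {
        cohort <- generate_cohort(config$sim)
        targets <- generate_target_list(config$sim)
        gen <- generate_transitions(cohort, targets, config$sim)
        utils::write.csv(cohort, pth("cohort.csv"),
                         row.names = FALSE, quote = FALSE)
        utils::write.csv(targets, pth("targets.csv"), row.names = FALSE,
                         quote = FALSE)
        write_transition_report(gen$transitions, pth("transitions.csv"))
        utils::write.csv(gen$reference, pth("reference.csv"),
                         row.names = FALSE, quote = FALSE)
        jsonlite::write_json(list(
          assignment = as.list(gen$truth$assignment),
          effect_table = gen$truth$effect_table,
          drift = gen$truth$drift,
          gps_injections = gen$truth$gps_injections,
          injection_sample = gen$truth$injection_sample),
          pth("truth.json"), auto_unbox = TRUE, digits = NA)
      }),
    quantify = list(
      params = config[c("quantifier_k", "min_fragments")],
      inputs = "transitions.csv",
      outputs = c("peptide_matrix.csv", "injection_map.csv"),
      fun = function() {
        tab <- read_transition_report(pth("transitions.csv"))
        pm <- quantify_peptides(tab, k = config$quantifier_k,
                                min_fragments = config$min_fragments)
        write_matrix_csv(pm, pth("peptide_matrix.csv"), id_col = "peptide")
        inj <- attr(pm, "injection")
        utils::write.csv(
          data.frame(sample_id = names(inj), injection_index = unname(inj)),
          pth("injection_map.csv"), row.names = FALSE, quote = FALSE)
      }),
    normalize = list(
      params = config[c("reference_level", "reference_k")],
      inputs = c("reference.csv", "peptide_matrix.csv", "injection_map.csv",
                 "transitions.csv"),
      outputs = c("corrected_peptides.csv", "qc_drift.csv"),
      fun = function() {
        ref <- utils::read.csv(pth("reference.csv"))
        panel <- reference_panel(ref, level = config$reference_level,
                                 k = config$reference_k)
        pm <- read_matrix_csv(pth("peptide_matrix.csv"))
        imap <- utils::read.csv(pth("injection_map.csv"))
        inj <- imap$injection_index[match(colnames(pm), imap$sample_id)]
        cf <- stats::setNames(panel$correction_factor,
                              colnames(panel$area))
        corrected <- apply_correction(pm, cf, injection = inj)
        write_matrix_csv(corrected, pth("corrected_peptides.csv"),
                         id_col = "peptide")
        fit <- fit_drift(panel)
        utils::write.csv(data.frame(
          slope = fit$slope, intercept = fit$intercept,
          r_squared = fit$r_squared,
          cv_pre = reference_cv(panel, corrected = FALSE),
          cv_post = reference_cv(panel, corrected = TRUE)),
          pth("qc_drift.csv"), row.names = FALSE, quote = FALSE)
      }),
    rollup = list(
      params = config["covariates"],
      inputs = c("corrected_peptides.csv", "targets.csv", "cohort.csv"),
      outputs = c("protein_matrix.csv", "protein_log2_residualized.csv",
                  "imputation_report.csv"),
      fun = function() {
        pm <- read_matrix_csv(pth("corrected_peptides.csv"))
        targets <- utils::read.csv(pth("targets.csv"))
        cohort <- utils::read.csv(pth("cohort.csv"))
        pep <- abundance_matrix(pm, level = "peptide",
                                stages = "corrected")
        attr(pep, "peptide_map") <- stats::setNames(
          targets$protein[!targets$is_reference],
          targets$peptide[!targets$is_reference])
        prot <- rollup_proteins(pep)
        write_matrix_csv(prot, pth("protein_matrix.csv"))
        case_cols <- intersect(colnames(prot), cohort$case_id)
        prot_cases <- abundance_matrix(
          unclass_matrix(prot)[, case_cols, drop = FALSE],
          level = "protein", stages = "corrected")
        imp <- impute_half_min(prot_cases)
        rep_ <- imputation_report(imp)
        final <- residualize_covariates(log2_transform(imp), cohort,
                                        config$covariates)
        write_matrix_csv(final, pth("protein_log2_residualized.csv"))
        utils::write.csv(data.frame(
          n_imputed = rep_$n_imputed, n_total = rep_$n_total,
          fraction = rep_$fraction,
          n_dropped = length(rep_$dropped)),
          pth("imputation_report.csv"), row.names = FALSE, quote = FALSE)
      }),
    diff = list(
      params = config["comparisons"],
      inputs = c("protein_log2_residualized.csv", "cohort.csv"),
      outputs = c("volcano.csv", "omnibus.csv"),
      fun = function() {
        m <- read_matrix_csv(pth("protein_log2_residualized.csv"))
        cohort <- utils::read.csv(pth("cohort.csv"))
        volc <- do.call(rbind, lapply(config$comparisons, function(cmp)
          volcano(m, cohort, cmp)))
        utils::write.csv(volc, pth("volcano.csv"), row.names = FALSE,
                         quote = FALSE)
        utils::write.csv(omnibus_tests(m, cohort), pth("omnibus.csv"),
                         row.names = FALSE, quote = FALSE)
      }),
    network = list(
      params = config$network,
      inputs = c("protein_log2_residualized.csv", "cohort.csv",
                 "volcano.csv"),
      outputs = c("modules.csv", "eigenproteins.csv", "module_trait.csv",
                  "pathology_ranking.csv", "module_fractions.csv"),
      fun = function() {
        m <- read_matrix_csv(pth("protein_log2_residualized.csv"))
        cohort <- utils::read.csv(pth("cohort.csv"))
        part <- build_network(m, config$network)
        own <- part$kme[cbind(seq_len(nrow(m)),
                              match(paste0("M", part$assignment),
                                    colnames(part$kme)))]
        utils::write.csv(data.frame(
          entity = names(part$assignment),
          module = ifelse(part$assignment == 0, "M0",
                          paste0("M", part$assignment)),
          kme_own = own),
          pth("modules.csv"), row.names = FALSE, quote = FALSE)
        write_matrix_csv(part$eigenproteins, pth("eigenproteins.csv"),
                         id_col = "module")
        utils::write.csv(
          module_trait_correlations(part, cohort),
          pth("module_trait.csv"), row.names = FALSE, quote = FALSE)
        utils::write.csv(pathology_ranking(m),
                         pth("pathology_ranking.csv"), row.names = FALSE,
                         quote = FALSE)
        volc <- utils::read.csv(pth("volcano.csv"))
        utils::write.csv(module_significance_fraction(volc, part),
                         pth("module_fractions.csv"), row.names = FALSE,
                         quote = FALSE)
      }),
    enrich = list(
      params = config["macro_clusters"],
      inputs = c("modules.csv", "targets.csv"),
      outputs = c("enrichment.csv", "macro_clusters.csv"),
      fun = function() {
        mods <- utils::read.csv(pth("modules.csv"))
        targets <- utils::read.csv(pth("targets.csv"))
        assign <- stats::setNames(
          as.integer(sub("^M", "", mods$module)), mods$entity)
        sets <- generate_annotation_sets(targets, config$sim)
        enr <- enrich_modules(assign, sets)
        utils::write.csv(enr, pth("enrichment.csv"), row.names = FALSE,
                         quote = FALSE)
        Z <- enrichment_z_matrix(enr)
        cc <- cocluster_z_matrix(Z, k = config$macro_clusters)
        utils::write.csv(data.frame(
          module = names(cc$macro_cluster),
          macro_cluster = unname(cc$macro_cluster)),
          pth("macro_clusters.csv"), row.names = FALSE, quote = FALSE)
      })
  )

  if (!through %in% names(stage_defs))
    config_error(sprintf("unknown stage '%s'", through))
  run_stages <- names(stage_defs)[seq_len(match(through, names(stage_defs)))]
  for (name in run_stages) {
    st <- stage_defs[[name]]
    phash <- .hash_obj(st$params)
    prev <- manifest$stages[[name]]
    out_paths <- pth(st$outputs)
    in_paths <- if (length(st$inputs)) pth(st$inputs) else character()
    hashes_match <- function(paths, recorded) {
      if (length(paths) == 0) return(TRUE)
      if (!all(file.exists(paths))) return(FALSE)
      cur <- .hash_files(paths)
      rec <- unlist(recorded)
      all(names(cur) %in% names(rec)) &&
        all(cur == rec[names(cur)])
    }
    # skip purely on parameters + input provenance; output corruption is
    # the downstream consumer's integrity check to raise
    up_to_date <- !force && !is.null(prev) &&
      prev$status %in% c("completed", "skipped") &&
      !is.null(prev$params_hash) &&
      identical(prev$params_hash, phash) &&
      all(file.exists(out_paths)) &&
      hashes_match(in_paths, prev$inputs)
    if (isTRUE(up_to_date)) {
      say("stage %-9s skipped (up to date)", name)
      manifest$stages[[name]]$status <- "skipped"
      next
    }
    .check_inputs(in_paths, manifest)
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ st$fun(); TRUE }, error = function(e) {
      manifest$stages[[name]] <- list(status = "failed",
                                      error = conditionMessage(e))
      jsonlite::write_json(manifest, man_path, auto_unbox = TRUE,
                           digits = NA)
      stop(e)
    })
    manifest$stages[[name]] <- list(
      status = "completed", params_hash = phash,
      inputs = as.list(.hash_files(in_paths)),
      outputs = as.list(.hash_files(out_paths)),
      wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
    say("stage %-9s completed in %.1fs", name,
        manifest$stages[[name]]$wall_time_s)
  }
  invisible(manifest)
}
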