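## End-to-end demonstration pipeline on the synthetic study.

demoHeader <- function(seed) {
  sprintf("# starrkit %s seed=%d",
          as.character(utils::packageVersion("starrkit")), seed)
}

writeTsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(demoHeader(seed), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Run the full demonstration pipeline on synthetic data
#'
#' Wires every stage end to end on a generated study: simulate genome and
#' reporter library, UMI-deduplicate, quantify and call enhancers against
#' the input background, rank activities, test differential activity
#' between LIF and RA, classify receptor-occupied sites, run motif
#' enrichment (active vs inactive) and the DR/IR/ER spacing scan, fit the
#' sequence classifier on the activity extremes, and cluster the
#' histone-modification matrix. Each stage writes TSV/BED output into
#' `outDir` and contributes to a machine-readable JSON summary that
#' includes precision/recall of enhancer calling against the planted
#' truth.
#'
#' The activity floor for the receptor-response classification is 0 here
#' (the desk-scale library spans lower absolute scores than a genome-wide
#' screen; [classifyResponseSites()] keeps its genome-scale default
#' otherwise), and the classifier trains on 25% extremes of the desk-scale
#' region set.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed; the run is fully deterministic given it.
#' @param config optional [SynthConfig-class]; defaults to
#'   `synthConfig(seed = seed)`.
#' @param fdr,minReplicates,minFragments enhancer-calling parameters.
#' @param quantiles number of activity groups.
#' @param extremeFraction classifier extreme fraction at desk scale.
#' @return the summary list, invisibly (also written to
#'   `summary.json`).
#' @export
runDemo <- function(outDir = tempfile("starrkit_demo_"), seed = 1L,
                    config = NULL, fdr = 0.05, minReplicates = 2L,
                    minFragments = 3L, quantiles = 5L,
                    extremeFraction = 0.25) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- synthConfig(seed = seed)
  summary <- list(seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("demo stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  sim <- stage("simulate", simulateGenome(config))
  lib <- stage("simulate", simulateReporterLibrary(config, sim))
  writeBed(sim$regions, file.path(outDir, "input_regions.bed"))
  writeTsv(sim$truth, file.path(outDir, "ground_truth.tsv"), seed)
  Biostrings::writeXStringSet(sim$genome, file.path(outDir, "genome.fa"))

  mol <- stage("dedup", dedupUmi(lib$fragments, mode = "exact"))
  summary$n_fragments <- nrow(lib$fragments)
  summary$n_molecules <- nrow(mol)

  se <- stage("call", {
    se <- quantifyRegions(sim$regions, mol, lib$input)
    conds <- unique(SummarizedExperiment::colData(se)$condition)
    ## call per condition; a region active in any condition is active
    perCond <- lapply(conds, function(cc)
      activityTable(callEnhancers(se, condition = cc, fdr = fdr,
                                  minReplicates = minReplicates,
                                  minFragments = minFragments))$is_active)
    se <- callEnhancers(se, fdr = fdr, minReplicates = minReplicates,
                        minFragments = minFragments)
    rd <- SummarizedExperiment::rowData(se)
    rd$is_active <- Reduce(`|`, perCond) | rd$is_active
    SummarizedExperiment::rowData(se) <- rd
    se
  })
  act <- activityTable(se)
  writeTsv(act, file.path(outDir, "region_activity.tsv"), seed)
  writeBed(sim$regions[act$is_active],
           file.path(outDir, "active_regions.bed"))
  truthActive <- sim$truth$is_active
  called <- act$is_active
  tp <- sum(called & truthActive)
  summary$n_active <- sum(called)
  summary$calling_precision <- if (sum(called)) tp / sum(called) else NA
  summary$calling_recall <- if (sum(truthActive)) tp / sum(truthActive)
                            else NA

  rank <- stage("rank", {
    aidx <- which(called)
    q <- activityQuantiles(act$log_score[aidx], k = min(quantiles,
                                                        length(aidx)))
    data.frame(region = act$region[aidx], log_score = act$log_score[aidx],
               group = q$group)
  })
  writeTsv(rank, file.path(outDir, "activity_quantiles.tsv"), seed)

  both <- all(c("LIF", "RA") %in%
              SummarizedExperiment::colData(se)$condition)
  if (both) {
    diff <- stage("diff", differentialEnhancers(se))
    writeTsv(diff, file.path(outDir, "differential.tsv"), seed)
    summary$n_ra_inducible <- sum(diff$class == "RA-inducible")
    summary$n_lif_dependent <- sum(diff$class == "LIF-dependent")

    rar <- stage("rar-classes", {
      peakIdx <- which(sim$truth$class %in%
                       c("RA-inducible", "LIF-dependent", "stable"))
      peaks <- sim$regions[peakIdx]
      tryCatch(classifyResponseSites(diff, sim$regions, peaks,
                                     fraction = 0.25, floor = 0),
               error = function(e) NULL)
    })
    if (!is.null(rar)) {
      for (s in c("induced", "repressed", "non_responding"))
        writeBed(sim$regions[rar[[s]]],
                 file.path(outDir, paste0("rar_", s, ".bed")))
      summary$rar_set_size <- rar$size

      spacing <- stage("spacing-scan", {
        sets <- lapply(rar[c("induced", "repressed", "non_responding")],
                       function(ids) fetchSequences(sim$genome,
                                                    sim$regions[ids]))
        spacingEnrichment(sets, buildAllComposites(rarHalfSite()),
                          seed = seed)
      })
      if (nrow(spacing$E))
        writeTsv(as.data.frame(spacing$Z),
                 file.path(outDir, "spacing_zscores.tsv"), seed)
      summary$n_spacing_variants_kept <- nrow(spacing$E)
    }
  }

  enr <- stage("motif-enrich", {
    seqs <- fetchSequences(sim$genome, sim$regions)
    fg <- seqs[called]
    bg <- seqs[!called]
    enrichTwoSets(fg, bg, sim$panel, seed = seed)
  })
  writeTsv(enr, file.path(outDir, "motif_enrichment.tsv"), seed)
  summary$n_enriched_motifs <- sum(enr$enriched)

  clf <- stage("classify", {
    seqs <- fetchSequences(sim$genome, sim$regions)
    ext <- selectExtremes(act$log_score, extremeFraction)
    idx <- c(ext$top, ext$bottom)
    labels <- factor(rep(c("active", "inactive"), each = ext$size),
                     levels = c("active", "inactive"))
    feats <- buildFeatureTable(seqs[idx], sim$panel)
    nestedCvElasticNet(feats, labels, seed = seed)
  })
  writeTsv(classifierCoefficients(clf),
           file.path(outDir, "classifier_coefficients.tsv"), seed)
  summary$classifier_mean_auc <- meanAUC(clf)
  summary$classifier_fold_auc <- foldAUC(clf)

  hm <- stage("cluster-hm", {
    hmx <- simulateHmMatrix(config, sim$regions)
    km <- kmeansHm(hmx$matrix, k = config@nHmClusters, seed = seed)
    list(matrix = hmx$matrix, planted = hmx$labels, labels = km$labels)
  })
  writeTsv(data.frame(region = rownames(hm$matrix), cluster = hm$labels),
           file.path(outDir, "hm_clusters.tsv"), seed)
  summary$hm_ari <- mclust::adjustedRandIndex(hm$planted, hm$labels)

  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
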