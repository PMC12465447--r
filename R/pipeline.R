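#' Validate a pipeline run configuration
#'
#' Checks a configuration (a named list or a YAML file path) against the
#' known keys, reporting every problem at once. Declared input files must
#' exist; numeric parameters must be positive; unknown keys are rejected
#' with a closest-match suggestion.
#'
#' @param config named list or path to a YAML config file.
#' @return the validated (defaults-filled) config list, or an error of
#'   class `cohesinHiC_config_error` whose message lists all problems.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    chrom_sizes = NULL, genes = NULL, expression = NULL,
    pairs_control = NULL, pairs_cko = NULL,
    peaks = list(), output_dir = NULL,
    bin_size_local = 5000, bin_size_compartment = 25000,
    group_size = 500, min_pair_distance = 1000,
    enhancer_min_distal = 2000, tss_half_window = 1000,
    promoter_upstream_bp = 500, pseudocount_frac = 0.05,
    mask_quantile = 0.02, seed = 1)
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  for (k in unknown) {
    sug <- agrep(k, names(defaults), max.distance = 0.4, value = TRUE)
    errs <- c(errs, sprintf("unknown key '%s'%s", k,
                            if (length(sug)) sprintf(" (did you mean '%s'?)", sug[1]) else ""))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  for (k in c("chrom_sizes", "genes", "expression", "pairs_control", "pairs_cko")) {
    if (is.null(cfg[[k]])) errs <- c(errs, sprintf("missing required input '%s'", k))
    else for (f in cfg[[k]]) if (!file.exists(f))
      errs <- c(errs, sprintf("%s: file not found: %s", k, f))
  }
  for (mk in names(cfg$peaks))
    if (!file.exists(cfg$peaks[[mk]]))
      errs <- c(errs, sprintf("peaks[%s]: file not found: %s", mk, cfg$peaks[[mk]]))
  for (k in c("bin_size_local", "bin_size_compartment", "group_size",
              "min_pair_distance", "enhancer_min_distal", "tss_half_window",
              "promoter_upstream_bp")) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0)
      errs <- c(errs, sprintf("parameter '%s' must be a single positive number", k))
  }
  if (length(errs))
    stop(structure(class = c("cohesinHiC_config_error", "error", "condition"),
                   list(message = paste0("invalid configuration:\n  - ",
                                         paste(errs, collapse = "\n  - ")),
                        call = NULL)))
  cfg
}

#' Run the full two-condition analysis pipeline
#'
#' Executes filter -> bin -> balance -> compartments -> ranked-group
#' features -> local gene-body interactions -> enhancer classification
#' and distal-enhancer analysis, writing TSV/bedGraph/JSON outputs and a
#' machine-readable run report. Deterministic for fixed config and
#' inputs.
#'
#' @param config validated config list or YAML path (see
#'   [validateConfig()]).
#' @return invisibly, a list with all major result objects and the run
#'   report.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  outDir <- cfg$output_dir %||% "."
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed, parameters = cfg[c(
    "bin_size_local", "bin_size_compartment", "group_size",
    "min_pair_distance", "enhancer_min_distal", "promoter_upstream_bp")])
  stage <- "inputs"
  res <- tryCatch({
    cs <- readChromSizes(cfg$chrom_sizes)
    genes <- readGeneTable(cfg$genes, cs)
    expr <- data.table::fread(cfg$expression)
    idx <- match(genes$gene_id, expr$gene_id)
    genes$log2cpm <- expr$log2cpm[idx]
    genes$log2fc <- expr$log2fc[idx]
    peaks <- lapply(names(cfg$peaks), function(mk)
      readBed(cfg$peaks[[mk]], cs, mark = mk))
    names(peaks) <- names(cfg$peaks)

    stage <- "pairs"
    gridL <- BinGrid(cfg$bin_size_local, cs)
    gridC <- BinGrid(cfg$bin_size_compartment, cs)
    conds <- list(control = cfg$pairs_control, cko = cfg$pairs_cko)
    mats <- lapply(conds, function(paths) {
      # replicate/dataset files are binned separately and pooled (raw
      # counts summed, weights recomputed)
      per <- lapply(paths, function(p)
        filterPairs(readPairs(p, cs), cfg$min_pair_distance))
      rep_total <- Reduce(`+`, lapply(per, `[[`, "report"))
      pool <- function(grid) {
        binned <- lapply(per, function(x) binPairs(x$pairs, grid)$matrices)
        setNames(lapply(names(cs), function(ch)
          poolMatrices(lapply(binned, `[[`, ch))), names(cs))
      }
      list(binned = list(local = pool(gridL), compartment = pool(gridC)),
           filter_report = rep_total)
    })
    report$filter <- lapply(mats, `[[`, "filter_report")

    stage <- "balance"
    for (cond in names(mats)) {
      for (lvl in names(mats[[cond]]$binned))
        mats[[cond]]$binned[[lvl]] <- lapply(
          mats[[cond]]$binned[[lvl]], krBalance,
          maskQuantile = cfg$mask_quantile)
    }

    stage <- "compartments"
    active <- binnedPeakDensity(peaks$H3K27ac, gridC)
    repress <- binnedPeakDensity(peaks$H3K9me3, gridC)
    profiles <- lapply(mats, function(m)
      compartmentProfile(m$binned$compartment, active, repress))
    delta <- deltaScores(profiles$control, profiles$cko)
    for (cond in names(profiles))
      writeBedGraph(profiles[[cond]],
                    path = file.path(outDir, sprintf("compartment_%s.bedgraph", cond)))
    writeBedGraph(delta, gridC, file.path(outDir, "compartment_delta.bedgraph"))

    stage <- "ranked_groups"
    groups <- rankAndGroup(delta, profiles$control, cfg$group_size)
    feat <- groupFeatureExpression(groups, genes)
    feat$genic_fraction <- groupFeatureGenicFraction(groups, genes)$genic_fraction
    for (mk in intersect(c("H3K27ac", "CTCF", "RAD21"), names(peaks)))
      feat[[paste0("dist_", mk)]] <- groupFeaturePeakDistance(
        groups, peaks[[mk]], genes, cfg$promoter_upstream_bp)$mean_distance
    data.table::fwrite(feat, file.path(outDir, "ranked_group_features.tsv"), sep = "\t")
    data.table::fwrite(groups@bins, file.path(outDir, "ranked_bins.tsv"), sep = "\t")

    stage <- "local_interactions"
    scoreT <- lapply(mats, function(m)
      geneBodyInteractionTable(m$binned$local, genes))
    local <- data.frame(gene_id = scoreT$control$gene_id,
                        chrom = scoreT$control$chrom,
                        n_bins = scoreT$control$n_bins,
                        score_ctrl = scoreT$control$score,
                        score_cko = scoreT$cko$score)
    pseudo <- cfg$pseudocount_frac * median(local$score_ctrl, na.rm = TRUE)
    local$fold_change <- interactionFoldChange(local$score_cko,
                                               local$score_ctrl, pseudo)
    data.table::fwrite(local, file.path(outDir, "gene_body_interactions.tsv"), sep = "\t")

    stage <- "enhancers"
    enhRes <- NULL
    if (all(c("H3K27ac", "H3K4me3") %in% names(peaks))) {
      enh <- classifyEnhancers(peaks$H3K27ac, peaks$H3K4me3, genes,
                               cfg$enhancer_min_distal, cfg$tss_half_window)
      down <- genes[!is.na(genes$log2fc) & genes$log2fc < -0.5 &
                      genes$biotype == "protein_coding"]
      enhRes <- enhancerDistanceVsDeltaScore(down, enh, genes, delta, gridC)
      data.table::fwrite(data.table::data.table(
        chrom = as.character(GenomeInfoDb::seqnames(enh)),
        start = GenomicRanges::start(enh) - 1L,
        end = GenomicRanges::end(enh),
        name = sprintf("enh_%d%s", seq_along(enh),
                       ifelse(enh$is_intergenic, "_intergenic", "")),
        distance_to_tss = enh$distance_to_tss),
        file.path(outDir, "enhancers.bed"), sep = "\t", col.names = FALSE)
      if (!is.null(enhRes$records))
        data.table::fwrite(enhRes$records,
                           file.path(outDir, "distal_enhancer_delta.tsv"), sep = "\t")
    }

    stage <- "report"
    report$n_genes <- length(genes)
    report$n_ranked_bins <- nrow(groups@bins)
    report$median_fold_change <- median(local$fold_change, na.rm = TRUE)
    if (!is.null(enhRes$test)) {
      report$distal_correlation <- unname(enhRes$test$estimate)
      report$distal_correlation_p <- enhRes$test$p.value
    }
    jsonlite::write_json(report, file.path(outDir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    list(genes = genes, peaks = peaks, matrices = mats, profiles = profiles,
         delta = delta, groups = groups, group_features = feat,
         local = local, enhancers = enhRes, report = report)
  }, error = function(e) {
    if (inherits(e, "cohesinHiC_config_error")) stop(e)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
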