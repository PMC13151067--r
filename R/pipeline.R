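#' @include selection-sim.R ngs-ingest.R enrichment.R features.R kinetics.R
NULL

#' Default pipeline configuration
#'
#' A fully explicit configuration list for [runPipeline()]; every setting the
#' pipeline consumes appears here, nothing is hidden. Serializable to YAML.
#'
#' @param seed campaign seed.
#' @param schema `"CX12C"` or `"CX10AcrK"`, or a schema YAML path.
#' @param depth sequencing depth per round.
#' @param nClones,nBinders naive library composition.
#' @param mode `"counts"` (direct count tables) or `"fastq"` (write FASTQ and
#'   re-ingest them).
#' @param topN peptides carried into featurization/embedding.
#' @param threshold consensus candidate frequency threshold.
#' @param kinetics optional list (`kon`, `koff`, `rmax`, `concentrations`,
#'   `noiseSd`) switching on the sensorgram simulation + global fit stage.
#' @return named list.
#' @export
defaultPipelineConfig <- function(seed = 1L, schema = "CX12C", depth = 1e5,
                                  nClones = 10000L, nBinders = 5L,
                                  mode = "counts", topN = 100L,
                                  threshold = 0.001, kinetics = NULL) {
  list(seed = seed, schema = schema, depth = depth, nClones = nClones,
       nBinders = nBinders, mode = mode, topN = topN, threshold = threshold,
       kinetics = kinetics)
}

.loadPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  need <- c("seed", "schema", "depth", "nClones", "nBinders", "mode",
            "topN", "threshold")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    problems <- c(problems, paste("missing config keys:",
                                  paste(miss, collapse = ", ")))
  }
  if (!is.null(config$mode) && !config$mode %in% c("counts", "fastq")) {
    problems <- c(problems, "mode must be 'counts' or 'fastq'")
  }
  if (!is.null(config$schema) && is.character(config$schema) &&
      !config$schema %in% c("CX12C", "CX10AcrK") &&
      !file.exists(config$schema)) {
    problems <- c(problems, paste0("schema '", config$schema,
                                   "' is neither built-in nor a file"))
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  config
}

.resolveSchema <- function(schema) {
  if (is(schema, "LibrarySchema")) return(schema)
  switch(schema,
         CX12C = schemaCX12C(),
         CX10AcrK = schemaCX10AcrK(),
         readSchema(schema))
}

# md5 of the canonical YAML serialization of the config
.configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config[order(names(config))], tf)
  unname(tools::md5sum(tf))
}

.writeStamped <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config_md5=%s", seed, hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full biopanning analysis pipeline
#'
#' simulate -> (optionally FASTQ round trip through ingest) -> diversity /
#' overlap / consensus -> featurize + embed the top peptides -> (optionally)
#' simulate and fit sensorgrams -> write tables, plots, a run manifest and a
#' markdown report to `outDir`. Every table carries the run seed and config
#' hash in a comment header; rerunning with the same config reproduces
#' identical tables.
#'
#' @param config a config list ([defaultPipelineConfig()]) or YAML path.
#' @param outDir output directory (created if needed).
#' @param makePlots emit PNG figures.
#' @return (invisibly) list with the in-memory stage outputs and `manifestPath`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        makePlots = TRUE) {
  config <- .loadPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(config)
  seed <- as.integer(config$seed)
  schema <- .resolveSchema(config$schema)
  simCfg <- simConfig(schema, nClones = config$nClones,
                      nBinders = config$nBinders, seed = seed,
                      campaigns = defaultCampaigns(depth = config$depth))
  rowCounts <- list()

  if (identical(config$mode, "fastq")) {
    fdir <- file.path(outDir, "fastq")
    camp <- runCampaign(simCfg, output = "fastq", dir = fdir)
    sheet <- demuxSheet(camp$demux$i5, camp$demux$i7, camp$demux$strategy,
                        camp$demux$round)
    ing <- ingestFastq(unname(camp$files), schema, sheet)
    pt <- ing$poolTable
    stats <- ing$stats
    statsDf <- data.frame(metric = c("total", "kept", names(dropped(stats))),
                          reads = c(totalReads(stats), keptReads(stats),
                                    unname(dropped(stats))))
    .writeStamped(statsDf, file.path(outDir, "ingest_stats.tsv"), seed, hash)
  } else {
    camp <- runCampaign(simCfg, output = "counts")
    pt <- camp$poolTable
  }
  rowCounts$poolTable <- nrow(pt)
  writePoolTable(pt, file.path(outDir, "pool_table.tsv"),
                 comments = sprintf("seed=%d config_md5=%s", seed, hash))

  finals <- finalRoundSamples(pt)
  divRows <- lapply(names(finals), function(s) {
    prof <- diversityProfile(pt, sample = finals[[s]])
    cbind(strategy = s, utils::head(prof$rankAbundance, 200L))
  })
  diversity <- do.call(rbind, divRows)
  .writeStamped(diversity, file.path(outDir, "diversity.tsv"), seed, hash)

  venn <- vennRegions(x = pt, samples = unname(finals), weighting = "reads")
  .writeStamped(venn[, c("region", "size", "fraction")],
                file.path(outDir, "venn_regions.tsv"), seed, hash)

  scatter <- abundanceScatter(pt, finals[[1]], finals[[2]])
  .writeStamped(scatter, file.path(outDir, "abundance_scatter.tsv"), seed, hash)

  consensus <- consensusHits(pt, threshold = config$threshold)
  .writeStamped(consensus, file.path(outDir, "consensus_hits.tsv"), seed, hash)
  rowCounts$consensus <- nrow(consensus)

  # top peptides of each final pool, pooled across strategies
  topPeps <- unique(unlist(lapply(unname(finals), function(s) {
    utils::head(diversityProfile(pt, sample = s)$rankAbundance$peptide,
                config$topN)
  })))
  embedding <- NULL
  if (length(topPeps) >= 5L) {
    desc <- descriptorTable(topPeps)
    .writeStamped(desc, file.path(outDir, "descriptors.tsv"), seed, hash)
    embedding <- embedAndCluster(desc, seed = seed)
    .writeStamped(embedding$coords, file.path(outDir, "embedding.tsv"),
                  seed, hash)
    rowCounts$embedding <- nrow(embedding$coords)
  }

  kinFit <- NULL
  if (!is.null(config$kinetics)) {
    kc <- config$kinetics
    grams <- simulateSensorgrams(kc$kon, kc$koff, kc$rmax,
                                 unlist(kc$concentrations),
                                 noiseSd = kc$noiseSd %||% 0, seed = seed)
    writeSensorgrams(grams, file.path(outDir, "sensorgrams.csv"))
    kinFit <- fitGlobal1to1(grams)
    kinDf <- data.frame(parameter = c("kon", "koff", "rmax", "kd", "rmse"),
                        value = c(kinFit@kon, kinFit@koff, kinFit@rmax,
                                  kinFit@kd, kinFit@rmse))
    .writeStamped(kinDf, file.path(outDir, "kinetic_fit.tsv"), seed, hash)
  }

  if (makePlots) {
    .pipelinePlots(outDir, diversity, scatter, embedding)
  }

  manifest <- list(seed = seed, configMd5 = hash, config = config,
                   rowCounts = rowCounts,
                   version = as.character(utils::packageVersion("cycloPan")))
  manifestPath <- file.path(outDir, "run_manifest.yaml")
  yaml::write_yaml(manifest, manifestPath)

  out <- list(poolTable = pt, diversity = diversity, venn = venn,
              scatter = scatter, consensus = consensus,
              embedding = embedding, kineticFit = kinFit,
              manifest = manifest, manifestPath = manifestPath,
              groundTruth = camp$manifest, outDir = outDir)
  reportPath <- file.path(outDir, "report.md")
  writeReport(out, reportPath)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pipelinePlots <- function(outDir, diversity, scatter, embedding) {
  grDevices::png(file.path(outDir, "rank_abundance.png"), 700, 500)
  strat <- unique(diversity$strategy)
  cols <- grDevices::hcl.colors(max(3L, length(strat)), "Dark 3")
  plot(NA, xlim = c(1, max(diversity$rank)), ylim = c(0, 1), log = "x",
       xlab = "peptide rank", ylab = "cumulative abundance fraction",
       main = "Final-round rank-abundance")
  for (i in seq_along(strat)) {
    d <- diversity[diversity$strategy == strat[i], ]
    graphics::lines(d$rank, d$cumFraction, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", strat, col = cols[seq_along(strat)], lwd = 2)
  grDevices::dev.off()

  grDevices::png(file.path(outDir, "abundance_scatter.png"), 600, 600)
  eps <- 0.5 / max(1, sum(scatter$fX > 0))
  regs <- factor(scatter$region)
  plot(scatter$fX + eps, scatter$fY + eps, log = "xy",
       col = as.integer(regs), pch = 16, cex = 0.6,
       xlab = "frequency (X)", ylab = "frequency (Y)",
       main = "Cross-strategy abundance")
  graphics::legend("topleft", levels(regs), col = seq_along(levels(regs)),
                   pch = 16, cex = 0.8)
  grDevices::dev.off()

  if (!is.null(embedding)) {
    grDevices::png(file.path(outDir, "embedding.png"), 600, 600)
    cl <- embedding$coords$cluster
    plot(embedding$coords$dim1, embedding$coords$dim2,
         col = ifelse(cl < 0, "grey60", cl + 1L), pch = 16,
         xlab = "dim 1", ylab = "dim 2",
         main = sprintf("%s embedding of top peptides",
                        toupper(embedding$params$method)))
    grDevices::dev.off()
  }
}

#' Write a human-readable run report
#'
#' Single markdown document summarising diversity, overlap, consensus hits,
#' the embedding and (when present) the kinetic fit; stages without outputs
#' appear as explicit gaps. Regenerating the report from the same outputs is
#' idempotent.
#'
#' @param run output list from [runPipeline()].
#' @param path report path (markdown).
#' @return `path`, invisibly.
#' @export
writeReport <- function(run, path) {
  L <- character()
  add <- function(...) L <<- c(L, ...)
  add("# Biopanning campaign report", "",
      sprintf("Seed: %d; config md5: %s", run$manifest$seed,
              run$manifest$configMd5), "")
  add("## Diversity (final rounds)", "")
  for (s in unique(run$diversity$strategy)) {
    d <- run$diversity[run$diversity$strategy == s, ]
    add(sprintf("- %s: top-1 fraction %.3f, top-5 fraction %.3f", s,
                d$cumFraction[1], d$cumFraction[min(5L, nrow(d))]))
  }
  add("", "## Overlap regions (read-weighted)", "",
      "| region | unique peptides | pool fraction |", "|---|---|---|")
  for (i in seq_len(nrow(run$venn))) {
    add(sprintf("| %s | %d | %.4f |", run$venn$region[i], run$venn$size[i],
                run$venn$fraction[i]))
  }
  add("", "## Consensus hits", "")
  if (nrow(run$consensus)) {
    top <- utils::head(run$consensus, 10L)
    add("| peptide | consensus rank | mean frequency | strategy-restricted |",
        "|---|---|---|---|")
    for (i in seq_len(nrow(top))) {
      add(sprintf("| %s | %s | %.4g | %s |", top$peptide[i],
                  ifelse(is.na(top$consensusRank[i]), "-",
                         top$consensusRank[i]),
                  top$meanFrequency[i], top$strategyRestricted[i]))
    }
  } else {
    add("No consensus candidates above threshold.")
  }
  add("", "## Embedding", "")
  if (!is.null(run$embedding)) {
    cl <- run$embedding$coords$cluster
    add(sprintf("%d peptides embedded (%s); %d cluster(s), %d noise points.",
                nrow(run$embedding$coords), run$embedding$params$method,
                length(unique(cl[cl > 0])), sum(cl < 0)))
  } else {
    add("No embedding (fewer than 5 top peptides).")
  }
  add("", "## Kinetics", "")
  if (!is.null(run$kineticFit)) {
    f <- run$kineticFit
    add(sprintf(
      "Global 1:1 fit: kon %.4g 1/(M*s), koff %.4g 1/s, KD %.4g M, RMSE %.3g nm.",
      f@kon, f@koff, f@kd, f@rmse))
  } else {
    add("No sensorgrams provided; kinetics section empty.")
  }
  writeLines(L, path)
  invisible(path)
}
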