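#' @include AllClasses.R schema.R
NULL

RESINS <- c("streptavidin", "NHS", "GSH")

# i5/i7 index barcodes assigned to (strategy, round) samples, Illumina-style
INDEX_I5 <- c("AGGCTATA", "GCCTCTAT", "AGGATAGG", "TCAGAGCC",
              "CTTCGCCT", "TAAGATTA", "ACGTCCTG", "GTCAGTAC")
INDEX_I7 <- c("CGAGTAAT", "TCTCCGGA", "AATGAGCG", "GGAATCTC",
              "TTCTGAAT", "ACGAATTC", "AGCTTCAG", "GCGCATTA")

#' Simulation configuration for a biopanning campaign
#'
#' Bundles the library schema, naive-library composition, the latent-parameter
#' distributions of the generative selection model, sequencing parameters, the
#' RNG seed, and one or more campaign schedules (see [campaignSchedule()]).
#'
#' The selection model, per clone \eqn{i} and round \eqn{r}: target occupancy
#' \eqn{\theta_i = T_r / (T_r + K_{D,i})}; negative-selection pass factor
#' \eqn{(1-\sigma_{i,\rho})^{k_{neg}}} when the round carries a negative
#' selection; capture \eqn{c_i = 1 - (1-\theta_i)(1-\sigma_{i,\rho})(1-c_0)};
#' per-wash retention \eqn{q_i = q_{ns} + (1-q_{ns})\max(\theta_i,
#' \sigma_{i,\rho})} applied \eqn{W_r} times; eluted weight
#' \eqn{e_i = a_i \cdot pass_i \cdot c_i \cdot q_i^{W_r}}; amplification
#' \eqn{a'_i \propto e_i g_i e^{\eta_i}}, \eqn{\eta_i \sim N(0, \tau)}.
#'
#' @param schema a [LibrarySchema-class].
#' @param nClones number of naive background clones.
#' @param nBinders number of planted true binders.
#' @param kdRange range (uM) for planted-binder dissociation constants,
#'   drawn log-uniformly.
#' @param stickinessPrevalence per-resin probability that a clone is resin-sticky.
#' @param stickinessShape Beta shape parameters for sticky clones' sigma.
#' @param stickinessMax upper scale for sigma (sigma = max * Beta draw, < 1).
#' @param fitnessSdLog lognormal sd of per-clone growth fitness.
#' @param tau amplification noise sd (log scale); 0 disables noise.
#' @param c0 baseline (target- and resin-independent) capture probability.
#' @param qNs per-wash retention floor for non-binders.
#' @param kNeg negative-selection strength (exponent on `1 - sigma`).
#' @param targetScale conversion from ug immobilized target to effective
#'   concentration on the occupancy scale (uM per ug).
#' @param abundanceSdLog lognormal sd of naive clone abundances (heavy tail).
#' @param errorRate per-base substitution rate in simulated sequencing.
#' @param qualityChar constant Phred+33 quality character for simulated reads.
#' @param seed integer RNG seed, recorded in every output.
#' @param campaigns named list of campaign schedules ([campaignSchedule()]).
#' @return a `SimConfig` (validated list).
#' @examples
#' cfg <- simConfig(schemaCX12C(), nClones = 100, seed = 1,
#'                  campaigns = defaultCampaigns(depth = 1000))
#' @export
simConfig <- function(schema,
                      nClones = 10000L,
                      nBinders = 5L,
                      kdRange = c(0.05, 5),
                      stickinessPrevalence = 0.05,
                      stickinessShape = c(5, 2),
                      stickinessMax = 0.9,
                      fitnessSdLog = 0.2,
                      tau = 0.3,
                      c0 = 0.01,
                      qNs = 0.8,
                      kNeg = 1,
                      targetScale = 20,
                      abundanceSdLog = 1,
                      errorRate = 1e-3,
                      qualityChar = "I",
                      seed = 1L,
                      campaigns = defaultCampaigns()) {
  cfg <- list(schema = schema, nClones = as.integer(nClones),
              nBinders = as.integer(nBinders), kdRange = kdRange,
              stickinessPrevalence = stickinessPrevalence,
              stickinessShape = stickinessShape, stickinessMax = stickinessMax,
              fitnessSdLog = fitnessSdLog, tau = tau, c0 = c0, qNs = qNs,
              kNeg = kNeg, targetScale = targetScale,
              abundanceSdLog = abundanceSdLog, errorRate = errorRate,
              qualityChar = qualityChar, seed = as.integer(seed),
              campaigns = campaigns)
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  stopifnot(is(cfg$schema, "LibrarySchema"))
  probs <- c(cfg$stickinessPrevalence, cfg$c0, cfg$qNs, cfg$errorRate)
  if (any(probs < 0 | probs > 1)) {
    stop("rates and probabilities must lie in [0, 1]")
  }
  if (cfg$stickinessMax < 0 || cfg$stickinessMax >= 1) {
    stop("stickinessMax must lie in [0, 1)")
  }
  if (cfg$nClones < 1L) stop("need at least one background clone")
  if (cfg$nBinders < 0L) stop("nBinders must be nonnegative")
  if (any(cfg$kdRange <= 0) || cfg$kdRange[1] > cfg$kdRange[2]) {
    stop("kdRange must be positive and ordered")
  }
  if (cfg$tau < 0 || cfg$fitnessSdLog < 0) stop("dispersions must be nonnegative")
  if (!length(cfg$campaigns)) stop("at least one campaign is required")
  for (sch in cfg$campaigns) validateSchedule(sch)
  pairs <- do.call(rbind, lapply(cfg$campaigns, function(s) s[, c("i5", "i7")]))
  if (anyDuplicated(pairs)) stop("index pairs must be unique per (strategy, round)")
  invisible(cfg)
}

#' Build a campaign schedule of selection rounds
#'
#' One row per selection round: resin used, immobilized target amount (ug),
#' wash count, negative-selection flag, sequencing depth, and the (i5, i7)
#' index pair identifying the round in pooled sequencing.
#'
#' @param strategy strategy id (single string).
#' @param resins resin per round (`"streptavidin"`, `"NHS"` or `"GSH"`).
#' @param targetUg immobilized target per round (ug); default mirrors the
#'   decreasing 10, 5, 2, 1 ug stringency ramp.
#' @param washes wash count per round (8 washes in round 1, 10 thereafter).
#' @param negSelect negative-selection flag per round.
#' @param depth sequencing depth per round.
#' @param indexOffset offset into the built-in index sets so parallel
#'   strategies receive disjoint (i5, i7) pairs.
#' @return data.frame with one row per round.
#' @export
campaignSchedule <- function(strategy, resins,
                             targetUg = c(10, 5, 2, 1),
                             washes = c(8L, 10L, 10L, 10L),
                             negSelect = rep(TRUE, length(resins)),
                             depth = 1e5,
                             indexOffset = 0L) {
  nr <- length(resins)
  stopifnot(length(targetUg) == nr, length(washes) == nr, length(negSelect) == nr)
  depth <- rep_len(depth, nr)
  idx <- indexOffset + seq_len(nr)
  data.frame(
    strategy = strategy, round = seq_len(nr), resin = resins,
    targetUg = targetUg, washes = as.integer(washes), negSelect = negSelect,
    depth = depth,
    i5 = INDEX_I5[(idx - 1L) %% length(INDEX_I5) + 1L],
    i7 = INDEX_I7[(idx - 1L) %/% length(INDEX_I5) %% length(INDEX_I7) + 1L],
    stringsAsFactors = FALSE
  )
}

validateSchedule <- function(sch) {
  need <- c("strategy", "round", "resin", "targetUg", "washes", "negSelect",
            "depth", "i5", "i7")
  if (!all(need %in% names(sch))) {
    stop("schedule must have columns ", paste(need, collapse = ", "))
  }
  if (any(sch$targetUg < 0)) stop("targetUg must be nonnegative")
  if (any(sch$washes < 0)) stop("washes must be nonnegative")
  if (any(sch$depth <= 0)) stop("depth must be positive")
  if (!all(sch$resin %in% RESINS)) {
    stop("resin must be one of ", paste(RESINS, collapse = ", "))
  }
  invisible(sch)
}

#' Default three-strategy alternating-resin campaign set
#'
#' Mirrors the parallel selection design used for the 12-mer library: one
#' streptavidin/NHS alternation, one all-GSH strategy, and one GSH/NHS
#' alternation, four rounds each with a 10, 5, 2, 1 ug target ramp and
#' 8, 10, 10, 10 washes.
#'
#' @param depth sequencing depth per round.
#' @return named list of schedules for [simConfig()].
#' @export
defaultCampaigns <- function(depth = 1e5) {
  list(
    strep_nhs = campaignSchedule("strep_nhs",
      c("streptavidin", "NHS", "streptavidin", "NHS"),
      depth = depth, indexOffset = 0L),
    gsh = campaignSchedule("gsh", rep("GSH", 4L), depth = depth,
      indexOffset = 4L),
    gsh_nhs = campaignSchedule("gsh_nhs", c("GSH", "NHS", "GSH", "NHS"),
      depth = depth, indexOffset = 8L)
  )
}

#' Single-resin campaign (streptavidin every round)
#'
#' The low-stringency control design in which resin-sticky parasites are never
#' counter-selected by a resin switch.
#'
#' @param depth sequencing depth per round.
#' @param resin the resin reused in every round.
#' @return named list with one schedule.
#' @export
singleResinCampaign <- function(depth = 1e5, resin = "streptavidin") {
  list(strep_only = campaignSchedule("strep_only", rep(resin, 4L),
                                     depth = depth, indexOffset = 12L))
}

# draw scaffold-valid variable-region DNA for n clones
.drawLibraryDna <- function(n, schema) {
  p <- scaffoldPattern(schema)
  sup <- suppressionMap(schema)
  map <- .codonTokenMap(suppression = sup)
  draw <- function(m) {
    cols <- lapply(seq_len(nrow(p)), function(i) {
      if (p$type[i] == "fixed") rep(p$scheme[i], m)
      else sample(expandDegenerateCodon(p$scheme[i]), m, replace = TRUE)
    })
    do.call(cbind, cols)
  }
  cod <- draw(n)
  # redraw clones hitting an unsuppressed stop until all decode
  repeat {
    bad <- which(rowSums(matrix(is.na(map[cod]), nrow = n)) > 0L)
    if (!length(bad)) break
    cod[bad, ] <- draw(length(bad))
  }
  dna <- do.call(paste0, asplit(cod, 2L))
  tok <- matrix(map[cod], nrow = n)
  multi <- nchar(tok) > 1L
  tok[multi] <- paste0("(", tok[multi], ")")
  list(dna = dna, peptide = do.call(paste0, asplit(tok, 2L)))
}

#' Generate a naive library pool with planted ground truth
#'
#' Draws variable-region DNA position-wise from the schema's codon schemes
#' (clones failing translation or scaffold validation are redrawn), assigns
#' heavy-tailed (lognormal) naive abundances, plants `nBinders` clones with
#' finite, log-uniform dissociation constants, sprinkles resin-specific
#' stickiness, and assigns lognormal growth fitness. Deterministic under the
#' config seed.
#'
#' @param config a [simConfig()].
#' @return a [ClonePool-class] of `nClones + nBinders` clones.
#' @export
generateNaiveLibrary <- function(config) {
  set.seed(config$seed)
  n <- config$nClones + config$nBinders
  lib <- .drawLibraryDna(n, config$schema)
  if (!length(lib$dna)) stop("no clones survived library generation")
  ab <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundanceSdLog)
  ab <- ab / sum(ab)
  kd <- rep(Inf, n)
  if (config$nBinders > 0L) {
    # binders occupy the first nBinders slots; their identity is recorded in
    # the campaign manifest, never leaked to downstream analytics
    kd[seq_len(config$nBinders)] <- exp(stats::runif(
      config$nBinders, log(config$kdRange[1]), log(config$kdRange[2])))
  }
  sig <- matrix(0, nrow = n, ncol = length(RESINS),
                dimnames = list(NULL, RESINS))
  bg <- which(!is.finite(kd))
  for (r in RESINS) {
    sticky <- bg[stats::runif(length(bg)) < config$stickinessPrevalence]
    sig[sticky, r] <- config$stickinessMax *
      stats::rbeta(length(sticky), config$stickinessShape[1],
                   config$stickinessShape[2])
  }
  fit <- stats::rlnorm(n, meanlog = 0, sdlog = config$fitnessSdLog)
  new("ClonePool", dna = lib$dna, peptide = lib$peptide, abundance = ab,
      kd = kd, stickiness = sig, fitness = fit)
}

#' Run one selection round (capture, wash, elution, amplification)
#'
#' Applies the generative update documented in [simConfig()] and returns the
#' pool with post-amplification abundances. With `config$tau == 0` the update
#' is the deterministic expectation.
#'
#' @param pool a [ClonePool-class] (abundances normalized).
#' @param spec one row of a campaign schedule.
#' @param config a [simConfig()].
#' @return the updated [ClonePool-class].
#' @export
runRound <- function(pool, spec, config) {
  sigma <- pool@stickiness[, spec$resin]
  theta <- occupancy(spec$targetUg * config$targetScale, pool@kd)
  pass <- if (isTRUE(spec$negSelect)) (1 - sigma)^config$kNeg else 1
  capture <- 1 - (1 - theta) * (1 - sigma) * (1 - config$c0)
  retention <- config$qNs + (1 - config$qNs) * pmax(theta, sigma)
  eluted <- pool@abundance * pass * capture * retention^spec$washes
  if (all(eluted == 0)) {
    stop("empty elution in ", spec$strategy, " round ", spec$round,
         ": selection too stringent for this pool")
  }
  noise <- if (config$tau > 0) {
    exp(stats::rnorm(length(eluted), 0, config$tau))
  } else 1
  amp <- eluted * pool@fitness * noise
  pool@abundance <- amp / sum(amp)
  pool
}

#' Fractional target occupancy
#'
#' `T / (T + KD)`; zero for non-binders (`KD = Inf`).
#'
#' @param targetConc effective target concentration (uM).
#' @param kd dissociation constant(s) (uM; `Inf` for non-binders).
#' @return occupancy in `[0, 1]`.
#' @export
occupancy <- function(targetConc, kd) {
  ifelse(is.finite(kd), targetConc / (targetConc + kd),
         ifelse(targetConc > 0, 0, 0))
}

#' Draw sequencing counts from a pool
#'
#' Multinomial read counts at the round's depth, aggregated by peptide
#' (distinct DNA encoding the same peptide pools together).
#'
#' @param pool a [ClonePool-class].
#' @param depth number of reads.
#' @return named integer vector (peptide -> count), zero-count peptides
#'   omitted.
#' @export
samplePoolCounts <- function(pool, depth) {
  if (depth <= 0) stop("sequencing depth must be positive")
  cnt <- stats::rmultinom(1L, size = depth, prob = pool@abundance)[, 1L]
  agg <- rowsum(cnt, pool@peptide)
  out <- stats::setNames(as.integer(agg[, 1L]), rownames(agg))
  out[out > 0L]
}

#' Simulate sequencing reads for a pool
#'
#' Draws multinomial counts at the round's depth, assembles each read as
#' `flank5 + variable region + flank3`, applies i.i.d. per-base substitution
#' errors at `config$errorRate`, and attaches an Illumina-convention header
#' carrying the round's `i7+i5` index pair. Quality is a constant configurable
#' character.
#'
#' @param pool a [ClonePool-class].
#' @param spec one schedule row (supplies depth and index pair).
#' @param config a [simConfig()].
#' @return data.frame with columns `id`, `seq`, `qual` (one row per read).
#' @export
sequencePool <- function(pool, spec, config) {
  cnt <- stats::rmultinom(1L, size = spec$depth, prob = pool@abundance)[, 1L]
  keep <- cnt > 0L
  reads <- rep(paste0(flanks(config$schema)["flank5"], pool@dna[keep],
                      flanks(config$schema)["flank3"]), cnt[keep])
  reads <- .addSubstitutionErrors(reads, config$errorRate)
  n <- length(reads)
  ids <- sprintf("SIM:%s:R%d:%d 1:N:0:%s+%s", spec$strategy, spec$round,
                 seq_len(n), spec$i7, spec$i5)
  data.frame(id = ids, seq = reads,
             qual = strrep(config$qualityChar, nchar(reads)),
             stringsAsFactors = FALSE)
}

# i.i.d. per-base substitutions at rate eps (always to a different base)
.addSubstitutionErrors <- function(reads, eps) {
  if (eps <= 0 || !length(reads)) return(reads)
  L <- nchar(reads)
  nerr <- stats::rbinom(length(reads), L, eps)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(L[i], nerr[i])
    chars <- strsplit(reads[i], "")[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Write simulated reads to FASTQ
#'
#' @param reads data.frame from [sequencePool()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Run a full multi-strategy biopanning campaign
#'
#' Chains [runRound()] and sequencing over every schedule in the config. All
#' strategies share one naive pool, as in a real split of a single library.
#' Output is either a [PoolTable-class] of per-(strategy, round) peptide
#' counts (`output = "counts"`) or FASTQ files per round plus a demux sheet
#' (`output = "fastq"`). Either way the ground-truth manifest -- each clone's
#' peptide, latent KD, per-resin stickiness and fitness -- is returned (and
#' written, in FASTQ mode) as the recovery oracle.
#'
#' @param config a [simConfig()].
#' @param output `"counts"` or `"fastq"`.
#' @param dir output directory (FASTQ mode).
#' @return list with `poolTable` (counts mode) or `files` + `demux` (FASTQ
#'   mode), plus `manifest`, `finalPools` (per-strategy [ClonePool-class]s)
#'   and `seed`.
#' @examples
#' cfg <- simConfig(schemaCX12C(), nClones = 200, seed = 7,
#'                  campaigns = defaultCampaigns(depth = 2000))
#' res <- runCampaign(cfg)
#' res$poolTable
#' @export
runCampaign <- function(config, output = c("counts", "fastq"), dir = NULL) {
  output <- match.arg(output)
  naive <- generateNaiveLibrary(config)  # seeds the RNG with config$seed
  manifest <- data.frame(
    peptide = naive@peptide, dna = naive@dna, kd = naive@kd,
    fitness = naive@fitness, naiveAbundance = naive@abundance,
    stringsAsFactors = FALSE
  )
  manifest <- cbind(manifest, as.data.frame(naive@stickiness))
  names(manifest)[6:8] <- paste0("sigma_", RESINS)

  counts <- list(); samples <- list(); files <- character(); demux <- list()
  finalPools <- list()
  if (output == "fastq") {
    if (is.null(dir)) stop("FASTQ output needs an output directory")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  }
  for (sname in names(config$campaigns)) {
    sch <- config$campaigns[[sname]]
    pool <- naive
    for (k in seq_len(nrow(sch))) {
      spec <- sch[k, ]
      pool <- runRound(pool, spec, config)
      sid <- sprintf("%s:R%d", spec$strategy, spec$round)
      if (output == "counts") {
        counts[[sid]] <- samplePoolCounts(pool, spec$depth)
        samples[[sid]] <- data.frame(strategy = spec$strategy,
                                     round = spec$round)
      } else {
        reads <- sequencePool(pool, spec, config)
        fp <- file.path(dir, sprintf("sim_%s_R%d.fastq", spec$strategy,
                                     spec$round))
        writeFastq(reads, fp)
        files[sid] <- fp
        demux[[sid]] <- data.frame(i5 = spec$i5, i7 = spec$i7,
                                   strategy = spec$strategy,
                                   round = spec$round,
                                   stringsAsFactors = FALSE)
      }
    }
    finalPools[[sname]] <- pool
  }
  out <- list(manifest = manifest, finalPools = finalPools, seed = config$seed)
  if (output == "counts") {
    out$poolTable <- poolTableFromCounts(counts, do.call(rbind, samples))
  } else {
    out$files <- files
    out$demux <- do.call(rbind, demux)
    rownames(out$demux) <- NULL
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(out$demux, file.path(dir, "demux.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
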