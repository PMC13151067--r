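#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' LibrarySchema: genotype-to-phenotype decoding for a displayed library
#'
#' A `LibrarySchema` describes how the variable region of a display library is
#' decoded into a macrocyclic peptide: an ordered scaffold pattern of fixed and
#' randomized positions, the degenerate codon scheme at each randomized
#' position, a suppression map reassigning stop codons to non-canonical residue
#' tokens, and the constant flanking DNA on either side of the variable region.
#'
#' Residue positions are 1-based; DNA intervals are 0-based half-open. ncAA
#' tokens are multi-character strings (e.g. `"AcrK"`), never single letters, so
#' extended alphabets stay unambiguous in serialized peptides such as
#' `"CWRVFIWGQGP(AcrK)"`.
#'
#' @slot name single string identifying the schema.
#' @slot pattern data.frame with columns `type` (`"fixed"`/`"random"`),
#'   `token` (required residue token for fixed positions, `NA` otherwise),
#'   `scheme` (IUPAC degenerate codon for random positions, fixed codon for
#'   fixed positions).
#' @slot suppression named character vector: codon -> residue token overrides
#'   applied before stop rejection.
#' @slot flank5,flank3 constant DNA immediately 5' / 3' of the variable region.
#'
#' @examples
#' sch <- schemaCX12C()
#' schemaName(sch)
#' variableRegionLength(sch)
#' @export
setClass("LibrarySchema",
  representation(
    name = "character",
    pattern = "data.frame",
    suppression = "character",
    flank5 = "character",
    flank3 = "character"
  )
)

setValidity("LibrarySchema", function(object) {
  msg <- character()
  p <- object@pattern
  need <- c("type", "token", "scheme")
  if (!all(need %in% names(p))) {
    return(sprintf("pattern must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(p) == 0L) msg <- c(msg, "pattern must have at least one position")
  if (!all(p$type %in% c("fixed", "random"))) {
    msg <- c(msg, "pattern$type must be 'fixed' or 'random'")
  }
  if (!all(nchar(p$scheme) == 3L)) msg <- c(msg, "all codon schemes must be length 3")
  fixed <- p$type == "fixed"
  if (any(fixed) && any(is.na(p$token[fixed]) | !nzchar(p$token[fixed]))) {
    msg <- c(msg, "fixed positions must carry a residue token")
  }
  if (length(object@flank5) != 1L || !nzchar(object@flank5)) {
    msg <- c(msg, "flank5 must be a nonempty string")
  }
  if (length(object@flank3) != 1L || !nzchar(object@flank3)) {
    msg <- c(msg, "flank3 must be a nonempty string")
  }
  if (length(object@suppression)) {
    stops <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
    if (!all(names(object@suppression) %in% stops)) {
      msg <- c(msg, "suppression may only override stop codons (TAA, TAG, TGA)")
    }
    bad <- !nzchar(object@suppression) | object@suppression %in% CANONICAL_RESIDUES
    if (any(bad)) {
      msg <- c(msg, "suppression tokens must be nonempty and not canonical single letters")
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ClonePool: latent state of a selection pool
#'
#' Holds, per clone, the variable-region DNA, the decoded peptide, the current
#' relative abundance, and the latent ground-truth parameters driving the
#' selection simulator: dissociation constant for the target (`Inf` for
#' non-binders, concentration units of micromolar throughout), resin-specific
#' stickiness in `[0, 1)` for each immobilization chemistry, and a
#' multiplicative growth fitness.
#'
#' @slot dna character vector of variable-region DNA.
#' @slot peptide serialized residue-token strings, parallel to `dna`.
#' @slot abundance relative abundances, nonnegative, summing to 1.
#' @slot kd latent dissociation constants (uM); `Inf` marks non-binders.
#' @slot stickiness numeric matrix, one column per resin, entries in `[0, 1)`.
#' @slot fitness positive growth-fitness multipliers.
#' @export
setClass("ClonePool",
  representation(
    dna = "character",
    peptide = "character",
    abundance = "numeric",
    kd = "numeric",
    stickiness = "matrix",
    fitness = "numeric"
  )
)

setValidity("ClonePool", function(object) {
  n <- length(object@dna)
  msg <- character()
  if (length(object@peptide) != n || length(object@abundance) != n ||
      length(object@kd) != n || length(object@fitness) != n ||
      nrow(object@stickiness) != n) {
    return("all per-clone slots must have the same length")
  }
  if (n == 0L) return("pool must contain at least one clone")
  if (any(object@abundance < 0)) msg <- c(msg, "abundances must be nonnegative")
  if (abs(sum(object@abundance) - 1) > 1e-9) {
    msg <- c(msg, "abundances must sum to 1 (tolerance 1e-9)")
  }
  if (any(object@kd <= 0)) msg <- c(msg, "kd must be positive (Inf for non-binders)")
  if (any(object@stickiness < 0 | object@stickiness >= 1)) {
    msg <- c(msg, "stickiness must lie in [0, 1)")
  }
  if (is.null(colnames(object@stickiness))) {
    msg <- c(msg, "stickiness columns must be named by resin")
  }
  if (any(object@fitness <= 0)) msg <- c(msg, "fitness must be positive")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' PoolTable: peptide counts per (strategy, round) sample
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per unique
#' peptide (serialized token string as rowname), one column per sequenced
#' sample, a single `counts` assay of nonnegative integers, and `colData`
#' columns `strategy` and `round`. Frequencies are derived, never stored:
#' `frequencies(x)` divides each column by its total.
#'
#' @export
setClass("PoolTable", contains = "SummarizedExperiment")

setValidity("PoolTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("PoolTable needs a 'counts' assay")
  }
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("strategy", "round") %in% names(cd))) {
    return("colData must carry 'strategy' and 'round'")
  }
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0) || any(m != round(m))) msg <- c(msg, "counts must be nonnegative integers")
  if (nrow(object) > 0L && is.null(rownames(object))) {
    msg <- c(msg, "rownames must hold peptide strings")
  }
  if (anyDuplicated(colnames(object))) msg <- c(msg, "sample names must be unique")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' IngestStats: read accounting through the ingest funnel
#'
#' Tracks every read from raw FASTQ to the count table: `kept` plus the sum of
#' all `dropped` reasons always equals `total`.
#'
#' @slot total total reads seen.
#' @slot kept reads surviving all filters.
#' @slot dropped named integer vector over the drop reasons
#'   `index-unmatched`, `flank-unmatched`, `low-quality`, `frame`, `stop`,
#'   `scaffold-fail`, `ambiguous`.
#' @export
setClass("IngestStats",
  representation(total = "integer", kept = "integer", dropped = "integer")
)

DROP_REASONS <- c("index-unmatched", "flank-unmatched", "low-quality",
                  "frame", "stop", "scaffold-fail", "ambiguous")

setValidity("IngestStats", function(object) {
  if (!identical(sort(names(object@dropped)), sort(DROP_REASONS))) {
    return("dropped must be named by the canonical drop reasons")
  }
  if (object@kept + sum(object@dropped) != object@total) {
    return("kept + sum(dropped) must equal total")
  }
  TRUE
})

#' KineticFit: result of a global 1:1 kinetic fit
#'
#' @slot kon association rate constant (1/(M*s)).
#' @slot koff dissociation rate constant (1/s).
#' @slot rmax saturating response (nm).
#' @slot offsets per-trace baseline offsets (nm).
#' @slot kd equilibrium dissociation constant `koff/kon` (M).
#' @slot stderr named standard errors for kon, koff, rmax (delta method from
#'   the log-scale Jacobian).
#' @slot rmse root-mean-square residual of the global fit (nm).
#' @slot converged logical convergence flag from the optimizer.
#' @slot info optimizer diagnostics (message, iterations, start used).
#' @export
setClass("KineticFit",
  representation(
    kon = "numeric", koff = "numeric", rmax = "numeric",
    offsets = "numeric", kd = "numeric", stderr = "numeric",
    rmse = "numeric", converged = "logical", info = "list"
  )
)

setValidity("KineticFit", function(object) {
  msg <- character()
  if (object@kon <= 0 || object@koff <= 0 || object@rmax <= 0) {
    msg <- c(msg, "kon, koff and rmax must be positive")
  }
  if (abs(object@kd - object@koff / object@kon) >
      1e-12 * max(object@kd, .Machine$double.eps)) {
    msg <- c(msg, "kd must equal koff/kon")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
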