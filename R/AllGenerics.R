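#' @include AllClasses.R
NULL

#' Accessors for cycloPan classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("schemaName", function(x) standardGeneric("schemaName"))
#' @rdname accessors
#' @export
setMethod("schemaName", "LibrarySchema", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("scaffoldPattern", function(x) standardGeneric("scaffoldPattern"))
#' @rdname accessors
#' @export
setMethod("scaffoldPattern", "LibrarySchema", function(x) x@pattern)

#' @rdname accessors
#' @export
setGeneric("suppressionMap", function(x) standardGeneric("suppressionMap"))
#' @rdname accessors
#' @export
setMethod("suppressionMap", "LibrarySchema", function(x) x@suppression)

#' @rdname accessors
#' @export
setGeneric("flanks", function(x) standardGeneric("flanks"))
#' @rdname accessors
#' @export
setMethod("flanks", "LibrarySchema", function(x) {
  c(flank5 = x@flank5, flank3 = x@flank3)
})

#' @rdname accessors
#' @export
setGeneric("variableRegionLength", function(x) standardGeneric("variableRegionLength"))
#' @rdname accessors
#' @export
setMethod("variableRegionLength", "LibrarySchema", function(x) 3L * nrow(x@pattern))

#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))
#' @rdname accessors
#' @export
setMethod("peptides", "ClonePool", function(x) x@peptide)
#' @rdname accessors
#' @export
setMethod("peptides", "PoolTable", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setMethod("abundances", "ClonePool", function(x) {
  stats::setNames(x@abundance, x@peptide)
})

#' @rdname accessors
#' @export
setGeneric("latentKd", function(x) standardGeneric("latentKd"))
#' @rdname accessors
#' @export
setMethod("latentKd", "ClonePool", function(x) stats::setNames(x@kd, x@peptide))

#' @rdname accessors
#' @export
setGeneric("stickiness", function(x) standardGeneric("stickiness"))
#' @rdname accessors
#' @export
setMethod("stickiness", "ClonePool", function(x) x@stickiness)

#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setMethod("frequencies", "PoolTable", function(x) {
  m <- SummarizedExperiment::assay(x, "counts")
  sweep(m, 2L, colSums(m), "/")
})

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setMethod("sampleInfo", "PoolTable", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname accessors
#' @export
setGeneric("dropped", function(x) standardGeneric("dropped"))
#' @rdname accessors
#' @export
setMethod("dropped", "IngestStats", function(x) x@dropped)

#' @rdname accessors
#' @export
setGeneric("keptReads", function(x) standardGeneric("keptReads"))
#' @rdname accessors
#' @export
setMethod("keptReads", "IngestStats", function(x) x@kept)

#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setMethod("totalReads", "IngestStats", function(x) x@total)

#' @rdname accessors
#' @export
setGeneric("kineticParams", function(x) standardGeneric("kineticParams"))
#' @rdname accessors
#' @export
setMethod("kineticParams", "KineticFit", function(x) {
  c(kon = x@kon, koff = x@koff, rmax = x@rmax, kd = x@kd)
})

setMethod("show", "LibrarySchema", function(object) {
  p <- object@pattern
  pat <- ifelse(p$type == "fixed", p$token, sprintf("X[%s]", p$scheme))
  cat("LibrarySchema '", object@name, "'\n", sep = "")
  cat("  pattern (", nrow(p), " positions): ", paste(pat, collapse = "-"), "\n", sep = "")
  if (length(object@suppression)) {
    cat("  suppression:", paste(names(object@suppression), "->",
                                object@suppression, collapse = ", "), "\n")
  } else cat("  suppression: none\n")
  cat("  variable region:", variableRegionLength(object), "nt; flanks",
      nchar(object@flank5), "/", nchar(object@flank3), "nt\n")
})

setMethod("show", "ClonePool", function(object) {
  n <- length(object@dna)
  nb <- sum(is.finite(object@kd))
  cat("ClonePool with", n, "clones (", nb, "finite-Kd binders )\n")
  cat("  resins:", paste(colnames(object@stickiness), collapse = ", "), "\n")
  top <- order(object@abundance, decreasing = TRUE)[seq_len(min(3L, n))]
  cat("  top abundance:", paste(sprintf("%s (%.3g)", object@peptide[top],
                                        object@abundance[top]), collapse = ", "), "\n")
})

setMethod("show", "PoolTable", function(object) {
  cat("PoolTable:", nrow(object), "peptides x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  strategies:", paste(unique(cd$strategy), collapse = ", "), "\n")
  cat("  rounds:", paste(sort(unique(cd$round)), collapse = ", "), "\n")
  cat("  reads/sample:", paste(colSums(SummarizedExperiment::assay(object, "counts")),
                               collapse = ", "), "\n")
})

setMethod("show", "IngestStats", function(object) {
  cat("IngestStats: kept", object@kept, "of", object@total, "reads\n")
  d <- object@dropped[object@dropped > 0]
  if (length(d)) {
    cat("  dropped:", paste(names(d), d, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit (1:1 global): kon = %.4g 1/(M*s), koff = %.4g 1/s\n",
              object@kon, object@koff))
  cat(sprintf("  KD = %.4g M, Rmax = %.3g nm, RMSE = %.3g nm, converged: %s\n",
              object@kd, object@rmax, object@rmse, object@converged))
})
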