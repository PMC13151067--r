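#' @include AllClasses.R
NULL

#' Build a PoolTable from per-sample peptide counts
#'
#' @param counts named list, one element per sample, each a named integer
#'   vector of peptide -> count.
#' @param sampleData data.frame with one row per sample (same order as
#'   `counts`) and columns `strategy`, `round`.
#' @return a [PoolTable-class].
#' @examples
#' poolTableFromCounts(
#'   list("s:R1" = c(CAAAC = 5L, CDDDC = 2L)),
#'   data.frame(strategy = "s", round = 1))
#' @export
poolTableFromCounts <- function(counts, sampleData) {
  stopifnot(length(counts) == nrow(sampleData))
  peps <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  m <- matrix(0L, nrow = length(peps), ncol = length(counts),
              dimnames = list(peps, names(counts)))
  for (j in seq_along(counts)) {
    m[names(counts[[j]]), j] <- as.integer(counts[[j]])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(sampleData, row.names = names(counts))
  )
  new("PoolTable", se)
}

#' Select one sample's counts
#'
#' @param x a [PoolTable-class].
#' @param strategy,round identify the sample; alternatively pass `sample`
#'   as a `"strategy:R<round>"` column name.
#' @param sample sample (column) name.
#' @return named integer vector of nonzero peptide counts.
#' @export
sampleCounts <- function(x, strategy = NULL, round = NULL, sample = NULL) {
  j <- .resolveSample(x, strategy, round, sample)
  m <- SummarizedExperiment::assay(x, "counts")
  cnt <- stats::setNames(as.integer(m[, j]), rownames(m))
  cnt[cnt > 0L]
}

.resolveSample <- function(x, strategy = NULL, round = NULL, sample = NULL) {
  if (!is.null(sample)) {
    if (!sample %in% colnames(x)) stop("no sample '", sample, "'")
    return(sample)
  }
  cd <- SummarizedExperiment::colData(x)
  j <- which(cd$strategy == strategy & cd$round == round)
  if (length(j) != 1L) {
    stop("no unique sample for strategy '", strategy, "' round ", round)
  }
  colnames(x)[j]
}

#' Final-round sample names per strategy
#'
#' @param x a [PoolTable-class].
#' @return named character vector: strategy -> column name of its last round.
#' @export
finalRoundSamples <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  strat <- unique(cd$strategy)
  stats::setNames(vapply(strat, function(s) {
    rows <- which(cd$strategy == s)
    colnames(x)[rows[which.max(cd$round[rows])]]
  }, character(1)), strat)
}

#' Read / write a PoolTable as TSV
#'
#' The on-disk dialect has columns `strategy`, `round`, `peptide`, `count`;
#' leading `#` comment lines are ignored on read and may carry provenance on
#' write. Externally produced peptide-count tables in the same dialect (e.g.
#' transcribed supplementary abundance tables) load through the same reader.
#'
#' @param x a [PoolTable-class].
#' @param path TSV path.
#' @param comments character vector of comment lines (without the `#`).
#' @return `readPoolTable` returns a [PoolTable-class]; `writePoolTable`
#'   returns `path` invisibly.
#' @export
writePoolTable <- function(x, path, comments = character()) {
  m <- SummarizedExperiment::assay(x, "counts")
  cd <- SummarizedExperiment::colData(x)
  rows <- lapply(seq_len(ncol(m)), function(j) {
    nz <- m[, j] > 0L
    data.frame(strategy = cd$strategy[j], round = cd$round[j],
               peptide = rownames(m)[nz], count = m[nz, j],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePoolTable
#' @export
readPoolTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c(peptide = "character"))
  need <- c("strategy", "round", "peptide", "count")
  if (!all(need %in% names(df))) {
    stop("pool table must have columns ", paste(need, collapse = ", "))
  }
  sid <- sprintf("%s:R%d", df$strategy, df$round)
  counts <- lapply(split(df, sid), function(d) {
    stats::setNames(as.integer(d$count), d$peptide)
  })
  sd <- unique(data.frame(sid = sid, strategy = df$strategy, round = df$round,
                          stringsAsFactors = FALSE))
  sd <- sd[match(names(counts), sd$sid), ]
  poolTableFromCounts(counts, sd[, c("strategy", "round")])
}
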