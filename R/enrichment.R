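#' @include AllClasses.R pool-table.R
NULL

#' Rank-abundance diversity profile of one sample
#'
#' Peptides sorted by descending count (ties broken lexicographically by
#' peptide string) with cumulative top-k fractions; the standard readout for
#' judging whether a selection round has collapsed onto a few clones.
#'
#' @param x a [PoolTable-class].
#' @param strategy,round,sample identify the sample (see [sampleCounts()]).
#' @return list with `rankAbundance` (data.frame: `rank`, `peptide`, `count`,
#'   `frequency`, `cumFraction`), `uniqueCount` and `total`.
#' @examples
#' pt <- poolTableFromCounts(list("s:R1" = c(A = 90L, B = 10L)),
#'                           data.frame(strategy = "s", round = 1))
#' diversityProfile(pt, sample = "s:R1")$rankAbundance
#' @export
diversityProfile <- function(x, strategy = NULL, round = NULL, sample = NULL) {
  cnt <- sampleCounts(x, strategy, round, sample)
  if (!length(cnt)) stop("sample is empty")
  ord <- order(-cnt, names(cnt))
  cnt <- cnt[ord]
  total <- sum(cnt)
  df <- data.frame(rank = seq_along(cnt), peptide = names(cnt),
                   count = as.integer(cnt), frequency = as.numeric(cnt) / total,
                   cumFraction = cumsum(as.numeric(cnt)) / total,
                   row.names = NULL, stringsAsFactors = FALSE)
  list(rankAbundance = df, uniqueCount = length(cnt), total = total)
}

#' Cumulative abundance fraction of the top-k peptides
#'
#' @param x a [PoolTable-class].
#' @param k number of top peptides.
#' @param strategy,round,sample identify the sample.
#' @return fraction in `[0, 1]`.
#' @export
topKFraction <- function(x, k, strategy = NULL, round = NULL, sample = NULL) {
  prof <- diversityProfile(x, strategy, round, sample)
  k <- min(k, prof$uniqueCount)
  prof$rankAbundance$cumFraction[k]
}

#' Round-over-round enrichment ratio of a peptide
#'
#' `(f_r + p) / (f_{r-1} + p)` with pseudo-frequency `p = 0.5 / total_{r-1}`
#' (half a read in the earlier round), so de-novo appearances get a finite
#' ratio and a peptide absent from both rounds gets exactly 1.
#'
#' @param x a [PoolTable-class].
#' @param peptide serialized peptide string.
#' @param strategy strategy id.
#' @param round the later round `r` (requires round `r - 1` to exist).
#' @return list with `ratio`, `fPrev`, `fCurr`, `pseudo`.
#' @export
enrichmentRatio <- function(x, peptide, strategy, round) {
  prev <- sampleCounts(x, strategy, round - 1L)
  curr <- sampleCounts(x, strategy, round)
  totPrev <- sum(prev)
  totCurr <- sum(curr)
  if (!totPrev || !totCurr) stop("both rounds must contain reads")
  p <- 0.5 / totPrev
  fPrev <- if (peptide %in% names(prev)) prev[[peptide]] / totPrev else 0
  fCurr <- if (peptide %in% names(curr)) curr[[peptide]] / totCurr else 0
  list(ratio = (fCurr + p) / (fPrev + p), fPrev = fPrev, fCurr = fCurr,
       pseudo = p)
}

# membership key per peptide over k sets, e.g. "110" for in-1, in-2, not-3
.regionKeys <- function(sets) {
  u <- sort(unique(unlist(sets, use.names = FALSE)))
  mem <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) mem <- matrix(mem, nrow = 1L)
  key <- apply(mem, 1L, function(b) paste(as.integer(b), collapse = ""))
  stats::setNames(key, u)
}

#' Exclusive overlap regions of 2 or 3 peptide sets
#'
#' Classic Venn decomposition: each of the `2^k - 1` exclusive regions gets
#' its member peptides, its size, and its pooled abundance fraction. With
#' `weighting = "reads"` (default) a region's fraction is the summed read
#' count of its peptides across all compared samples divided by the total
#' reads of those samples; `weighting = "unique"` uses unique-sequence share
#' of the union instead.
#'
#' @param sets named list of 2 or 3 character vectors (unique peptides per
#'   pool), or `NULL` to derive them from `samples`.
#' @param x optional [PoolTable-class] supplying counts for read weighting.
#' @param samples sample (column) names in `x` to compare (used when `sets`
#'   is `NULL`, and for read weighting).
#' @param weighting `"reads"` or `"unique"`.
#' @return data.frame with columns `region` (e.g. `"A&B"`, exclusive),
#'   `size`, `fraction`, plus a `members` list-column.
#' @examples
#' vennRegions(list(A = c("x", "y"), B = c("y", "z")))
#' @export
vennRegions <- function(sets = NULL, x = NULL, samples = NULL,
                        weighting = c("reads", "unique")) {
  weighting <- match.arg(weighting)
  if (is.null(sets)) {
    stopifnot(!is.null(x), !is.null(samples))
    sets <- lapply(samples, function(s) names(sampleCounts(x, sample = s)))
    names(sets) <- samples
  }
  k <- length(sets)
  if (!k %in% c(2L, 3L)) stop("vennRegions compares 2 or 3 sets")
  if (any(!vapply(sets, length, integer(1)))) stop("sets must be nonempty")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_len(k)]
  keys <- .regionKeys(sets)
  allKeys <- apply(expand.grid(rep(list(c(1L, 0L)), k))[-(2L^k), , drop = FALSE],
                   1L, paste, collapse = "")
  counts <- NULL
  totalReadsAll <- NA_real_
  if (weighting == "reads") {
    if (is.null(x) || is.null(samples)) {
      stop("read weighting needs a PoolTable and sample names")
    }
    m <- SummarizedExperiment::assay(x, "counts")[, samples, drop = FALSE]
    counts <- rowSums(m)
    totalReadsAll <- sum(m)
  }
  rows <- lapply(allKeys, function(kk) {
    members <- names(keys)[keys == kk]
    frac <- if (weighting == "unique") {
      length(members) / length(keys)
    } else {
      sum(counts[members]) / totalReadsAll
    }
    inSets <- names(sets)[strsplit(kk, "")[[1]] == "1"]
    data.frame(region = paste(inSets, collapse = "&"),
               size = length(members), fraction = frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(allKeys, function(kk) names(keys)[keys == kk])
  out
}

#' Paired abundance scatter between two samples
#'
#' Every peptide in the union of two samples, with its frequency in each
#' (zero where absent) and the exclusive Venn region it belongs to, matching
#' the region coloring of [vennRegions()].
#'
#' @param x a [PoolTable-class].
#' @param sampleX,sampleY sample (column) names.
#' @return data.frame with columns `peptide`, `fX`, `fY`, `region`.
#' @export
abundanceScatter <- function(x, sampleX, sampleY) {
  cx <- sampleCounts(x, sample = sampleX)
  cy <- sampleCounts(x, sample = sampleY)
  u <- sort(union(names(cx), names(cy)))
  fx <- ifelse(u %in% names(cx), cx[u] / sum(cx), 0)
  fy <- ifelse(u %in% names(cy), cy[u] / sum(cy), 0)
  region <- ifelse(fx > 0 & fy > 0, paste(sampleX, sampleY, sep = "&"),
                   ifelse(fx > 0, sampleX, sampleY))
  data.frame(peptide = u, fX = unname(fx), fY = unname(fy), region = region,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Consensus hit ranking across parallel selection strategies
#'
#' Candidate peptides are those whose final-round frequency exceeds
#' `threshold` in at least one strategy. Each candidate gets a per-strategy
#' competition rank ("1224"-style) within that strategy's final-round pool,
#' and a consensus rank equal to its worst per-strategy rank -- a peptide must
#' enrich everywhere to rank well. Candidates absent from any strategy's
#' final pool are flagged `strategyRestricted` (parasite suspicion: enrichment
#' tied to one immobilization chemistry) and carry no consensus rank.
#'
#' @param x a [PoolTable-class].
#' @param strategies strategy ids (default: all); at least 2.
#' @param finalRounds optional named vector strategy -> round (default: each
#'   strategy's last round).
#' @param threshold candidate frequency threshold (default 0.001, i.e. 0.1%).
#' @param topN truncate the ranking to the best `topN` consensus hits.
#' @return data.frame: `peptide`, one `rank_<strategy>` column per strategy,
#'   `consensusRank`, `meanFrequency`, `strategyRestricted`; sorted by
#'   consensus rank, ties by mean frequency descending, flagged peptides last.
#' @export
consensusHits <- function(x, strategies = NULL, finalRounds = NULL,
                          threshold = 0.001, topN = Inf) {
  cd <- SummarizedExperiment::colData(x)
  if (is.null(strategies)) strategies <- unique(cd$strategy)
  if (length(strategies) < 2L) stop("consensus needs at least 2 strategies")
  finals <- finalRoundSamples(x)[strategies]
  if (!is.null(finalRounds)) {
    finals <- stats::setNames(sprintf("%s:R%d", strategies,
                                      finalRounds[strategies]), strategies)
  }
  freq <- list(); rank <- list()
  for (s in strategies) {
    cnt <- sampleCounts(x, sample = finals[[s]])
    freq[[s]] <- cnt / sum(cnt)
    rank[[s]] <- base::rank(-cnt, ties.method = "min")
  }
  candidates <- sort(unique(unlist(lapply(strategies, function(s) {
    names(freq[[s]])[freq[[s]] > threshold]
  }))))
  if (!length(candidates)) {
    out <- data.frame(peptide = character(0))
    for (s in strategies) out[[paste0("rank_", s)]] <- integer(0)
    out$consensusRank <- integer(0)
    out$meanFrequency <- numeric(0)
    out$strategyRestricted <- logical(0)
    return(out)
  }
  rk <- sapply(strategies, function(s) {
    r <- rep(NA_integer_, length(candidates))
    hit <- candidates %in% names(rank[[s]])
    r[hit] <- rank[[s]][candidates[hit]]
    r
  })
  rk <- matrix(rk, nrow = length(candidates),
               dimnames = list(candidates, strategies))
  fq <- sapply(strategies, function(s) {
    f <- rep(0, length(candidates))
    hit <- candidates %in% names(freq[[s]])
    f[hit] <- freq[[s]][candidates[hit]]
    f
  })
  fq <- matrix(fq, nrow = length(candidates))
  restricted <- rowSums(is.na(rk)) > 0L
  consensus <- ifelse(restricted, NA_integer_, apply(rk, 1L, max))
  out <- data.frame(peptide = candidates, stringsAsFactors = FALSE)
  for (s in strategies) out[[paste0("rank_", s)]] <- rk[, s]
  out$consensusRank <- consensus
  out$meanFrequency <- rowMeans(fq)
  out$strategyRestricted <- restricted
  ord <- order(restricted, consensus, -out$meanFrequency, out$peptide)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n = if (is.finite(topN)) topN else nrow(out))
}
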