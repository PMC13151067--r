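#' @include AllClasses.R schema.R pool-table.R
NULL

newIngestStats <- function(total = 0L, kept = 0L,
                           dropped = stats::setNames(integer(length(DROP_REASONS)),
                                                     DROP_REASONS)) {
  new("IngestStats", total = as.integer(total), kept = as.integer(kept),
      dropped = dropped)
}

#' Combine ingest statistics
#'
#' @param ... [IngestStats-class] objects.
#' @return the elementwise sum, itself a valid [IngestStats-class].
#' @export
combineStats <- function(...) {
  xs <- list(...)
  newIngestStats(
    total = sum(vapply(xs, totalReads, integer(1))),
    kept = sum(vapply(xs, keptReads, integer(1))),
    dropped = Reduce(`+`, lapply(xs, dropped))
  )
}

#' Build a demultiplexing sheet
#'
#' @param i5,i7 index sequences per sample.
#' @param strategy,round sample identity per index pair.
#' @param tolerance allowed Hamming mismatches per index (0 or 1).
#' @return classed data.frame for [demultiplex()].
#' @export
demuxSheet <- function(i5, i7, strategy, round, tolerance = 0L) {
  if (!tolerance %in% c(0L, 1L)) stop("tolerance must be 0 or 1")
  df <- data.frame(i5 = toupper(i5), i7 = toupper(i7), strategy = strategy,
                   round = as.integer(round), stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("i5", "i7")])) stop("index pairs must be unique")
  attr(df, "tolerance") <- as.integer(tolerance)
  class(df) <- c("DemuxSheet", "data.frame")
  df
}

#' Read FASTQ into an in-memory read set
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] (Phred+33 qualities)
#' returning plain character vectors, the representation all ingest steps
#' consume. Malformed records surface as a parse error naming the file.
#'
#' @param paths FASTQ file path(s).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
readFastqReads <- function(paths) {
  parts <- lapply(paths, function(p) {
    tryCatch({
      x <- Biostrings::readDNAStringSet(p, format = "fastq",
                                        with.qualities = TRUE)
      qual <- S4Vectors::mcols(x)$qualities
      if (any(BiocGenerics::width(qual) != BiocGenerics::width(x))) {
        stop("quality/sequence length mismatch")
      }
      data.frame(id = names(x), seq = as.character(x),
                 qual = as.character(qual), stringsAsFactors = FALSE)
    }, error = function(e) {
      stop("FASTQ parse error in '", p, "': ", conditionMessage(e),
           call. = FALSE)
    })
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# vectorized Hamming distance between equal-length strings and one pattern
.hamming <- function(strings, pattern) {
  n <- nchar(pattern)
  d <- rep.int(n, length(strings))
  ok <- nchar(strings) == n
  if (any(ok)) {
    sm <- do.call(rbind, strsplit(strings[ok], ""))
    pm <- strsplit(pattern, "")[[1]]
    d[ok] <- rowSums(sm != rep(pm, each = sum(ok)))
  }
  d
}

#' Demultiplex reads by (i5, i7) index pair
#'
#' Index pairs are parsed from Illumina-convention headers
#' (`... 1:N:0:<i7>+<i5>`). A read is assigned to the unique sample whose
#' pair lies within the sheet's Hamming tolerance; reads with no header pair,
#' no sample within tolerance, or two equidistant nearest samples are dropped
#' as `index-unmatched`.
#'
#' @param reads data.frame from [readFastqReads()].
#' @param sheet a [demuxSheet()].
#' @return list with `assignment` (character vector, `NA` = unmatched,
#'   otherwise `"strategy:R<round>"`) and `stats` ([IngestStats-class]
#'   counting only the index-unmatched drops at this stage).
#' @export
demultiplex <- function(reads, sheet) {
  tol <- attr(sheet, "tolerance")
  m <- regmatches(reads$id, regexec("[0-9]:[A-Z]:[0-9]+:([ACGTN]+)\\+([ACGTN]+)", reads$id))
  i7 <- vapply(m, function(g) if (length(g) == 3L) g[2] else NA_character_,
               character(1))
  i5 <- vapply(m, function(g) if (length(g) == 3L) g[3] else NA_character_,
               character(1))
  n <- nrow(reads)
  dist <- matrix(NA_integer_, nrow = n, ncol = nrow(sheet))
  parsed <- !is.na(i7) & !is.na(i5)
  for (k in seq_len(nrow(sheet))) {
    d <- rep.int(NA_integer_, n)
    d[parsed] <- .hamming(i7[parsed], sheet$i7[k]) +
      .hamming(i5[parsed], sheet$i5[k])
    dist[, k] <- d
  }
  assignment <- rep(NA_character_, n)
  if (any(parsed)) {
    dsub <- dist[parsed, , drop = FALSE]
    best <- apply(dsub, 1L, min)
    nbest <- rowSums(dsub == best)
    ok <- best <= tol & nbest == 1L
    sid <- sprintf("%s:R%d", sheet$strategy, sheet$round)
    assignment[which(parsed)[ok]] <- sid[apply(dsub[ok, , drop = FALSE], 1L,
                                               which.min)]
  }
  drops <- stats::setNames(integer(length(DROP_REASONS)), DROP_REASONS)
  drops["index-unmatched"] <- sum(is.na(assignment))
  list(assignment = assignment,
       stats = newIngestStats(total = n, kept = sum(!is.na(assignment)),
                              dropped = drops))
}

#' Extract the variable region of one read
#'
#' Locates the schema's 5' flank (exact, or with at most `flankMismatch`
#' substitutions), takes the following `variableRegionLength(schema)` window,
#' and verifies the 3' flank follows. The window's mean Phred quality must
#' meet `minQ`.
#'
#' @param seq read sequence.
#' @param qual Phred+33 quality string.
#' @param schema a [LibrarySchema-class].
#' @param minQ minimum mean Phred quality of the window.
#' @param flankMismatch allowed substitutions per flank (0 or 1).
#' @return list with `status` (`"ok"`, `"flank-unmatched"` or
#'   `"low-quality"`) and on success `window` (the DNA substring).
#' @export
extractVariableRegion <- function(seq, qual, schema, minQ = 20,
                                  flankMismatch = 0L) {
  r <- .extractMany(seq, qual, schema, minQ, flankMismatch)
  if (r$status == "ok") list(status = "ok", window = r$window)
  else list(status = r$status, window = NA_character_)
}

# vectorized extraction; returns list(window = chr NA-on-reject, status = chr)
.extractMany <- function(seqs, quals, schema, minQ = 20, flankMismatch = 0L) {
  n <- length(seqs)
  L <- variableRegionLength(schema)
  fl <- flanks(schema)
  status <- rep("flank-unmatched", n)
  window <- rep(NA_character_, n)
  if (!n) return(list(window = window, status = status))
  subj <- Biostrings::DNAStringSet(seqs)
  m5 <- Biostrings::vmatchPattern(fl["flank5"], subj,
                                  max.mismatch = flankMismatch)
  starts <- vapply(as.list(m5), function(ir) {
    if (length(ir) >= 1L) BiocGenerics::start(ir)[1L] else NA_integer_
  }, integer(1))
  f5end <- starts + nchar(fl["flank5"]) - 1L
  wstart <- f5end + 1L
  wend <- f5end + L
  found <- !is.na(starts) & wend + nchar(fl["flank3"]) <= nchar(seqs)
  if (any(found)) {
    f3obs <- substr(seqs[found], wend[found] + 1L,
                    wend[found] + nchar(fl["flank3"]))
    f3ok <- .hamming(f3obs, unname(fl["flank3"])) <= flankMismatch
    idx <- which(found)[f3ok]
    if (length(idx)) {
      qwin <- substr(quals[idx], wstart[idx], wend[idx])
      meanq <- vapply(qwin, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
                      USE.NAMES = FALSE)
      lowq <- meanq < minQ
      status[idx[lowq]] <- "low-quality"
      good <- idx[!lowq]
      status[good] <- "ok"
      window[good] <- substr(seqs[good], wstart[good], wend[good])
    }
  }
  list(window = window, status = status)
}

#' Build a peptide count table from demultiplexed reads
#'
#' Per sample: extract the variable region, translate it under the schema's
#' suppression map, scaffold-filter, and aggregate identical peptides into
#' counts. Read accounting is conserved: `kept + sum(dropped) == total`.
#'
#' @param reads data.frame from [readFastqReads()].
#' @param assignment per-read sample id (`NA` = unmatched), as produced by
#'   [demultiplex()].
#' @param sheet the [demuxSheet()] (supplies strategy/round per sample).
#' @param schema a [LibrarySchema-class].
#' @param minQ minimum mean window Phred quality.
#' @param flankMismatch allowed substitutions per flank.
#' @return list with `poolTable` ([PoolTable-class]) and `stats`
#'   ([IngestStats-class]).
#' @export
buildPoolTable <- function(reads, assignment, sheet, schema, minQ = 20,
                           flankMismatch = 0L) {
  drops <- stats::setNames(integer(length(DROP_REASONS)), DROP_REASONS)
  drops["index-unmatched"] <- sum(is.na(assignment))
  counts <- list()
  sampleData <- list()
  sids <- sprintf("%s:R%d", sheet$strategy, sheet$round)
  for (k in seq_along(sids)) {
    sid <- sids[k]
    sel <- which(!is.na(assignment) & assignment == sid)
    pep <- character(0)
    if (length(sel)) {
      ext <- .extractMany(reads$seq[sel], reads$qual[sel], schema, minQ,
                          flankMismatch)
      for (reason in c("flank-unmatched", "low-quality")) {
        drops[reason] <- drops[reason] + sum(ext$status == reason)
      }
      ok <- ext$status == "ok"
      tr <- .translateMany(ext$window[ok], suppressionMap(schema))
      for (reason in c("frame", "stop", "ambiguous")) {
        drops[reason] <- drops[reason] + sum(tr$status == reason)
      }
      pep <- tr$peptide[tr$status == "ok"]
      if (length(pep)) {
        tab <- table(pep)
        valid <- .matchesScaffoldMany(names(tab), schema)
        drops["scaffold-fail"] <- drops["scaffold-fail"] +
          sum(tab[!valid])
        tab <- tab[valid]
        pep <- rep(names(tab), tab)  # kept reads after scaffold filter
        if (length(tab)) {
          counts[[sid]] <- stats::setNames(as.integer(tab), names(tab))
          sampleData[[sid]] <- data.frame(strategy = sheet$strategy[k],
                                          round = sheet$round[k])
        }
      }
    }
    if (!sid %in% names(counts)) {
      counts[[sid]] <- stats::setNames(integer(0), character(0))
      sampleData[[sid]] <- data.frame(strategy = sheet$strategy[k],
                                      round = sheet$round[k])
    }
  }
  kept <- sum(vapply(counts, sum, numeric(1)))
  stats <- newIngestStats(total = nrow(reads), kept = kept, dropped = drops)
  list(poolTable = poolTableFromCounts(counts, do.call(rbind, sampleData)),
       stats = stats)
}

#' One-call FASTQ ingest
#'
#' [readFastqReads()] + [demultiplex()] + [buildPoolTable()].
#'
#' @param paths FASTQ file path(s).
#' @param schema a [LibrarySchema-class].
#' @param sheet a [demuxSheet()].
#' @param minQ minimum mean window Phred quality.
#' @param flankMismatch allowed substitutions per flank.
#' @return list with `poolTable` and `stats`.
#' @export
ingestFastq <- function(paths, schema, sheet, minQ = 20, flankMismatch = 0L) {
  reads <- readFastqReads(paths)
  dm <- demultiplex(reads, sheet)
  buildPoolTable(reads, dm$assignment, sheet, schema, minQ = minQ,
                 flankMismatch = flankMismatch)
}
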