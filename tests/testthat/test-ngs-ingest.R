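toySheet <- function(tolerance = 0L) {
  demuxSheet(i5 = c("AGGCTATA", "GCCTCTAT"),
             i7 = c("CGAGTAAT", "CGAGTAAT"),
             strategy = c("s1", "s1"), round = c(1L, 2L),
             tolerance = tolerance)
}

readWith <- function(i7, i5, seq, qual = strrep("I", nchar(seq))) {
  data.frame(id = sprintf("X:1 1:N:0:%s+%s", i7, i5), seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

test_that("demultiplexing assigns by nearest index pair and drops ties", {
  schema <- schemaCX12C()
  fl <- flanks(schema)
  body <- paste0(fl["flank5"], strrep("GCT", 14), fl["flank3"])
  exact <- readWith("CGAGTAAT", "AGGCTATA", body)
  oneOff <- readWith("CGAGTAAC", "AGGCTATA", body)
  # AGGCTATA vs GCCTCTAT differ at many positions; a read halfway between
  # two sheet rows in i5 cannot arise at tolerance 1, so build an exact tie:
  # i5 differs from both sheet entries by >1 under same i7
  tieSheet <- demuxSheet(i5 = c("AAAAAAAA", "AAAAAATT"),
                         i7 = c("CGAGTAAT", "CGAGTAAT"),
                         strategy = c("a", "b"), round = c(1L, 1L),
                         tolerance = 1L)
  tie <- readWith("CGAGTAAT", "AAAAAAAT", body)

  d0 <- demultiplex(exact, toySheet(0L))
  expect_identical(d0$assignment, "s1:R1")
  d1 <- demultiplex(oneOff, toySheet(0L))
  expect_true(is.na(d1$assignment))
  d2 <- demultiplex(oneOff, toySheet(1L))
  expect_identical(d2$assignment, "s1:R1")
  dt <- demultiplex(tie, tieSheet)
  expect_true(is.na(dt$assignment))
  expect_identical(unname(dropped(dt$stats)["index-unmatched"]), 1L)
})

test_that("variable-region extraction honors flanks and quality threshold", {
  schema <- schemaCX12C()
  fl <- flanks(schema)
  vr <- strrep("GCT", 14)
  good <- paste0(fl["flank5"], vr, fl["flank3"])
  r <- extractVariableRegion(good, strrep("I", nchar(good)), schema)
  expect_identical(r$status, "ok")
  expect_identical(r$window, vr)
  # missing 5' flank
  r2 <- extractVariableRegion(paste0(strrep("A", 20), vr, fl["flank3"]),
                              strrep("I", 82), schema)
  expect_identical(r2$status, "flank-unmatched")
  # low-quality window: '#' is Phred 2
  qual <- paste0(strrep("I", nchar(fl["flank5"])), strrep("#", nchar(vr)),
                 strrep("I", nchar(fl["flank3"])))
  r3 <- extractVariableRegion(good, qual, schema, minQ = 20)
  expect_identical(r3$status, "low-quality")
  # one flank mismatch tolerated when allowed
  mut <- good
  substr(mut, 1, 1) <- "T"
  expect_identical(extractVariableRegion(mut, strrep("I", nchar(mut)),
                                         schema)$status, "flank-unmatched")
  expect_identical(extractVariableRegion(mut, strrep("I", nchar(mut)), schema,
                                         flankMismatch = 1L)$status, "ok")
})

test_that("clean reads of one clone aggregate to a single count", {
  schema <- schemaCX12C()
  fl <- flanks(schema)
  vr <- strrep("GCT", 14)  # CAAAA...C? no: GCT = A; need C..C scaffold
  vr <- paste0("TGT", strrep("GCT", 12), "TGT")
  body <- paste0(fl["flank5"], vr, fl["flank3"])
  reads <- do.call(rbind, replicate(100, readWith("CGAGTAAT", "AGGCTATA", body),
                                    simplify = FALSE))
  out <- buildPoolTable(reads, rep("s1:R1", 100), toySheet(), schema)
  cnt <- sampleCounts(out$poolTable, sample = "s1:R1")
  expect_identical(unname(cnt), 100L)
  expect_identical(names(cnt), paste0("C", strrep("A", 12), "C"))
  expect_identical(keptReads(out$stats), 100L)
})

test_that("reads with internal stops are dropped under the stop reason", {
  schema <- schemaCX12C()
  fl <- flanks(schema)
  vr <- paste0("TGT", "TAA", strrep("GCT", 11), "TGT")
  body <- paste0(fl["flank5"], vr, fl["flank3"])
  reads <- readWith("CGAGTAAT", "AGGCTATA", body)
  out <- buildPoolTable(reads, "s1:R1", toySheet(), schema)
  expect_identical(unname(dropped(out$stats)["stop"]), 1L)
  expect_identical(keptReads(out$stats), 0L)
})

test_that("read accounting is conserved on fuzzed inputs", {
  schema <- schemaCX12C()
  for (seed in 1:6) {
    sheet <- toySheet(0L)
    reads <- makeFuzzedReads(seed, sheet, schema, n = 250L)
    dm <- demultiplex(reads, sheet)
    out <- buildPoolTable(reads, dm$assignment, sheet, schema)
    st <- out$stats
    expect_identical(keptReads(st) + sum(dropped(st)), totalReads(st))
    expect_identical(totalReads(st), 250L)
    # kept reads equal the pool table mass
    expect_identical(keptReads(st),
                     as.integer(sum(SummarizedExperiment::assay(out$poolTable,
                                                                "counts"))))
  }
})

test_that("ingest is order-independent", {
  schema <- schemaCX12C()
  sheet <- toySheet(0L)
  reads <- makeFuzzedReads(42, sheet, schema, n = 200L)
  dm <- demultiplex(reads, sheet)
  out1 <- buildPoolTable(reads, dm$assignment, sheet, schema)
  set.seed(1)
  perm <- sample(nrow(reads))
  out2 <- buildPoolTable(reads[perm, ], dm$assignment[perm], sheet, schema)
  expect_identical(
    SummarizedExperiment::assay(out1$poolTable, "counts"),
    SummarizedExperiment::assay(out2$poolTable, "counts"))
})

test_that("error-free FASTQ round-trip recovers the emitted counts exactly", {
  cfg <- simConfig(schemaCX12C(), nClones = 300, seed = 23, errorRate = 0,
                   campaigns = defaultCampaigns(depth = 2000))
  dir <- tempfile()
  camp <- runCampaign(cfg, output = "fastq", dir = dir)
  sheet <- demuxSheet(camp$demux$i5, camp$demux$i7, camp$demux$strategy,
                      camp$demux$round)
  ing <- ingestFastq(unname(camp$files), cfg$schema, sheet)
  expect_identical(keptReads(ing$stats), totalReads(ing$stats))
  # with the same seed, counts-mode emission consumes the identical RNG
  # stream, so the multinomial draws coincide read for read
  ref <- runCampaign(cfg, output = "counts")
  expect_identical(
    SummarizedExperiment::assay(ing$poolTable, "counts"),
    SummarizedExperiment::assay(ref$poolTable, "counts")[
      rownames(ing$poolTable), colnames(ing$poolTable)])
  unlink(dir, recursive = TRUE)
})

test_that("substitution errors appear at close to the configured rate", {
  cfg <- simConfig(schemaCX12C(), nClones = 50, seed = 29, errorRate = 5e-3,
                   campaigns = defaultCampaigns(depth = 4000))
  pool <- generateNaiveLibrary(cfg)
  spec <- cfg$campaigns$gsh[1, ]
  set.seed(31)
  reads <- sequencePool(pool, spec, cfg)
  fl <- flanks(cfg$schema)
  clean <- paste0(fl["flank5"], pool@dna, fl["flank3"])
  L <- nchar(clean[1])
  pMut <- 1 - (1 - cfg$errorRate)^L
  obs <- mean(!reads$seq %in% clean)
  sd3 <- 3 * sqrt(pMut * (1 - pMut) / nrow(reads))
  expect_lt(abs(obs - pMut), sd3)
})

test_that("malformed FASTQ raises a parse error naming the file", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "II"), bad)  # truncated quality
  expect_error(readFastqReads(bad), "parse error")
})
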