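# shared fixtures, all generated in code

# tiny pool table: two strategies, two rounds each
makeToyPoolTable <- function() {
  poolTableFromCounts(
    list(
      "s1:R1" = c(CAAAC = 50L, CDDDC = 30L, CEEEC = 20L),
      "s1:R2" = c(CAAAC = 90L, CDDDC = 10L),
      "s2:R1" = c(CAAAC = 40L, CFFFC = 60L),
      "s2:R2" = c(CAAAC = 70L, CFFFC = 30L)
    ),
    data.frame(strategy = c("s1", "s1", "s2", "s2"), round = c(1, 2, 1, 2))
  )
}

# descriptor-level two-population fixture: clouds separated by >= 10
# within-population SDs in GRAVY and charge
makeTwoPopulationFixture <- function(seed, n = 30L) {
  set.seed(seed)
  data.frame(
    peptide = sprintf("pep%03d", seq_len(2L * n)),
    gravy = c(stats::rnorm(n, 3, 0.1), stats::rnorm(n, -2, 0.1)),
    charge = c(stats::rnorm(n, -0.2, 0.05), stats::rnorm(n, 3, 0.05)),
    aliphatic = c(stats::rnorm(n, 250, 5), stats::rnorm(n, 20, 5)),
    stringsAsFactors = FALSE
  )
}

# cluster-recovery accuracy against a two-population truth; noise and
# cross-assigned points count as errors
clusterAccuracy <- function(cluster, truth) {
  ok <- 0L
  for (g in unique(truth)) {
    cc <- cluster[truth == g]
    cc <- cc[cc > 0]
    if (length(cc)) ok <- ok + max(table(cc))
  }
  ok / length(truth)
}

# random FASTQ-style read set with valid headers drawn from a demux sheet,
# plus some corrupted reads, for conservation fuzz tests
makeFuzzedReads <- function(seed, sheet, schema, n = 300L) {
  set.seed(seed)
  fl <- flanks(schema)
  L <- variableRegionLength(schema)
  randDna <- function(m, len) {
    vapply(seq_len(m), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    }, character(1))
  }
  k <- sample(nrow(sheet), n, replace = TRUE)
  kind <- sample(c("clean", "noflank", "short", "badindex"), n, TRUE,
                 prob = c(0.5, 0.2, 0.15, 0.15))
  seqs <- character(n)
  ids <- sprintf("FUZZ:%d 1:N:0:%s+%s", seq_len(n), sheet$i7[k], sheet$i5[k])
  for (i in seq_len(n)) {
    seqs[i] <- switch(kind[i],
      clean = paste0(fl["flank5"], randDna(1L, L), fl["flank3"]),
      noflank = randDna(1L, L + nchar(fl["flank5"]) + nchar(fl["flank3"])),
      short = paste0(fl["flank5"], randDna(1L, max(1L, L %/% 2L))),
      badindex = paste0(fl["flank5"], randDna(1L, L), fl["flank3"])
    )
    if (kind[i] == "badindex") {
      ids[i] <- sprintf("FUZZ:%d 1:N:0:%s+%s", i,
                        paste(rep("A", nchar(sheet$i7[1])), collapse = ""),
                        paste(rep("T", nchar(sheet$i5[1])), collapse = ""))
    }
  }
  data.frame(id = ids, seq = seqs, qual = strrep("I", nchar(seqs)),
             stringsAsFactors = FALSE)
}

# brute-force per-codon translation oracle (independent of the package path)
oracleTranslate <- function(dna, suppression = character()) {
  if (nchar(dna) %% 3 != 0) return(list(status = "frame"))
  if (grepl("[^ACGT]", dna)) return(list(status = "ambiguous"))
  code <- Biostrings::GENETIC_CODE
  tokens <- character(0)
  for (i in seq(1, nchar(dna), by = 3)) {
    cod <- substr(dna, i, i + 2)
    if (cod %in% names(suppression)) {
      tokens <- c(tokens, suppression[[cod]])
    } else if (code[[cod]] == "*") {
      return(list(status = "stop"))
    } else {
      tokens <- c(tokens, code[[cod]])
    }
  }
  list(status = "ok", tokens = tokens)
}
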