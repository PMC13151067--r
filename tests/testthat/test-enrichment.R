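test_that("diversity profile orders peptides and accumulates fractions", {
  pt <- makeToyPoolTable()
  prof <- diversityProfile(pt, sample = "s1:R1")
  expect_identical(prof$rankAbundance$peptide, c("CAAAC", "CDDDC", "CEEEC"))
  expect_equal(prof$rankAbundance$cumFraction, c(0.5, 0.8, 1.0))
  expect_equal(topKFraction(pt, 1, sample = "s1:R2"), 0.9)
  # ties broken lexicographically; equal counts give top-k = k/n
  ptEq <- poolTableFromCounts(list("e:R1" = c(CB = 5L, CA = 5L, CC = 5L)),
                              data.frame(strategy = "e", round = 1))
  profEq <- diversityProfile(ptEq, sample = "e:R1")
  expect_identical(profEq$rankAbundance$peptide, c("CA", "CB", "CC"))
  for (k in 1:3) expect_equal(topKFraction(ptEq, k, sample = "e:R1"), k / 3)
  # monotone, reaching 1 at the unique count
  fr <- vapply(1:3, topKFraction, numeric(1), x = pt, sample = "s1:R1")
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[3], 1)
})

test_that("enrichment ratios use the half-read pseudo-count", {
  pt <- poolTableFromCounts(
    list("s:R1" = c(CA = 1L, CB = 999L), "s:R2" = c(CA = 100L, CB = 900L)),
    data.frame(strategy = c("s", "s"), round = c(1, 2)))
  r <- enrichmentRatio(pt, "CA", "s", 2)
  expect_equal(r$ratio, (0.1 + 0.0005) / (0.001 + 0.0005))
  # absent in both rounds: pseudo-count symmetry gives exactly 1
  expect_equal(enrichmentRatio(pt, "CZZZC", "s", 2)$ratio, 1)
  # de-novo appearance stays finite
  r2 <- enrichmentRatio(pt, "CB", "s", 2)
  expect_true(is.finite(r2$ratio))
  expect_error(enrichmentRatio(pt, "CA", "s", 3), "no unique sample")
})

test_that("venn regions decompose exactly and sum to the union", {
  v <- vennRegions(list(A = c("a", "b"), B = c("b", "c"), C = c("b", "d")),
                   weighting = "unique")
  get <- function(region) v$size[v$region == region]
  expect_identical(get("A&B&C"), 1L)
  expect_identical(get("A"), 1L)
  expect_identical(get("B"), 1L)
  expect_identical(get("C"), 1L)
  expect_identical(sum(v$size), 4L)
  # disjoint sets: all intersection regions empty
  v2 <- vennRegions(list(A = "x", B = "y"), weighting = "unique")
  expect_identical(v2$size[v2$region == "A&B"], 0L)
})

test_that("venn regions match a brute-force membership oracle on random triples", {
  set.seed(97)
  for (i in 1:200) {
    universe <- sprintf("p%02d", 1:25)
    sets <- lapply(1:3, function(j) sample(universe, sample(3:15, 1)))
    names(sets) <- c("A", "B", "C")
    v <- vennRegions(sets, weighting = "unique")
    u <- unique(unlist(sets))
    # oracle: classify every union member by direct membership tests
    oracle <- table(vapply(u, function(p) {
      paste(names(sets)[vapply(sets, function(s) p %in% s, logical(1))],
            collapse = "&")
    }, character(1)))
    for (k in seq_len(nrow(v))) {
      expected <- if (v$region[k] %in% names(oracle)) {
        as.integer(oracle[[v$region[k]]])
      } else 0L
      expect_identical(v$size[k], expected)
    }
    expect_identical(sum(v$size), length(u))
    # exclusive regions are pairwise disjoint
    mem <- v$members[lengths(v$members) > 0]
    expect_identical(anyDuplicated(unlist(mem)), 0L)
  }
})

test_that("read-weighted region fractions divide pooled counts by pooled totals", {
  pt <- poolTableFromCounts(
    list("x:R1" = c(CA = 60L, CB = 40L), "y:R1" = c(CB = 10L, CC = 90L)),
    data.frame(strategy = c("x", "y"), round = c(1, 1)))
  v <- vennRegions(x = pt, samples = c("x:R1", "y:R1"), weighting = "reads")
  shared <- v$fraction[v$region == "x:R1&y:R1"]
  expect_equal(shared, (40 + 10) / 200)
  expect_equal(sum(v$fraction), 1)
})

test_that("abundance scatter pairs frequencies with venn-consistent regions", {
  pt <- makeToyPoolTable()
  sc <- abundanceScatter(pt, "s1:R2", "s2:R2")
  expect_identical(sc$fY[sc$peptide == "CDDDC"], 0)
  expect_equal(sc$fX[sc$peptide == "CAAAC"], 0.9)
  expect_equal(sc$fY[sc$peptide == "CAAAC"], 0.7)
  expect_identical(sc$region[sc$peptide == "CDDDC"], "s1:R2")
  expect_identical(sc$region[sc$peptide == "CAAAC"], "s1:R2&s2:R2")
  # identical samples sit on the diagonal
  sc2 <- abundanceScatter(pt, "s1:R2", "s1:R2")
  expect_equal(sc2$fX, sc2$fY)
})

test_that("consensus ranking takes the worst per-strategy rank and flags restricted peptides", {
  pt <- poolTableFromCounts(
    list("a:R4" = c(CAAA = 500L, CBBB = 300L, CCCC = 200L),
         "b:R4" = c(CAAA = 600L, CBBB = 150L, CDDD = 250L),
         "c:R4" = c(CAAA = 700L, CBBB = 200L, CCCC = 100L)),
    data.frame(strategy = c("a", "b", "c"), round = c(4, 4, 4)))
  ch <- consensusHits(pt)
  expect_identical(ch$peptide[1], "CAAA")
  expect_identical(ch$consensusRank[1], 1L)
  # CBBB: ranks 2, 3, 2 -> consensus 3
  expect_identical(ch$consensusRank[ch$peptide == "CBBB"], 3L)
  # CCCC absent from strategy b -> flagged, no consensus rank
  expect_true(ch$strategyRestricted[ch$peptide == "CCCC"])
  expect_true(is.na(ch$consensusRank[ch$peptide == "CCCC"]))
  # consensus rank >= every per-strategy rank
  done <- !ch$strategyRestricted
  rkCols <- paste0("rank_", c("a", "b", "c"))
  expect_true(all(ch$consensusRank[done] >=
                    apply(ch[done, rkCols], 1, max)))
})

test_that("consensus is invariant to input order and count rescaling", {
  pt <- makeToyPoolTable()
  ch1 <- consensusHits(pt, threshold = 0)
  # scale one sample's counts uniformly
  cnts <- list(
    "s1:R1" = sampleCounts(pt, sample = "s1:R1"),
    "s1:R2" = sampleCounts(pt, sample = "s1:R2") * 7L,
    "s2:R1" = sampleCounts(pt, sample = "s2:R1"),
    "s2:R2" = sampleCounts(pt, sample = "s2:R2")
  )
  pt2 <- poolTableFromCounts(cnts, sampleInfo(pt))
  ch2 <- consensusHits(pt2, threshold = 0)
  expect_identical(ch1$peptide, ch2$peptide)
  expect_identical(ch1$consensusRank, ch2$consensusRank)
  # permute peptide order in construction
  perm <- list(
    "s1:R1" = rev(sampleCounts(pt, sample = "s1:R1")),
    "s1:R2" = rev(sampleCounts(pt, sample = "s1:R2")),
    "s2:R1" = rev(sampleCounts(pt, sample = "s2:R1")),
    "s2:R2" = rev(sampleCounts(pt, sample = "s2:R2"))
  )
  ch3 <- consensusHits(poolTableFromCounts(perm, sampleInfo(pt)),
                       threshold = 0)
  expect_identical(ch1$peptide, ch3$peptide)
  expect_identical(ch1$consensusRank, ch3$consensusRank)
})

test_that("pool tables round-trip through the TSV dialect", {
  pt <- makeToyPoolTable()
  tf <- tempfile(fileext = ".tsv")
  writePoolTable(pt, tf, comments = "seed=1")
  back <- readPoolTable(tf)
  expect_identical(
    SummarizedExperiment::assay(back, "counts")[rownames(pt), colnames(pt)],
    SummarizedExperiment::assay(pt, "counts"))
  expect_true(startsWith(readLines(tf, n = 1), "#"))
})
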