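smallConfig <- function(seed = 1L, ...) {
  simConfig(schemaCX12C(), nClones = 300L, nBinders = 3L, seed = seed,
            campaigns = defaultCampaigns(depth = 3000), ...)
}

test_that("naive library is scaffold-valid, normalized and seeded", {
  cfg <- simConfig(schemaCX12C(), nClones = 1000L, nBinders = 5L, seed = 5,
                   kdRange = c(0.05, 5))
  pool <- generateNaiveLibrary(cfg)
  peps <- peptides(pool)
  expect_length(peps, 1005L)
  expect_true(all(startsWith(peps, "C") & endsWith(peps, "C")))
  expect_true(all(nchar(peps) == 14L))
  expect_equal(sum(abundances(pool)), 1, tolerance = 1e-12)
  expect_identical(sum(is.finite(latentKd(pool))), 5L)
  kds <- latentKd(pool)[is.finite(latentKd(pool))]
  expect_true(all(kds >= 0.05 & kds <= 5))
  # determinism: same seed, byte-identical pool
  pool2 <- generateNaiveLibrary(cfg)
  expect_identical(pool, pool2)
})

test_that("round update follows the occupancy/wash/elution arithmetic", {
  # two clones, theta = (0.9, 0.1), no stickiness, no washes, no noise:
  # posterior abundance proportional to a * theta
  pool <- new("ClonePool", dna = c("TGT", "TGT"), peptide = c("A", "B"),
              abundance = c(0.5, 0.5), kd = c(1 / 9, 9),
              stickiness = matrix(0, 2, 3,
                                  dimnames = list(NULL, c("streptavidin",
                                                          "NHS", "GSH"))),
              fitness = c(1, 1))
  cfg <- simConfig(schemaCX12C(), nClones = 10, tau = 0, c0 = 0, qNs = 0.5,
                   targetScale = 1)
  spec <- data.frame(strategy = "s", round = 1, resin = "streptavidin",
                     targetUg = 1, washes = 0L, negSelect = FALSE, depth = 10,
                     i5 = "A", i7 = "A")
  out <- runRound(pool, spec, cfg)
  expect_equal(unname(abundances(out)), c(0.9, 0.1), tolerance = 1e-12)
})

test_that("non-binders with zero stickiness and zero baseline elute nothing", {
  pool <- new("ClonePool", dna = c("TGT", "TGT"), peptide = c("A", "B"),
              abundance = c(0.5, 0.5), kd = c(0.1, Inf),
              stickiness = matrix(0, 2, 3,
                                  dimnames = list(NULL, c("streptavidin",
                                                          "NHS", "GSH"))),
              fitness = c(1, 1))
  cfg <- simConfig(schemaCX12C(), nClones = 10, tau = 0, c0 = 0)
  spec <- data.frame(strategy = "s", round = 1, resin = "GSH", targetUg = 1,
                     washes = 2L, negSelect = FALSE, depth = 10,
                     i5 = "A", i7 = "A")
  out <- runRound(pool, spec, cfg)
  expect_equal(unname(abundances(out))[2], 0)
  # all-zero elution raises the over-stringency error
  pool@kd <- c(Inf, Inf)
  expect_error(runRound(pool, spec, cfg), "empty elution")
})

test_that("noise-free multi-round frequencies match a closed-form iteration", {
  cfg <- smallConfig(seed = 21, tau = 0)
  pool <- generateNaiveLibrary(cfg)
  sch <- cfg$campaigns$strep_nhs
  # independent closed-form iteration of the update rule
  a <- pool@abundance
  for (k in seq_len(nrow(sch))) {
    sp <- sch[k, ]
    sigma <- pool@stickiness[, sp$resin]
    theta <- ifelse(is.finite(pool@kd),
                    sp$targetUg * cfg$targetScale /
                      (sp$targetUg * cfg$targetScale + pool@kd), 0)
    pass <- (1 - sigma)^cfg$kNeg
    cap <- 1 - (1 - theta) * (1 - sigma) * (1 - cfg$c0)
    ret <- cfg$qNs + (1 - cfg$qNs) * pmax(theta, sigma)
    w <- a * pass * cap * ret^sp$washes * pool@fitness
    a <- w / sum(w)
  }
  sim <- pool
  for (k in seq_len(nrow(sch))) sim <- runRound(sim, sch[k, ], cfg)
  expect_equal(unname(sim@abundance), unname(a), tolerance = 1e-12)
})

test_that("weaker binders never elute more, all else equal", {
  cfg <- smallConfig(seed = 2, tau = 0)
  kds <- c(0.01, 0.1, 1, 10, 1e6, Inf)
  pool <- new("ClonePool", dna = rep("TGT", 6), peptide = LETTERS[1:6],
              abundance = rep(1 / 6, 6), kd = kds,
              stickiness = matrix(0, 6, 3,
                                  dimnames = list(NULL, c("streptavidin",
                                                          "NHS", "GSH"))),
              fitness = rep(1, 6))
  spec <- data.frame(strategy = "s", round = 1, resin = "NHS", targetUg = 2,
                     washes = 5L, negSelect = TRUE, depth = 10,
                     i5 = "A", i7 = "A")
  out <- runRound(pool, spec, cfg)
  expect_true(all(diff(unname(abundances(out))) <= 1e-15))
})

test_that("a planted binder strictly gains frequency each round, noise-free", {
  cfg <- simConfig(schemaCX12C(), nClones = 500, nBinders = 1, seed = 8,
                   kdRange = c(0.1, 0.1), tau = 0,
                   campaigns = defaultCampaigns(depth = 1e4))
  pool <- generateNaiveLibrary(cfg)
  b <- which(is.finite(pool@kd))
  freqs <- numeric(0)
  sch <- cfg$campaigns$gsh
  for (k in seq_len(nrow(sch))) {
    pool <- runRound(pool, sch[k, ], cfg)
    freqs <- c(freqs, pool@abundance[b])
  }
  expect_true(all(diff(freqs) > 0))
})

test_that("sequencing counts land within binomial bounds and reads carry the index pair", {
  pool <- new("ClonePool", dna = c(strrep("TGT", 14), strrep("GCT", 14)),
              peptide = c("A", "B"), abundance = c(0.9, 0.1),
              kd = c(Inf, Inf),
              stickiness = matrix(0, 2, 3,
                                  dimnames = list(NULL, c("streptavidin",
                                                          "NHS", "GSH"))),
              fitness = c(1, 1))
  cfg <- simConfig(schemaCX12C(), nClones = 10, errorRate = 0, seed = 4)
  spec <- data.frame(strategy = "s", round = 2, resin = "GSH", targetUg = 1,
                     washes = 0L, negSelect = FALSE, depth = 10000,
                     i5 = "AGGCTATA", i7 = "CGAGTAAT")
  set.seed(99)
  reads <- sequencePool(pool, spec, cfg)
  expect_identical(nrow(reads), 10000L)
  fl <- flanks(cfg$schema)
  vrA <- paste0(fl["flank5"], strrep("TGT", 14), fl["flank3"])
  nA <- sum(reads$seq == vrA)
  sd3 <- 3 * sqrt(10000 * 0.9 * 0.1)
  expect_lt(abs(nA - 9000), sd3)
  expect_true(all(reads$seq %in% c(vrA, paste0(fl["flank5"], strrep("GCT", 14),
                                               fl["flank3"]))))
  expect_true(all(grepl("1:N:0:CGAGTAAT\\+AGGCTATA", reads$id)))
})

test_that("eluted weight never exceeds input weight clone-wise", {
  cfg <- smallConfig(seed = 31, tau = 0)
  pool <- generateNaiveLibrary(cfg)
  sp <- cfg$campaigns$gsh[1, ]
  sigma <- pool@stickiness[, sp$resin]
  theta <- ifelse(is.finite(pool@kd),
                  sp$targetUg * cfg$targetScale /
                    (sp$targetUg * cfg$targetScale + pool@kd), 0)
  eluted <- pool@abundance * (1 - sigma)^cfg$kNeg *
    (1 - (1 - theta) * (1 - sigma) * (1 - cfg$c0)) *
    (cfg$qNs + (1 - cfg$qNs) * pmax(theta, sigma))^sp$washes
  expect_true(all(eluted <= pool@abundance + 1e-15))
})

test_that("campaigns are deterministic under a fixed seed, FASTQ included", {
  cfg <- simConfig(schemaCX12C(), nClones = 100, seed = 17,
                   campaigns = defaultCampaigns(depth = 500))
  r1 <- runCampaign(cfg)
  r2 <- runCampaign(cfg)
  expect_identical(
    SummarizedExperiment::assay(r1$poolTable, "counts"),
    SummarizedExperiment::assay(r2$poolTable, "counts"))
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- runCampaign(cfg, output = "fastq", dir = d1)
  f2 <- runCampaign(cfg, output = "fastq", dir = d2)
  for (k in seq_along(f1$files)) {
    expect_identical(readLines(f1$files[[k]]), readLines(f2$files[[k]]))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a resin-sticky clone enriches more when its resin is reused every round", {
  # one GSH-sticky clone against plain background, no binders, no noise
  n <- 50L
  sig <- matrix(0, n, 3, dimnames = list(NULL, c("streptavidin", "NHS", "GSH")))
  sig[1, "GSH"] <- 0.7
  pool <- new("ClonePool", dna = rep(strrep("TGT", 14), n),
              peptide = sprintf("P%02d", seq_len(n)),
              abundance = rep(1 / n, n), kd = rep(Inf, n),
              stickiness = sig, fitness = rep(1, n))
  cfg <- simConfig(schemaCX12C(), nClones = 10, tau = 0)
  runSchedule <- function(resins) {
    p <- pool
    for (k in seq_along(resins)) {
      sp <- data.frame(strategy = "s", round = k, resin = resins[k],
                       targetUg = 1, washes = 8L, negSelect = TRUE,
                       depth = 10, i5 = "A", i7 = "A")
      p <- runRound(p, sp, cfg)
    }
    p@abundance[1]
  }
  fGshOnly <- runSchedule(rep("GSH", 4))
  fAlternating <- runSchedule(c("streptavidin", "NHS", "streptavidin", "NHS"))
  expect_gt(fGshOnly, fAlternating)
})

test_that("config validation rejects out-of-range rates and duplicate index pairs", {
  expect_error(simConfig(schemaCX12C(), qNs = 1.2), "\\[0, 1\\]")
  expect_error(simConfig(schemaCX12C(), stickinessMax = 1), "stickinessMax")
  expect_error(simConfig(schemaCX12C(), kdRange = c(5, 1)), "ordered")
  camps <- defaultCampaigns(depth = 100)
  camps$gsh$i5 <- camps$strep_nhs$i5
  camps$gsh$i7 <- camps$strep_nhs$i7
  expect_error(simConfig(schemaCX12C(), campaigns = camps), "unique")
})
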