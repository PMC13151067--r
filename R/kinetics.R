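#' @include AllClasses.R
NULL

#' Closed-form 1:1 binding model response
#'
#' Association: `R(t) = Req * (1 - exp(-kobs * (t - tA)))` with
#' `kobs = kon * C + koff` and `Req = Rmax * C / (C + KD)`. Dissociation:
#' `R(t) = R(tD) * exp(-koff * (t - tD))`. No mass-transport limitation is
#' modeled.
#'
#' @param t time points (s).
#' @param conc analyte concentration (M).
#' @param kon,koff,rmax kinetic parameters (1/(M*s), 1/s, nm); all positive.
#' @param tA association start (s).
#' @param tD dissociation start (s).
#' @return response (nm) at each `t`; baseline (t < tA) is 0.
#' @examples
#' model1to1(c(0, 300, 1e6), conc = 1e-7, kon = 1e4, koff = 1e-3,
#'           rmax = 2, tA = 0, tD = 2e6)
#' @export
model1to1 <- function(t, conc, kon, koff, rmax, tA = 0, tD = Inf) {
  if (kon <= 0 || koff <= 0 || rmax <= 0 || conc <= 0) {
    stop("kon, koff, rmax and conc must all be positive")
  }
  kd <- koff / kon
  kobs <- kon * conc + koff
  req <- rmax * conc / (conc + kd)
  r <- numeric(length(t))
  assoc <- t >= tA & t < tD
  r[assoc] <- req * (1 - exp(-kobs * (t[assoc] - tA)))
  if (any(t >= tD)) {
    rAtD <- req * (1 - exp(-kobs * (tD - tA)))
    dis <- t >= tD
    r[dis] <- rAtD * exp(-koff * (t[dis] - tD))
  }
  r
}

#' Simulate a multi-concentration sensorgram set
#'
#' One trace per analyte concentration, with the standard phase layout
#' (5 min baseline, 210 s association, 5 min dissociation by default) and
#' i.i.d. Gaussian noise.
#'
#' @param kon,koff,rmax true kinetic parameters.
#' @param concentrations analyte concentrations (M), at least 2.
#' @param noiseSd Gaussian noise sd (nm); 0 for noiseless traces.
#' @param seed RNG seed.
#' @param baseline,association,dissociation phase durations (s).
#' @param dt sampling interval (s).
#' @return data.frame in the long sensorgram dialect: `trace`, `conc`,
#'   `phase` (`baseline`/`association`/`dissociation`), `t`, `response`;
#'   attributes `tA` and `tD` record the phase boundaries.
#' @export
simulateSensorgrams <- function(kon, koff, rmax, concentrations,
                                noiseSd = 0, seed = 1L,
                                baseline = 300, association = 210,
                                dissociation = 300, dt = 1) {
  if (length(concentrations) < 2L) stop("need at least 2 concentrations")
  set.seed(seed)
  tA <- baseline
  tD <- baseline + association
  tEnd <- tD + dissociation
  tt <- seq(0, tEnd, by = dt)
  phase <- ifelse(tt < tA, "baseline",
                  ifelse(tt < tD, "association", "dissociation"))
  out <- do.call(rbind, lapply(seq_along(concentrations), function(i) {
    C <- concentrations[i]
    r <- model1to1(tt, C, kon, koff, rmax, tA = tA, tD = tD)
    if (noiseSd > 0) r <- r + stats::rnorm(length(r), 0, noiseSd)
    data.frame(trace = paste0("trace", i), conc = C, phase = phase, t = tt,
               response = r, stringsAsFactors = FALSE)
  }))
  attr(out, "tA") <- tA
  attr(out, "tD") <- tD
  out
}

#' Read / write sensorgrams in the long CSV dialect
#'
#' Columns `trace`, `conc`, `phase`, `t`, `response`; phase boundaries are
#' recovered from the phase labels.
#'
#' @param grams sensorgram data.frame.
#' @param path CSV path.
#' @return `readSensorgrams` returns the data.frame with `tA`/`tD`
#'   attributes; `writeSensorgrams` returns `path` invisibly.
#' @export
writeSensorgrams <- function(grams, path) {
  utils::write.csv(grams, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSensorgrams
#' @export
readSensorgrams <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trace", "conc", "phase", "t", "response")
  if (!all(need %in% names(g))) {
    stop("sensorgram CSV must have columns ", paste(need, collapse = ", "))
  }
  attr(g, "tA") <- min(g$t[g$phase == "association"])
  attr(g, "tD") <- min(g$t[g$phase == "dissociation"])
  g
}

# residuals of the global model for log-scale parameters
.globalResiduals <- function(par, grams, tA, tD, traces) {
  kon <- exp(par[1]); koff <- exp(par[2]); rmax <- exp(par[3])
  offs <- par[-(1:3)]
  unlist(lapply(seq_along(traces), function(i) {
    g <- grams[grams$trace == traces[i], ]
    pred <- model1to1(g$t, g$conc[1], kon, koff, rmax, tA = tA, tD = tD) +
      offs[i]
    g$response - pred
  }), use.names = FALSE)
}

# linearization start: per-trace single-exponential rise fitted by profiling
# the amplitude over a kobs grid, then kobs regressed on concentration
.linearizationStart <- function(grams, tA, tD, traces) {
  kobs <- conc <- amp <- numeric(length(traces))
  kGrid <- 10^seq(-4, 0, length.out = 60L)
  for (i in seq_along(traces)) {
    g <- grams[grams$trace == traces[i] & grams$phase == "association", ]
    conc[i] <- g$conc[1]
    tt <- g$t - tA
    sse <- vapply(kGrid, function(k) {
      f <- 1 - exp(-k * tt)
      a <- sum(g$response * f) / sum(f * f)
      sum((g$response - a * f)^2)
    }, numeric(1))
    kBest <- kGrid[which.min(sse)]
    f <- 1 - exp(-kBest * tt)
    kobs[i] <- kBest
    amp[i] <- sum(g$response * f) / sum(f * f)
  }
  fit <- stats::lm(kobs ~ conc)
  kon0 <- unname(stats::coef(fit)[2])
  koff0 <- unname(stats::coef(fit)[1])
  if (!is.finite(kon0) || kon0 <= 0) kon0 <- max(kobs) / max(conc)
  if (!is.finite(koff0) || koff0 <= 0) koff0 <- min(kobs) / 2
  kd0 <- koff0 / kon0
  rmax0 <- max(amp * (conc + kd0) / conc, max(abs(amp)), 1e-3)
  c(log(kon0), log(koff0), log(rmax0))
}

#' Global 1:1 kinetic fit over a multi-concentration sensorgram set
#'
#' Least-squares over association and dissociation phases jointly, with a
#' single (kon, koff, Rmax) shared across traces and a per-trace additive
#' baseline offset. Parameters are fitted on the log scale from multiple
#' starts (a kobs-linearization seed plus perturbations); standard errors
#' come from the Jacobian by the delta method. Non-convergence is flagged in
#' the result, never silent.
#'
#' @param grams sensorgram data.frame ([simulateSensorgrams()] /
#'   [readSensorgrams()]).
#' @param nStarts number of optimizer starts.
#' @return a [KineticFit-class].
#' @export
fitGlobal1to1 <- function(grams, nStarts = 4L) {
  tA <- attr(grams, "tA")
  tD <- attr(grams, "tD")
  if (is.null(tA) || is.null(tD)) {
    tA <- min(grams$t[grams$phase == "association"])
    tD <- min(grams$t[grams$phase == "dissociation"])
  }
  traces <- unique(grams$trace)
  concs <- vapply(traces, function(tr) grams$conc[grams$trace == tr][1],
                  numeric(1))
  if (length(unique(concs)) < 2L) {
    stop("global fit needs at least 2 distinct concentrations")
  }
  if (max(concs) / min(concs) < 4) {
    stop("concentrations must span at least 4-fold")
  }
  fitData <- grams[grams$phase %in% c("association", "dissociation"), ]
  start0 <- .linearizationStart(grams, tA, tD, traces)
  starts <- list(c(start0, rep(0, length(traces))))
  set.seed(1234L)
  for (k in seq_len(max(0L, nStarts - 1L))) {
    starts[[k + 1L]] <- c(start0 + stats::rnorm(3, 0, 0.7),
                          rep(0, length(traces)))
  }
  best <- NULL
  for (st in starts) {
    nOff <- length(traces)
    lower <- c(log(1), log(1e-7), log(1e-4), rep(-10, nOff))
    upper <- c(log(1e10), log(10), log(1e4), rep(10, nOff))
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = .globalResiduals, grams = fitData,
                         tA = tA, tD = tD, traces = traces,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop("global fit failed from every start")
  p <- best$par
  kon <- exp(p[1]); koff <- exp(p[2]); rmax <- exp(p[3])
  nres <- length(.globalResiduals(p, fitData, tA, tD, traces))
  dof <- nres - length(p)
  s2 <- best$deviance / dof
  se <- rep(NA_real_, 3)
  covLog <- tryCatch(s2 * solve(best$hessian), error = function(e) NULL)
  if (!is.null(covLog)) {
    seLog <- sqrt(pmax(diag(covLog)[1:3], 0))
    se <- c(kon, koff, rmax) * seLog  # delta method from log scale
  }
  converged <- best$info %in% 1:4
  new("KineticFit",
      kon = kon, koff = koff, rmax = rmax,
      offsets = stats::setNames(p[-(1:3)], traces),
      kd = koff / kon,
      stderr = stats::setNames(se, c("kon", "koff", "rmax")),
      rmse = sqrt(best$deviance / nres),
      converged = converged,
      info = list(message = best$message, niter = best$niter,
                  start = starts[[1]][1:3]))
}

#' Fold selectivity between two affinities
#'
#' Ratio of the off-target to the target dissociation constant; values above
#' 1 mean tighter binding to the target.
#'
#' @param kdOfftarget,kdTarget dissociation constants (same units), positive.
#' @return the fold ratio.
#' @examples
#' foldSelectivity(639.2e-9, 136e-9)  # ~4.7
#' @export
foldSelectivity <- function(kdOfftarget, kdTarget) {
  if (any(c(kdOfftarget, kdTarget) <= 0)) {
    stop("dissociation constants must be positive")
  }
  kdOfftarget / kdTarget
}

#' Classify alanine-scan variants by affinity fold change
#'
#' Fold change is `KD(variant) / KD(parent)`. Classes: `essential` (> 9),
#' `intermediate` (4, 9], `mild` [2, 4], `neutral` (< 2). Boundary cases:
#' fold 9 is intermediate, folds 2 and 4 are mild. Variants with a missing
#' KD are flagged `not-determined`.
#'
#' @param parentKd parent peptide KD (positive).
#' @param variantKd named numeric vector of variant KDs (NA = not measured).
#' @return data.frame: `variant`, `kd`, `fold`, `class`.
#' @examples
#' classifyAlaScan(136e-9, c(W3A = 1.5e-6, S2A = 300e-9))
#' @export
classifyAlaScan <- function(parentKd, variantKd) {
  if (parentKd <= 0) stop("parent KD must be positive")
  fold <- variantKd / parentKd
  cls <- ifelse(is.na(fold), "not-determined",
         ifelse(fold > 9, "essential",
         ifelse(fold > 4, "intermediate",
         ifelse(fold >= 2, "mild", "neutral"))))
  data.frame(variant = names(variantKd), kd = unname(variantKd),
             fold = unname(fold), class = unname(cls),
             row.names = NULL, stringsAsFactors = FALSE)
}
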