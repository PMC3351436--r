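#' Spin-pair and field constants for 15N relaxation
#'
#' Precomputes the dipolar and CSA interaction constants and the relevant
#' angular frequencies for an amide 15N-1H spin pair at one field. Defaults
#' (rNH = 1.02 Angstrom, Dsigma = -172 ppm) follow the conventions commonly
#' used with the classic model-free fitting programs; both are configurable.
#'
#' @param fieldMHz spectrometer 1H frequency (MHz).
#' @param rNH N-H bond length (Angstrom); default 1.02.
#' @param csa 15N chemical shift anisotropy (ppm); default -172.
#' @return list with elements `fieldMHz`, `rNH`, `csa`, `wH`, `wN` (signed,
#'   rad/s), `d2` (dipolar constant squared, (rad/s)^2), `c2` (CSA constant
#'   squared), `gammaRatio` (gammaH/gammaN, negative).
#' @export
spinParameters <- function(fieldMHz, rNH = 1.02, csa = -172) {
  stopifnot(fieldMHz > 0, rNH > 0)
  gH <- 2.6752218744e8          # 1H gyromagnetic ratio, rad/s/T
  gN <- -2.7126189e7            # 15N gyromagnetic ratio, rad/s/T (negative)
  hbar <- 1.054571817e-34
  mu0 <- 4e-7 * pi
  wH <- 2 * pi * fieldMHz * 1e6
  B0 <- wH / gH
  wN <- gN * B0
  r <- rNH * 1e-10
  d <- mu0 * hbar * gH * gN / (4 * pi * r^3)
  list(fieldMHz = fieldMHz, rNH = rNH, csa = csa, wH = wH, wN = wN,
       d2 = d * d, c2 = (wN * csa * 1e-6)^2 / 3, gammaRatio = gH / gN)
}

#' Lipari-Szabo spectral density
#'
#' `J(w) = (2/5) [ S2 tm / (1 + (w tm)^2) + (Sf2 - S2) t' / (1 + (w t')^2) ]`
#' with `1/t' = 1/tm + 1/te`. The simple (models M1-M4) form has `Sf2 = 1`;
#' the extended (M5) form uses the fast-motion amplitude `Sf2 < 1` with
#' `S2 = Sf2 * Ss2`. With `S2 = 1` the internal term vanishes and
#' `J(0) = (2/5) tm`; for `te = 0` J is monotone non-increasing in `|w|`.
#'
#' @param omega angular frequency (rad/s); vectorized; sign is ignored
#'   (J is even).
#' @param tm global rotational correlation time (ns), > 0.
#' @param s2 generalized order parameter in [0, 1].
#' @param te effective internal correlation time (ps), >= 0.
#' @param sf2 fast-motion order parameter in [0, 1] (1 for models M1-M4).
#' @return J(omega) in s/rad.
#' @export
spectralDensity <- function(omega, tm, s2, te = 0, sf2 = 1) {
  stopifnot(tm > 0, te >= 0)
  tmS <- tm * 1e-9
  teS <- te * 1e-12
  w <- abs(omega)
  out <- s2 * tmS / (1 + (w * tmS)^2)
  if (teS > 0) {
    tp <- 1 / (1 / tmS + 1 / teS)
    out <- out + (sf2 - s2) * tp / (1 + (w * tp)^2)
  }
  0.4 * out
}

# axially symmetric top: three-exponential J weighted by the N-H vector angle
.spectralDensityAxial <- function(omega, tm, s2, te, sf2, ratio, angle) {
  tmS <- tm * 1e-9; teS <- te * 1e-12
  Diso <- 1 / (6 * tmS)
  Dperp <- 3 * Diso / (ratio + 2)
  Dpar <- ratio * Dperp
  tk <- c(1 / (6 * Dperp),
          1 / (5 * Dperp + Dpar),
          1 / (2 * Dperp + 4 * Dpar))
  cz <- cos(angle); sz <- sin(angle)
  A <- c((1.5 * cz^2 - 0.5)^2, 3 * sz^2 * cz^2, 0.75 * sz^4)
  w <- abs(omega)
  out <- 0
  for (kk in 1:3) {
    term <- s2 * tk[kk] / (1 + (w * tk[kk])^2)
    if (teS > 0) {
      tp <- 1 / (1 / tk[kk] + 1 / teS)
      term <- term + (sf2 - s2) * tp / (1 + (w * tp)^2)
    }
    out <- out + A[kk] * term
  }
  0.4 * out
}

#' Predict R1, R2 and NOE from model-free parameters
#'
#' Standard dipolar + CSA combinations of the spectral density evaluated at
#' `{0, wN, wH - wN, wH, wH + wN}`:
#' `R1 = (d2/4)[J(wH-wN) + 3 J(wN) + 6 J(wH+wN)] + c2 J(wN)`,
#' `R2 = (d2/8)[4 J(0) + J(wH-wN) + 3 J(wN) + 6 J(wH) + 6 J(wH+wN)]
#'       + (c2/6)[4 J(0) + 3 J(wN)] + Rex`,
#' `NOE = 1 + (gammaH/gammaN)(d2/4)[6 J(wH+wN) - J(wH-wN)] / R1`.
#' The exchange contribution Rex enters R2 only. Arguments `s2`, `te`, `rex`,
#' `sf2` are vectorized (recycled to a common length).
#'
#' @param s2 order parameter(s) in [0, 1].
#' @param tm global correlation time (ns).
#' @param te internal correlation time(s) (ps).
#' @param rex exchange contribution(s) to R2 (1/s).
#' @param sf2 fast-motion order parameter(s) (1 for M1-M4).
#' @param spin a [spinParameters()] list.
#' @param diffusion NULL for isotropic tumbling (default), or
#'   `list(ratio = Dpar/Dperp, angle = <radians>)` for an axially symmetric
#'   diffusion tensor with the N-H vector at `angle` from the symmetry axis;
#'   `ratio = 1` reduces exactly to isotropic.
#' @return data.frame with columns `R1`, `R2` (1/s) and `NOE`.
#' @export
predictRates <- function(s2, tm, te = 0, rex = 0, sf2 = 1, spin,
                         diffusion = NULL) {
  n <- max(length(s2), length(te), length(rex), length(sf2))
  s2 <- rep_len(s2, n); te <- rep_len(te, n)
  rex <- rep_len(rex, n); sf2 <- rep_len(sf2, n)
  stopifnot(all(s2 >= 0 & s2 <= 1), all(te >= 0), all(rex >= 0),
            all(sf2 >= 0 & sf2 <= 1))
  Jf <- if (is.null(diffusion)) {
    function(w, i) spectralDensity(w, tm, s2[i], te[i], sf2[i])
  } else {
    function(w, i) .spectralDensityAxial(w, tm, s2[i], te[i], sf2[i],
                                         diffusion$ratio, diffusion$angle)
  }
  R1 <- R2 <- NOE <- numeric(n)
  for (i in seq_len(n)) {
    JHmN <- Jf(spin$wH - spin$wN, i)
    JN <- Jf(spin$wN, i)
    JHpN <- Jf(spin$wH + spin$wN, i)
    JH <- Jf(spin$wH, i)
    J0 <- Jf(0, i)
    R1[i] <- (spin$d2 / 4) * (JHmN + 3 * JN + 6 * JHpN) + spin$c2 * JN
    R2[i] <- (spin$d2 / 8) * (4 * J0 + JHmN + 3 * JN + 6 * JH + 6 * JHpN) +
      (spin$c2 / 6) * (4 * J0 + 3 * JN) + rex[i]
    NOE[i] <- 1 + (spin$d2 / 4) * spin$gammaRatio * (6 * JHpN - JHmN) / R1[i]
  }
  data.frame(R1 = R1, R2 = R2, NOE = NOE)
}

#' Estimate the global rotational correlation time from R2/R1
#'
#' Takes the trimmed mean of R2/R1 over residues whose NOE is at or above a
#' rigidity cutoff (excluding flexible residues whose internal motion, and
#' trimming residues whose exchange contribution, would bias the ratio), and
#' inverts it through the rigid isotropic relation (S2 = 1, te = 0, Rex = 0)
#' by 1-D root finding. The rigid R2/R1 ratio is independent of S2 when
#' te = 0, so data forward-generated at a known tm are recovered exactly in
#' the noise-free limit.
#'
#' @param ds a [RelaxationDataset-class].
#' @param trim two-sided trim fraction for the mean of R2/R1; default 0.1.
#' @param noeCutoff minimum NOE for a residue to count as rigid; default 0.65.
#' @param spin optional [spinParameters()]; defaults to the dataset's field
#'   with standard constants.
#' @return tm in ns.
#' @export
estimateTm <- function(ds, trim = 0.1, noeCutoff = 0.65, spin = NULL) {
  stopifnot(is(ds, "RelaxationDataset"))
  if (is.null(spin)) spin <- spinParameters(ds@fieldMHz)
  d <- ds@data
  ok <- !is.na(d$R1) & !is.na(d$R2) & !is.na(d$NOE) & d$NOE >= noeCutoff
  if (sum(ok) < 5L)
    stop("too few rigid residues (", sum(ok), " with NOE >= ", noeCutoff,
         ") to estimate tm; supply tm manually")
  target <- mean(d$R2[ok] / d$R1[ok], trim = trim)
  f <- function(tm) {
    r <- predictRates(1, tm, 0, 0, 1, spin)
    r$R2 / r$R1 - target
  }
  if (f(0.1) > 0) stop("R2/R1 ratio below the rigid-limit range; check data")
  stats::uniroot(f, c(0.1, 100), tol = 1e-8)$root
}

.mfModels <- list(
  M1 = list(par = "s2",                     np = 1L),
  M2 = list(par = c("s2", "te"),            np = 2L),
  M3 = list(par = c("s2", "rex"),           np = 2L),
  M4 = list(par = c("s2", "te", "rex"),     np = 3L),
  M5 = list(par = c("sf2", "ss2", "te"),    np = 3L))

.mfBounds <- list(s2 = c(1e-3, 1), te = c(0, 5000), rex = c(0, 50),
                  sf2 = c(1e-3, 1), ss2 = c(1e-3, 1))

.mfExpand <- function(model, par) {
  p <- list(s2 = NA, te = 0, rex = 0, sf2 = 1)
  nm <- .mfModels[[model]]$par
  for (k in seq_along(nm)) p[[nm[k]]] <- par[k]
  if (model == "M5") { p$s2 <- p$sf2 * p$ss2 }
  if (is.na(p$s2)) p$s2 <- par[1]
  p
}

# lean scalar rate kernel used inside the fit loops; identical maths to
# predictRates (asserted by a test) but without data.frame overhead
.mfRates <- function(s2, tm, te, rex, sf2, spin, diffusion) {
  if (!is.null(diffusion)) {
    Jf <- function(w) .spectralDensityAxial(w, tm, s2, te, sf2,
                                            diffusion$ratio, diffusion$angle)
  } else {
    tmS <- tm * 1e-9; teS <- te * 1e-12
    Jf <- function(w) {
      w <- abs(w)
      out <- s2 * tmS / (1 + (w * tmS)^2)
      if (teS > 0) {
        tp <- 1 / (1 / tmS + 1 / teS)
        out <- out + (sf2 - s2) * tp / (1 + (w * tp)^2)
      }
      0.4 * out
    }
  }
  JHmN <- Jf(spin$wH - spin$wN); JN <- Jf(spin$wN)
  JHpN <- Jf(spin$wH + spin$wN); JH <- Jf(spin$wH); J0 <- Jf(0)
  R1 <- (spin$d2 / 4) * (JHmN + 3 * JN + 6 * JHpN) + spin$c2 * JN
  R2 <- (spin$d2 / 8) * (4 * J0 + JHmN + 3 * JN + 6 * JH + 6 * JHpN) +
    (spin$c2 / 6) * (4 * J0 + 3 * JN) + rex
  c(R1, R2, 1 + (spin$d2 / 4) * spin$gammaRatio * (6 * JHpN - JHmN) / R1)
}

.mfChi2 <- function(model, par, obs, err, tm, spin, diffusion) {
  p <- .mfExpand(model, par)
  r <- .mfRates(p$s2, tm, p$te, p$rex, p$sf2, spin, diffusion)
  sum(((r - obs) / err)^2)
}

.mfStartGrid <- function(model) {
  s2g <- c(0.3, 0.5, 0.7, 0.85, 0.95)
  teg <- c(0, 20, 100, 500)
  rexg <- c(0, 2, 5)
  switch(model,
    M1 = expand.grid(s2 = s2g),
    M2 = expand.grid(s2 = s2g, te = teg),
    M3 = expand.grid(s2 = s2g, rex = rexg),
    M4 = expand.grid(s2 = s2g, te = teg, rex = rexg),
    M5 = expand.grid(sf2 = c(0.6, 0.8, 0.95), ss2 = s2g, te = teg))
}

.mfFitModel <- function(model, obs, err, tm, spin, diffusion, warmStarts) {
  grid <- as.matrix(.mfStartGrid(model))
  chi <- vapply(seq_len(nrow(grid)), function(i)
    .mfChi2(model, grid[i, ], obs, err, tm, spin, diffusion), numeric(1))
  starts <- list(unname(grid[which.min(chi), ]))
  for (w in warmStarts) starts <- c(starts, list(w))
  nm <- .mfModels[[model]]$par
  lo <- vapply(nm, function(k) .mfBounds[[k]][1], numeric(1))
  hi <- vapply(nm, function(k) .mfBounds[[k]][2], numeric(1))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lo), hi)
    fit <- tryCatch(
      stats::optim(st, function(p) .mfChi2(model, p, obs, err, tm, spin,
                                           diffusion),
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) return(NULL)
  converged <- best$convergence == 0
  if (!converged) {
    # L-BFGS-B reports a line-search failure (code 52) when the finite-
    # difference gradient is flat at the optimum; call the fit converged
    # when a restart from the returned point cannot improve it
    again <- tryCatch(
      stats::optim(best$par, function(p) .mfChi2(model, p, obs, err, tm, spin,
                                                 diffusion),
                   method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(again)) {
      if (again$value < best$value) best[c("par", "value")] <-
        again[c("par", "value")]
      converged <- again$value >= best$value - 1e-8 * (1 + best$value)
    }
  }
  # polish + covariance-based uncertainties
  h <- tryCatch(stats::optimHess(best$par, function(p)
    .mfChi2(model, p, obs, err, tm, spin, diffusion)), error = function(e) NULL)
  se <- rep(NA_real_, length(best$par))
  if (!is.null(h)) {
    cv <- tryCatch(solve(h), error = function(e) NULL)
    if (!is.null(cv)) {
      dg <- 2 * diag(as.matrix(cv))
      se[dg > 0] <- sqrt(dg[dg > 0])
    }
  }
  names(se) <- nm
  list(model = model, par = stats::setNames(best$par, nm), se = se,
       chi2 = best$value, aic = best$value + 2 * .mfModels[[model]]$np,
       converged = converged)
}

.mfSelect <- function(fits, criterion) {
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) return(NULL)
  if (criterion == "aic") {
    aics <- vapply(fits, `[[`, numeric(1), "aic")
    nps <- vapply(fits, function(f) .mfModels[[f$model]]$np, integer(1))
    return(fits[[order(aics, nps)[1]]])
  }
  # F-test mode: walk from the simplest model, accepting a nested extension
  # only when it improves the fit significantly (alpha = 0.05); models with
  # zero residual degrees of freedom are accepted only when the current
  # model fails a chi-square goodness-of-fit test at the same alpha.
  byName <- stats::setNames(fits, vapply(fits, `[[`, character(1), "model"))
  nobs <- 3
  cur <- byName[["M1"]]
  if (is.null(cur)) return(.mfSelect(fits, "aic"))
  for (cand in c("M2", "M3", "M4", "M5")) {
    f <- byName[[cand]]
    if (is.null(f)) next
    dp <- .mfModels[[cand]]$np - .mfModels[[cur$model]]$np
    if (dp <= 0) next
    dofC <- nobs - .mfModels[[cand]]$np
    if (dofC > 0) {
      Fv <- ((cur$chi2 - f$chi2) / dp) / (f$chi2 / dofC)
      if (is.finite(Fv) &&
          stats::pf(Fv, dp, dofC, lower.tail = FALSE) < 0.05) cur <- f
    } else {
      dofCur <- nobs - .mfModels[[cur$model]]$np
      if (dofCur > 0 &&
          stats::pchisq(cur$chi2, dofCur, lower.tail = FALSE) < 0.05 &&
          f$chi2 < cur$chi2) cur <- f
    }
  }
  cur
}

#' Fit the five standard model-free models to one residue
#'
#' Weighted least squares of the observed (R1, R2, NOE) triple against
#' [predictRates()] for each of the five standard models
#' (M1: S2; M2: S2, te; M3: S2, Rex; M4: S2, te, Rex; M5: Sf2, Ss2, te with
#' S2 = Sf2 Ss2), each from a deterministic multi-start grid
#' (S2 in 0.3-0.95, te in 0, 20, 100, 500 ps, Rex in 0, 2, 5 1/s) refined by
#' bounded quasi-Newton optimization; richer models are additionally warm
#' started from the best nested solution, which guarantees the nesting
#' property chi2(M4) <= chi2(M2) <= chi2(M1) and chi2(M4) <= chi2(M3). The
#' best model is selected by AIC (`chi2 + 2p`; default) or by nested F-tests.
#'
#' @param r1,r2,noe observed rates (1/s) and NOE.
#' @param tm global correlation time (ns).
#' @param spin a [spinParameters()] list.
#' @param errors optional `c(eR1, eR2, eNOE)`; defaults to the 2/2/3 percent
#'   floors (with an absolute floor of 0.02 on the NOE error).
#' @param models subset of `c("M1","M2","M3","M4","M5")` to try.
#' @param criterion `"aic"` (default) or `"ftest"`.
#' @param diffusion as in [predictRates()].
#' @return list: `model`, `s2`, `te`, `rex`, `sf2`, their standard errors
#'   (`se.s2`, `se.te`, `se.rex`), `chi2`, `aic`, `converged`, and `allFits`
#'   (per-model chi2/aic table).
#' @export
fitResidue <- function(r1, r2, noe, tm, spin, errors = NULL,
                       models = c("M1", "M2", "M3", "M4", "M5"),
                       criterion = c("aic", "ftest"), diffusion = NULL) {
  criterion <- match.arg(criterion)
  models <- match.arg(models, several.ok = TRUE)
  if (anyNA(c(r1, r2, noe)))
    return(list(model = NA_character_, s2 = NA_real_, te = NA_real_,
                rex = NA_real_, sf2 = NA_real_, se.s2 = NA_real_,
                se.te = NA_real_, se.rex = NA_real_, chi2 = NA_real_,
                aic = NA_real_, converged = FALSE, allFits = NULL))
  if (is.null(errors)) errors <- c(NA, NA, NA)
  err <- c(ifelse(is.na(errors[1]), 0.02 * r1, errors[1]),
           ifelse(is.na(errors[2]), 0.02 * r2, errors[2]),
           ifelse(is.na(errors[3]), max(0.03 * abs(noe), 0.02), errors[3]))
  obs <- c(r1, r2, noe)
  fits <- list()
  warm <- function(from, to) {
    f <- fits[[from]]
    if (is.null(f)) return(list())
    p <- .mfExpand(from, f$par)
    list(vapply(.mfModels[[to]]$par, function(k)
      switch(k, s2 = p$s2, te = p$te, rex = p$rex, sf2 = max(p$sf2, p$s2),
             ss2 = if (p$sf2 > 0) p$s2 / max(p$sf2, 1e-3) else p$s2),
      numeric(1)))
  }
  for (m in c("M1", "M2", "M3", "M4", "M5")) {
    if (!m %in% models) next
    ws <- switch(m, M1 = list(),
                 M2 = warm("M1", "M2"), M3 = warm("M1", "M3"),
                 M4 = c(warm("M2", "M4"), warm("M3", "M4")),
                 M5 = warm("M2", "M5"))
    fits[[m]] <- .mfFitModel(m, obs, err, tm, spin, diffusion, ws)
  }
  sel <- .mfSelect(fits, criterion)
  if (is.null(sel) || !sel$converged)
    return(list(model = NA_character_, s2 = NA_real_, te = NA_real_,
                rex = NA_real_, sf2 = NA_real_, se.s2 = NA_real_,
                se.te = NA_real_, se.rex = NA_real_, chi2 = NA_real_,
                aic = NA_real_, converged = FALSE, allFits = fits))
  p <- .mfExpand(sel$model, sel$par)
  list(model = sel$model, s2 = p$s2, te = p$te, rex = p$rex, sf2 = p$sf2,
       se.s2 = unname(sel$se["s2"]), se.te = unname(sel$se["te"]),
       se.rex = unname(sel$se["rex"]),
       chi2 = sel$chi2, aic = sel$aic, converged = TRUE, allFits = fits)
}

#' Model-free analysis of a relaxation dataset
#'
#' Estimates the global correlation time (unless supplied), fits each residue
#' in the analysis range with [fitResidue()], and summarizes the order
#' parameters: mean and SD of S2 over converged residues in the range, the
#' flexibility threshold `mean - 2 SD`, and the residues at or below it.
#' The whole procedure is deterministic for a fixed input.
#'
#' @param ds a [RelaxationDataset-class].
#' @param range `c(first, last)` inclusive residue-id analysis window.
#' @param criterion model selection criterion, `"aic"` or `"ftest"`.
#' @param tm global correlation time (ns); NULL (default) = [estimateTm()].
#' @param spin optional [spinParameters()]; defaults to the dataset's field.
#' @param models models to try.
#' @param diffusion as in [predictRates()].
#' @return a [ModelFreeFit-class].
#' @export
fitDataset <- function(ds, range, criterion = c("aic", "ftest"), tm = NULL,
                       spin = NULL, models = c("M1", "M2", "M3", "M4", "M5"),
                       diffusion = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(is(ds, "RelaxationDataset"), length(range) == 2L)
  if (is.null(spin)) spin <- spinParameters(ds@fieldMHz)
  d <- ds@data
  inRange <- d$residue >= range[1] & d$residue <= range[2]
  if (!any(inRange)) stop("no residues of the dataset fall in range ",
                          range[1], "-", range[2])
  d <- d[inRange, , drop = FALSE]
  if (is.null(tm)) tm <- estimateTm(ds, spin = spin)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    f <- fitResidue(d$R1[i], d$R2[i], d$NOE[i], tm, spin,
                    errors = c(d$eR1[i], d$eR2[i], d$eNOE[i]),
                    models = models, criterion = criterion,
                    diffusion = diffusion)
    data.frame(residue = d$residue[i], model = f$model, s2 = f$s2,
               te = f$te, rex = f$rex, sf2 = f$sf2, chi2 = f$chi2,
               aic = f$aic, se.s2 = f$se.s2, se.te = f$se.te,
               se.rex = f$se.rex, converged = f$converged)
  })
  res <- do.call(rbind, rows)
  conv <- res[res$converged, , drop = FALSE]
  meanS2 <- mean(conv$s2)
  sdS2 <- stats::sd(conv$s2)
  thr <- s2Threshold(meanS2, sdS2, 2)
  new("ModelFreeFit", residues = res, tm = tm,
      diffusion = if (is.null(diffusion)) "isotropic" else "axial",
      summary = list(range = as.integer(range), n = nrow(conv),
                     meanS2 = meanS2, sdS2 = sdS2, flexThreshold = thr,
                     flexibleResidues = conv$residue[conv$s2 <= thr]))
}

#' Order-parameter flexibility threshold
#'
#' `mean - k * sd`: residues with S2 at or below this value are classed
#' flexible. With the conventional `k = 2`, an S2 summary of 0.79 +/- 0.13
#' gives the threshold 0.53.
#'
#' @param mean mean S2 over the analysis range.
#' @param sd standard deviation of S2.
#' @param k SD multiplier; default 2.
#' @return the threshold `mean - k * sd`.
#' @export
s2Threshold <- function(mean, sd, k = 2) {
  stopifnot(sd >= 0, k >= 0)
  mean - k * sd
}
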