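# Small deterministic RNG (Lehmer / Park-Miller) used only to build the
# reference fold, so that fold construction never disturbs R's global RNG
# stream and is identical across platforms.
.lcgNew <- function(seed) {
  s <- as.double((seed %% 2147483646) + 1)
  list(next01 = function() {
    s <<- (s * 16807) %% 2147483647
    s / 2147483647
  })
}

.lcgNorm <- function(rng, n) {
  u1 <- vapply(seq_len(n), function(i) rng$next01(), numeric(1))
  u2 <- vapply(seq_len(n), function(i) rng$next01(), numeric(1))
  sqrt(-2 * log(pmax(u1, 1e-12))) * cos(2 * pi * u2)
}

# Compact self-avoiding walk on the cubic lattice inside a bounding cube,
# found by randomized depth-first search with backtracking. Deterministic
# given the seed.
.sawFold <- function(n, seed) {
  bound <- ceiling(((2.5 * n)^(1 / 3) - 1) / 2)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (attempt in 0:4) {
    rng <- .lcgNew(seed + attempt)
    b <- bound + attempt %/% 2
    key <- function(p) paste(p, collapse = ",")
    occ <- new.env(hash = TRUE)
    path <- matrix(NA_real_, n, 3)
    path[1, ] <- c(0, 0, 0)
    assign(key(path[1, ]), TRUE, envir = occ)
    # stack of shuffled, not-yet-tried direction indices per position
    shuffled <- function() order(vapply(1:6, function(i) rng$next01(), numeric(1)))
    tries <- list(shuffled())
    depth <- 1L
    steps <- 0L
    while (depth < n && steps < 2e5) {
      steps <- steps + 1L
      t <- tries[[depth]]
      if (!length(t)) {           # dead end: backtrack
        if (depth == 1L) break
        rm(list = key(path[depth, ]), envir = occ)
        tries[[depth]] <- NULL
        depth <- depth - 1L
        next
      }
      tries[[depth]] <- t[-1]
      cand <- path[depth, ] + dirs[t[1], ]
      if (any(abs(cand) > b) || exists(key(cand), envir = occ)) next
      depth <- depth + 1L
      path[depth, ] <- cand
      assign(key(cand), TRUE, envir = occ)
      tries[[depth]] <- shuffled()
    }
    if (depth == n) return(path)
  }
  stop("could not grow a self-avoiding fold; try another foldSeed")
}

#' Specification for a Gaussian-network synthetic trajectory
#'
#' Describes a harmonic contact-network (GNM) stand-in for an MD trajectory:
#' residues sit on a compact self-avoiding 3-D chain (3.8 Angstrom virtual
#' bond, small jitter), contacts within `contactCutoff` become springs, and
#' frames are drawn independently as reference + correlated Gaussian
#' displacements whose per-axis covariance is `amplitude` times the
#' pseudo-inverse of the spring-weighted contact Laplacian. Perturbations
#' multiply the spring constant of every contact incident to the named
#' residue set, emulating local stiffening (multiplier > 1, e.g. a ligand
#' clamping its binding site) or softening (multiplier < 1, e.g. a distal
#' region gaining conformational freedom).
#'
#' @param nResidues number of residues; default 131 (an FGF2-sized analysis
#'   window).
#' @param firstResidue author id of the first residue; default 25, so the
#'   default window is ids 25-155.
#' @param contactCutoff spring cutoff on the reference structure (Angstrom);
#'   default 7.5.
#' @param springConstant base spring constant (arbitrary units); default 1.
#' @param amplitude temperature-like displacement scale (Angstrom^2 per
#'   spring-constant unit); default 3, giving a typical folded-core RMSF of
#'   about 0.8 Angstrom.
#' @param perturbations list of `list(residues = <ids>, multiplier = <x>)`;
#'   multipliers must be > 0 and residue sets within range.
#' @param nFrames frames to draw; default 2000.
#' @param seed RNG seed for the frame displacements (mandatory determinism).
#' @param foldSeed seed for the reference fold; keep identical between an
#'   apo/holo pair so the two states share reference and contacts.
#' @param spacing virtual bond length (Angstrom); default 3.8.
#' @param jitter SD of deterministic positional jitter on the lattice fold
#'   (Angstrom); default 0.3.
#' @return a `gnmSpec` list.
#' @export
gnmSpec <- function(nResidues = 131, firstResidue = 25, contactCutoff = 7.5,
                    springConstant = 1, amplitude = 3, perturbations = list(),
                    nFrames = 2000, seed = 1, foldSeed = 42, spacing = 3.8,
                    jitter = 0.3) {
  ids <- seq.int(firstResidue, firstResidue + nResidues - 1L)
  for (p in perturbations) {
    stopifnot(is.numeric(p$multiplier), p$multiplier > 0)
    if (!all(p$residues %in% ids))
      stop("perturbation residues outside the residue range")
  }
  structure(list(nResidues = as.integer(nResidues),
                 firstResidue = as.integer(firstResidue),
                 contactCutoff = contactCutoff,
                 springConstant = springConstant, amplitude = amplitude,
                 perturbations = perturbations, nFrames = as.integer(nFrames),
                 seed = as.integer(seed), foldSeed = as.integer(foldSeed),
                 spacing = spacing, jitter = jitter,
                 rng = "frames: R Mersenne-Twister; fold: Lehmer LCG"),
            class = "gnmSpec")
}

#' Reference coordinates of a GNM spec
#'
#' @param spec a [gnmSpec()].
#' @return numeric matrix nResidues x 3 (Angstrom), rownames = residue ids.
#' @export
gnmReference <- function(spec) {
  stopifnot(inherits(spec, "gnmSpec"))
  lat <- .sawFold(spec$nResidues, spec$foldSeed)
  rng <- .lcgNew(spec$foldSeed + 7919L)
  ref <- lat * spec$spacing +
    matrix(.lcgNorm(rng, 3 * spec$nResidues), ncol = 3) * spec$jitter
  rownames(ref) <- seq.int(spec$firstResidue,
                           spec$firstResidue + spec$nResidues - 1L)
  ref
}

.gnmLaplacian <- function(spec, ref) {
  n <- spec$nResidues
  dm <- as.matrix(stats::dist(ref))
  K <- (dm <= spec$contactCutoff) * spec$springConstant
  diag(K) <- 0
  ids <- as.integer(rownames(ref))
  for (p in spec$perturbations) {
    touch <- ids %in% p$residues
    mult <- outer(touch, touch, `|`) * (p$multiplier - 1) + 1
    K <- K * mult
  }
  diag(K) <- 0
  L <- diag(rowSums(K)) - K
  dimnames(L) <- list(ids, ids)
  L
}

#' Target per-axis displacement covariance of a GNM spec
#'
#' `amplitude * pinv(L)` with L the spring-weighted contact Laplacian; the
#' covariance each axis of the sampled displacements converges to. Errors out
#' when the contact graph is disconnected (more than one zero mode).
#'
#' @param spec a [gnmSpec()].
#' @return covariance matrix (Angstrom^2), rownames = residue ids.
#' @export
gnmCovariance <- function(spec) {
  ref <- gnmReference(spec)
  L <- .gnmLaplacian(spec, ref)
  e <- eigen(L, symmetric = TRUE)
  zero <- e$values < 1e-9 * max(e$values)
  if (sum(zero) != 1L)
    stop("contact graph is disconnected (", sum(zero),
         " zero modes); increase contactCutoff")
  keep <- which(!zero)
  C <- e$vectors[, keep] %*% (t(e$vectors[, keep]) / e$values[keep]) *
    spec$amplitude
  dimnames(C) <- dimnames(L)
  C
}

#' Sample a synthetic trajectory from a GNM spec
#'
#' Frames are independent draws: reference + correlated Gaussian
#' displacements with per-axis covariance [gnmCovariance()] (isotropic across
#' the three axes). Identical specs (seed included) give identical
#' trajectories; an apo/holo pair built with the same `foldSeed` differs only
#' through the perturbation multipliers.
#'
#' @param spec a [gnmSpec()].
#' @return a [Trajectory-class].
#' @export
gnmTrajectory <- function(spec) {
  ref <- gnmReference(spec)
  L <- .gnmLaplacian(spec, ref)
  e <- eigen(L, symmetric = TRUE)
  zero <- e$values < 1e-9 * max(e$values)
  if (sum(zero) != 1L)
    stop("contact graph is disconnected (", sum(zero),
         " zero modes); increase contactCutoff")
  keep <- which(!zero)
  B <- e$vectors[, keep] %*% diag(sqrt(spec$amplitude / e$values[keep]))
  n <- spec$nResidues
  nf <- spec$nFrames
  coords <- array(NA_real_, c(nf, n, 3))
  set.seed(spec$seed)
  for (ax in 1:3) {
    disp <- B %*% matrix(stats::rnorm(ncol(B) * nf), ncol(B), nf)
    coords[, , ax] <- t(ref[, ax] + disp)
  }
  Trajectory(coords, as.integer(rownames(ref)), atomName = "CA")
}

#' Paired apo/holo GNM specs with implanted perturbations
#'
#' The packaged ground-truth fixture: an FGF2-sized window (131 residues,
#' ids 25-155) whose holo state stiffens every contact of a 5-residue
#' "binding site" (ids 128-132) five-fold and softens every contact of a
#' 4-residue distal "allosteric" region (ids 109-112) to 0.2x. Apo and holo
#' share the reference fold and contact map and differ only in the spring
#' multipliers; their frame seeds are decoupled so the two trajectories are
#' independent samples.
#'
#' @param seed base seed; the apo trajectory uses `seed`, the holo
#'   trajectory `seed + 104729`.
#' @param nFrames frames per state; default 2000.
#' @return list with elements `apo`, `holo` (both [gnmSpec()]), `site`,
#'   `distal` (the implanted residue sets).
#' @export
demoGNMSpecs <- function(seed = 1, nFrames = 2000) {
  site <- 128:132
  distal <- 109:112
  list(apo = gnmSpec(nFrames = nFrames, seed = seed),
       holo = gnmSpec(nFrames = nFrames, seed = seed + 104729L,
                      perturbations = list(
                        list(residues = site, multiplier = 5),
                        list(residues = distal, multiplier = 0.2))),
       site = site, distal = distal)
}

#' Specification for a synthetic relaxation dataset
#'
#' Per-residue true dynamics parameters plus a global correlation time and
#' field; [generateRelaxation()] forward-models rates from them and adds
#' fractional Gaussian noise.
#'
#' @param residue integer residue ids.
#' @param s2 true order parameters.
#' @param te true internal correlation times (ps).
#' @param rex true exchange contributions (1/s).
#' @param sf2 true fast-motion order parameters (1 = simple models).
#' @param tm global correlation time (ns); default 8.
#' @param fieldMHz spectrometer 1H frequency; default 500.
#' @param noise fractional Gaussian noise per rate,
#'   `c(R1 = , R2 = , NOE = )`; default 2/2/3 percent.
#' @param seed RNG seed.
#' @return a `relaxSpec` list.
#' @export
relaxSpec <- function(residue, s2, te = 0, rex = 0, sf2 = 1, tm = 8,
                      fieldMHz = 500,
                      noise = c(R1 = 0.02, R2 = 0.02, NOE = 0.03), seed = 1) {
  n <- length(residue)
  truth <- data.frame(residue = as.integer(residue),
                      s2 = rep_len(s2, n), te = rep_len(te, n),
                      rex = rep_len(rex, n), sf2 = rep_len(sf2, n))
  stopifnot(all(truth$s2 >= 0 & truth$s2 <= 1), all(truth$te >= 0),
            all(truth$rex >= 0), tm > 0, all(noise >= 0))
  structure(list(truth = truth, tm = tm, fieldMHz = fieldMHz,
                 noise = noise, seed = as.integer(seed),
                 rng = "R Mersenne-Twister"),
            class = "relaxSpec")
}

#' Generate a relaxation dataset from known dynamics parameters
#'
#' Rates are forward-modelled with [predictRates()]; R1rho is generated as R2
#' minus the exchange term (an on-resonance spin lock quenches Rex), which is
#' what makes the R2/R1rho ratio an exchange probe. Fractional Gaussian noise
#' at the spec's levels is added and the same fractions become the stored
#' uncertainties (NA when the noise fraction is zero, in which case the
#' dataset equals the forward predictions exactly). The generating truth is
#' attached to the returned object.
#'
#' @param spec a [relaxSpec()].
#' @return a [RelaxationDataset-class] with the `truth` slot filled.
#' @export
generateRelaxation <- function(spec) {
  stopifnot(inherits(spec, "relaxSpec"))
  spin <- spinParameters(spec$fieldMHz)
  tr <- spec$truth
  r <- predictRates(tr$s2, spec$tm, tr$te, tr$rex, tr$sf2, spin)
  r1rho <- r$R2 - tr$rex
  n <- nrow(tr)
  set.seed(spec$seed)
  jig <- function(x, frac) if (frac > 0) x * (1 + frac * stats::rnorm(n)) else x
  R1 <- jig(r$R1, spec$noise["R1"])
  R2 <- jig(r$R2, spec$noise["R2"])
  NOE <- if (spec$noise["NOE"] > 0)
    r$NOE + spec$noise["NOE"] * abs(r$NOE) * stats::rnorm(n) else r$NOE
  R1rho <- jig(r1rho, spec$noise["R2"])
  e <- function(x, frac) if (frac > 0) frac * abs(x) else NA_real_
  RelaxationDataset(tr$residue, R1, R2, NOE, R1rho,
                    e(r$R1, spec$noise["R1"]), e(r$R2, spec$noise["R2"]),
                    e(r$NOE, spec$noise["NOE"]), e(r1rho, spec$noise["R2"]),
                    fieldMHz = spec$fieldMHz,
                    truth = cbind(tr, tm = spec$tm))
}

#' FGF2-like demo relaxation spec
#'
#' 124 residues (ids 30-153) at 500 MHz, tm = 8 ns: a 10-residue flexible
#' tail (ids 30-39, S2 = 0.30, te = 500 ps), a rigid core (S2 = 0.80-0.85,
#' a minority with te = 50 ps), and five exchange-bearing residues
#' (ids 85, 95, 105, 115, 125) with Rex of 3-5 1/s, the magnitude typically
#' seen for micro-millisecond conformational exchange.
#'
#' @param seed RNG seed.
#' @param noise noise fractions as in [relaxSpec()]; set to `c(R1 = 0, R2 =
#'   0, NOE = 0)` for exact forward data.
#' @return a [relaxSpec()].
#' @export
demoRelaxSpec <- function(seed = 1,
                          noise = c(R1 = 0.02, R2 = 0.02, NOE = 0.03)) {
  ids <- 30:153
  s2 <- ifelse(ids <= 39, 0.30, ifelse(ids %% 10 == 0, 0.80, 0.85))
  te <- ifelse(ids <= 39, 500, ifelse(ids %% 10 == 0, 50, 0))
  rex <- numeric(length(ids))
  rex[match(c(85, 95, 105, 115, 125), ids)] <- c(3, 3.5, 4, 4.5, 5)
  relaxSpec(ids, s2, te, rex, tm = 8, fieldMHz = 500, noise = noise,
            seed = seed)
}

#' Specification for paired synthetic apo/holo peak tables
#'
#' @param residues integer residue ids.
#' @param shifted data.frame `residue`, `ddH`, `ddN` (ppm) of implanted
#'   chemical shift changes (holo minus apo).
#' @param apoSuppressed data.frame `residue`, `factor` of residues whose apo
#'   intensity is suppressed (e.g. exchange-broadened) and recovers to
#'   baseline in the holo spectrum.
#' @param intensityChanged data.frame `residue`, `ratio` of implanted
#'   holo/apo intensity ratios.
#' @param shiftNoise SD of Gaussian shift noise per spectrum (ppm).
#' @param intensityNoise fractional Gaussian intensity noise per spectrum.
#' @param seed RNG seed.
#' @return a `peakSpec` list.
#' @export
peakSpec <- function(residues = 25:155, shifted = NULL, apoSuppressed = NULL,
                     intensityChanged = NULL, shiftNoise = 0,
                     intensityNoise = 0, seed = 1) {
  empty <- function(x, cols) if (is.null(x))
    stats::setNames(data.frame(matrix(numeric(), 0, length(cols))), cols) else x
  shifted <- empty(shifted, c("residue", "ddH", "ddN"))
  apoSuppressed <- empty(apoSuppressed, c("residue", "factor"))
  intensityChanged <- empty(intensityChanged, c("residue", "ratio"))
  for (s in list(shifted$residue, apoSuppressed$residue,
                 intensityChanged$residue))
    if (!all(s %in% residues)) stop("implanted residues outside the range")
  structure(list(residues = as.integer(residues), shifted = shifted,
                 apoSuppressed = apoSuppressed,
                 intensityChanged = intensityChanged,
                 shiftNoise = shiftNoise, intensityNoise = intensityNoise,
                 seed = as.integer(seed), rng = "R Mersenne-Twister"),
            class = "peakSpec")
}

#' Generate paired apo/holo peak tables with implanted perturbations
#'
#' Baseline shifts and intensities are drawn once (per seed); the holo table
#' adds the implanted shift changes and intensity ratios; independent
#' measurement noise is then added to each spectrum. With an empty implant
#' set and zero noise the two tables are identical.
#'
#' @param spec a [peakSpec()].
#' @return list with elements `apo`, `holo` ([PeakTable-class]) and `truth`
#'   (the implant tables).
#' @export
generatePeakTables <- function(spec) {
  stopifnot(inherits(spec, "peakSpec"))
  n <- length(spec$residues)
  set.seed(spec$seed)
  dH <- 7.5 + 2.0 * stats::runif(n)
  dN <- 105 + 25 * stats::runif(n)
  inten <- exp(stats::rnorm(n, 0, 0.2))
  apoI <- inten
  sup <- match(spec$apoSuppressed$residue, spec$residues)
  apoI[sup] <- apoI[sup] * spec$apoSuppressed$factor
  holoH <- dH; holoN <- dN; holoI <- inten
  sh <- match(spec$shifted$residue, spec$residues)
  holoH[sh] <- holoH[sh] + spec$shifted$ddH
  holoN[sh] <- holoN[sh] + spec$shifted$ddN
  ic <- match(spec$intensityChanged$residue, spec$residues)
  holoI[ic] <- inten[ic] * spec$intensityChanged$ratio
  addNoise <- function(H, N, I) {
    if (spec$shiftNoise > 0) {
      H <- H + stats::rnorm(n, 0, spec$shiftNoise)
      N <- N + stats::rnorm(n, 0, 5 * spec$shiftNoise)  # 15N ppm scale
    }
    if (spec$intensityNoise > 0)
      I <- I * (1 + spec$intensityNoise * stats::rnorm(n))
    list(H = H, N = N, I = I)
  }
  a <- addNoise(dH, dN, apoI)
  h <- addNoise(holoH, holoN, holoI)
  list(apo = PeakTable(spec$residues, a$H, a$N, a$I),
       holo = PeakTable(spec$residues, h$H, h$N, h$I),
       truth = list(shifted = spec$shifted,
                    apoSuppressed = spec$apoSuppressed,
                    intensityChanged = spec$intensityChanged))
}

#' FGF2-like demo peak spec
#'
#' Ids 25-155 with implanted binding-site perturbations modelled on the
#' canonical apo/holo HSQC picture: large combined shift changes at two
#' binding-site residues (129 and 144), and three residues (129, 144, 145)
#' whose apo intensity is exchange-suppressed to 0.2x baseline and recovers
#' to the spectrum average upon binding.
#'
#' @param seed RNG seed.
#' @param shiftNoise,intensityNoise noise levels; defaults 0.003 ppm and
#'   5 percent.
#' @return a [peakSpec()].
#' @export
demoPeakSpec <- function(seed = 1, shiftNoise = 0.003, intensityNoise = 0.05) {
  peakSpec(residues = 25:155,
           shifted = data.frame(residue = c(129, 144),
                                ddH = c(0.08, 0.06), ddN = c(0.50, 0.35)),
           apoSuppressed = data.frame(residue = c(129, 144, 145),
                                      factor = 0.2),
           shiftNoise = shiftNoise, intensityNoise = intensityNoise,
           seed = seed)
}
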