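.matchPeaks <- function(apo, holo) {
  a <- apo@data; h <- holo@data
  key <- function(d) paste(d$residue, d$sidechain)
  common <- intersect(key(a), key(h))
  if (!length(common)) stop("no residues in common between the two peak tables")
  skipped <- union(setdiff(key(a), common), setdiff(key(h), common))
  if (length(skipped))
    warning(length(skipped), " unmatched peak(s) skipped")
  ia <- match(common, key(a)); ih <- match(common, key(h))
  list(apo = a[ia, , drop = FALSE], holo = h[ih, , drop = FALSE])
}

#' Combined and separate chemical shift perturbation
#'
#' Per matched residue, the 1H and 15N shift changes upon binding
#' (`ddH = dH_holo - dH_apo`, `ddN = dN_holo - dN_apo`) and the combined
#' perturbation `ddComb = sqrt(ddH^2 + (alpha * ddN)^2)` with the usual
#' 15N down-weighting `alpha` (default 0.154). The combined value is invariant
#' under a uniform referencing offset applied to both spectra and is monotone
#' in both `|ddH|` and `|ddN|`. Residues present in only one table are
#' skipped with a warning.
#'
#' @param apo,holo [PeakTable-class] objects.
#' @param alpha 15N weighting factor in (0, 1]; default 0.154.
#' @return data.frame with columns `residue`, `sidechain`, `ddH`, `ddN`,
#'   `ddComb` (all ppm) and `significant` (all FALSE until
#'   [cspSignificance()] is applied).
#' @export
csp <- function(apo, holo, alpha = 0.154) {
  stopifnot(is(apo, "PeakTable"), is(holo, "PeakTable"),
            alpha > 0, alpha <= 1)
  m <- .matchPeaks(apo, holo)
  ddH <- m$holo$dH - m$apo$dH
  ddN <- m$holo$dN - m$apo$dN
  out <- data.frame(residue = m$apo$residue, sidechain = m$apo$sidechain,
                    ddH = ddH, ddN = ddN,
                    ddComb = sqrt(ddH^2 + (alpha * ddN)^2),
                    significant = FALSE)
  attr(out, "alpha") <- alpha
  out[order(out$sidechain, out$residue), , drop = FALSE]
}

#' Flag significant chemical shift perturbations
#'
#' Two criteria. `"mean_sd"` (default, standard CSP practice): iteratively
#' exclude residues whose combined shift exceeds `mean + k * SD` of the
#' retained set and recompute until stable; the excluded set is flagged.
#' `"fixed"`: flag `ddComb > cutoff`. With all-equal perturbations nothing is
#' flagged (the threshold test is strict).
#'
#' @param records output of [csp()].
#' @param method `"mean_sd"` or `"fixed"`.
#' @param k SD multiplier for `"mean_sd"`; default 3.
#' @param cutoff ppm cutoff for `"fixed"`.
#' @return `records` with the `significant` column filled in; the final
#'   threshold is attached as attribute `"threshold"`.
#' @export
cspSignificance <- function(records, method = c("mean_sd", "fixed"),
                            k = 3, cutoff = NULL) {
  method <- match.arg(method)
  x <- records$ddComb
  if (method == "fixed") {
    if (is.null(cutoff)) stop("method 'fixed' needs a cutoff")
    thr <- cutoff
    flag <- x > thr
  } else {
    keep <- !is.na(x)
    repeat {
      thr <- mean(x[keep]) + k * stats::sd(x[keep])
      if (is.na(thr)) { thr <- Inf; break }  # single residue left
      drop <- keep & x > thr
      if (!any(drop)) break
      keep <- keep & !drop
    }
    flag <- !is.na(x) & x > thr
  }
  records$significant <- flag
  attr(records, "threshold") <- thr
  records
}

.normalizeIntensities <- function(d, norm) {
  out <- rep(NA_real_, nrow(d))
  for (grp in unique(d$sidechain)) {
    i <- d$sidechain == grp
    stat <- switch(norm, mean = mean(d$intensity[i], na.rm = TRUE),
                   median = stats::median(d$intensity[i], na.rm = TRUE))
    if (!is.finite(stat) || stat == 0)
      stop("zero or undefined intensity normalizer")
    out[i] <- d$intensity[i] / stat
  }
  out
}

#' Normalized peak-intensity changes upon binding
#'
#' Each spectrum is normalized by the chosen statistic of its own non-missing
#' peak intensities; backbone and side-chain peaks are normalized within
#' their own groups. The per-residue ratio `I_holo_norm / I_apo_norm` is
#' classified `"increased"` above `upThr`, `"decreased"` below `downThr`,
#' `"unchanged"` otherwise. A peak that is missing in exactly one spectrum is
#' reported as `"appeared"` / `"disappeared"` (exchange-broadened peaks are a
#' distinct class, never ratio 0 or Inf); missing in both gives NA. The
#' classification is invariant under a global rescaling of either spectrum.
#'
#' @param apo,holo [PeakTable-class] objects.
#' @param norm `"mean"` (default) or `"median"`.
#' @param upThr,downThr classification thresholds; defaults 1.5 and 0.67.
#' @return data.frame with columns `residue`, `sidechain`, `iApoNorm`,
#'   `iHoloNorm`, `ratio`, `class`.
#' @export
intensityChange <- function(apo, holo, norm = c("mean", "median"),
                            upThr = 1.5, downThr = 0.67) {
  norm <- match.arg(norm)
  stopifnot(upThr > downThr, downThr > 0)
  m <- .matchPeaks(apo, holo)
  ia <- .normalizeIntensities(m$apo, norm)
  ih <- .normalizeIntensities(m$holo, norm)
  ratio <- ih / ia
  cls <- ifelse(is.na(ia) & is.na(ih), NA_character_,
         ifelse(is.na(ih), "disappeared",
         ifelse(is.na(ia), "appeared",
         ifelse(ratio > upThr, "increased",
         ifelse(ratio < downThr, "decreased", "unchanged")))))
  out <- data.frame(residue = m$apo$residue, sidechain = m$apo$sidechain,
                    iApoNorm = ia, iHoloNorm = ih, ratio = ratio, class = cls)
  out[order(out$sidechain, out$residue), , drop = FALSE]
}

#' Conformational-exchange flags from R2/R1rho ratios
#'
#' R2 carries the microsecond-millisecond exchange contribution Rex while the
#' rotating-frame rate R1rho does not, so ratios significantly above one
#' report conformational exchange. A residue is flagged when its ratio
#' exceeds `mean + k * SD` of the ratios over the dataset (default `k = 1`)
#' by more than its own uncertainty: ratio errors are propagated in
#' quadrature from the input errors and a ratio within one propagated error
#' of the threshold is not called (ratios dominated by their errors are set
#' aside, as is standard for this diagnostic). Without input errors the bare
#' threshold applies. The flag set is monotone non-increasing in `k`.
#'
#' @param ds a [RelaxationDataset-class] with both R2 and R1rho.
#' @param k SD multiplier; default 1.
#' @return data.frame with columns `residue`, `ratio`, `error` (NA when input
#'   errors are absent), `flagged`; threshold attached as attribute
#'   `"threshold"`.
#' @export
exchangeFlags <- function(ds, k = 1) {
  stopifnot(is(ds, "RelaxationDataset"), k > 0)
  d <- ds@data
  ok <- !is.na(d$R2) & !is.na(d$R1rho) & d$R1rho > 0
  if (!any(ok)) stop("no residues with both R2 and R1rho")
  d <- d[ok, , drop = FALSE]
  ratio <- d$R2 / d$R1rho
  err <- ratio * sqrt((d$eR2 / d$R2)^2 + (d$eR1rho / d$R1rho)^2)
  thr <- mean(ratio) + k * stats::sd(ratio)
  margin <- ifelse(is.na(err), 0, err)
  out <- data.frame(residue = d$residue, ratio = ratio, error = err,
                    flagged = ratio - margin > thr)
  attr(out, "threshold") <- thr
  out
}

#' Classify ePHOGSY NOE/ROE hydration intensities
#'
#' Water-selective NOE and ROE intensities are normalized per spectrum (mean
#' over non-missing peaks), binned into three proximity classes (`"high"`,
#' `"medium"`, `"low"`) by two thresholds, and compared between states: a
#' change flag is raised where the holo/apo intensity ratio deviates from one
#' by more than `changeFrac` (default 0.5, i.e. beyond +/-50 percent).
#' Residues with an ROE correlation may owe their water peak to chemical
#' exchange rather than a resident water molecule, so they are excluded from
#' water-proximity claims (`waterProximal` forced FALSE) but retained in the
#' record. Default thresholds are the tertiles of the apo normalized NOE
#' intensities.
#'
#' @param apoNoe,apoRoe,holoNoe,holoRoe [PeakTable-class] objects from the
#'   NOE- and ROE-step experiments.
#' @param thresholds two increasing class boundaries on normalized intensity;
#'   NULL (default) = apo-NOE tertiles.
#' @param changeFrac change-flag threshold on `|ratio - 1|`; default 0.5.
#' @return data.frame with per-residue normalized intensities, `noeClass`,
#'   `roeClass`, `noeChange`, `roeChange`, `hasRoe`, `waterProximal`.
#' @export
ephogsyClassify <- function(apoNoe, apoRoe, holoNoe, holoRoe,
                            thresholds = NULL, changeFrac = 0.5) {
  stopifnot(changeFrac > 0)
  norm1 <- function(pt) {
    d <- pt@data[!pt@data$sidechain, , drop = FALSE]
    m <- mean(d$intensity, na.rm = TRUE)
    if (!is.finite(m) || m == 0) stop("zero or undefined intensity normalizer")
    stats::setNames(d$intensity / m, d$residue)
  }
  an <- norm1(apoNoe); ar <- norm1(apoRoe)
  hn <- norm1(holoNoe); hr <- norm1(holoRoe)
  ids <- sort(as.integer(unique(c(names(an), names(hn)))))
  g <- function(v) unname(v[as.character(ids)])
  an <- g(an); ar <- g(ar); hn <- g(hn); hr <- g(hr)
  if (is.null(thresholds))
    thresholds <- unname(stats::quantile(an, c(1, 2) / 3, na.rm = TRUE))
  stopifnot(length(thresholds) == 2L, diff(thresholds) >= 0)
  classify <- function(v) ifelse(is.na(v), NA_character_,
                          ifelse(v > thresholds[2], "high",
                          ifelse(v > thresholds[1], "medium", "low")))
  chg <- function(a, h) !is.na(a) & !is.na(h) & abs(h / a - 1) > changeFrac
  hasRoe <- !is.na(ar) | !is.na(hr)
  data.frame(residue = ids,
             noeApo = an, noeHolo = hn, roeApo = ar, roeHolo = hr,
             noeClass = classify(an), roeClass = classify(ar),
             noeChange = chg(an, hn), roeChange = chg(ar, hr),
             hasRoe = hasRoe,
             waterProximal = classify(an) == "high" & !hasRoe)
}
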