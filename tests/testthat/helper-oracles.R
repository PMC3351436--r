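# Independent brute-force oracles and fixture builders. These deliberately
# share no code with the package internals: plain double/triple loops and
# two-pass statistics.

# coords: frames x n x 3
oracleDF <- function(coords) {
  nf <- dim(coords)[1]; n <- dim(coords)[2]
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- numeric(nf)
    for (f in seq_len(nf))
      d[f] <- sqrt(sum((coords[f, i, ] - coords[f, j, ])^2))
    m <- sum(d) / nf
    out[i, j] <- sum((d - m)^2) / nf
  }
  out
}

oracleStrainPerFrame <- function(coords, adjacency) {
  nf <- dim(coords)[1]; n <- dim(coords)[2]
  dbar <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (f in seq_len(nf))
      dbar[i, j] <- dbar[i, j] +
        sqrt(sum((coords[f, i, ] - coords[f, j, ])^2)) / nf
  }
  s <- matrix(NA_real_, n, nf)
  for (i in seq_len(n)) {
    nb <- which(adjacency[i, ])
    if (!length(nb)) next
    for (f in seq_len(nf)) {
      acc <- 0
      for (j in nb) {
        d <- sqrt(sum((coords[f, i, ] - coords[f, j, ])^2))
        acc <- acc + (d - dbar[i, j])^2
      }
      s[i, f] <- acc / length(nb)
    }
  }
  s
}

randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply an independent random rigid-body transform to every frame
rigidScramble <- function(coords, seed = 1) {
  set.seed(seed)
  out <- coords
  for (f in seq_len(dim(coords)[1])) {
    R <- randomRotation()
    t <- rnorm(3, sd = 20)
    out[f, , ] <- coords[f, , ] %*% R + rep(t, each = dim(coords)[2])
  }
  out
}

randomCoords <- function(nFrames, n, seed = 1, spread = 5) {
  set.seed(seed)
  array(rnorm(nFrames * n * 3, sd = spread), c(nFrames, n, 3))
}

writePDBFixture <- function(path, frames, ids, atom = "CA",
                            extraAtomResidue = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0
  for (f in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (r in seq_along(ids)) {
      serial <- serial + 1
      writeLines(sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, atom, ids[r],
        frames[[f]][r, 1], frames[[f]][r, 2], frames[[f]][r, 3]), con)
    }
    if (!is.null(extraAtomResidue)) {
      serial <- serial + 1
      writeLines(sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
        serial, "N", extraAtomResidue, 0, 0, 0), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

simplePeakTable <- function(ids, dH, dN, intensity = 1, sidechain = FALSE) {
  PeakTable(ids, dH, dN, intensity, sidechain)
}
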