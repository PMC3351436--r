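# Builds a small but complete synthetic input set in a temp dir and returns
# the config. Trajectories are kept short here; the full-scale recovery runs
# live with the acceptance checks.
makePipelineInputs <- function(dir, seed = 11, nFrames = 300,
                               withPeaks = TRUE, withRelax = TRUE) {
  sp <- demoGNMSpecs(seed = seed, nFrames = nFrames)
  writeTrajectoryTable(gnmTrajectory(sp$apo), file.path(dir, "apo.traj"))
  writeTrajectoryTable(gnmTrajectory(sp$holo), file.path(dir, "holo.traj"))
  cfg <- list(range = c(25, 155),
              trajectories = list(apo = "apo.traj", holo = "holo.traj",
                                  format = "table"))
  if (withPeaks) {
    pk <- generatePeakTables(demoPeakSpec(seed = seed))
    writePeakTable(pk$apo, file.path(dir, "apo_hsqc.tsv"))
    writePeakTable(pk$holo, file.path(dir, "holo_hsqc.tsv"))
    cfg$peaks <- list(apo = "apo_hsqc.tsv", holo = "holo_hsqc.tsv")
  }
  if (withRelax) {
    writeRelaxationTable(generateRelaxation(demoRelaxSpec(seed = seed)),
                         file.path(dir, "apo_relax.tsv"))
    ids <- 30:153
    s2 <- ifelse(ids <= 39, 0.30, ifelse(ids %% 10 == 0, 0.80, 0.85))
    s2[ids %in% 109:112] <- 0.55                    # distal region softens
    te <- ifelse(ids <= 39, 500, ifelse(ids %% 10 == 0, 50, 0))
    rex <- numeric(length(ids))
    rex[match(c(85, 95, 105, 115), ids)] <- c(3, 3.5, 4, 4.5)  # 125 quenched
    writeRelaxationTable(generateRelaxation(
      relaxSpec(ids, s2, te, rex, seed = seed + 1)),
      file.path(dir, "holo_relax.tsv"))
    cfg$relaxation <- list(apo = "apo_relax.tsv", holo = "holo_relax.tsv")
  }
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  file.path(dir, "config.yaml")
}
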