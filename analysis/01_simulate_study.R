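#!/usr/bin/env Rscript

# Draw the reference synthetic study: 2 sites x 12 tanks x 6 fish x 180 s of
# group swimming, plus 142 seven-landmark specimens with the site/sex
# structure of the field sampling. Writes the raw data in the exact formats
# the field pipeline reads (generic-csv trajectories, TPS landmarks), so the
# downstream scripts exercise the real parsers.
#
# Usage: Rscript analysis/01_simulate_study.R [seed]

library(shoalmorph)

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/study_data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Simulating the reference two-site study (seed ", seed, ") ...")
study <- simulate_study(reference_study_preset(), seed = seed)

for (g in study$groups) {
  write_group_csv(g, file.path(out, paste0(g$tank_id, ".csv")))
}
write_tps(study$landmarks, file.path(out, "landmarks.tps"))
meta <- data.frame(
  id = vapply(study$landmarks, function(s) as.character(s$fish_id), character(1)),
  site = vapply(study$landmarks, function(s) as.character(s$site), character(1)),
  sex = vapply(study$landmarks, function(s) s$sex, character(1)))
write.table(meta, file.path(out, "landmark_metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(as.character(seed), file.path(out, "seed.txt"))

message("Wrote ", length(study$groups), " tank trajectory files and ",
        length(study$landmarks), " landmark specimens to ", out)
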