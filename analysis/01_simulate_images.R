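#!/usr/bin/env Rscript

# Stage 1 — simulate the specimen image archive.
#
# Builds the spectral world (illuminant, UVS receptor set, five-channel
# camera) and renders a small archive of multi-channel specimen photographs:
# 3 species x 2 sexes x 2 views, with species differing in body UV
# reflectance, males more UV-reflective than females, backs more than
# bellies, and per-image lighting gain and sensor noise varying. Images and
# ground truth go to scratch/ (they are regenerated at will); the specimen
# manifest goes to results/.

suppressMessages(library(uvplume))

out_img <- "scratch/images"
dir.create(out_img, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

world <- make_world(1)

uv_body <- c(sp1 = 0.50, sp2 = 0.25, sp3 = 0.02) # species UV gradient
manifest <- expand.grid(species = names(uv_body), sex = c("M", "F"),
                        view = c("back", "belly"), stringsAsFactors = FALSE)
manifest$specimen <- sprintf("%s_%s_%s", manifest$species, manifest$sex,
                             manifest$view)

set.seed(10)
manifest$gain <- round(runif(nrow(manifest), 0.8, 1.6), 3)
manifest$seed <- 100 + seq_len(nrow(manifest))

for (i in seq_len(nrow(manifest))) {
  m <- manifest[i, ]
  uv <- uv_body[[m$species]] +
    (if (m$sex == "M") 0.10 else 0) - (if (m$view == "belly") 0.05 else 0)
  uv <- max(uv, 0.005)
  sp <- specimen_spectra(world)
  sp$body <- make_spectrum("uv_plus_yellow", world, uv = uv, vis = 0.5)
  sp$head <- make_spectrum("uv_plus_yellow", world, uv = min(uv + 0.1, 0.7),
                           vis = 0.35)
  img <- make_specimen_image(world, spectra = sp, gain = m$gain,
                             noise_sd = 1, seed = m$seed)
  write_specimen_image(img, out_img, m$specimen)
}

write.csv(manifest, "results/specimen_manifest.csv", row.names = FALSE)
message(sprintf("rendered %d specimen images (%d species) to %s",
                nrow(manifest), length(uv_body), out_img))
message("manifest: results/specimen_manifest.csv")
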