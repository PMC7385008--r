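#!/usr/bin/env Rscript
# Build the five study phantoms -- straight tubes of internal diameter 2, 3
# and 5 mm plus the high- and low-curvature swing-site tubes -- and write
# them as binary STL together with a manifest.  These are the inputs every
# later analysis consumes.

suppressPackageStartupMessages(library(vesselwss))

out_dir <- "results/phantoms"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

specs <- phantom_set(length = 50)
manifest <- character(0)
for (name in names(specs)) {
  spec <- specs[[name]]
  mesh <- generate_tube_mesh(spec)
  path <- file.path(out_dir, paste0(name, ".stl"))
  write_stl(mesh, path)
  line <- sprintf(
    "%s: D = %g mm, L = %g mm, kind = %s%s, %d vertices, %d triangles, watertight = %s",
    name, spec$internal_diameter, spec$length, spec$path_kind,
    if (!is.na(spec$arc_radius)) sprintf(" (arc radius %g mm)",
                                         spec$arc_radius) else "",
    nrow(mesh$vertices), nrow(mesh$triangles), is_watertight(mesh)
  )
  manifest <- c(manifest, line)
  cat(line, "\n")
}
writeLines(manifest, file.path(out_dir, "manifest.txt"))
cat("wrote", length(specs), "phantom meshes to", out_dir, "\n")
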