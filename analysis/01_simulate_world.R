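#!/usr/bin/env Rscript
# Stage 1: generate the synthetic world, meta-analytic maps, lesion cohort,
# and surrogate tracts; write the shared volumes and cohort summary.

source(file.path("analysis", "00_common.R"))

cfg <- load_config()
out <- file.path(cfg$output_dir, "assets")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

log_line("config hash:", config_hash(cfg))

world <- build_world(cfg)
print(world)
write_volume_nifti(world$gm_mask, file.path(out, "gm_mask.nii.gz"),
                   cfg$world$voxel_size_mm)
write_volume_nifti(world$planted_networks,
                   file.path(out, "planted_networks.nii.gz"),
                   cfg$world$voxel_size_mm)
write_volume_nifti(vascular_atlas(world, "two"),
                   file.path(out, "vascular_two.nii.gz"),
                   cfg$world$voxel_size_mm)
write_volume_nifti(vascular_atlas(world, "coarse"),
                   file.path(out, "vascular_coarse.nii.gz"),
                   cfg$world$voxel_size_mm)

lesions <- build_lesions(cfg, world)
print(lesions)
tracts <- build_tracts(cfg, world)

sizes <- vapply(lesions$patients, function(p) sum(p$lesion), numeric(1))
cohort_df <- data.frame(
  patient_id = vapply(lesions$patients, `[[`, character(1), "patient_id"),
  lesion_vox = sizes)
write_tsv_atomic(cohort_df, file.path(out, "cohort.tsv"))

# lesion frequency map: a quick sanity visual of coverage
freq <- Reduce(`+`, lapply(lesions$patients, `[[`, "lesion")) /
  length(lesions$patients)
write_volume_nifti(freq, file.path(out, "lesion_frequency.nii.gz"),
                   cfg$world$voxel_size_mm)

manifest <- data.frame(
  key = c("config_hash", "world_seed", "lesion_seed", "tract_seed",
          "n_patients", "gm_voxels"),
  value = c(config_hash(cfg),
            derive_seed(cfg$master_seed, "study/world"),
            derive_seed(cfg$master_seed, "study/lesions"),
            derive_seed(cfg$master_seed, "study/tracts"),
            length(lesions$patients), sum(world$gm_mask)))
write_tsv_atomic(manifest, file.path(out, "manifest.tsv"))
log_line("stage 1 complete:", out)
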