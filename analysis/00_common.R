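# Shared helpers sourced by every analysis driver. All upstream objects are
# pure functions of (config, master_seed), so each stage can rebuild what it
# needs and artifacts on disk stay human-readable summaries.

suppressMessages(library(vitrials))

load_config <- function() {
  path <- file.path("analysis", "config.yaml")
  if (!file.exists(path)) stop("no analysis/config.yaml; run from the repo root")
  read_run_config(path)
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing artifact ", path, "; run Rscript analysis/", stage,
         " first", call. = FALSE)
  }
  invisible(path)
}

build_world <- function(cfg) {
  generate_world(grid_spec(unlist(cfg$world$dims), cfg$world$voxel_size_mm),
                 n_networks = cfg$world$n_networks,
                 seed = derive_seed(cfg$master_seed, "study/world"))
}

build_receptors <- function(cfg, world) {
  generate_receptors(world, n_receptors = cfg$maps$n_receptors,
                     smoothness_vox = cfg$maps$receptor_smoothness_vox,
                     seed = derive_seed(cfg$master_seed, "study/receptors"))
}

build_transcriptome <- function(cfg, world) {
  generate_transcriptome(world,
                         sites_per_network = cfg$maps$transcriptome_sites_per_network,
                         n_genes = cfg$maps$transcriptome_genes,
                         seed = derive_seed(cfg$master_seed, "study/tx"))
}

build_term_matrix <- function(cfg, world) {
  generate_term_matrix(world, terms_per_network = cfg$maps$terms_per_network,
                       noise_sd = cfg$maps$term_noise_sd,
                       seed = derive_seed(cfg$master_seed, "study/terms"))
}

build_lesions <- function(cfg, world) {
  generate_lesions(world, n_patients = cfg$cohort$n_patients,
                   size_range_vox = unlist(cfg$cohort$lesion_size_vox),
                   seed = derive_seed(cfg$master_seed, "study/lesions"))
}

build_tracts <- function(cfg, world) {
  generate_tracts(world, n_subjects = cfg$cohort$tract_subjects,
                  bundles_per_subject = cfg$cohort$tract_bundles_per_subject,
                  seed = derive_seed(cfg$master_seed, "study/tracts"))
}

build_pair <- function(cfg, world, network_id) {
  if (cfg$ground_truth$criterion == "receptome") {
    subdivide_receptome(network_mask(world, network_id),
                        build_receptors(cfg, world), network_id = network_id)
  } else {
    subdivide_transcriptome(network_mask(world, network_id),
                            build_transcriptome(cfg, world),
                            network_id = network_id)
  }
}

log_line <- function(...) {
  cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "|", ..., "\n")
}
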