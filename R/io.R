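#' Write a volume as NIfTI with an identity-scaled affine
#'
#' @param vol 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel edge length recorded in the header.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(vol, path, voxel_size_mm = 2) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and validate a binary lesion mask from NIfTI
#'
#' Values must be within `1e-6` of 0 or 1; an expected shape may be
#' enforced so a cohort shares one grid.
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param expect_dims optional 3-vector of required dimensions.
#' @return integer 0/1 array.
#' @export
read_mask_nifti <- function(path, expect_dims = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  if (!is.null(expect_dims) && !identical(dim(vol), as.integer(expect_dims))) {
    stop("shape mismatch in ", basename(path), ": (",
         paste(dim(vol), collapse = ","), ") expected (",
         paste(expect_dims, collapse = ","), ")")
  }
  r <- round(vol)
  if (any(abs(vol - r) > 1e-6) || any(!r %in% c(0, 1))) {
    stop("non-binary data in ", basename(path))
  }
  array(as.integer(r), dim(vol))
}

#' Read a lesion cohort directory of NIfTI masks
#'
#' All volumes must share one grid; mismatches name the offending files.
#'
#' @param dir directory of `.nii`/`.nii.gz` masks.
#' @return a `lesion_cohort` (seed `NA`: real data).
#' @export
read_lesion_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no NIfTI files under ", dir)
  first <- read_mask_nifti(files[1])
  patients <- lapply(files, function(f) {
    vol <- tryCatch(read_mask_nifti(f, expect_dims = dim(first)),
                    error = function(e) {
                      stop("cohort shape error: ", basename(files[1]), " vs ",
                           basename(f), ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    meta <- parse_lesion_filename(basename(f))
    list(patient_id = meta$id, lesion = vol, age = meta$age, sex = meta$sex)
  })
  structure(list(patients = patients, seed = NA), class = "lesion_cohort")
}

#' Parse the deposited lesion filename convention
#'
#' `lesion{arbitrary_id}_{age}_{sex}.nii.gz`, with `NA` for unavailable
#' fields. Non-conforming names fall back to an id-only record with a
#' warning.
#'
#' @param name file name.
#' @return list with `id`, `age` (integer or `NA`), `sex` (character or
#'   `NA`).
#' @export
parse_lesion_filename <- function(name) {
  base <- sub("\\.nii(\\.gz)?$", "", name)
  m <- regmatches(base, regexec("^lesion([^_]+)_([^_]+)_([^_]+)$", base))[[1]]
  if (length(m) == 4) {
    age <- suppressWarnings(as.integer(m[3]))
    sex <- if (m[4] == "NA") NA_character_ else m[4]
    return(list(id = m[2], age = age, sex = sex))
  }
  warning("non-conforming lesion filename: ", name, "; using it as the id")
  list(id = base, age = NA_integer_, sex = NA_character_)
}

#' Atomically write a data.frame as TSV
#'
#' Writes to a temporary file in the target directory and renames, so
#' interrupted runs never leave a partial table.
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv_atomic <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a structured run configuration (YAML)
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Stable hash of a configuration for provenance logging
#'
#' @param config named list.
#' @return integer hash.
#' @export
config_hash <- function(config) {
  derive_seed(0, paste(deparse(config), collapse = "\n"))
}
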