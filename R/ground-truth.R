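#' Outcome noise configuration
#'
#' `TE` is the treatment effect, the probability of a favourable outcome
#' under an individually suitable treatment, `P(Y = 1 | W = w*)`. `RE` is
#' the recovery effect, the spontaneous favourable-outcome probability.
#' `TE = 1, RE = 0` is the noiseless endpoint. Two outcome semantics are
#' available: `"branch"` (default) — `Y ~ Bernoulli(TE)` when the allocated
#' treatment is suitable, else `Bernoulli(RE)`; `"or"` — an
#' immune-or-responder composition `Y = I | (R & suitable)` with
#' `I ~ Bern(RE)`, `R ~ Bern(TE)`.
#'
#' @param TE,RE reals in `[0, 1]`.
#' @param model `"branch"` or `"or"`.
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(TE, RE, model = c("branch", "or")) {
  model <- match.arg(model)
  stopifnot(TE >= 0, TE <= 1, RE >= 0, RE <= 1)
  structure(list(TE = TE, RE = RE, model = model), class = "noise_config")
}

#' Binarize a probabilistic disconnectome
#'
#' Strict threshold: a voxel is included iff its value is greater than
#' `threshold` (a value of exactly 0.5 is excluded at the default).
#'
#' @param map volume with values in `[0, 1]`.
#' @param threshold default 0.5.
#' @return binary volume.
#' @export
binarize_disconnectome <- function(map, threshold = 0.5) {
  if (any(map < 0 | map > 1)) stop("disconnectome values must lie in [0, 1]")
  out <- array(0L, dim(map))
  out[map > threshold] <- 1L
  out
}

#' Fraction of a subnetwork covered by a lesion
#'
#' `|lesion n subnetwork| / |subnetwork|`.
#'
#' @param lesion_mask,subnetwork_mask binary volumes of identical shape.
#' @return real in `[0, 1]`.
#' @export
subnetwork_overlap <- function(lesion_mask, subnetwork_mask) {
  stopifnot_same_shape(lesion_mask, subnetwork_mask)
  denom <- sum(subnetwork_mask != 0)
  if (denom == 0) stop("empty subnetwork mask")
  sum(lesion_mask != 0 & subnetwork_mask != 0) / denom
}

#' Designate treatment responsiveness of one lesion
#'
#' A lesion is responsive to a treatment iff its overlap with the
#' corresponding subnetwork strictly exceeds `threshold` (default 5% of the
#' subnetwork's volume).
#'
#' @param lesion_mask binary volume (lesion or binarized disconnectome).
#' @param pair a `subnetwork_pair`.
#' @param threshold overlap threshold, default 0.05.
#' @return named integer vector `c(r_A, r_B)` with entries in `{0, 1}`.
#' @export
designate <- function(lesion_mask, pair, threshold = 0.05) {
  c(r_A = as.integer(subnetwork_overlap(lesion_mask, pair$mask_A) > threshold),
    r_B = as.integer(subnetwork_overlap(lesion_mask, pair$mask_B) > threshold))
}

#' Assemble the hidden ground truth for a virtual trial cohort
#'
#' For each patient the designating mask is the lesion itself
#' (`rep_kind = "lesion"`) or the binarized disconnectome
#' (`rep_kind = "disconnectome"`, requires `tracts`). Patients responsive to
#' neither treatment are excluded. Each retained record carries
#' `s = r_A - r_B`, the optimal arm `w_star` (`"either"` for dual
#' responders), and the true individual effect
#' `tau = s * (TE - RE)` (effect-scaled default) or `tau = s`
#' (`tau_scale = "sign"`).
#'
#' @param cohort a `lesion_cohort`.
#' @param pair a `subnetwork_pair`.
#' @param rep_kind `"lesion"` or `"disconnectome"`.
#' @param tracts a `tract_set` (required for disconnectomes).
#' @param noise a `noise_config`.
#' @param overlap_threshold responsiveness threshold (default 0.05).
#' @param disconnectome_threshold binarization threshold (default 0.5).
#' @param tau_scale `"effect"` (default) or `"sign"`.
#' @return data.frame of class `responsiveness_records` with columns
#'   `patient_id`, `r_A`, `r_B`, `s`, `w_star`, `tau`, `rep_kind`.
#' @export
build_cohort <- function(cohort, pair, rep_kind = c("lesion", "disconnectome"),
                         tracts = NULL, noise = noise_config(1, 0),
                         overlap_threshold = 0.05,
                         disconnectome_threshold = 0.5,
                         tau_scale = c("effect", "sign")) {
  rep_kind <- match.arg(rep_kind)
  tau_scale <- match.arg(tau_scale)
  if (rep_kind == "disconnectome" && is.null(tracts)) {
    stop("disconnectome representation requires a tract set")
  }
  rows <- lapply(cohort$patients, function(p) {
    mask <- if (rep_kind == "lesion") p$lesion else {
      binarize_disconnectome(compute_disconnectome(p$lesion, tracts),
                             disconnectome_threshold)
    }
    r <- designate(mask, pair, overlap_threshold)
    if (r[["r_A"]] + r[["r_B"]] == 0) return(NULL)
    s <- r[["r_A"]] - r[["r_B"]]
    data.frame(patient_id = p$patient_id, r_A = r[["r_A"]], r_B = r[["r_B"]],
               s = s,
               w_star = if (s > 0) "A" else if (s < 0) "B" else "either",
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    stop("empty trial: no patient is responsive to either treatment")
  }
  out <- do.call(rbind, rows)
  out$tau <- if (tau_scale == "effect") out$s * (noise$TE - noise$RE) else out$s
  out$rep_kind <- rep_kind
  class(out) <- c("responsiveness_records", "data.frame")
  out
}

#' Expected outcome probability under an allocated treatment
#'
#' Branch semantics (default): returns `TE` when the allocation is
#' individually suitable (`w == w_star`, or `w_star == "either"`), else
#' `RE`. OR semantics: `1 - (1 - RE) * (1 - TE * suitable)`.
#'
#' @param record one row of a `responsiveness_records` data.frame (or any
#'   list with a `w_star` field).
#' @param w `"A"` or `"B"`.
#' @param noise a `noise_config`.
#' @return probability in `[0, 1]`.
#' @export
expected_outcomes <- function(record, w, noise) {
  suitable <- record$w_star == "either" | record$w_star == w
  if (noise$model == "branch") {
    ifelse(suitable, noise$TE, noise$RE)
  } else {
    1 - (1 - noise$RE) * (1 - noise$TE * as.numeric(suitable))
  }
}
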