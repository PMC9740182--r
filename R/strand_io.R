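#' Write a cohort bundle to disk
#'
#' Writes the metadata table (`metadata.csv`), one strand CSV per subject
#' under `strands/` (columns: `point`, one column per element, `S` for
#' sulfur) and a versioned JSON manifest (`manifest.json`, schema
#' `hairdyn-manifest-v1`) echoing the generator configuration.
#'
#' @param cohort List as returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "strands"), recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(dir, "metadata.csv")
  write.csv(cohort$subjects, meta_path, row.names = FALSE)
  files <- character(0)
  for (p in cohort$profiles) {
    df <- data.frame(point = p$points, p$channels, S = p$sulfur,
                     check.names = FALSE)
    f <- file.path("strands", paste0(p$subject_id, ".csv"))
    utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                       file.path(dir, f), sep = ",", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  cfg <- cohort$config
  manifest <- list(schema = "hairdyn-manifest-v1",
                   config = unclass(cfg),
                   seed = if (!is.null(cfg)) cfg$seed else NA,
                   panel = colnames(cohort$profiles[[1]]$channels),
                   metadata = "metadata.csv", strands = files)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Read a cohort bundle from its manifest
#'
#' Validates the manifest schema, the declared element panel, uniqueness of
#' subject ids and non-negativity of intensities, and reconstructs subject
#' records and strand profiles. Latent generator parameters are not part of
#' the file format, so a written-then-read cohort carries observed data only.
#'
#' @param manifest_path Path to `manifest.json`.
#'
#' @return List with `subjects` and `profiles`, as in [generate_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$schema, "hairdyn-manifest-v1"))
    stop("unsupported manifest schema: ", manifest$schema)
  dir <- dirname(manifest_path)
  subjects <- read.csv(file.path(dir, manifest$metadata),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id in metadata: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  panel <- manifest$panel
  profiles <- vector("list", length(manifest$strands))
  for (i in seq_along(manifest$strands)) {
    f <- file.path(dir, manifest$strands[i])
    sid <- sub("\\.csv$", "", basename(f))
    if (!file.exists(f))
      stop("strand file missing for subject ", sid, ": ", f)
    df <- read.csv(f, check.names = FALSE)
    missing_cols <- setdiff(c("point", panel, "S"), names(df))
    if (length(missing_cols))
      stop("strand of subject ", sid, " lacks declared columns: ",
           paste(missing_cols, collapse = ", "))
    profiles[[i]] <- strand_profile(sid, as.matrix(df[, panel, drop = FALSE]),
                                    df$S)
  }
  names(profiles) <- vapply(profiles, `[[`, "", "subject_id")
  list(subjects = subjects, profiles = profiles, config = manifest$config)
}

#' Element-to-sulfur ratio matrix for one strand
#'
#' Divides every element channel point-wise by the sulfur channel, the
#' standard normalisation against hair-matrix density variation. Points where
#' sulfur is non-positive or any value is missing are dropped from all
#' elements of the subject (a common retained index keeps the series evenly
#' sampled, which delay embedding requires); the drop count is reported via
#' `message()`.
#'
#' @param profile A [strand_profile()].
#' @param max_drop_fraction Strands losing more than this fraction of points
#'   are rejected as unusable (default 0.1).
#'
#' @return Numeric matrix of ratios (points x elements) with attribute
#'   `retained` giving the retained point indices.
#' @export
ratio_matrix <- function(profile, max_drop_fraction = 0.1) {
  n <- length(profile$sulfur)
  keep <- profile$sulfur > 0 & !is.na(profile$sulfur) &
    stats::complete.cases(profile$channels)
  dropped <- sum(!keep)
  if (dropped > max_drop_fraction * n)
    stop("subject ", profile$subject_id, ": ", dropped, " of ", n,
         " points unusable (> ", 100 * max_drop_fraction, "%)")
  if (dropped > 0)
    message("subject ", profile$subject_id, ": dropped ", dropped,
            " point(s) on the common index")
  ratios <- profile$channels[keep, , drop = FALSE] / profile$sulfur[keep]
  attr(ratios, "retained") <- which(keep)
  ratios
}

#' Single-element ratio series
#'
#' @param profile A [strand_profile()].
#' @param element Element label, must be present in the profile.
#' @param max_drop_fraction Passed to [ratio_matrix()].
#'
#' @return List of class `ratio_series` with `subject_id`, `element`,
#'   `values` and `n_points`.
#' @export
to_ratio_series <- function(profile, element, max_drop_fraction = 0.1) {
  if (!element %in% colnames(profile$channels))
    stop("element ", element, " absent from profile of subject ",
         profile$subject_id)
  rm_ <- ratio_matrix(profile, max_drop_fraction)
  structure(list(subject_id = profile$subject_id, element = element,
                 values = as.numeric(rm_[, element]), n_points = nrow(rm_)),
            class = "ratio_series")
}
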