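#' Subject metadata table
#'
#' Validates a subject metadata data.frame for the three-group tremor design:
#' `group` in {TD, ET, HC}; `duration` (years) required and non-negative for
#' every patient (TD, ET) and absent (NA) for HC; clinical scores (MoCA,
#' MMSE, HAM_A, HAM_D, VHI) may be NA for HC — absences are explicit NA,
#' never sentinel numbers.
#'
#' @param df data.frame with at least columns `subject_id`, `group`, `age`,
#'   `sex`; optionally `education`, `duration`, `hy_stage` and score columns.
#' @return the validated data.frame (group as factor TD/ET/HC), class
#'   `subject_metadata` prepended.
#' @export
subject_metadata <- function(df) {
  req <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_fmt("metadata missing required column(s): %s",
             paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id)) {
    stop_fmt("uniqueness error: duplicate subject ids: %s",
             paste(unique(df$subject_id[duplicated(df$subject_id)]),
                   collapse = ", "))
  }
  if (!all(df$group %in% c("TD", "ET", "HC"))) {
    stop_fmt("group must be one of TD, ET, HC")
  }
  if (!all(df$sex %in% c("M", "F"))) stop_fmt("sex must be M or F")
  df$group <- factor(df$group, levels = c("TD", "ET", "HC"))
  if (!"duration" %in% names(df)) df$duration <- NA_real_
  pat <- df$group != "HC"
  if (any(pat & is.na(df$duration))) {
    stop_fmt("duration is required for every TD and ET subject (missing: %s)",
             paste(df$subject_id[pat & is.na(df$duration)], collapse = ", "))
  }
  if (any(df$duration < 0, na.rm = TRUE)) {
    stop_fmt("duration must be >= 0")
  }
  class(df) <- c("subject_metadata", class(df))
  df
}

#' Morphometry dataset container
#'
#' Bundles the per-subject cortical thickness matrix (mm), subcortical
#' volume table (mm^3), subject metadata and the atlas, with rows of
#' `thickness` and `volumes` aligned to the metadata order.
#'
#' @param thickness subjects x vertices numeric matrix, strictly positive,
#'   no missing entries; rownames are subject ids.
#' @param volumes data.frame of subjects x structures volumes; must contain
#'   at least `Pallidum.L`, `Pallidum.R`, `Thalamus.L`, `Thalamus.R`.
#' @param subjects a `subject_metadata` data.frame (or coercible).
#' @param atlas a `surface_atlas` with as many vertices as `thickness`
#'   columns.
#' @return object of class `morphometry_dataset`.
#' @export
morphometry_dataset <- function(thickness, volumes, subjects, atlas) {
  if (!inherits(subjects, "subject_metadata")) {
    subjects <- subject_metadata(subjects)
  }
  n <- nrow(subjects)
  if (nrow(thickness) != n || nrow(volumes) != n) {
    stop_fmt("row counts differ: thickness %d, volumes %d, subjects %d",
             nrow(thickness), nrow(volumes), n)
  }
  if (anyNA(thickness)) stop_fmt("validation error: thickness has missing entries")
  if (any(thickness <= 0)) {
    bad <- which(thickness <= 0, arr.ind = TRUE)[1, ]
    stop_fmt("validation error: non-positive thickness at subject %s vertex %d",
             rownames(thickness)[bad[1]] %||% bad[1], bad[2])
  }
  if (ncol(thickness) != length(atlas$vertex_ids)) {
    stop_fmt("thickness has %d vertices, atlas has %d",
             ncol(thickness), length(atlas$vertex_ids))
  }
  need <- c("Pallidum.L", "Pallidum.R", "Thalamus.L", "Thalamus.R")
  miss <- setdiff(need, names(volumes))
  if (length(miss)) {
    stop_fmt("volumes must include structure(s): %s", paste(miss, collapse = ", "))
  }
  rn <- rownames(thickness)
  if (!is.null(rn) && !identical(rn, as.character(subjects$subject_id))) {
    stop_fmt("thickness row order does not match subject order")
  }
  rownames(thickness) <- as.character(subjects$subject_id)
  rownames(volumes) <- as.character(subjects$subject_id)
  structure(list(thickness = thickness, volumes = volumes,
                 subjects = subjects, atlas = atlas),
            class = "morphometry_dataset")
}

#' @export
print.morphometry_dataset <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf(
    "morphometry_dataset: %d subjects (TD %d / ET %d / HC %d), %d vertices, %d structures\n",
    nrow(x$subjects), tab["TD"], tab["ET"], tab["HC"],
    ncol(x$thickness), ncol(x$volumes)))
  invisible(x)
}

#' Assemble a dataset from separate tables
#'
#' Aligns a thickness table, a volume table and a metadata table by subject
#' id (first column or `subject_id` column) and validates the result.  Any
#' id mismatch between the three tables is a hard error listing the
#' symmetric difference.
#'
#' @param thickness_table data.frame: subject id column + one column per
#'   vertex.
#' @param volume_table data.frame: subject id column + one column per
#'   structure.
#' @param metadata_table data.frame of subject metadata.
#' @param atlas a `surface_atlas`.
#' @return a `morphometry_dataset`.
#' @export
assemble_dataset <- function(thickness_table, volume_table, metadata_table,
                             atlas) {
  idcol <- function(df) {
    if ("subject_id" %in% names(df)) as.character(df$subject_id)
    else as.character(df[[1]])
  }
  ids_m <- idcol(metadata_table)
  for (nm in c("thickness", "volume")) {
    tab <- if (nm == "thickness") thickness_table else volume_table
    ids <- idcol(tab)
    d1 <- setdiff(ids_m, ids); d2 <- setdiff(ids, ids_m)
    if (length(d1) || length(d2)) {
      stop_fmt("alignment error in %s table; missing: {%s}; extra: {%s}",
               nm, paste(d1, collapse = ", "), paste(d2, collapse = ", "))
    }
  }
  dropid <- function(df) {
    keep <- setdiff(names(df), "subject_id")
    if (!"subject_id" %in% names(df)) keep <- names(df)[-1]
    df[match(ids_m, idcol(df)), keep, drop = FALSE]
  }
  thick <- as.matrix(dropid(thickness_table))
  storage.mode(thick) <- "double"
  rownames(thick) <- ids_m
  vols <- dropid(volume_table)
  meta <- metadata_table
  meta$subject_id <- ids_m
  morphometry_dataset(thick, vols, subject_metadata(meta), atlas)
}

#' Row-subset a dataset
#' @param dataset a `morphometry_dataset`.
#' @param idx logical or integer subject index.
#' @return the subset `morphometry_dataset`.
#' @export
subset_dataset <- function(dataset, idx) {
  sub <- dataset$subjects[idx, , drop = FALSE]
  class(sub) <- class(dataset$subjects)
  morphometry_dataset(dataset$thickness[idx, , drop = FALSE],
                      dataset$volumes[idx, , drop = FALSE],
                      sub, dataset$atlas)
}

#' Early-stage subgroup filter
#'
#' Subsets the patient group named by `rule` to its early-stage members,
#' keeping HC unchanged and dropping the other patient group:
#' `td_hy_le2` keeps TD with Hoehn-Yahr stage <= 2; `et_duration_lt10`
#' keeps ET with disease duration strictly below 10 years.
#'
#' @param dataset a `morphometry_dataset`.
#' @param rule `"td_hy_le2"` or `"et_duration_lt10"`.
#' @return the filtered `morphometry_dataset`; attribute `counts` records
#'   retained group sizes.  Warns (does not error) if no patient survives.
#' @export
early_stage_filter <- function(dataset,
                               rule = c("td_hy_le2", "et_duration_lt10")) {
  rule <- match.arg(rule)
  meta <- dataset$subjects
  if (rule == "td_hy_le2") {
    if (!any(meta$group == "TD")) {
      stop_fmt("usage error: rule td_hy_le2 needs TD subjects in the dataset")
    }
    if (!"hy_stage" %in% names(meta) || all(is.na(meta$hy_stage[meta$group == "TD"]))) {
      stop_fmt("usage error: td_hy_le2 requires H-Y stage for TD subjects")
    }
    keep <- (meta$group == "HC") |
      (meta$group == "TD" & !is.na(meta$hy_stage) & meta$hy_stage <= 2)
  } else {
    if (!any(meta$group == "ET")) {
      stop_fmt("usage error: rule et_duration_lt10 needs ET subjects in the dataset")
    }
    keep <- (meta$group == "HC") |
      (meta$group == "ET" & meta$duration < 10)  # strictly less than 10 years
  }
  out <- subset_dataset(dataset, which(keep))
  counts <- table(out$subjects$group)
  if (sum(counts[c("TD", "ET")]) == 0) {
    warn_fmt("early_stage_filter: no patient satisfies rule %s", rule)
  }
  attr(out, "counts") <- counts
  out
}
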