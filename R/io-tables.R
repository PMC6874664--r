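## Flat tables: electrodes, atlas files, cohort (outcome predictor) tables.
## All are comma-delimited text with a mandatory header; missing optional
## numerics are empty cells, never sentinel numbers.

electrodeFlagCols <- c("soz", "spike", "lesion", "artifact", "resected")
electrodeCols <- c("patient_id", "electrode_id", "vertex_id", "x", "y", "z",
                   electrodeFlagCols, "mi", "z")

#' Names of the outcome-model predictors
#'
#' The eleven predictors of the seizure-outcome logistic models, in canonical
#' order: demographics and seizure burden (`age`, `gender`, `daily_seizures`,
#' `n_aeds`), laterality and imaging (`left_hemisphere`, `mri_lesion`),
#' recording and surgical variables (`habitual_seizures_during_ecog`,
#' `incomplete_soz_resection`, `extratemporal_resection`, `resection_size`)
#' and the coupling summary (`subtraction_mi_z`).
#'
#' @param model `"full"` keeps all eleven; `"no-mi"` drops
#'   `subtraction_mi_z`; `"no-soz"` drops the two SOZ-dependent variables
#'   (`habitual_seizures_during_ecog`, `incomplete_soz_resection`) while
#'   keeping `subtraction_mi_z`.
#' @return Character vector of predictor column names.
#' @export
modelPredictors <- function(model = c("full", "no-mi", "no-soz")) {
  model <- match.arg(model)
  full <- c("age", "gender", "daily_seizures", "n_aeds", "left_hemisphere",
            "mri_lesion", "habitual_seizures_during_ecog",
            "incomplete_soz_resection", "extratemporal_resection",
            "resection_size", "subtraction_mi_z")
  switch(model,
         "full" = full,
         "no-mi" = setdiff(full, "subtraction_mi_z"),
         "no-soz" = setdiff(full, c("habitual_seizures_during_ecog",
                                    "incomplete_soz_resection")))
}

#' Validate an electrode table
#'
#' Enforces the electrode-table contract: unique (patient_id, electrode_id)
#' pairs, strict 0/1 flags, anatomical information present as a vertex index
#' and/or xyz millimetre coordinates, and non-negative MI where given. Rows
#' flagged `artifact = 1` are retained but excluded from all computation.
#'
#' @param df data.frame with (a subset of) the electrode-table columns
#'   `patient_id, electrode_id, vertex_id, x, y, z, soz, spike, lesion,
#'   artifact, resected, mi, z`.
#' @return The validated (flag-coerced) data.frame, invisibly classed as-is.
#' @export
validateElectrodeTable <- function(df) {
  need <- c("patient_id", "electrode_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("electrode table lacks required column(s): %s",
          paste(miss, collapse = ", "))
  key <- paste(df$patient_id, df$electrode_id, sep = "\r")
  if (anyDuplicated(key))
    stopf("duplicate (patient_id, electrode_id): %s",
          paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  hasVertex <- "vertex_id" %in% names(df) && any(!is.na(df$vertex_id))
  hasXyz <- all(c("x", "y", "z") %in% names(df))
  if (!hasVertex && !hasXyz)
    stopf("electrode table needs 'vertex_id' and/or 'x','y','z' columns")
  if ("vertex_id" %in% names(df)) {
    v <- df$vertex_id[!is.na(df$vertex_id)]
    if (length(v) && (any(v < 1) || any(v != round(v))))
      stopf("'vertex_id' must contain positive (1-based) integers")
  }
  for (fc in intersect(electrodeFlagCols, names(df)))
    df[[fc]] <- asFlag(df[[fc]], fc)
  for (fc in setdiff(electrodeFlagCols, names(df)))
    df[[fc]] <- 0L
  if ("mi" %in% names(df) && any(df$mi < 0, na.rm = TRUE))
    stopf("'mi' must be non-negative")
  df
}

#' Identify non-epileptic electrode rows
#'
#' A recording site is non-epileptic when it is involved in neither the
#' seizure-onset zone, nor interictal spike discharges, nor an epileptogenic
#' lesion (`soz = spike = lesion = 0`). Artifact-flagged rows are never
#' non-epileptic for computation purposes.
#'
#' @param df a validated electrode table.
#' @return Logical vector, one entry per row.
#' @export
isNonEpileptic <- function(df) {
  df$soz == 0L & df$spike == 0L & df$lesion == 0L & df$artifact == 0L
}

#' Read / write an electrode table
#'
#' Comma-delimited text with a mandatory header. Empty cells represent
#' missing optional numerics (`vertex_id`, `x`, `y`, `z`, `mi`, `z`).
#'
#' @param path file path.
#' @return `readElectrodeTable()`: the validated data.frame.
#' @export
readElectrodeTable <- function(path) {
  if (!file.exists(path)) stopf("electrode table not found: '%s'", path)
  df <- utils::read.csv(path, check.names = FALSE)
  for (cc in intersect(c("patient_id", "electrode_id"), names(df)))
    df[[cc]] <- as.character(df[[cc]])
  validateElectrodeTable(df)
}

#' @rdname readElectrodeTable
#' @param df a validated electrode table.
#' @export
writeElectrodeTable <- function(df, path) {
  writeCsvFull(df, path)
}

#' Read / write a normative atlas file
#'
#' Columns: `vertex_id` (1-based, one row per mesh vertex), `mean_mi`,
#' `sd_mi`, `k`, `n_pool`.
#'
#' @param path file path.
#' @return `readAtlas()`: a [NormativeAtlas-class].
#' @export
readAtlas <- function(path) {
  if (!file.exists(path)) stopf("atlas file not found: '%s'", path)
  df <- utils::read.csv(path)
  need <- c("vertex_id", "mean_mi", "sd_mi", "k", "n_pool")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("atlas file lacks column(s): %s", paste(miss, collapse = ", "))
  if (!setequal(df$vertex_id, seq_len(nrow(df))))
    stopf("atlas must have exactly one record per vertex 1..V")
  df <- df[order(df$vertex_id), ]
  normativeAtlas(df$mean_mi, df$sd_mi, df$k[1L], df$n_pool[1L])
}

#' @rdname readAtlas
#' @param atlas a [NormativeAtlas-class].
#' @export
writeAtlas <- function(atlas, path) {
  stopifnot(is(atlas, "NormativeAtlas"))
  df <- data.frame(vertex_id = seq_along(atlas@meanMi),
                   mean_mi = atlas@meanMi, sd_mi = atlas@sdMi,
                   k = atlas@k, n_pool = atlas@nPool)
  writeCsvFull(df, path)
}

#' Read a cohort (outcome predictor) table
#'
#' Comma-delimited with the eleven predictor columns (see
#' [modelPredictors()]) plus `outcome` (1 = complete seizure freedom, ILAE
#' class 1; 0 otherwise). An optional `patient_id` column is carried through.
#'
#' @param path file path.
#' @return Validated data.frame.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stopf("cohort table not found: '%s'", path)
  df <- utils::read.csv(path, check.names = FALSE)
  validateCohortTable(df)
}

#' @rdname readCohortTable
#' @param df a cohort data.frame.
#' @export
validateCohortTable <- function(df) {
  need <- c(modelPredictors("full"), "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("cohort table lacks column(s): %s", paste(miss, collapse = ", "))
  bin <- c("gender", "daily_seizures", "left_hemisphere", "mri_lesion",
           "habitual_seizures_during_ecog", "incomplete_soz_resection",
           "extratemporal_resection", "outcome")
  for (b in bin) df[[b]] <- asFlag(df[[b]], b)
  if (any(df$resection_size < 0 | df$resection_size > 100, na.rm = TRUE))
    stopf("'resection_size' must lie in [0, 100] (percent of hemisphere)")
  if (any(df$n_aeds < 0, na.rm = TRUE)) stopf("'n_aeds' must be >= 0")
  if (anyNA(df[need])) stopf("cohort table must not contain missing cells")
  df
}
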