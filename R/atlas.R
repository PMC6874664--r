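#' Assign electrodes to their nearest mesh vertex
#'
#' Returns the index of the mesh vertex with minimum Euclidean distance to
#' each coordinate; ties are broken by the lowest vertex index.
#'
#' @param xyz numeric length-3 coordinate (mm) or an n x 3 matrix.
#' @param mesh a [SurfaceMesh-class].
#' @return Integer vertex index (vector of indices for matrix input).
#' @export
assignVertex <- function(xyz, mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  v <- mesh@vertices
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L) stopf("'xyz' must have 3 columns")
  out <- integer(nrow(xyz))
  for (i in seq_len(nrow(xyz)))
    out[i] <- which.min(distSqToPoints(xyz[i, ], v))
  out
}

electrodeCoords <- function(df, mesh = NULL) {
  if (all(c("x", "y", "z") %in% names(df)) &&
      !anyNA(df$x) && !anyNA(df$y) && !anyNA(df$z))
    return(cbind(df$x, df$y, df$z))
  if (is.null(mesh) || !("vertex_id" %in% names(df)) || anyNA(df$vertex_id))
    stopf("electrodes need xyz coordinates, or vertex_id plus a mesh")
  mesh@vertices[df$vertex_id, , drop = FALSE]
}

#' Build the normative modulation-index atlas
#'
#' At every vertex of the average-brain mesh, selects the `k` pool
#' electrodes with the smallest Euclidean distance to the vertex (ties by
#' pool row order) and records the mean and sample standard deviation
#' (denominator `k - 1`) of their MI values. The pool must consist solely of
#' non-epileptic, artifact-free sites with MI present.
#'
#' @param pool validated electrode table of non-epileptic sites with `mi`.
#' @param mesh a [SurfaceMesh-class].
#' @param k neighbourhood size (default 30).
#' @return A [NormativeAtlas-class] (with per-vertex distance to the k-th
#'   neighbour retained as a diagnostic).
#' @export
buildAtlas <- function(pool, mesh, k = 30) {
  stopifnot(is(mesh, "SurfaceMesh"))
  pool <- validateElectrodeTable(pool)
  if (!("mi" %in% names(pool)) || anyNA(pool$mi))
    stopf("every pool electrode must carry an 'mi' value")
  if (!all(isNonEpileptic(pool)))
    stopf("pool contains epileptic or artifact rows (soz/spike/lesion/artifact must all be 0)")
  k <- as.integer(k)
  if (k < 2L) stopf("'k' must be at least 2")
  if (nrow(pool) < k)
    stopf("pool size %d is smaller than k = %d", nrow(pool), k)
  pc <- electrodeCoords(pool, mesh)
  v <- mesh@vertices
  nv <- nrow(v)
  mu <- numeric(nv); sd_ <- numeric(nv); kth <- numeric(nv)
  mi <- pool$mi
  for (i in seq_len(nv)) {
    d2 <- distSqToPoints(v[i, ], pc)
    nb <- order(d2)[seq_len(k)]        # stable: ties by pool row order
    mu[i] <- mean(mi[nb])
    sd_[i] <- stats::sd(mi[nb])
    kth[i] <- sqrt(d2[nb[k]])
  }
  atlas <- normativeAtlas(mu, sd_, k, nrow(pool))
  atlas@kthDist <- kth
  atlas
}

#' MI z-scores against the normative atlas
#'
#' Standardises each electrode's MI against the normative mean and SD at its
#' mesh vertex: `z = (mi - mean_v) / sd_v`. Artifact-flagged electrodes are
#' excluded. Where the atlas SD is zero the z-score is undefined (`NA`, with
#' a warning), never infinite.
#'
#' Within an atlas cohort, scoring should exclude the scored patient's own
#' sites from the pool to avoid self-normalisation: `loo = TRUE` rebuilds
#' the atlas once per patient without that patient (leave-one-patient-out),
#' and `excludePatient` does the same for a single named patient.
#' Cross-cohort scoring (patients who did not contribute to the pool) uses
#' the prebuilt `atlas` directly.
#'
#' @param electrodes validated electrode table with `mi`.
#' @param atlas a [NormativeAtlas-class]; may be `NULL` when `pool` is given.
#' @param mesh a [SurfaceMesh-class]; needed to place electrodes lacking
#'   `vertex_id` and to rebuild pools.
#' @param pool the non-epileptic pool table (required for `loo` /
#'   `excludePatient` rebuilds, or when `atlas` is `NULL`).
#' @param k neighbourhood size for pool rebuilds (default: the atlas's k,
#'   else 30).
#' @param excludePatient patient id whose sites are removed from the pool
#'   before scoring (no-op if the patient is not in the pool).
#' @param loo leave-one-patient-out scoring for every patient in
#'   `electrodes`.
#' @return data.frame (z-score table): `patient_id`, `electrode_id`,
#'   `vertex_id`, `mi`, `z`, `distance_to_kth_neighbor`, plus the clinical
#'   flag columns carried over.
#' @export
miZscore <- function(electrodes, atlas = NULL, mesh = NULL, pool = NULL,
                     k = NULL, excludePatient = NULL, loo = FALSE) {
  electrodes <- validateElectrodeTable(electrodes)
  if (!("mi" %in% names(electrodes)))
    stopf("electrodes must carry an 'mi' column to be z-scored")
  electrodes <- electrodes[electrodes$artifact == 0L, , drop = FALSE]
  if (!nrow(electrodes)) stopf("no artifact-free electrodes to score")
  if (is.null(k))
    k <- if (!is.null(atlas)) atlasK(atlas) else 30L
  if (is.null(atlas) && is.null(pool))
    stopf("provide an 'atlas' or a 'pool' to build one from")

  needVertex <- !("vertex_id" %in% names(electrodes)) ||
    anyNA(electrodes$vertex_id)
  if (needVertex) {
    if (is.null(mesh))
      stopf("a 'mesh' is required to assign vertices from coordinates")
    electrodes$vertex_id <- assignVertex(electrodeCoords(electrodes), mesh)
  }

  if (loo) {
    if (is.null(pool) || is.null(mesh))
      stopf("leave-one-patient-out scoring needs 'pool' and 'mesh'")
    parts <- lapply(unique(electrodes$patient_id), function(p) {
      sub <- electrodes[electrodes$patient_id == p, , drop = FALSE]
      miZscore(sub, atlas = NULL, mesh = mesh, pool = pool, k = k,
               excludePatient = p)
    })
    return(do.call(rbind, parts))
  }

  if (!is.null(excludePatient)) {
    if (is.null(pool) || is.null(mesh))
      stopf("'excludePatient' needs 'pool' and 'mesh' to rebuild the atlas")
    if (excludePatient %in% pool$patient_id) {
      pool <- pool[pool$patient_id != excludePatient, , drop = FALSE]
      atlas <- NULL
    }
  }
  if (is.null(atlas)) atlas <- buildAtlas(pool, mesh, k = k)
  nv <- length(atlas@meanMi)
  if (any(electrodes$vertex_id > nv))
    stopf("electrode vertex_id exceeds atlas size (%d vertices)", nv)

  mu <- atlas@meanMi[electrodes$vertex_id]
  sg <- atlas@sdMi[electrodes$vertex_id]
  z <- ifelse(sg > 0, (electrodes$mi - mu) / sg, NA_real_)
  if (anyNA(z))
    warnf("%d electrode(s) at vertices with zero normative SD: z undefined",
          sum(is.na(z)))
  kd <- if (length(atlas@kthDist)) atlas@kthDist[electrodes$vertex_id]
        else NA_real_
  out <- electrodes
  out$z <- z
  out$distance_to_kth_neighbor <- kd
  out
}

#' Subtraction MI z-score of one patient
#'
#' Mean MI z-score over all resected electrodes minus the mean over all
#' preserved electrodes. A patient scores high when high-deviation cortex
#' was removed and low-deviation cortex spared.
#'
#' @param ztab z-score table (see [miZscore()]) for a single patient.
#' @return data.frame with `patient_id`, `mean_z_resected`,
#'   `mean_z_preserved`, `subtraction_mi_z`.
#' @export
subtractionMiZscore <- function(ztab) {
  if (length(unique(ztab$patient_id)) != 1L)
    stopf("subtractionMiZscore() expects a single patient's table")
  z <- ztab$z[!is.na(ztab$z)]
  res <- ztab$resected[!is.na(ztab$z)]
  if (!sum(res == 1L)) stopf("patient '%s' has no scored resected electrodes",
                             ztab$patient_id[1L])
  if (!sum(res == 0L)) stopf("patient '%s' has no scored preserved electrodes",
                             ztab$patient_id[1L])
  mr <- mean(z[res == 1L]); mp <- mean(z[res == 0L])
  data.frame(patient_id = ztab$patient_id[1L], mean_z_resected = mr,
             mean_z_preserved = mp, subtraction_mi_z = mr - mp,
             stringsAsFactors = FALSE)
}

#' @rdname subtractionMiZscore
#' @details `cohortSubtractionScores()` applies the computation per patient,
#'   skipping (with a message) patients lacking a resected or preserved side.
#' @export
cohortSubtractionScores <- function(ztab) {
  parts <- lapply(unique(ztab$patient_id), function(p) {
    sub <- ztab[ztab$patient_id == p, , drop = FALSE]
    tryCatch(subtractionMiZscore(sub), error = function(e) {
      message("skipping patient '", p, "': ", conditionMessage(e))
      NULL
    })
  })
  do.call(rbind, parts)
}

#' Per-patient SOZ and non-SOZ median z-scores
#'
#' Median MI z-score within the seizure-onset zone and outside it, for one
#' patient (even counts give the mean of the two central values, as usual).
#'
#' @param ztab z-score table for a single patient.
#' @return data.frame with `patient_id`, `median_z_soz`, `median_z_nonsoz`,
#'   `n_soz`, `n_nonsoz`.
#' @export
patientSozMedians <- function(ztab) {
  if (length(unique(ztab$patient_id)) != 1L)
    stopf("patientSozMedians() expects a single patient's table")
  ok <- !is.na(ztab$z)
  zs <- ztab$z[ok & ztab$soz == 1L]
  zn <- ztab$z[ok & ztab$soz == 0L]
  if (!length(zs))
    stopf("patient '%s' has no SOZ electrodes", ztab$patient_id[1L])
  if (!length(zn))
    stopf("patient '%s' has no non-SOZ electrodes", ztab$patient_id[1L])
  data.frame(patient_id = ztab$patient_id[1L],
             median_z_soz = stats::median(zs),
             median_z_nonsoz = stats::median(zn),
             n_soz = length(zs), n_nonsoz = length(zn),
             stringsAsFactors = FALSE)
}

#' @rdname patientSozMedians
#' @details `cohortSozMedians()` applies the computation per patient,
#'   skipping (with a message) patients without SOZ or non-SOZ electrodes —
#'   mirroring cohorts in which not every patient's recording captured the
#'   SOZ.
#' @export
cohortSozMedians <- function(ztab) {
  parts <- lapply(unique(ztab$patient_id), function(p) {
    sub <- ztab[ztab$patient_id == p, , drop = FALSE]
    tryCatch(patientSozMedians(sub), error = function(e) {
      message("skipping patient '", p, "': ", conditionMessage(e))
      NULL
    })
  })
  do.call(rbind, parts)
}
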