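#' Triangulated sphere mesh
#'
#' Deterministic latitude/longitude triangulation of a sphere, used as a
#' stand-in cortical surface for simulations and tests (the package treats
#' any supplied mesh as authoritative; this one simply provides a closed
#' surface at brain-like scale).
#'
#' @param nLat number of latitude rings between the poles (>= 2).
#' @param nLon number of longitudes (>= 3).
#' @param radius sphere radius in mm (default 70, roughly hemispheric scale).
#' @return A [SurfaceMesh-class] with `(nLat - 1) * nLon + 2` vertices.
#' @export
sphereMesh <- function(nLat = 12, nLon = 16, radius = 70) {
  stopifnot(nLat >= 2, nLon >= 3)
  theta <- pi * seq_len(nLat - 1) / nLat
  phi <- 2 * pi * (seq_len(nLon) - 1) / nLon
  ring <- function(th) cbind(radius * sin(th) * cos(phi),
                             radius * sin(th) * sin(phi),
                             radius * cos(th))
  v <- rbind(c(0, 0, radius), do.call(rbind, lapply(theta, ring)),
             c(0, 0, -radius))
  idx <- function(i, j) 1L + (i - 1L) * nLon + ((j - 1L) %% nLon) + 1L
  f <- list()
  for (j in seq_len(nLon)) {                       # pole caps
    f[[length(f) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
    f[[length(f) + 1L]] <- c(nrow(v), idx(nLat - 1L, j + 1L),
                             idx(nLat - 1L, j))
  }
  for (i in seq_len(nLat - 2L)) for (j in seq_len(nLon)) {
    f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
    f[[length(f) + 1L]] <- c(idx(i, j + 1L), idx(i + 1L, j), idx(i + 1L, j + 1L))
  }
  surfaceMesh(v, do.call(rbind, f))
}

#' Parameters of a synthetic coupled signal
#'
#' Defaults emulate interictal slow-wave sleep ECoG at clinical acquisition
#' settings: 30-second epochs sampled at 1000 Hz, a 3.5 Hz slow wave of
#' 150 microvolts, high-frequency activity in 150--300 Hz at 10 microvolts
#' with its amplitude modulated by the slow-wave phase, and 5 microvolts of
#' broadband instrument noise.
#'
#' @param duration seconds (default 30).
#' @param rate Hz (default 1000; must exceed twice the amplitude band edge).
#' @param fPhase slow-wave frequency, Hz, within 3--4 (default 3.5).
#' @param ampBand amplitude band, Hz (default 150--300).
#' @param couplingDepth c in [0, 1]: envelope = 1 + c * cos(phase).
#' @param slowAmp,hfaAmp,noiseSd amplitudes in microvolts.
#' @param seed integer seed.
#' @return Named list of validated parameters.
#' @export
pacParams <- function(duration = 30, rate = 1000, fPhase = 3.5,
                      ampBand = c(150, 300), couplingDepth = 0.5,
                      slowAmp = 150, hfaAmp = 10, noiseSd = 5, seed = 1) {
  if (duration <= 0) stopf("'duration' must be positive")
  if (rate <= 2 * ampBand[2L])
    stopf("'rate' must exceed twice the amplitude band's upper edge")
  if (couplingDepth < 0 || couplingDepth > 1)
    stopf("'couplingDepth' must lie in [0, 1]")
  list(duration = duration, rate = rate, fPhase = fPhase,
       ampBand = as.numeric(ampBand), couplingDepth = couplingDepth,
       slowAmp = slowAmp, hfaAmp = hfaAmp, noiseSd = noiseSd,
       seed = as.integer(seed))
}

#' Simulate a phase-amplitude-coupled channel
#'
#' Generates `x(t) = slowAmp * sin(2 pi f t) + (1 + c * cos(phi(t))) *
#' hfaAmp * g(t) + noise`, where `phi` is the slow component's phase (zero
#' at its positive peak), `g` is band-limited unit-variance noise in the
#' amplitude band, and the additive noise is white. The same seed yields
#' bit-identical output.
#'
#' @param p a [pacParams()] list.
#' @return A one-channel [EcogRecording-class].
#' @export
simulatePacSignal <- function(p = pacParams()) {
  set.seed(p$seed)
  n <- round(p$duration * p$rate)
  t <- (seq_len(n) - 1) / p$rate
  phi <- (2 * pi * p$fPhase * t - pi / 2 + pi) %% (2 * pi) - pi
  slow <- p$slowAmp * sin(2 * pi * p$fPhase * t)
  g <- bandpassFilter(stats::rnorm(n), p$ampBand, p$rate)
  g <- g / stats::sd(g)
  x <- slow + (1 + p$couplingDepth * cos(phi)) * p$hfaAmp * g +
    stats::rnorm(n, sd = p$noiseSd)
  ecogRecording(matrix(x, nrow = 1L), p$rate, "sim1")
}

#' Scatter electrodes over a mesh
#'
#' Samples `n` distinct mesh vertices without replacement and returns an
#' electrode table with coordinates copied from the mesh and all clinical
#' flags zero.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param n number of electrodes (<= number of vertices).
#' @param seed integer seed.
#' @param patientId patient label (default `"P1"`).
#' @return Validated electrode table.
#' @export
simulateLayout <- function(mesh, n, seed = 1, patientId = "P1") {
  stopifnot(is(mesh, "SurfaceMesh"))
  nv <- nVertices(mesh)
  if (n > nv) stopf("cannot place %d electrodes on %d vertices", n, nv)
  set.seed(seed)
  vid <- sample.int(nv, n)
  xyz <- mesh@vertices[vid, , drop = FALSE]
  validateElectrodeTable(data.frame(
    patient_id = patientId,
    electrode_id = sprintf("E%03d", seq_len(n)),
    vertex_id = vid, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    soz = 0L, spike = 0L, lesion = 0L, artifact = 0L, resected = 0L,
    stringsAsFactors = FALSE))
}

#' Smooth normative MI field over a mesh
#'
#' A low-order spatial trend: `field(v) = base * exp(a . s(v))` with `s(v)`
#' the vertex coordinates rescaled to [-1, 1] per axis and fixed direction
#' weights (0.5, 1, 0.75) scaled by `range`. Optionally adds a posterior
#' (minimum-y) Gaussian hotspot emulating the elevated occipital coupling
#' seen in normative recordings.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param base baseline MI level (default 0.5, arbitrary units).
#' @param range log-scale amplitude of the spatial trend (default 0.3).
#' @param hotspot add the posterior hotspot (default `FALSE`).
#' @return Numeric vector, one positive field value per vertex.
#' @export
normativeMiField <- function(mesh, base = 0.5, range = 0.3, hotspot = FALSE) {
  v <- mesh@vertices
  s <- apply(v, 2L, function(col) {
    w <- diff(range(col)); if (w == 0) col * 0 else 2 * (col - min(col)) / w - 1
  })
  a <- range * c(0.5, 1, 0.75)
  f <- base * exp(as.numeric(s %*% a))
  if (hotspot) {
    pole <- v[which.min(v[, 2L]), ]
    d2 <- distSqToPoints(pole, v)
    f <- f + 0.4 * base * exp(-d2 / (2 * 20^2))
  }
  f
}

#' Parameters of a synthetic surgical cohort
#'
#' Defaults follow the study conditions the pipeline is meant for: 123
#' patients with on average about 100 electrodes each, roughly 15% of
#' captured sites in the seizure-onset zone, an SOZ coupling elevation of
#' one local-SD unit, and outcome log-odds set to the full-model odds
#' ratios of the outcome battery (e.g. 1.45 per subtraction z-score unit,
#' 0.39 per additional AED, 0.03 for incomplete SOZ resection) around a 73%
#' success rate.
#'
#' @param nPatients number of patients (>= 2).
#' @param electrodesPerPatient electrodes per patient (>= 4).
#' @param sozFraction fraction of a patient's electrodes in the SOZ.
#' @param sozZShift delta: additive MI shift at SOZ sites, in units of the
#'   local site-noise SD.
#' @param beta named log-odds vector over the 11 predictors (see
#'   [modelPredictors()]); missing names default as documented.
#' @param successRate marginal probability of surgical success used to set
#'   the model intercept (default 0.73).
#' @param spikeFraction extra fraction of electrodes flagged as spike halo
#'   around the SOZ (default 0.10).
#' @param artifactFraction fraction of electrodes flagged artifact
#'   (default 0.02).
#' @param habitualRate probability that a patient's habitual seizures are
#'   captured during recording, so that SOZ flags exist (default 0.85).
#' @param incompleteRate probability of incomplete SOZ resection
#'   (default 0.25).
#' @param fieldBase,fieldRange,siteNoiseSd normative field parameters (see
#'   [normativeMiField()]) and the per-site MI noise SD.
#' @param hotspot passed to [normativeMiField()].
#' @param seed integer seed.
#' @return Named parameter list.
#' @export
cohortParams <- function(nPatients = 123, electrodesPerPatient = 100,
                         sozFraction = 0.15, sozZShift = 1,
                         beta = NULL, successRate = 0.73,
                         spikeFraction = 0.10, artifactFraction = 0.02,
                         habitualRate = 0.85, incompleteRate = 0.25,
                         fieldBase = 0.5, fieldRange = 0.3,
                         siteNoiseSd = 0.08, hotspot = FALSE, seed = 1) {
  if (nPatients < 2L) stopf("'nPatients' must be >= 2")
  if (electrodesPerPatient < 4L) stopf("'electrodesPerPatient' must be >= 4")
  if (sozFraction <= 0 || sozFraction >= 1)
    stopf("'sozFraction' must lie in (0, 1)")
  defaultBeta <- c(age = log(1.04), gender = log(1.36),
                   daily_seizures = log(1.39), n_aeds = log(0.39),
                   left_hemisphere = log(0.69), mri_lesion = log(1.20),
                   habitual_seizures_during_ecog = log(3.93),
                   incomplete_soz_resection = log(0.03),
                   extratemporal_resection = log(1.33),
                   resection_size = log(0.98),
                   subtraction_mi_z = log(1.45))
  if (!is.null(beta)) {
    bad <- setdiff(names(beta), names(defaultBeta))
    if (length(bad)) stopf("unknown beta name(s): %s",
                           paste(bad, collapse = ", "))
    defaultBeta[names(beta)] <- beta
  }
  list(nPatients = as.integer(nPatients),
       electrodesPerPatient = as.integer(electrodesPerPatient),
       sozFraction = sozFraction, sozZShift = sozZShift, beta = defaultBeta,
       successRate = successRate, spikeFraction = spikeFraction,
       artifactFraction = artifactFraction, habitualRate = habitualRate,
       incompleteRate = incompleteRate, fieldBase = fieldBase,
       fieldRange = fieldRange, siteNoiseSd = siteNoiseSd,
       hotspot = hotspot, seed = as.integer(seed))
}

#' Simulate a surgical cohort with known ground truth
#'
#' Per patient: an electrode layout scattered on the mesh; MI values drawn
#' from the smooth normative field plus independent site noise, with SOZ
#' sites elevated by `sozZShift` local-SD units; a spatially contiguous SOZ
#' and spike halo; a resection mask covering the spike halo and (depending
#' on the patient's `incomplete_soz_resection` status) all or part of the
#' SOZ; clinical covariates from documented distributions; and a binary
#' outcome drawn from a logistic model over the 11 predictors using the
#' patient's true (noise-free-standardised) subtraction MI z-score. The
#' generating `sozZShift` and `beta` are returned so that the pipeline's
#' recovery of them can be tested.
#'
#' @param cp a [cohortParams()] list.
#' @param mesh a [SurfaceMesh-class].
#' @return List with `electrodes` (validated electrode table with `mi`),
#'   `cohort` (validated cohort table with `patient_id`), and `truth`
#'   (list: `sozZShift`, `beta`, `field`, `siteNoiseSd`, `intercept`).
#' @export
simulateCohort <- function(cp = cohortParams(), mesh = sphereMesh(18, 24)) {
  stopifnot(is(mesh, "SurfaceMesh"))
  nv <- nVertices(mesh)
  nE <- cp$electrodesPerPatient
  if (nE > nv)
    stopf("electrodesPerPatient (%d) exceeds mesh vertices (%d)", nE, nv)
  set.seed(cp$seed)
  layoutSeeds <- sample.int(.Machine$integer.max - 1L, cp$nPatients)
  field <- normativeMiField(mesh, cp$fieldBase, cp$fieldRange, cp$hotspot)

  np <- cp$nPatients
  cov <- data.frame(
    patient_id = sprintf("P%03d", seq_len(np)),
    age = stats::runif(np, 4, 44),
    gender = stats::rbinom(np, 1, 0.5),
    daily_seizures = stats::rbinom(np, 1, 0.3),
    n_aeds = 1 + stats::rpois(np, 1.5),
    left_hemisphere = stats::rbinom(np, 1, 0.5),
    mri_lesion = stats::rbinom(np, 1, 0.5),
    habitual_seizures_during_ecog = stats::rbinom(np, 1, cp$habitualRate),
    incomplete_soz_resection = stats::rbinom(np, 1, cp$incompleteRate),
    extratemporal_resection = stats::rbinom(np, 1, 0.5),
    stringsAsFactors = FALSE)

  elecParts <- vector("list", np)
  subz <- numeric(np)
  resSize <- numeric(np)
  for (i in seq_len(np)) {
    tab <- simulateLayout(mesh, nE, seed = layoutSeeds[i],
                          patientId = cov$patient_id[i])
    xyz <- cbind(tab$x, tab$y, tab$z)
    ## spatially contiguous SOZ around a random focus, spike halo around it
    focus <- xyz[sample.int(nE, 1L), ]
    ord <- order(distSqToPoints(focus, xyz))
    nSoz <- max(1L, round(cp$sozFraction * nE))
    nHalo <- round(cp$spikeFraction * nE)
    sozIdx <- ord[seq_len(nSoz)]
    haloIdx <- ord[nSoz + seq_len(nHalo)]
    captured <- cov$habitual_seizures_during_ecog[i] == 1L
    if (captured) tab$soz[sozIdx] <- 1L
    tab$spike[c(sozIdx, haloIdx)] <- 1L
    if (cov$mri_lesion[i] == 1L)
      tab$lesion[ord[seq_len(max(1L, nSoz %/% 2L))]] <- 1L
    tab$artifact[stats::runif(nE) < cp$artifactFraction] <- 1L
    ## resection covers the spike halo; SOZ fully or partly per status
    resIdx <- haloIdx
    if (cov$incomplete_soz_resection[i] == 1L && nSoz > 1L) {
      keepOut <- sample(sozIdx, max(1L, round(0.4 * nSoz)))
      resIdx <- c(resIdx, setdiff(sozIdx, keepOut))
    } else resIdx <- c(resIdx, sozIdx)
    tab$resected[resIdx] <- 1L

    mi <- field[tab$vertex_id] + stats::rnorm(nE, sd = cp$siteNoiseSd)
    mi[sozIdx] <- mi[sozIdx] + cp$sozZShift * cp$siteNoiseSd
    mi <- pmax(mi, 0)
    tab$mi <- mi
    zTrue <- (mi - field[tab$vertex_id]) / cp$siteNoiseSd
    ok <- tab$artifact == 0L
    res <- tab$resected == 1L & ok
    pre <- tab$resected == 0L & ok
    subz[i] <- mean(zTrue[res]) - mean(zTrue[pre])
    resSize[i] <- min(91.6, max(0.6, 100 * sum(res) / nE *
                                  exp(stats::rnorm(1, 0, 0.3))))
    elecParts[[i]] <- tab
  }
  electrodes <- validateElectrodeTable(do.call(rbind, elecParts))

  cov$resection_size <- resSize
  cov$subtraction_mi_z <- subz
  X <- as.matrix(cov[modelPredictors("full")])
  lp <- as.numeric(scale(X, center = TRUE, scale = FALSE) %*% cp$beta)
  intercept <- stats::qlogis(cp$successRate)
  cov$outcome <- stats::rbinom(np, 1, stats::plogis(intercept + lp))
  cohort <- validateCohortTable(cov)
  list(electrodes = electrodes, cohort = cohort,
       truth = list(sozZShift = cp$sozZShift, beta = cp$beta, field = field,
                    siteNoiseSd = cp$siteNoiseSd, intercept = intercept))
}
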