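poolOnSphere <- function(n, seed, mesh = sphereMesh(10, 14)) {
  set.seed(seed)
  vid <- sample.int(nVertices(mesh), n, replace = TRUE)
  # jitter off-vertex so electrode coordinates are generic points
  xyz <- vertices(mesh)[vid, ] + matrix(rnorm(3 * n, sd = 2), ncol = 3)
  validateElectrodeTable(data.frame(
    patient_id = paste0("P", rep_len(1:8, n)),
    electrode_id = paste0("E", seq_len(n)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    soz = 0L, spike = 0L, lesion = 0L, artifact = 0L, resected = 0L,
    mi = abs(rnorm(n, 0.5, 0.1)), stringsAsFactors = FALSE))
}

test_that("assignVertex returns the closest vertex with low-index ties", {
  mesh <- sphereMesh(6, 8, radius = 10)
  expect_equal(assignVertex(vertices(mesh)[7, ], mesh), 7L)
  # a point exactly equidistant to vertices 2 and 5 resolves to vertex 2
  tieMesh <- surfaceMesh(rbind(c(0, 0, 9), c(1, 0, 0), c(0, 9, 0),
                               c(9, 9, 9), c(-1, 0, 0), c(-9, 9, 9)),
                         matrix(c(1, 2, 3), 1))
  expect_equal(assignVertex(c(0, 0.3, 0), tieMesh), 2L)

  v <- vertices(mesh)
  set.seed(8)
  pts <- matrix(rnorm(300, sd = 12), ncol = 3)
  brute <- apply(pts, 1, function(p)
    which.min(colSums((t(v) - p)^2)))
  expect_equal(assignVertex(pts, mesh), as.integer(brute))
})

test_that("buildAtlas matches hand computations in degenerate cases", {
  mesh <- sphereMesh(4, 6, radius = 5)
  pool <- poolOnSphere(6, seed = 2, mesh = mesh)
  # k equal to pool size: every vertex sees the whole pool
  atlas <- buildAtlas(pool, mesh, k = nrow(pool))
  expect_equal(atlasMean(atlas), rep(mean(pool$mi), nVertices(mesh)))
  expect_equal(atlasSd(atlas), rep(sd(pool$mi), nVertices(mesh)))

  pool2 <- pool[1:2, ]; pool2$mi <- c(1, 3)
  atlas2 <- buildAtlas(pool2, mesh, k = 2)
  expect_equal(atlasMean(atlas2), rep(2, nVertices(mesh)))
  expect_equal(atlasSd(atlas2), rep(sqrt(2), nVertices(mesh)))
})

test_that("buildAtlas rejects epileptic rows and undersized pools", {
  mesh <- sphereMesh(4, 6)
  pool <- poolOnSphere(10, seed = 3, mesh = mesh)
  expect_error(buildAtlas(pool, mesh, k = 11), "smaller than k")
  bad <- pool; bad$soz[1] <- 1L
  expect_error(buildAtlas(bad, mesh, k = 3), "epileptic")
  bad2 <- pool; bad2$artifact[2] <- 1L
  expect_error(buildAtlas(bad2, mesh, k = 3), "epileptic")
  expect_error(buildAtlas(pool, mesh, k = 1), "at least 2")
})

test_that("atlas neighbourhoods match an exhaustive distance sort", {
  mesh <- sphereMesh(10, 14)
  pool <- poolOnSphere(200, seed = 4, mesh = mesh)
  k <- 30
  atlas <- buildAtlas(pool, mesh, k = k)
  v <- vertices(mesh)
  pc <- cbind(pool$x, pool$y, pool$z)
  for (i in sample.int(nVertices(mesh), 25)) {
    d <- sqrt(colSums((t(pc) - v[i, ])^2))
    nb <- order(d)[1:k]
    expect_equal(atlasMean(atlas)[i], mean(pool$mi[nb]))
    expect_equal(atlasSd(atlas)[i], sd(pool$mi[nb]))
    # selected neighbours are never farther than any unselected site
    expect_lte(max(d[nb]), min(d[-nb]) + 1e-12)
  }
})

test_that("z-scores standardise MI against the local atlas", {
  mesh <- sphereMesh(8, 10)
  pool <- poolOnSphere(120, seed = 5, mesh = mesh)
  atlas <- buildAtlas(pool, mesh, k = 30)
  el <- data.frame(patient_id = "Q1", electrode_id = c("A", "B"),
                   vertex_id = c(10L, 10L), soz = 0L, spike = 0L,
                   lesion = 0L, artifact = 0L, resected = 0L,
                   mi = c(atlasMean(atlas)[10],
                          atlasMean(atlas)[10] + atlasSd(atlas)[10]))
  z <- miZscore(el, atlas)
  expect_equal(z$z, c(0, 1), tolerance = 1e-12)
})

test_that("zero atlas SD yields NA z with a warning, never infinity", {
  mesh <- sphereMesh(4, 6)
  pool <- poolOnSphere(5, seed = 6, mesh = mesh)
  pool$mi <- rep(0.4, 5)                       # duplicated MI values
  atlas <- buildAtlas(pool, mesh, k = 5)
  el <- data.frame(patient_id = "Q1", electrode_id = "A", vertex_id = 1L,
                   soz = 0L, spike = 0L, lesion = 0L, artifact = 0L,
                   resected = 0L, mi = 0.9)
  expect_warning(z <- miZscore(el, atlas), "zero normative SD")
  expect_true(is.na(z$z))
})

test_that("z-scoring is invariant to common affine rescaling of MI", {
  mesh <- sphereMesh(8, 10)
  pool <- poolOnSphere(100, seed = 7, mesh = mesh)
  el <- poolOnSphere(20, seed = 77, mesh = mesh)
  el$patient_id <- "Q9"; el$electrode_id <- paste0("Z", 1:20)
  z1 <- miZscore(el, mesh = mesh, pool = pool, k = 20)
  a <- 3.7; b <- 0.9
  pool2 <- pool; pool2$mi <- a * pool$mi + b
  el2 <- el; el2$mi <- a * el$mi + b
  z2 <- miZscore(el2, mesh = mesh, pool = pool2, k = 20)
  expect_equal(z2$z, z1$z, tolerance = 1e-9)
})

test_that("k = pool size reduces z-scoring to global standardisation", {
  mesh <- sphereMesh(8, 10)
  pool <- poolOnSphere(50, seed = 9, mesh = mesh)
  el <- pool[1:10, ]; el$patient_id <- "Q1"
  z <- miZscore(el, mesh = mesh, pool = pool, k = 50)
  expect_equal(z$z, (el$mi - mean(pool$mi)) / sd(pool$mi), tolerance = 1e-12)
})

test_that("excludePatient removes that patient's sites from the pool", {
  mesh <- sphereMesh(8, 10)
  pool <- poolOnSphere(100, seed = 10, mesh = mesh)
  el <- pool[pool$patient_id == "P1", ]
  zAll <- miZscore(el, mesh = mesh, pool = pool, k = 80)
  zLoo <- miZscore(el, mesh = mesh, pool = pool, k = 80,
                   excludePatient = "P1")
  expect_false(isTRUE(all.equal(zAll$z, zLoo$z)))
  # excluding a patient not in the pool is a no-op
  zNoop <- miZscore(el, mesh = mesh, pool = pool, k = 80,
                    excludePatient = "nobody")
  expect_equal(zNoop$z, zAll$z)
})

test_that("artifact electrodes are excluded from scoring", {
  mesh <- sphereMesh(8, 10)
  pool <- poolOnSphere(60, seed = 12, mesh = mesh)
  el <- pool[1:6, ]; el$patient_id <- "Q1"
  el$artifact <- c(1L, rep(0L, 5))
  z <- miZscore(el, mesh = mesh, pool = pool, k = 30)
  expect_equal(nrow(z), 5)
  expect_false("E1" %in% z$electrode_id)
})

test_that("subtraction score is the resected-minus-preserved mean z", {
  zt <- data.frame(patient_id = "P1", electrode_id = paste0("E", 1:3),
                   z = c(1.0, 1.4, 0.2), resected = c(1L, 1L, 0L),
                   soz = 0L)
  s <- subtractionMiZscore(zt)
  expect_equal(s$subtraction_mi_z, 1.0)
  expect_equal(s$mean_z_resected, 1.2)

  same <- zt; same$z <- 0.7
  expect_equal(subtractionMiZscore(same)$subtraction_mi_z, 0)

  set.seed(20)
  zr <- data.frame(patient_id = "P2", electrode_id = paste0("E", 1:50),
                   z = rnorm(50), resected = rbinom(50, 1, 0.4), soz = 0L)
  s2 <- subtractionMiZscore(zr)
  expect_equal(s2$subtraction_mi_z,
               mean(zr$z[zr$resected == 1]) - mean(zr$z[zr$resected == 0]))

  oneSide <- zt; oneSide$resected <- 1L
  expect_error(subtractionMiZscore(oneSide), "preserved")
  oneSide$resected <- 0L
  expect_error(subtractionMiZscore(oneSide), "resected")
})

test_that("per-patient SOZ medians follow the sort-based definition", {
  zt <- data.frame(patient_id = "P1", electrode_id = paste0("E", 1:3),
                   z = c(1, 3, 0), soz = c(1L, 1L, 0L), resected = 0L)
  m <- patientSozMedians(zt)
  expect_equal(m$median_z_soz, 2)
  expect_equal(m$median_z_nonsoz, 0)

  single <- zt[c(1, 3), ]
  m2 <- patientSozMedians(single)
  expect_equal(m2$median_z_soz, 1)
  expect_equal(m2$median_z_nonsoz, 0)

  set.seed(21)
  zr <- data.frame(patient_id = "P3", electrode_id = paste0("E", 1:30),
                   z = rnorm(30), soz = rbinom(30, 1, 0.3), resected = 0L)
  m3 <- patientSozMedians(zr)
  expect_equal(m3$median_z_soz, median(sort(zr$z[zr$soz == 1])))
  expect_equal(m3$median_z_nonsoz, median(sort(zr$z[zr$soz == 0])))

  noSoz <- zt; noSoz$soz <- 0L
  expect_error(patientSozMedians(noSoz), "no SOZ")
  expect_message(out <- cohortSozMedians(noSoz), "skipping")
  expect_null(out)
})

test_that("SOZ z-shift recovery: grand median contrast tracks the shift", {
  mesh <- sphereMesh(14, 20)
  for (delta in c(0.5, 1.0)) {
    cp <- cohortParams(nPatients = 50, electrodesPerPatient = 100,
                       sozZShift = delta, habitualRate = 1,
                       seed = 100 + delta * 10)
    sim <- simulateCohort(cp, mesh)
    el <- sim$electrodes
    pool <- el[isNonEpileptic(el), ]
    z <- miZscore(el, mesh = mesh, pool = pool, k = 30)
    med <- cohortSozMedians(z)
    rec <- median(med$median_z_soz) - median(med$median_z_nonsoz)
    expect_gt(rec, 0.8 * delta)
    expect_lt(rec, 1.2 * delta)
  }
})
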