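# fixtures are generated in code; nothing binary ships with the package

# minimal EDF writer (test-only): one record per second, int16 with unit
# scaling so integer-valued samples round-trip exactly
writeMiniEdf <- function(path, mat, rate, labels = rownames(mat)) {
  stopifnot(ncol(mat) %% rate == 0)
  ns <- nrow(mat)
  if (is.null(labels)) labels <- paste0("sig", seq_len(ns))
  nRec <- ncol(mat) / rate
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = w, flag = "-")
    substr(s, 1, w)
  }
  wr <- function(x, w) writeChar(paste0(vapply(x, pad, "", w = w),
                                        collapse = ""),
                                 con, eos = NULL)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44); wr(nRec, 8); wr("1", 8); wr(ns, 4)
  wr(labels, 16); wr(rep("", ns), 80); wr(rep("uV", ns), 8)
  wr(rep(-32768, ns), 8); wr(rep(32767, ns), 8)
  wr(rep(-32768, ns), 8); wr(rep(32767, ns), 8)
  wr(rep("", ns), 80); wr(rep(rate, ns), 8); wr(rep("", ns), 32)
  for (r in seq_len(nRec)) {
    cols <- (r - 1) * rate + seq_len(rate)
    for (s in seq_len(ns))
      writeBin(as.integer(round(mat[s, cols])), con, size = 2,
               endian = "little")
  }
  invisible(path)
}

# unit tetrahedron as OBJ text
writeTetraObj <- function(path) {
  writeLines(c("# tetrahedron",
               "v 0 0 0", "v 1 0 0", "v 0 1 0", "v 0 0 1",
               "f 1 2 3", "f 1 2 4", "f 1 3 4", "f 2 3 4"), path)
  invisible(path)
}

# write any SurfaceMesh as a Wavefront OBJ (test-only)
writeMeshObj <- function(mesh, path) {
  v <- pacAtlas::vertices(mesh); f <- pacAtlas::faces(mesh)
  writeLines(c(sprintf("v %.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}

# small electrode table used across io tests
exampleElectrodes <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P2"),
    electrode_id = c("E1", "E2", "E1"),
    x = c(0, 1, 2), y = c(0, 1, 2), z = c(0, 0, 1),
    soz = c(1L, 0L, 0L), spike = c(0L, 0L, 1L), lesion = 0L,
    artifact = c(0L, 0L, 0L), resected = c(1L, 0L, 0L),
    mi = c(0.5, 0.2, 0.3), stringsAsFactors = FALSE)
}
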