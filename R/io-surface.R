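#' Read a triangulated surface mesh
#'
#' Supports Wavefront OBJ (`v`/`f` records; 1-based indices, `f v/vt/vn`
#' forms accepted) and a plain vertex/face text format: a first line
#' `V F`, then V lines of `x y z`, then F lines of three 1-based vertex
#' indices. Both loaders yield identical [SurfaceMesh-class] objects for the
#' same geometry.
#'
#' @param path file path.
#' @param format `"obj"`, `"vertex_face_text"`, or `"auto"` (by extension).
#' @return A [SurfaceMesh-class].
#' @export
readSurface <- function(path, format = c("auto", "obj", "vertex_face_text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("surface file not found: '%s'", path)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj"
              else "vertex_face_text"
  if (format == "obj") readObj(path) else readVertexFaceText(path)
}

readObj <- function(path) {
  ln <- trimAscii(readLines(path, warn = FALSE))
  vLines <- ln[startsWith(ln, "v ")]
  fLines <- ln[startsWith(ln, "f ")]
  if (!length(vLines) || !length(fLines))
    stopf("'%s' contains no vertices or no faces", path)
  v <- do.call(rbind, lapply(strsplit(sub("^v\\s+", "", vLines), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  f <- do.call(rbind, lapply(strsplit(sub("^f\\s+", "", fLines), "\\s+"),
    function(p) {
      if (length(p) != 3L)
        stopf("only triangular faces are supported (got %d vertices)",
              length(p))
      as.integer(vapply(strsplit(p, "/"), `[`, character(1), 1L))
    }))
  if (anyNA(v) || anyNA(f)) stopf("'%s': unparseable vertex or face line", path)
  checkFaceRange(f, nrow(v), path)
  surfaceMesh(v, f)
}

readVertexFaceText <- function(path) {
  ln <- trimAscii(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  hdr <- as.integer(strsplit(ln[1L], "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr))
    stopf("'%s': first line must be 'V F' counts", path)
  nv <- hdr[1L]; nf <- hdr[2L]
  if (length(ln) < 1L + nv + nf) stopf("'%s': truncated vertex/face file", path)
  num <- function(rows, nfld) {
    m <- do.call(rbind, lapply(strsplit(rows, "\\s+"),
                               function(p) as.numeric(p[seq_len(nfld)])))
    if (anyNA(m)) stopf("'%s': unparseable numeric line", path)
    m
  }
  v <- num(ln[1L + seq_len(nv)], 3L)
  f <- num(ln[1L + nv + seq_len(nf)], 3L)
  checkFaceRange(f, nv, path)
  surfaceMesh(v, f)
}

checkFaceRange <- function(f, nv, path) {
  if (min(f) < 1L || max(f) > nv)
    stopf("'%s': face index %d outside 1..%d",
          path, if (min(f) < 1L) min(f) else max(f), nv)
  invisible(TRUE)
}
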