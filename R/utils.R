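## internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## coerce a flag column to strict 0/1
asFlag <- function(x, name) {
  if (is.logical(x)) x <- as.integer(x)
  x <- suppressWarnings(as.numeric(x))
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stopf("column '%s' must contain only 0/1 values", name)
  as.integer(x)
}

## write a csv preserving doubles to full precision (17 significant digits)
writeCsvFull <- function(df, path) {
  for (j in names(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA
      df[[j]] <- v
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

## squared Euclidean distances from one point to a coordinate matrix
distSqToPoints <- function(p, coords) {
  (coords[, 1] - p[1])^2 + (coords[, 2] - p[2])^2 + (coords[, 3] - p[3])^2
}
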