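#' Read an STL file (binary or ASCII)
#'
#' The dialect is auto-detected. Vertices repeated across facets are welded
#' by exact coordinate match (STL stores each facet's corners verbatim), so
#' the welding is deterministic and has no tolerance parameter.
#'
#' @param path path to an STL file.
#' @return a `triangle_mesh`.
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(size, 512))
  close(con)
  ascii_bytes <- head[head >= as.raw(0x09) & head <= as.raw(0x7e)]
  txt <- rawToChar(ascii_bytes)
  is_ascii <- grepl("^\\s*solid", txt) && grepl("facet", txt)
  if (!is_ascii && size >= 84) {
    # trust the binary structure if the byte count is consistent
    is_ascii <- FALSE
  } else if (!is_ascii) {
    stop("not a valid STL file (too short for binary, no ASCII 'solid'): ",
         path)
  }
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, size)
  weld_triangle_soup(tri)
}

read_stl_binary <- function(path, size) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  expected <- 84 + n * 50
  if (expected != size)
    stop("binary STL facet count mismatch at byte offset 80: header ",
         "declares ", n, " facets (", expected, " bytes) but file has ",
         size, " bytes")
  raw <- readBin(con, "raw", n = size - 84)
  # each facet: 12 float32 (normal + 3 vertices) + uint16 attribute
  m <- matrix(raw, nrow = 50)
  vals <- readBin(as.vector(m[1:48, , drop = FALSE]), "numeric", size = 4,
                  n = 12L * n, endian = "little")
  vals <- matrix(vals, nrow = 12)
  v <- matrix(as.vector(vals[4:12, , drop = FALSE]), ncol = 3, byrow = TRUE)
  v
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  nfacet <- sum(grepl("^\\s*facet\\s", lines))
  nend <- sum(grepl("^\\s*endfacet", lines))
  if (nfacet != nend || length(vx) != 3L * nfacet)
    stop("ASCII STL structure error: ", nfacet, " 'facet', ", nend,
         " 'endfacet', ", length(vx), " 'vertex' lines")
  if (nfacet == 0) stop("ASCII STL contains no facets")
  nums <- t(vapply(strsplit(trimws(vx), "\\s+"),
                   function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(nums))) stop("ASCII STL contains non-numeric vertices")
  nums
}

# internal: triangle soup (3 rows per facet) -> welded triangle_mesh.
# exact coordinate match via the %a (hex float) representation.
weld_triangle_soup <- function(v) {
  key <- sprintf("%a_%a_%a", v[, 1], v[, 2], v[, 3])
  first <- !duplicated(key)
  idx <- match(key, key[first])
  triangle_mesh(v[first, , drop = FALSE],
                matrix(idx, ncol = 3, byrow = TRUE))
}

#' Write an STL file
#'
#' Binary STL stores coordinates as 32-bit floats; a write/read round trip
#' preserves geometry to float precision (bit-for-bit once coordinates are
#' representable as float32). ASCII uses exponent notation with 9 significant
#' digits.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param dialect "binary" or "ascii".
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  validate_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(rep(as.raw(0), 80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    dat <- t(cbind(n, a, b, cc))       # 12 floats per facet, column per facet
    facet_raw <- writeBin(as.numeric(dat), raw(), size = 4,
                          endian = "little")
    fm <- matrix(facet_raw, nrow = 48)
    out <- rbind(fm, matrix(as.raw(0), 2, nrow(f)))
    writeBin(as.vector(out), con)
  } else {
    fmt <- function(x) sprintf("%.9e", x)
    lines <- character(7L * nrow(f))
    i <- seq_len(nrow(f))
    lines[7 * i - 6] <- sprintf("  facet normal %s %s %s",
                                fmt(n[, 1]), fmt(n[, 2]), fmt(n[, 3]))
    lines[7 * i - 5] <- "    outer loop"
    lines[7 * i - 4] <- sprintf("      vertex %s %s %s",
                                fmt(a[, 1]), fmt(a[, 2]), fmt(a[, 3]))
    lines[7 * i - 3] <- sprintf("      vertex %s %s %s",
                                fmt(b[, 1]), fmt(b[, 2]), fmt(b[, 3]))
    lines[7 * i - 2] <- sprintf("      vertex %s %s %s",
                                fmt(cc[, 1]), fmt(cc[, 2]), fmt(cc[, 3]))
    lines[7 * i - 1] <- "    endloop"
    lines[7 * i] <- "  endfacet"
    writeLines(c("solid radioplan", lines, "endsolid radioplan"), path)
  }
  invisible(path)
}
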