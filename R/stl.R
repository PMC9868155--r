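# STL surface-mesh I/O (binary and ASCII).
#
# Vertex coordinates are quantized to IEEE single precision on write for
# both variants -- binary STL stores float32 by definition, and quantizing
# the ASCII variant identically guarantees that the two formats describe
# bit-identical geometry (and that binary write/read round-trips exactly).

float32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4L),
                               "double", n = length(x), size = 4L)

face_normals <- function(vertices, faces) {
  v1 <- vertices[faces[, 1L], , drop = FALSE]
  v2 <- vertices[faces[, 2L], , drop = FALSE]
  v3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Write a surface mesh to STL
#'
#' @param mesh an `airway_mesh` (vertices in mm).
#' @param path output file path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "airway_mesh"))
  v <- matrix(float32(mesh$vertices), ncol = 3L)
  f <- mesh$faces
  nf <- nrow(f)
  nrm <- matrix(float32(face_normals(v, f)), ncol = 3L)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    # 12 floats + attribute short per facet, written in one block
    tri <- matrix(0, nrow = nf, ncol = 12L)
    tri[, 1:3] <- nrm
    tri[, 4:6] <- v[f[, 1L], , drop = FALSE]
    tri[, 7:9] <- v[f[, 2L], , drop = FALSE]
    tri[, 10:12] <- v[f[, 3L], , drop = FALSE]
    for (i in seq_len(nf)) {
      writeBin(tri[i, ], con, size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid airway", con)
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1L], p[2L], p[3L])
    out <- character(7L * nf)
    j <- 0L
    for (i in seq_len(nf)) {
      out[j + 1L] <- paste("facet normal", fmt(nrm[i, ]))
      out[j + 2L] <- "  outer loop"
      out[j + 3L] <- paste("    vertex", fmt(v[f[i, 1L], ]))
      out[j + 4L] <- paste("    vertex", fmt(v[f[i, 2L], ]))
      out[j + 5L] <- paste("    vertex", fmt(v[f[i, 3L], ]))
      out[j + 6L] <- "  endloop"
      out[j + 7L] <- "endfacet"
      j <- j + 7L
    }
    writeLines(out, con)
    writeLines("endsolid airway", con)
  }
  invisible(path)
}

#' Read a surface mesh from STL
#'
#' Auto-detects binary vs ASCII. The triangle soup is returned as-is
#' (vertices are not merged); coordinates are assumed to be mm.
#'
#' @param path STL file path.
#' @return An `airway_mesh`.
#' @export
read_stl <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) {
    stop("empty or unreadable STL file: ", path, call. = FALSE)
  }
  if (info$size < 15) stop("malformed STL file: ", path, call. = FALSE)
  head <- readBin(path, "raw", n = min(info$size, 512L))
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    !any(head == as.raw(0L))
  if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nf) || nf < 1L) stop("malformed binary STL: ", path, call. = FALSE)
  verts <- matrix(0, nrow = 3L * nf, ncol = 3L)
  for (i in seq_len(nf)) {
    vals <- readBin(con, "double", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    if (length(vals) < 12L) stop("truncated binary STL: ", path, call. = FALSE)
    verts[3L * i - 2L, ] <- vals[4:6]
    verts[3L * i - 1L, ] <- vals[7:9]
    verts[3L * i, ] <- vals[10:12]
  }
  soup_to_mesh(verts)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) < 12L || length(vlines) %% 3L != 0L) {
    stop("malformed ASCII STL (", length(vlines), " vertex lines): ", path,
         call. = FALSE)
  }
  nums <- lapply(strsplit(trimws(vlines), "\\s+"),
                 function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  # coordinates were written from float32 values; snapping back makes the
  # parsed geometry bit-identical to the binary variant
  soup_to_mesh(matrix(float32(verts), ncol = 3L))
}

soup_to_mesh <- function(verts) {
  nf <- nrow(verts) / 3L
  if (nf < 4L) stop("STL mesh has fewer than 4 faces", call. = FALSE)
  structure(
    list(vertices = verts,
         faces = matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)),
    class = "airway_mesh"
  )
}
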