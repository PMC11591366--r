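#' Read a triangle mesh from PLY, STL, or OBJ
#'
#' Supports ASCII and binary little-endian PLY, ASCII and binary STL, and
#' OBJ (geometry only). Coordinates are taken as millimetres; no unit
#' metadata is trusted or rescaled. The loaded mesh is cleaned: duplicate
#' vertices merged (so STL vertex soup collapses to shared vertices) and
#' degenerate faces dropped.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"ply"`, `"stl"`, `"obj"`. `"auto"` detects
#'   from the file extension.
#' @return A [trimesh].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "stl", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "stl", "obj"))
      stop_io(sprintf("cannot detect mesh format from extension '.%s'", ext))
    format <- ext
  }
  res <- switch(format,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path)
  )
  trimesh(res$vertices, res$faces)
}

#' Write a triangle mesh to PLY, STL, or OBJ
#'
#' PLY and OBJ are written as ASCII; STL as ASCII by default or binary with
#' `binary = TRUE`.
#'
#' @param mesh A [trimesh].
#' @param path Output path; format detected from extension unless given.
#' @param format One of `"auto"`, `"ply"`, `"stl"`, `"obj"`.
#' @param binary Write binary STL instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "stl", "obj"),
                       binary = FALSE) {
  stopifnot(inherits(mesh, "trimesh"))
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  switch(format,
    ply = write_ply(mesh, path),
    stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
    obj = write_obj(mesh, path),
    stop_io(sprintf("unsupported mesh format '%s'", format))
  )
  invisible(path)
}

# ---- PLY ----------------------------------------------------------------

read_ply <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  hpos <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(hpos) == 0L) stop_io("unexpected end of PLY header")
  nl <- hpos
  while (nl <= length(raw) && raw[nl] != as.raw(0x0a)) nl <- nl + 1L
  header <- strsplit(rawToChar(raw[1:(nl - 1L)]), "\r?\n")[[1]]
  body <- raw[seq.int(nl + 1L, length(raw))]
  con <- rawConnection(body)
  on.exit(close(con))
  if (trimws(header[1]) != "ply") stop_io("not a PLY file")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stop_io("PLY missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop_io(sprintf("unsupported PLY format '%s'", fmt))

  # parse elements and their properties in order
  elements <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop_io("PLY lacks vertex or face element")

  if (fmt == "ascii") {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    pos <- 0L
    out <- list()
    for (el in elements) {
      rows <- txt[pos + seq_len(el$count)]
      pos <- pos + el$count
      out[[el$name]] <- rows
    }
    vprops <- vapply(elements$vertex$props, `[[`, "", "name")
    vdat <- do.call(rbind, lapply(strsplit(trimws(out$vertex), "\\s+"), as.numeric))
    xyz <- vdat[, match(c("x", "y", "z"), vprops), drop = FALSE]
    fdat <- lapply(strsplit(trimws(out$face), "\\s+"), as.integer)
    faces <- do.call(rbind, lapply(fdat, function(r) {
      n <- r[1]
      if (n != 3L) stop_io("only triangular PLY faces are supported")
      r[2:4]
    }))
  } else {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    read_scalar <- function(type, n) {
      sz <- sizes[[type]]
      if (type %in% c("float", "float32", "double", "float64"))
        readBin(con, "numeric", n = n, size = sz, endian = "little")
      else
        readBin(con, "integer", n = n, size = sz,
                signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")),
                endian = "little")
    }
    xyz <- NULL
    faces <- NULL
    for (el in elements) {
      if (all(!vapply(el$props, `[[`, TRUE, "list"))) {
        types <- vapply(el$props, `[[`, "", "type")
        if (length(unique(types)) == 1L) {
          dat <- matrix(read_scalar(types[1], el$count * length(types)),
                        ncol = length(types), byrow = TRUE)
        } else {
          dat <- matrix(NA_real_, el$count, length(types))
          for (i in seq_len(el$count))
            for (j in seq_along(types)) dat[i, j] <- read_scalar(types[j], 1L)
        }
        if (el$name == "vertex") {
          vprops <- vapply(el$props, `[[`, "", "name")
          xyz <- dat[, match(c("x", "y", "z"), vprops), drop = FALSE]
        }
      } else {
        rows <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          vals <- list()
          for (pr in el$props) {
            if (pr$list) {
              cnt <- read_scalar(pr$count_type, 1L)
              vals[[pr$name]] <- read_scalar(pr$type, cnt)
            } else {
              vals[[pr$name]] <- read_scalar(pr$type, 1L)
            }
          }
          rows[[i]] <- vals
        }
        if (el$name == "face") {
          key <- intersect(c("vertex_indices", "vertex_index"),
                           names(rows[[1]]))[1]
          faces <- do.call(rbind, lapply(rows, function(r) {
            v <- r[[key]]
            if (length(v) != 3L) stop_io("only triangular PLY faces are supported")
            v
          }))
        }
      }
    }
  }
  list(vertices = xyz, faces = faces + 1L)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment written by cartscan",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

# ---- STL ----------------------------------------------------------------

read_stl <- function(path) {
  size <- file.size(path)
  con <- file(path, "rb")
  header <- readBin(con, "raw", n = min(84L, size))
  close(con)
  is_binary <- FALSE
  ntri <- 0L
  if (size >= 84L) {
    ntri <- readBin(header[81:84], "integer", size = 4L, endian = "little")
    if (!is.na(ntri) && ntri > 0L && size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) read_stl_binary(path, ntri) else read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop_io("malformed ASCII STL")
  dat <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                               function(t) as.numeric(t[2:4])))
  nf <- nrow(dat) / 3L
  list(vertices = dat, faces = matrix(seq_len(3L * nf), ncol = 3, byrow = TRUE))
}

read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  readBin(con, "integer", size = 4L, endian = "little")
  verts <- matrix(NA_real_, 3L * ntri, 3)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L) # attribute byte count
    verts[3L * i - 2L, ] <- vals[4:6]
    verts[3L * i - 1L, ] <- vals[7:9]
    verts[3L * i, ] <- vals[10:12]
  }
  list(vertices = verts,
       faces = matrix(seq_len(3L * ntri), ncol = 3, byrow = TRUE))
}

write_stl_ascii <- function(mesh, path) {
  fn <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid cartscan", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
    writeLines("    outer loop", con)
    for (k in 1:3) {
      p <- v[f[i, k], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines("endsolid cartscan", con)
}

write_stl_binary <- function(mesh, path) {
  fn <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    writeBin(c(fn[i, ], t(v[f[i, ], ])), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
}

# ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", txt, value = TRUE)
  flines <- grep("^f\\s", txt, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L)
    stop_io("OBJ file has no geometry")
  verts <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                                 function(t) as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(t) {
    idx <- as.integer(vapply(strsplit(t[-1], "/"), `[[`, "", 1L))
    if (length(idx) != 3L) stop_io("only triangular OBJ faces are supported")
    if (any(idx < 0L)) stop_io("negative OBJ indices are not supported")
    idx
  }))
  list(vertices = verts, faces = faces)
}

write_obj <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# written by cartscan", con)
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
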