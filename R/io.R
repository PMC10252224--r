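# Readers and writers for facial surface scans (PLY ascii / binary
# little-endian, OBJ vertices, XYZ-CSV) and landmark files (JSON, CSV).
# Mesh connectivity is always discarded: only vertex coordinates matter here.

.plyTypeSize <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                  short = 2, ushort = 2, int16 = 2, uint16 = 2,
                  int = 4, uint = 4, int32 = 4, uint32 = 4,
                  float = 4, float32 = 4, double = 8, float64 = 8)

.readPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()  # each: list(name, count, props = data.frame(name, type))
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("unexpected end of PLY header in ", path)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element")
      elements[[length(elements) + 1]] <-
        list(name = tok[2], count = as.integer(tok[3]),
             props = data.frame(name = character(), type = character(),
                                list = logical(), stringsAsFactors = FALSE))
    else if (tok[1] == "property") {
      i <- length(elements)
      if (i == 0) stop("PLY property before any element in ", path)
      if (tok[2] == "list")
        elements[[i]]$props <- rbind(elements[[i]]$props,
          data.frame(name = tok[5], type = tok[4], list = TRUE))
      else
        elements[[i]]$props <- rbind(elements[[i]]$props,
          data.frame(name = tok[3], type = tok[2], list = FALSE))
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt)) stop("PLY header without format line in ", path)
  vi <- which(vapply(elements, function(e) e$name == "vertex", logical(1)))
  if (length(vi) != 1) stop("PLY file must contain one vertex element: ", path)
  ve <- elements[[vi]]
  if (any(ve$props$list)) stop("list properties on vertices are not supported: ", path)
  need <- match(c("x", "y", "z"), ve$props$name)
  if (anyNA(need)) stop("PLY vertex element lacks x/y/z properties: ", path)
  n <- ve$count
  if (fmt == "ascii") {
    if (vi != 1) stop("only vertex-first ascii PLY files are supported: ", path)
    vals <- scan(con, what = numeric(), n = n * nrow(ve$props), quiet = TRUE)
    m <- matrix(vals, ncol = nrow(ve$props), byrow = TRUE)
    m[, need, drop = FALSE]
  } else if (fmt == "binary_little_endian") {
    if (vi != 1) stop("only vertex-first binary PLY files are supported: ", path)
    sizes <- .plyTypeSize[ve$props$type]
    if (anyNA(sizes)) stop("unknown PLY property type in ", path)
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = n * stride)
    if (length(raw) < n * stride) stop("truncated PLY vertex data in ", path)
    offs <- c(0, cumsum(sizes))[seq_along(sizes)]
    getcol <- function(j) {
      sz <- sizes[j]
      sel <- rep(offs[j] + seq_len(sz), n) + rep((0:(n - 1)) * stride, each = sz)
      ty <- ve$props$type[j]
      what <- if (ty %in% c("float", "float32", "double", "float64")) "double" else "integer"
      readBin(raw[sel], what, n = n, size = sz, endian = "little",
              signed = !(ty %in% c("uchar", "uint8", "ushort", "uint16")))
    }
    cbind(getcol(need[1]), getcol(need[2]), getcol(need[3]))
  } else stop("unsupported PLY format '", fmt, "' in ", path)
}

.readObj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  v <- lines[startsWith(lines, "v ") | startsWith(lines, "v\t")]
  if (length(v) == 0) stop("no vertex ('v') records in OBJ file: ", path)
  m <- t(vapply(strsplit(trimws(v), "\\s+"),
                function(tok) as.numeric(tok[2:4]), numeric(3)))
  m
}

.readXyzCsv <- function(path) {
  first <- readLines(path, n = 1)
  toks <- strsplit(first, "[,\t ]+")[[1]]
  hasHeader <- any(is.na(suppressWarnings(as.numeric(toks))))
  m <- utils::read.csv(path, header = hasHeader)
  if (ncol(m) < 3) stop("XYZ-CSV file needs at least 3 columns: ", path)
  as.matrix(m[, 1:3])
}

#' Read a point cloud from disk
#'
#' Reads PLY (ascii or binary little-endian), OBJ (vertex records only) or
#' XYZ-CSV (three columns, header optional) files. Connectivity, normals and
#' colors are discarded.
#'
#' @param path file path.
#' @param format one of "auto" (by extension), "ply", "obj", "xyz".
#' @return a \linkS4class{FaceCloud}.
#' @export
readPointCloud <- function(path, format = c("auto", "ply", "obj", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj",
                     xyz = "xyz", csv = "xyz", txt = "xyz",
                     stop("cannot infer point-cloud format from extension '.",
                          ext, "' of ", path))
  }
  m <- switch(format, ply = .readPly(path), obj = .readObj(path),
              xyz = .readXyzCsv(path))
  if (nrow(m) < 4) stop("point cloud in ", path, " has fewer than 4 points")
  if (!all(is.finite(m))) stop("non-finite coordinates in ", path)
  faceCloud(m)
}

#' Write a point cloud to disk
#'
#' PLY output uses double-precision vertex properties so that a write/read
#' round trip reproduces coordinates exactly (ascii uses full-precision
#' decimal text, binary uses little-endian doubles).
#'
#' @param cloud a \linkS4class{FaceCloud}.
#' @param path output file path.
#' @param format "ply", "obj" or "xyz".
#' @param binary for PLY: write binary little-endian instead of ascii.
#' @return the path, invisibly.
#' @export
writePointCloud <- function(cloud, path, format = c("ply", "obj", "xyz"),
                            binary = FALSE) {
  format <- match.arg(format)
  p <- cloud@points
  if (format == "ply") {
    hdr <- c("ply",
             if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
             sprintf("element vertex %d", nrow(p)),
             "property double x", "property double y", "property double z",
             "end_header")
    if (binary) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(hdr, con, sep = "\n")
      writeBin(as.numeric(t(p)), con, size = 8, endian = "little")
    } else {
      writeLines(c(hdr, sprintf("%.17g %.17g %.17g", p[, 1], p[, 2], p[, 3])),
                 path)
    }
  } else if (format == "obj") {
    writeLines(sprintf("v %.17g %.17g %.17g", p[, 1], p[, 2], p[, 3]), path)
  } else {
    utils::write.csv(data.frame(x = p[, 1], y = p[, 2], z = p[, 3]),
                     path, row.names = FALSE)
  }
  invisible(path)
}

#' Construct a LandmarkSet
#'
#' @param coords numeric N x 3 matrix with unique landmark row names.
#' @param unit coordinate frame label, default "mm".
#' @return a \linkS4class{LandmarkSet}.
#' @export
landmarkSet <- function(coords, unit = "mm") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- NULL
  new("LandmarkSet", coords = coords, unit = unit)
}

#' Read landmarks from JSON or CSV
#'
#' JSON files map landmark name to an xyz triple; CSV files have columns
#' name, x, y, z. Coordinates are in mm.
#'
#' @param path file path (.json or .csv).
#' @return a \linkS4class{LandmarkSet}.
#' @export
readLandmarks <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    m <- do.call(rbind, lapply(lst, as.numeric))
    rownames(m) <- names(lst)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    m <- as.matrix(df[, c("x", "y", "z")])
    rownames(m) <- df$name
  }
  landmarkSet(m)
}

#' Write landmarks to JSON or CSV
#'
#' @param lms a \linkS4class{LandmarkSet}.
#' @param path output path; format chosen by extension (.json or .csv).
#' @return the path, invisibly.
#' @export
writeLandmarks <- function(lms, path) {
  m <- lms@coords
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    lst <- stats::setNames(lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])),
                           rownames(m))
    jsonlite::write_json(lst, path, digits = NA)
  } else {
    utils::write.csv(data.frame(name = rownames(m), x = m[, 1], y = m[, 2],
                                z = m[, 3]), path, row.names = FALSE)
  }
  invisible(path)
}
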