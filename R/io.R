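#' @include AllClasses.R AllGenerics.R
NULL

# PLY scalar types and byte sizes
.plyTypes <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
               short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
               int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
.plyIsFloat <- function(type) type %in% c("float", "float32", "double", "float64")

.fmtNum <- function(x) sprintf("%.17g", x)

#' Read and write PLY files
#'
#' `writePly()` writes a [PointCloud-class] or [TriangleMesh-class] as ASCII
#' or binary little-endian PLY; per-point/per-face region labels are stored
#' as an integer `label` property with the label dictionary in header
#' comments, per-point scalars in a `quality` property (written at full
#' double precision so they round-trip exactly), and colors as `uchar`
#' `red`/`green`/`blue`. `readPly()` restores the object; a `quality`
#' property, when present, is attached as attribute `"quality"`.
#'
#' @param x a [PointCloud-class] or [TriangleMesh-class].
#' @param path file path.
#' @param binary write binary little-endian instead of ASCII.
#' @param scalars optional per-point numeric vector (stored as `quality`).
#' @param colors optional per-point colors (any R color specification).
#' @return `readPly()` returns a [PointCloud-class] or
#'   [TriangleMesh-class]; `writePly()` returns `path` invisibly.
#' @export
writePly <- function(x, path, binary = FALSE, scalars = NULL, colors = NULL) {
  isMesh <- is(x, "TriangleMesh")
  P <- if (isMesh) x@vertices else x@points
  n <- nrow(P)
  hasNormals <- !isMesh && nrow(x@normals) > 0
  labels <- if (isMesh) x@faceLabels else x@labels
  hasLabels <- length(labels) > 0
  dict <- if (hasLabels) sort(unique(labels)) else character()
  hasScalars <- !is.null(scalars)
  hasColors <- !is.null(colors)
  if (hasScalars && length(scalars) != n)
    .stopInvalid("scalars must have one value per point")
  if (hasColors && length(colors) != n)
    .stopInvalid("colors must have one value per point")

  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              "comment written by fidreg")
  if (hasLabels)
    header <- c(header, sprintf("comment label %d %s",
                                seq_along(dict) - 1L, dict))
  header <- c(header,
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z")
  if (hasNormals)
    header <- c(header, "property double nx", "property double ny",
                "property double nz")
  if (hasColors)
    header <- c(header, "property uchar red", "property uchar green",
                "property uchar blue")
  if (hasScalars)
    header <- c(header, "property double quality")
  if (!isMesh && hasLabels)
    header <- c(header, "property int label")
  if (isMesh) {
    header <- c(header, sprintf("element face %d", nrow(x@faces)),
                "property list uchar int vertex_indices")
    if (hasLabels) header <- c(header, "property int label")
  }
  header <- c(header, "end_header")

  rgb <- if (hasColors) t(grDevices::col2rgb(colors)) else NULL
  labIdx <- if (hasLabels) match(labels, dict) - 1L else NULL

  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(P[i, ], con, size = 8, endian = "little")
      if (hasNormals) writeBin(x@normals[i, ], con, size = 8,
                               endian = "little")
      if (hasColors) writeBin(as.raw(rgb[i, ]), con)
      if (hasScalars) writeBin(scalars[i], con, size = 8, endian = "little")
      if (!isMesh && hasLabels)
        writeBin(labIdx[i], con, size = 4, endian = "little")
    }
    if (isMesh) {
      for (i in seq_len(nrow(x@faces))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(x@faces[i, ] - 1L), con, size = 4,
                 endian = "little")
        if (hasLabels) writeBin(labIdx[i], con, size = 4, endian = "little")
      }
    }
  } else {
    rows <- apply(P, 1, function(r) paste(.fmtNum(r), collapse = " "))
    if (hasNormals)
      rows <- paste(rows, apply(x@normals, 1,
                                function(r) paste(.fmtNum(r), collapse = " ")))
    if (hasColors)
      rows <- paste(rows, rgb[, 1], rgb[, 2], rgb[, 3])
    if (hasScalars) rows <- paste(rows, .fmtNum(scalars))
    if (!isMesh && hasLabels) rows <- paste(rows, labIdx)
    writeLines(rows, con, sep = "\n")
    if (isMesh) {
      frows <- paste(3L, x@faces[, 1] - 1L, x@faces[, 2] - 1L,
                     x@faces[, 3] - 1L)
      if (hasLabels) frows <- paste(frows, labIdx)
      writeLines(frows, con, sep = "\n")
    }
  }
  invisible(path)
}

#' @rdname writePly
#' @export
readPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, 1)
    if (!length(line)) .stopInvalid("truncated PLY header")
    header <- c(header, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format\\s+(\\S+).*", "\\1", grep("^format", header,
                                                value = TRUE)[1])
  binary <- fmt == "binary_little_endian"
  if (!binary && fmt != "ascii")
    .stopInvalid(sprintf("unsupported PLY format '%s'", fmt))
  # label dictionary from comments
  labLines <- grep("^comment label ", header, value = TRUE)
  dict <- if (length(labLines)) {
    parts <- strsplit(sub("^comment label ", "", labLines), " ")
    stats::setNames(vapply(parts, `[`, "", 2),
                    vapply(parts, `[`, "", 1))
  } else character()

  # parse element/property structure
  elements <- list()
  current <- NULL
  for (line in header) {
    if (grepl("^element ", line)) {
      if (!is.null(current)) elements[[current$name]] <- current
      tok <- strsplit(line, "\\s+")[[1]]
      current <- list(name = tok[2], count = as.integer(tok[3]),
                      props = list())
    } else if (grepl("^property ", line) && !is.null(current)) {
      tok <- strsplit(line, "\\s+")[[1]]
      if (tok[2] == "list") {
        current$props[[tok[5]]] <- list(list = TRUE, countType = tok[3],
                                        type = tok[4])
      } else {
        current$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(current)) elements[[current$name]] <- current

  data <- list()
  for (el in elements) {
    if (el$count == 0) { data[[el$name]] <- list(); next }
    if (binary) {
      data[[el$name]] <- .readPlyBinaryElement(con, el)
    } else {
      data[[el$name]] <- .readPlyAsciiElement(con, el)
    }
  }

  v <- data$vertex
  if (is.null(v)) .stopInvalid("PLY has no vertex element")
  P <- cbind(v$x, v$y, v$z)
  normals <- if (!is.null(v$nx)) cbind(v$nx, v$ny, v$nz) else NULL
  vlabels <- if (!is.null(v$label) && length(dict))
    unname(dict[as.character(v$label)]) else NULL

  f <- data$face
  if (!is.null(f) && !is.null(f$vertex_indices) &&
      length(f$vertex_indices)) {
    F <- do.call(rbind, f$vertex_indices) + 1L
    flabels <- if (!is.null(f$label) && length(dict))
      unname(dict[as.character(f$label)]) else character()
    out <- triangleMesh(P, F, flabels)
  } else {
    out <- pointCloud(P, normals = normals, labels = vlabels)
  }
  if (!is.null(v$quality)) attr(out, "quality") <- v$quality
  out
}

.readPlyAsciiElement <- function(con, el) {
  lines <- readLines(con, el$count)
  toks <- strsplit(trimws(lines), "\\s+")
  out <- list()
  anyList <- any(vapply(el$props, `[[`, TRUE, "list"))
  if (!anyList) {
    m <- matrix(as.numeric(unlist(toks)), nrow = el$count, byrow = TRUE)
    for (j in seq_along(el$props)) out[[names(el$props)[j]]] <- m[, j]
    return(out)
  }
  # general path: walk tokens per row
  for (nm in names(el$props)) out[[nm]] <- vector("list", el$count)
  for (i in seq_len(el$count)) {
    t <- as.numeric(toks[[i]])
    pos <- 1L
    for (nm in names(el$props)) {
      pr <- el$props[[nm]]
      if (pr$list) {
        cnt <- as.integer(t[pos])
        out[[nm]][[i]] <- as.integer(t[pos + seq_len(cnt)])
        pos <- pos + 1L + cnt
      } else {
        out[[nm]][[i]] <- t[pos]
        pos <- pos + 1L
      }
    }
  }
  for (nm in names(el$props))
    if (!el$props[[nm]]$list) out[[nm]] <- unlist(out[[nm]])
  out
}

.readBinValue <- function(raw, type) {
  sz <- .plyTypes[[type]]
  if (.plyIsFloat(type)) {
    readBin(raw, "double", n = length(raw) %/% sz, size = sz,
            endian = "little")
  } else {
    signed <- !startsWith(type, "u")
    readBin(raw, "integer", n = length(raw) %/% sz, size = sz,
            signed = if (sz < 4) signed else TRUE, endian = "little")
  }
}

.readPlyBinaryElement <- function(con, el) {
  out <- list()
  anyList <- any(vapply(el$props, `[[`, TRUE, "list"))
  if (!anyList) {
    sizes <- vapply(el$props, function(p) .plyTypes[[p$type]], 1L)
    rowSize <- sum(sizes)
    raw <- readBin(con, "raw", n = rowSize * el$count)
    offs <- c(0L, cumsum(sizes))
    base <- rep((seq_len(el$count) - 1L) * rowSize, each = 1L)
    for (j in seq_along(el$props)) {
      idx <- as.vector(outer(seq_len(sizes[j]) + offs[j], base, `+`))
      out[[names(el$props)[j]]] <- .readBinValue(raw[idx],
                                                 el$props[[j]]$type)
    }
    return(out)
  }
  # row-wise walk (list properties have variable size)
  for (nm in names(el$props)) out[[nm]] <- vector("list", el$count)
  for (i in seq_len(el$count)) {
    for (nm in names(el$props)) {
      pr <- el$props[[nm]]
      if (pr$list) {
        cnt <- .readBinValue(readBin(con, "raw",
                                     n = .plyTypes[[pr$countType]]),
                             pr$countType)
        out[[nm]][[i]] <- .readBinValue(
          readBin(con, "raw", n = cnt * .plyTypes[[pr$type]]), pr$type)
      } else {
        out[[nm]][[i]] <- .readBinValue(
          readBin(con, "raw", n = .plyTypes[[pr$type]]), pr$type)
      }
    }
  }
  for (nm in names(el$props))
    if (!el$props[[nm]]$list) out[[nm]] <- unlist(out[[nm]])
  out
}

#' Read and write OBJ files
#'
#' Wavefront OBJ with `v`/`f` records; face labels are stored as `g` group
#' names and restored on read. A file without faces reads back as a
#' [PointCloud-class].
#'
#' @param x a [TriangleMesh-class] or [PointCloud-class].
#' @param path file path.
#' @return `readObj()` returns a [TriangleMesh-class] or
#'   [PointCloud-class]; `writeObj()` returns `path` invisibly.
#' @export
writeObj <- function(x, path) {
  isMesh <- is(x, "TriangleMesh")
  P <- if (isMesh) x@vertices else x@points
  lines <- paste("v", .fmtNum(P[, 1]), .fmtNum(P[, 2]), .fmtNum(P[, 3]))
  if (isMesh) {
    F <- x@faces
    labs <- if (length(x@faceLabels)) x@faceLabels else rep("default",
                                                            nrow(F))
    ord <- order(match(labs, unique(labs)))
    F <- F[ord, , drop = FALSE]
    labs <- labs[ord]
    grp <- c(TRUE, labs[-1] != labs[-length(labs)])
    frows <- paste("f", F[, 1], F[, 2], F[, 3])
    body <- character(0)
    for (i in seq_along(frows)) {
      if (grp[i]) body <- c(body, paste("g", labs[i]))
      body <- c(body, frows[i])
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeObj
#' @export
readObj <- function(path) {
  lines <- readLines(path)
  vt <- grepl("^v ", lines)
  P <- matrix(as.numeric(unlist(strsplit(trimws(sub("^v ", "",
                                                    lines[vt])), "\\s+"))),
              ncol = 3, byrow = TRUE)
  ft <- grepl("^f ", lines) | grepl("^g ", lines)
  if (!any(grepl("^f ", lines))) return(pointCloud(P))
  F <- matrix(integer(), 0, 3)
  labs <- character()
  cur <- "default"
  for (line in lines[ft]) {
    if (startsWith(line, "g ")) {
      cur <- sub("^g ", "", line)
    } else {
      tok <- strsplit(trimws(sub("^f ", "", line)), "\\s+")[[1]]
      idx <- as.integer(sub("/.*", "", tok))
      F <- rbind(F, idx[1:3])
      labs <- c(labs, cur)
    }
  }
  if (all(labs == "default")) labs <- character()
  triangleMesh(P, F, labs)
}

#' Read and write binary STL files
#'
#' Binary STL stores one float32 normal and three float32 vertices per
#' triangle; coordinates are quantized to single precision and vertices are
#' de-duplicated on read. Labels are not representable in STL.
#'
#' @param x a [TriangleMesh-class].
#' @param path file path.
#' @return `readStl()` returns a [TriangleMesh-class]; `writeStl()` returns
#'   `path` invisibly.
#' @export
writeStl <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  nf <- nrow(x@faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  N <- .triNormals(x@vertices, x@faces)
  for (i in seq_len(nf)) {
    writeBin(N[i, ], con, size = 4, endian = "little")
    writeBin(as.vector(t(x@vertices[x@faces[i, ], ])), con, size = 4,
             endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

#' @rdname writeStl
#' @export
readStl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  raw <- readBin(con, "raw", nf * 50)
  idx <- as.vector(outer(1:48, (seq_len(nf) - 1L) * 50L, `+`))
  vals <- matrix(readBin(raw[idx], "double", n = 12L * nf, size = 4,
                         endian = "little"), ncol = 12, byrow = TRUE)
  tri <- matrix(t(vals[, 4:12, drop = FALSE]), ncol = 3, byrow = TRUE)
  key <- apply(tri, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  V <- tri[uk, , drop = FALSE]
  F <- matrix(match(key, key[uk]), ncol = 3, byrow = TRUE)
  triangleMesh(V, F)
}

#' Read and write XYZ point files
#'
#' Whitespace-delimited `x y z` (optionally `nx ny nz`) per line.
#'
#' @param x a [PointCloud-class].
#' @param path file path.
#' @return `readXyz()` returns a [PointCloud-class]; `writeXyz()` returns
#'   `path` invisibly.
#' @export
writeXyz <- function(x, path) {
  m <- x@points
  if (nrow(x@normals) > 0) m <- cbind(m, x@normals)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeXyz
#' @export
readXyz <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (ncol(m) >= 6) pointCloud(m[, 1:3], normals = m[, 4:6])
  else pointCloud(m[, 1:3, drop = FALSE])
}
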