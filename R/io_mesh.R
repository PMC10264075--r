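#' Read a triangle mesh (ASCII PLY, OBJ, or STL)
#'
#' Format is chosen by file extension.  PLY and OBJ preserve vertex order;
#' STL stores free triangles, so vertices are merged by exact coordinate
#' match on load (face count unchanged).  Degenerate zero-area faces are
#' dropped by the `bone_mesh` constructor.  Only ASCII variants are read.
#'
#' @param path mesh file ending in `.ply`, `.obj`, or `.stl`.
#' @return a `bone_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl(path),
         stop("unknown mesh format: .", ext,
              " (supported: ply, obj, stl)"))
}

#' Write a triangle mesh (ASCII PLY, OBJ, or STL)
#'
#' @param mesh a `bone_mesh`.
#' @param path output file; extension selects the format.
#' @param digits significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, digits = 12) {
  stopifnot(inherits(mesh, "bone_mesh"))
  ext <- tolower(tools::file_ext(path))
  fmt <- function(M) apply(M, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  V <- mesh$vertices; Fc <- mesh$faces
  lines <- switch(ext,
    ply = c("ply", "format ascii 1.0",
            paste("element vertex", nrow(V)),
            "property float x", "property float y", "property float z",
            paste("element face", nrow(Fc)),
            "property list uchar int vertex_indices", "end_header",
            fmt(V),
            apply(Fc - 1L, 1, function(r) paste(c(3L, r), collapse = " "))),
    obj = c(paste("v", fmt(V)),
            apply(Fc, 1, function(r) paste(c("f", r), collapse = " "))),
    stl = {
      out <- "solid mesh"
      for (i in seq_len(nrow(Fc))) {
        tri <- V[Fc[i, ], , drop = FALSE]
        n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
        nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
        out <- c(out,
                 paste("facet normal",
                       paste(formatC(n, digits = digits, format = "g"),
                             collapse = " ")),
                 "outer loop",
                 paste("vertex", fmt(tri)),
                 "endloop", "endfacet")
      }
      c(out, "endsolid mesh")
    },
    stop("unknown mesh format: .", ext))
  writeLines(lines, path)
  invisible(path)
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop("PLY header not terminated")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element\\s+vertex\\s+", "",
                       grep("element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+", "",
                       grep("element\\s+face", hdr, value = TRUE)[1]))
  if (is.na(nf)) nf <- 0L
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vl <- body[seq_len(nv)]
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "[ \t]+"), function(x)
    as.numeric(x[1:3])))
  Fc <- NULL
  if (nf > 0) {
    fl <- body[nv + seq_len(nf)]
    Fc <- do.call(rbind, lapply(strsplit(trimws(fl), "[ \t]+"), function(x) {
      x <- as.integer(x)
      if (x[1] != 3L) stop("non-triangular PLY face")
      x[2:4] + 1L
    }))
  }
  bone_mesh(V, if (is.null(Fc)) matrix(integer(0), 0, 3) else Fc)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertices in OBJ file: ", path)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "[ \t]+"), function(x)
    as.numeric(x[2:4])))
  Fc <- do.call(rbind, lapply(strsplit(trimws(fl), "[ \t]+"), function(x) {
    idx <- as.integer(sub("/.*", "", x[-1]))
    if (length(idx) != 3L) stop("non-triangular OBJ face")
    idx
  }))
  bone_mesh(V, if (is.null(Fc)) matrix(integer(0), 0, 3) else Fc)
}

read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(grep("^\\s*solid", lines[1])))
    stop("only ASCII STL is supported")
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L) stop("malformed STL: vertex count not a multiple of 3")
  P <- do.call(rbind, lapply(strsplit(trimws(vl), "[ \t]+"), function(x)
    as.numeric(x[2:4])))
  key <- apply(P, 1, paste, collapse = "|")
  uniq <- !duplicated(key)
  V <- P[uniq, , drop = FALSE]
  idx <- match(key, key[uniq])
  Fc <- matrix(idx, ncol = 3, byrow = TRUE)
  bone_mesh(V, Fc)
}
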