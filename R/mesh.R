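#' Triangle meshes and STL input/output
#'
#' Meshes carry vertices in millimetres and 1-based face indices. STL is
#' read in both dialects (ASCII "solid ..." and little-endian binary);
#' vertices are welded by exact floating-point equality, so reading is
#' deterministic and reversible.
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param faces M x 3 integer matrix of 1-based vertex indices.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (!all(is.finite(vertices)))
    stop_ss("invalid_mesh_error", "non-finite vertex coordinates")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_ss("invalid_mesh_error", "face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  list(normals = n / ifelse(len > 0, len, 1), areas = len / 2)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `triangle_mesh`.
#' @export
mesh_area <- function(mesh) sum(face_normals(mesh)$areas)

# Weld exactly-equal vertices: returns mesh with deduplicated vertex table.
weld_vertices <- function(tri_verts, n_tri) {
  key <- paste(sprintf("%.17g", tri_verts[, 1]),
               sprintf("%.17g", tri_verts[, 2]),
               sprintf("%.17g", tri_verts[, 3]))
  idx <- match(key, key)                 # first occurrence index per row
  uniq <- !duplicated(idx)
  remap <- cumsum(uniq)[idx]
  triangle_mesh(tri_verts[uniq, , drop = FALSE],
                matrix(remap, ncol = 3, byrow = TRUE))
}

#' Read an STL file
#'
#' Detects the dialect: little-endian binary (80-byte header + uint32
#' triangle count) or ASCII (`solid ...`). Vertices are welded by exact
#' equality; the face count equals the file's triangle count.
#'
#' @param path STL file path.
#' @return a `triangle_mesh`.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 84L)
  fsize <- file.size(path)
  is_binary <- FALSE
  if (length(head) == 84L) {
    n_tri <- readBin(head[81:84], "integer", size = 4L, endian = "little")
    if (n_tri >= 0 && fsize == 84 + 50 * as.numeric(n_tri)) is_binary <- TRUE
    # a binary file can also start with "solid"; trust the size arithmetic
    if (!is_binary && !identical(rawToChar(head[1:5]), "solid")) {
      if (n_tri >= 0 && fsize < 84 + 50 * as.numeric(n_tri))
        stop_ss("stl_truncated_error",
                "binary STL declares %d triangles but holds only %d bytes of %d expected",
                n_tri, fsize, 84 + 50 * n_tri)
      stop_ss("stl_parse_error", "not a recognizable STL file: %s", path)
    }
  } else if (length(head) < 15L) {
    stop_ss("stl_parse_error", "file too short to be STL: %s", path)
  }
  if (is_binary) {
    n_tri <- readBin(head[81:84], "integer", size = 4L, endian = "little")
    tri_verts <- matrix(NA_real_, 3 * n_tri, 3)
    for (i in seq_len(n_tri)) {
      rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      readBin(con, "integer", n = 1L, size = 2L, endian = "little")  # attr bytes
      if (length(rec) < 12L)
        stop_ss("stl_truncated_error", "binary STL truncated at triangle %d", i)
      tri_verts[3 * i - 2:0, ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
    return(weld_vertices(tri_verts, n_tri))
  }
  read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop_ss("stl_parse_error",
            "ASCII STL has %d vertex lines (not a multiple of 3): %s",
            length(vl), path)
  toks <- strsplit(trimws(lines[vl]), "\\s+")
  bad <- which(vapply(toks, length, integer(1)) != 4L)
  if (length(bad))
    stop_ss("stl_parse_error", "malformed vertex record at line %d", vl[bad[1]])
  v <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (any(!is.finite(v)))
    stop_ss("stl_parse_error", "non-numeric vertex coordinate near line %d",
            vl[which(!stats::complete.cases(v))[1]])
  # STL carries float32 coordinates; snap parsed decimals back onto the
  # float32 grid so both dialects decode to identical meshes
  weld_vertices(matrix(float32(v), ncol = 3), nrow(v) / 3L)
}

#' Write an STL file
#'
#' Normals are recomputed from the vertex winding. Binary output is
#' byte-deterministic for a given mesh (attribute byte count written as 0);
#' ASCII output prints coordinates after rounding through float32 with
#' enough digits for an exact float32 round trip, so the two dialects read
#' back as identical meshes.
#'
#' @param mesh a `triangle_mesh` (non-empty).
#' @param path output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (nrow(mesh$faces) == 0L) stop_ss("invalid_mesh_error", "refusing to write empty mesh")
  v32 <- matrix(float32(mesh$vertices), ncol = 3)
  m32 <- triangle_mesh(v32, mesh$faces)
  fn <- face_normals(m32)
  nrm <- matrix(float32(fn$normals), ncol = 3)
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "scopesight binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(mesh$faces)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(mesh$faces))) {
      rec <- c(nrm[i, ], t(v32[m32$faces[i, ], ]))
      writeBin(as.numeric(rec), con, size = 4L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    }
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    out <- character(7 * nrow(m32$faces) + 2)
    out[1] <- "solid scopesight"
    k <- 2L
    for (i in seq_len(nrow(m32$faces))) {
      tri <- v32[m32$faces[i, ], , drop = FALSE]
      out[k] <- sprintf("  facet normal %s %s %s",
                        fmt(nrm[i, 1]), fmt(nrm[i, 2]), fmt(nrm[i, 3]))
      out[k + 1] <- "    outer loop"
      out[k + 2:4] <- sprintf("      vertex %s %s %s",
                              fmt(tri[, 1]), fmt(tri[, 2]), fmt(tri[, 3]))
      out[k + 5] <- "    endloop"
      out[k + 6] <- "  endfacet"
      k <- k + 7L
    }
    out[k] <- "endsolid scopesight"
    writeLines(out, path)
  }
  invisible(path)
}

#' Rigidly transform a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @param t a `rigid_transform` (frame labels are not enforced on meshes).
#' @return the transformed `triangle_mesh`; topology unchanged.
#' @export
transform_mesh <- function(mesh, t) {
  stopifnot(is_rigid_transform(t))
  triangle_mesh(sweep(mesh$vertices %*% t(t$R), 2, t$t, `+`), mesh$faces)
}

#' Organ model: a named mesh placed in the model base frame
#'
#' @param name organ name from the controlled vocabulary (`skin`, `radius`,
#'   `ulna`, `humerus`, `radial nerve`, `ulnar nerve`, `median nerve`,
#'   `musculocutaneous nerve`, `frame`).
#' @param mesh a `triangle_mesh` in organ-local coordinates.
#' @param T_MO `rigid_transform` from the model base frame `M` to the organ
#'   frame; static for a session.
#' @return list of class `organ_model`.
#' @export
organ_model <- function(name, mesh, T_MO) {
  vocab <- c("skin", "radius", "ulna", "humerus", "radial nerve",
             "ulnar nerve", "median nerve", "musculocutaneous nerve", "frame")
  if (!name %in% vocab)
    stop_ss("config_error", "organ name '%s' not in controlled vocabulary", name)
  stopifnot(inherits(mesh, "triangle_mesh"), is_rigid_transform(T_MO))
  structure(list(name = name, mesh = mesh, T_MO = T_MO), class = "organ_model")
}

# Organ mesh expressed in the model base frame M.
organ_mesh_in_model_frame <- function(organ) {
  transform_mesh(organ$mesh, invert(organ$T_MO))
}

#' Write / read an organ-set manifest
#'
#' JSON listing organ name -> STL path -> 4x4 `T_MO`; STLs are written
#' next to the manifest.
#'
#' @param organs list of `organ_model`s; @param dir output directory;
#' @param dialect STL dialect.
#' @export
write_organ_manifest <- function(organs, dir, dialect = "binary") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(organs, function(o) {
    fname <- paste0(gsub(" ", "_", o$name), ".stl")
    write_stl(o$mesh, file.path(dir, fname), dialect = dialect)
    list(name = o$name, stl = fname, T_MO = unname(as_homogeneous(o$T_MO)))
  })
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}

#' @rdname write_organ_manifest
#' @param path manifest path.
#' @export
read_organ_manifest <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  dir <- dirname(path)
  lapply(entries, function(e) {
    m <- matrix(unlist(e$T_MO), 4, 4, byrow = TRUE)
    organ_model(e$name, read_stl(file.path(dir, e$stl)),
                from_homogeneous(m, from = "M", to = e$name))
  })
}
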