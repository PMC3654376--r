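#' Read and write triangulated meshes (ASCII OFF and PLY)
#'
#' `read_mesh()` dispatches on the file extension (`.off` or `.ply`). Both
#' formats are read in their ASCII forms. Hemisphere labels are taken from a
#' per-vertex integer `hemisphere` property (0 = left, 1 = right) when the PLY
#' file carries one, from a one-column sidecar file `<path>.hemi` (one
#' `left`/`right` label per vertex) when present, and otherwise default to the
#' sign of x.
#'
#' @param path file path.
#' @param mesh a [cortical_mesh()].
#' @param hemisphere_sidecar logical; also write the `<path>.hemi` label
#'   sidecar (always written for OFF; for PLY the labels are embedded).
#' @return `read_mesh()` returns a [cortical_mesh()]; writers return the path
#'   invisibly.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    off = read_off(path),
    ply = read_ply(path),
    stop("unsupported mesh format '.", ext, "' (expected .off or .ply)")
  )
  sidecar <- paste0(path, ".hemi")
  if (is.null(mesh$hemisphere_from_file) || !mesh$hemisphere_from_file) {
    if (file.exists(sidecar)) {
      h <- scan(sidecar, what = character(), quiet = TRUE)
      mesh <- cortical_mesh(mesh$vertices, mesh$triangles, hemisphere = h)
    }
  }
  mesh$hemisphere_from_file <- NULL
  mesh
}

read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  if (toupper(trimws(txt[1L])) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = txt[2L], quiet = TRUE)
  nv <- counts[1L]
  nf <- counts[2L]
  vals <- scan(text = txt[3:(2 + nv)], quiet = TRUE)
  vertices <- matrix(vals, ncol = 3L, byrow = TRUE)
  fvals <- scan(text = txt[(3 + nv):(2 + nv + nf)], quiet = TRUE)
  faces <- matrix(fvals, ncol = 4L, byrow = TRUE)
  if (any(faces[, 1L] != 3L)) stop("OFF reader supports triangular faces only")
  mesh <- cortical_mesh(vertices, faces[, 2:4] + 1L)
  mesh$hemisphere_from_file <- FALSE
  mesh
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path, hemisphere_sidecar = FALSE) {
  stopifnot(inherits(mesh, "cortical_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    off = write_off(mesh, path),
    ply = write_ply(mesh, path),
    stop("unsupported mesh format '.", ext, "'")
  )
  if (hemisphere_sidecar || ext == "off") {
    writeLines(mesh$hemisphere, paste0(path, ".hemi"))
  }
  invisible(path)
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(apply(mesh$vertices, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1L, function(r)
    paste(c(3L, r), collapse = " ")), con)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (trimws(txt[1L]) != "ply") stop("not a PLY file: ", path)
  endhdr <- which(trimws(txt) == "end_header")[1L]
  hdr <- trimws(txt[seq_len(endhdr)])
  if (!any(grepl("^format ascii", hdr))) {
    stop("only ASCII PLY is supported")
  }
  elem_lines <- grep("^element ", hdr)
  elems <- do.call(rbind, lapply(strsplit(hdr[elem_lines], "\\s+"), function(p)
    data.frame(name = p[2L], n = as.integer(p[3L]))))
  # properties of the vertex element, in declaration order
  vtx_i <- elem_lines[elems$name == "vertex"]
  nxt <- c(elem_lines, endhdr)[which(c(elem_lines, endhdr) > vtx_i)][1L]
  vprops <- hdr[(vtx_i + 1L):(nxt - 1L)]
  vprops <- vprops[grepl("^property ", vprops)]
  vnames <- vapply(strsplit(vprops, "\\s+"), function(p) p[length(p)], "")
  nv <- elems$n[elems$name == "vertex"]
  nf <- elems$n[elems$name == "face"]
  body <- txt[-seq_len(endhdr)]
  body <- body[nzchar(trimws(body))]
  vvals <- scan(text = body[seq_len(nv)], quiet = TRUE)
  vmat <- matrix(vvals, ncol = length(vnames), byrow = TRUE)
  colnames(vmat) <- vnames
  fvals <- scan(text = body[(nv + 1L):(nv + nf)], quiet = TRUE)
  fmat <- matrix(fvals, ncol = 4L, byrow = TRUE)
  if (any(fmat[, 1L] != 3L)) stop("PLY reader supports triangular faces only")
  hemi <- NULL
  from_file <- FALSE
  if ("hemisphere" %in% vnames) {
    hemi <- ifelse(vmat[, "hemisphere"] > 0, "right", "left")
    from_file <- TRUE
  }
  mesh <- cortical_mesh(vmat[, c("x", "y", "z")], fmat[, 2:4] + 1L,
                        hemisphere = hemi)
  mesh$hemisphere_from_file <- from_file
  mesh
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$triangles)
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nv),
    "property double x", "property double y", "property double z",
    "property uchar hemisphere",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  hemi01 <- as.integer(mesh$hemisphere == "right")
  writeLines(paste(
    formatC(mesh$vertices[, 1L], format = "g", digits = 17),
    formatC(mesh$vertices[, 2L], format = "g", digits = 17),
    formatC(mesh$vertices[, 3L], format = "g", digits = 17),
    hemi01
  ), con)
  writeLines(paste(3L, mesh$triangles[, 1L] - 1L, mesh$triangles[, 2L] - 1L,
                   mesh$triangles[, 3L] - 1L), con)
}
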