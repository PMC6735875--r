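#' Read and write meshes as ASCII PLY
#'
#' Minimal ASCII PLY support covering the vertex (`x y z`) and face
#' (`vertex_indices` list) elements used for endocardial shells. Face
#' indices are 0-based on disk (PLY convention) and 1-based in memory.
#'
#' @param path File path ending in `.ply`.
#' @return [read_mesh_ply()] returns a [surface_mesh()];
#'   [write_mesh_ply()] returns `path` invisibly.
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  assert_that(length(lines) > 0 && trimws(lines[[1]]) == "ply",
              "not a PLY file: %s", path)
  end_header <- match("end_header", trimws(lines))
  assert_that(!is.na(end_header), "PLY header not terminated")
  header <- lines[seq_len(end_header)]
  fmt <- grep("^format", header, value = TRUE)
  assert_that(length(fmt) == 1 && grepl("ascii", fmt),
              "only ASCII PLY is supported")
  elems <- grep("^element", header)
  counts <- list()
  for (i in elems) {
    parts <- strsplit(trimws(header[[i]]), "\\s+")[[1]]
    counts[[parts[2]]] <- as.integer(parts[3])
  }
  nv <- counts[["vertex"]] %||% 0L
  nf <- counts[["face"]] %||% 0L
  assert_that(nv > 0 && nf > 0, "PLY must declare vertex and face elements")
  body <- lines[(end_header + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vtx <- body[seq_len(nv)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vtx), "\\s+"), function(p) {
    as.numeric(p[1:3])
  }))
  fl <- body[nv + seq_len(nf)]
  fm <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(p) {
    k <- as.integer(p[1])
    assert_that(k == 3L, "only triangle faces are supported (got %d-gon)", k)
    as.integer(p[2:4]) + 1L
  }))
  surface_mesh(vm, fm)
}

#' @rdname read_mesh_ply
#' @param mesh A [surface_mesh()] to write.
#' @export
write_mesh_ply <- function(mesh, path) {
  nv <- n_vertices(mesh)
  nf <- nrow(mesh$faces)
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header"
  )
  vtx <- apply(mesh$vertices, 1, function(v) {
    paste(format(v, digits = 10, scientific = FALSE, trim = TRUE), collapse = " ")
  })
  fcs <- apply(mesh$faces - 1L, 1, function(f) paste(c(3L, f), collapse = " "))
  writeLines(c(header, vtx, fcs), path)
  invisible(path)
}
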