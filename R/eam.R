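#' Per-vertex scalar maps
#'
#' A node map is a tibble with one row per mesh vertex: `vertex_id`,
#' `value` (mV or ms; `NA` while unknown), and `known` (`TRUE` at vertices
#' carrying a measurement, the Dirichlet constraints of the interpolation).
#'
#' @param values Numeric per-vertex values (`NA` allowed where unknown).
#' @param known Logical per-vertex measured flag; defaults to `!is.na(values)`.
#' @return A tibble of class `node_map`.
#' @export
node_map <- function(values, known = !is.na(values)) {
  assert_that(length(values) == length(known),
              "values and known must have equal length")
  assert_that(all(is.finite(values[known])), "known values must be finite")
  out <- tibble::tibble(vertex_id = seq_along(values),
                        value = as.numeric(values), known = as.logical(known))
  class(out) <- c("node_map", class(out))
  out
}

#' Assign electrogram samples to mesh vertices
#'
#' Each sample is assigned to its nearest mesh vertex; a vertex receiving
#' multiple samples takes their mean. Vertices with at least one sample are
#' flagged known and act as the fixed boundary condition for
#' [relax_interpolate()]. Samples must already be in the mesh frame.
#'
#' @param samples Tibble with `x_mm`, `y_mm`, `z_mm`, `bipolar_mV` and
#'   optionally `lat_ms` columns (as from [simulate_egm_samples()], after
#'   registration into the mesh frame).
#' @param mesh A [surface_mesh()].
#' @return A list with `voltage` and `lat` [node_map()]s (the `lat` map has
#'   no known vertices when `lat_ms` is absent) and `assignment`, the
#'   per-sample nearest vertex index.
#' @export
assign_egm_to_nodes <- function(samples, mesh) {
  assert_that(is.data.frame(samples) && nrow(samples) > 0,
              "at least one electrogram sample is required")
  assert_that(all(c("x_mm", "y_mm", "z_mm", "bipolar_mV") %in% names(samples)),
              "samples need columns x_mm, y_mm, z_mm, bipolar_mV")
  nv <- n_vertices(mesh)
  idx <- as.integer(nearest_index(samples, mesh$vertices))
  mean_by_vertex <- function(x) {
    ok <- !is.na(x)
    if (!any(ok)) return(node_map(rep(NA_real_, nv)))
    m <- tapply(x[ok], idx[ok], mean)
    vals <- rep(NA_real_, nv)
    vals[as.integer(names(m))] <- as.numeric(m)
    node_map(vals)
  }
  volt <- mean_by_vertex(samples$bipolar_mV)
  lat <- if ("lat_ms" %in% names(samples)) {
    mean_by_vertex(samples$lat_ms)
  } else {
    node_map(rep(NA_real_, nv))
  }
  list(voltage = volt, lat = lat, assignment = idx)
}

# Accept either a surface_mesh or a bare vertex graph (list with
# n_vertices and an edge matrix); interpolation only needs the graph.
as_vertex_graph <- function(mesh) {
  if (inherits(mesh, "surface_mesh")) {
    list(n = n_vertices(mesh), edges = mesh$edges, mesh = mesh)
  } else if (is.list(mesh) && !is.null(mesh$edges) && !is.null(mesh$n_vertices)) {
    list(n = as.integer(mesh$n_vertices),
         edges = matrix(as.integer(as.matrix(mesh$edges)), ncol = 2),
         mesh = NULL)
  } else {
    stop_config("mesh must be a surface_mesh or a list(n_vertices, edges)")
  }
}

graph_components <- function(n, edges) {
  adj <- split(c(edges[, 2], edges[, 1]),
               factor(c(edges[, 1], edges[, 2]), levels = seq_len(n)))
  comp <- integer(n)
  label <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    label <- label + 1L
    queue <- start
    comp[start] <- label
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- label
      queue <- c(queue, new)
    }
  }
  comp
}

# Cotangent edge weights from mesh faces (clamped at a small positive floor
# so the system stays an M-matrix on poor triangulations).
cotangent_weights <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  wts <- new.env()
  half_cot <- function(i, j, k) {
    a <- v[i, ] - v[k, ]; b <- v[j, ] - v[k, ]
    cr <- sqrt(sum(crossprod3(a, b)^2))
    sum(a * b) / max(cr, 1e-12) / 2
  }
  key <- function(i, j) paste0(min(i, j), "_", max(i, j))
  for (r in seq_len(nrow(f))) {
    tri <- f[r, ]
    combs <- rbind(c(1, 2, 3), c(2, 3, 1), c(1, 3, 2))
    for (c_ in 1:3) {
      i <- tri[combs[c_, 1]]; j <- tri[combs[c_, 2]]; k <- tri[combs[c_, 3]]
      id <- key(i, j)
      wts[[id]] <- (wts[[id]] %||% 0) + half_cot(i, j, k)
    }
  }
  e <- mesh$edges
  w <- vapply(seq_len(nrow(e)), function(r) {
    pmax(wts[[key(e[r, 1], e[r, 2])]] %||% 0, 1e-8)
  }, numeric(1))
  w
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Laplacian (relaxation) interpolation over the mesh
#'
#' Fills the unknown vertices of a partial node map by solving the discrete
#' Laplace equation on the vertex-edge graph with the measured vertices as
#' fixed (Dirichlet) boundary conditions: with uniform weights each unknown
#' vertex equals the mean of its neighbours, the steady state of the
#' relaxation that colour-map interpolation on mapping platforms performs.
#' Solved directly as a sparse linear system.
#'
#' @param partial A [node_map()] with at least one known vertex.
#' @param mesh A [surface_mesh()], or a bare graph
#'   `list(n_vertices =, edges =)`.
#' @param weights `"uniform"` (default, combinatorial Laplacian) or
#'   `"cotangent"` (geometry-aware weights; requires a real mesh).
#' @return A fully defined [node_map()] (`known` flags preserved).
#' @export
#' @examples
#' path <- list(n_vertices = 5L, edges = cbind(1:4, 2:5))
#' pm <- node_map(c(0, NA, NA, NA, 1))
#' relax_interpolate(pm, path)$value  # linear ramp 0, .25, .5, .75, 1
relax_interpolate <- function(partial, mesh, weights = c("uniform", "cotangent")) {
  weights <- match.arg(weights)
  g <- as_vertex_graph(mesh)
  assert_that(nrow(partial) == g$n,
              "node map length (%d) does not match vertex count (%d)",
              nrow(partial), g$n)
  known <- partial$known
  assert_that(any(known), "no known vertices: interpolation is unconstrained")
  comp <- graph_components(g$n, g$edges)
  bad <- setdiff(unique(comp), unique(comp[known]))
  assert_that(length(bad) == 0,
              "mesh component %s contains no known vertex",
              paste(bad, collapse = ", "))
  vals <- partial$value
  if (all(known)) return(node_map(vals, known))
  w <- if (weights == "cotangent") {
    assert_that(!is.null(g$mesh), "cotangent weights need a surface_mesh")
    cotangent_weights(g$mesh)
  } else {
    rep(1, nrow(g$edges))
  }
  i <- c(g$edges[, 1], g$edges[, 2])
  j <- c(g$edges[, 2], g$edges[, 1])
  ww <- c(w, w)
  wmat <- Matrix::sparseMatrix(i = i, j = j, x = ww, dims = c(g$n, g$n))
  lap <- Matrix::Diagonal(x = Matrix::rowSums(wmat)) - wmat
  u <- which(!known)
  k <- which(known)
  rhs <- -lap[u, k, drop = FALSE] %*% vals[k]
  sol <- Matrix::solve(lap[u, u, drop = FALSE], rhs)
  vals[u] <- as.numeric(sol)
  assert_that(all(is.finite(vals)), "interpolation produced non-finite values")
  node_map(vals, known)
}

#' Binarize a voltage map at an abnormality threshold
#'
#' Labels a vertex abnormal (1) when its bipolar voltage is strictly below
#' the threshold, the conventional `< 1.5 mV` rule for abnormal myocardium.
#'
#' @param map A fully defined [node_map()] or numeric vector of voltages.
#' @param threshold_mV Voltage threshold in mV (default 1.5).
#' @return Integer 0/1 vector (1 = abnormal/low voltage).
#' @export
binarize_map <- function(map, threshold_mV = 1.5) {
  vals <- if (is.data.frame(map)) map$value else as.numeric(map)
  assert_that(all(is.finite(vals)),
              "map has non-finite values; interpolate before binarizing")
  as.integer(vals < threshold_mV)
}

#' Classify stimulus-to-QRS conduction delays
#'
#' Non-capturing sites are categorised `no_capture` and excluded from the
#' proportions. Captured sites are `normal` when S-QRS is at most `slow_ms`
#' and `slow` when strictly above it (slow conduction); sites at or above
#' `very_slow_ms` are additionally flagged. Proportions are over captured
#' sites.
#'
#' @param sites Tibble with `captured` (logical) and `s_qrs_ms` columns (as
#'   from [simulate_pace_sites()]).
#' @param slow_ms Slow-conduction threshold (ms); default 40.
#' @param very_slow_ms Very-slow flag threshold (ms); default 80.
#' @return A list of class `sqrs_classification`: `sites` (input plus
#'   `category` and `very_slow` columns) and `summary` (one-row tibble of
#'   counts and percentages).
#' @export
#' @examples
#' sites <- tibble::tibble(captured = c(TRUE, TRUE, FALSE),
#'                         s_qrs_ms = c(30, 65, NA))
#' classify_sqrs(sites)$summary
classify_sqrs <- function(sites, slow_ms = 40, very_slow_ms = 80) {
  assert_that(all(c("captured", "s_qrs_ms") %in% names(sites)),
              "sites need columns captured, s_qrs_ms")
  assert_that(0 < slow_ms && slow_ms < very_slow_ms,
              "thresholds must satisfy 0 < slow_ms < very_slow_ms")
  sq <- sites$s_qrs_ms
  cap <- sites$captured
  assert_that(all(is.na(sq) | sq >= 0), "negative S-QRS interval")
  assert_that(all(!cap == is.na(sq)),
              "s_qrs_ms must be present exactly at captured sites")
  category <- dplyr::case_when(
    !cap ~ "no_capture",
    sq > slow_ms ~ "slow",
    TRUE ~ "normal"
  )
  very_slow <- cap & sq >= very_slow_ms
  n_cap <- sum(cap)
  pct <- function(k) if (n_cap > 0) 100 * k / n_cap else NA_real_
  summary <- tibble::tibble(
    n_total = length(cap),
    n_captured = n_cap,
    n_no_capture = sum(!cap),
    n_normal = sum(category == "normal"),
    n_slow = sum(category == "slow"),
    n_very_slow = sum(very_slow),
    pct_normal = pct(sum(category == "normal")),
    pct_slow = pct(sum(category == "slow")),
    pct_very_slow = pct(sum(very_slow))
  )
  out <- list(
    sites = dplyr::mutate(sites, category = category, very_slow = very_slow),
    summary = summary,
    slow_ms = slow_ms, very_slow_ms = very_slow_ms
  )
  class(out) <- "sqrs_classification"
  out
}

#' @export
print.sqrs_classification <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<sqrs_classification: %d sites, %d captured; %d (%.1f%%) <=%g ms, %d (%.1f%%) >%g ms, %d (%.1f%%) >=%g ms>\n",
    s$n_total, s$n_captured, s$n_normal, s$pct_normal, x$slow_ms,
    s$n_slow, s$pct_slow, x$slow_ms, s$n_very_slow, s$pct_very_slow,
    x$very_slow_ms))
  invisible(x)
}

#' Electrogram signal-to-noise ratio
#'
#' Peak-to-peak amplitude divided by the baseline noise level (both mV);
#' in-scanner baseline noise is typically around 0.1 mV.
#'
#' @param amplitude_mV Peak-to-peak amplitude(s), mV.
#' @param noise_mV Baseline noise level, mV; must be positive.
#' @return Numeric ratio(s).
#' @export
#' @examples
#' egm_snr(4.478, 0.1)  # 44.78
egm_snr <- function(amplitude_mV, noise_mV = 0.1) {
  assert_that(all(noise_mV > 0), "noise_mV must be positive")
  amplitude_mV / noise_mV
}
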