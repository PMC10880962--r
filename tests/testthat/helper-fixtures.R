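# Fixtures built in code: a structured box mesh (uniform Kuhn tets) for FE
# patch/closed-form tests, cached default rudiment artefacts so the suite
# builds them once, and small constructors used across files.

make_box_mesh <- function(L = c(1, 1, 1), h = 0.25, region = "MC") {
  nx <- round(L[1] / h); ny <- round(L[2] / h); nz <- round(L[3] / h)
  vid <- function(i, j, k) 1 + i + (nx + 1) * (j + (ny + 1) * k)
  idx <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  corner <- function(di, dj, dk) vid(idx$i + di, idx$j + dj, idx$k + dk)
  v <- cbind(corner(0, 0, 0), corner(1, 0, 0), corner(0, 1, 0), corner(1, 1, 0),
             corner(0, 0, 1), corner(1, 0, 1), corner(0, 1, 1), corner(1, 1, 1))
  paths <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                 c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  elems <- do.call(rbind, lapply(1:6, function(t) v[, paths[t, ]]))
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  nodes <- cbind(g$i * h, g$j * h, g$k * h)
  vol <- tet_volumes(nodes, elems)
  elems[vol < 0, c(3, 4)] <- elems[vol < 0, c(4, 3)]
  m <- list(nodes = nodes, elems = elems,
            region = rep(match(region, c("MC", "PQ", "CH", "interzone")),
                         nrow(elems)),
            region_labels = c("MC", "PQ", "CH", "interzone"), h = h,
            landmarks = list(joint_centre = c(0, 0, 0),
                             joint_line_dir = c(0, 1, 0),
                             retroarticular = c(L[1] / 2, 0, -L[3])),
            frame = diag(3))
  rownames(m$frame) <- c("AP", "ML", "VD")
  class(m) <- "labelled_tet_mesh"
  m
}

# cached default rudiment (built once per test run)
default_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_rudiment_mesh(rudiment_spec(), seed = 1L)
    cache
  }
})

uniform_node_field <- function(mesh, T) {
  structure(list(tensors = matrix(rep(jawgrowth:::voigt6(T),
                                      each = nrow(mesh$nodes)), ncol = 6),
                 kind = "test", params = list()),
            class = "node_growth_field")
}

regular_tetrahedron <- function(edge = 1) {
  edge * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
}

as_set <- function(pos, ids = seq_len(nrow(pos)), dpf = 4) {
  out <- tibble::tibble(cell_id = ids, x_um = pos[, 1], y_um = pos[, 2],
                        z_um = pos[, 3], timepoint_dpf = dpf)
  class(out) <- c("centroid_set", class(out))
  out
}
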