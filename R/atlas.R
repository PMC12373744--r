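#' Surface atlas on a 2-D grid mesh
#'
#' A `surface_atlas` is an abstract stand-in for a cortical surface
#' parcellation: a set of vertices with an undirected adjacency structure and
#' a partition into named, connected regions.  The mesh is a 2-D grid graph
#' (4-neighbour adjacency); cluster-level inference in this package depends
#' only on adjacency, not on any geometric embedding, so a grid exercises the
#' same topology as a sphere with far simpler code.
#'
#' @param n_regions number of regions (>= 2).
#' @param vertices_per_region vertices in each region (>= 4); regions are
#'   rectangular blocks and hence connected.
#' @param seed kept for API symmetry; the layout is fully deterministic.
#' @param region_names optional character vector of length `n_regions`.
#'   Defaults to `"REG<k>.L"` / `"REG<k>.R"` with the hemisphere assigned by
#'   grid half, following the `<Name>.<Hemisphere>` convention used for
#'   cortical labels (e.g. `PCUN.R`, `MOF.R`).
#'
#' @return An object of class `surface_atlas` with fields `vertex_ids`,
#'   `coords` (grid row/column per vertex), `region_of_vertex`,
#'   `region_names`, `edges` (2-column matrix, each undirected edge once)
#'   and `graph` (the igraph object used for connected components).
#' @export
#' @examples
#' atl <- make_atlas(4, 25)
#' length(atl$vertex_ids)      # 100
#' atl$region_names
make_atlas <- function(n_regions, vertices_per_region, seed = 1L,
                       region_names = NULL) {
  if (n_regions < 2) {
    stop_fmt("configuration error: n_regions must be >= 2 (got %d)", n_regions)
  }
  if (vertices_per_region < 4) {
    stop_fmt(paste0("configuration error: vertices_per_region must be >= 4 ",
                    "(got %d); clusters need room"), vertices_per_region)
  }
  n_regions <- as.integer(n_regions)
  vpr <- as.integer(vertices_per_region)

  # region block shape: the divisor pair of vpr closest to square
  divs <- which(vpr %% seq_len(vpr) == 0)
  br <- max(divs[divs <= floor(sqrt(vpr))])
  bc <- vpr %/% br

  # region layout: near-square grid of blocks, row-major, last row may be short
  ncg <- ceiling(sqrt(n_regions))
  nrg <- ceiling(n_regions / ncg)

  if (is.null(region_names)) {
    hemi <- ifelse(((seq_len(n_regions) - 1L) %% ncg) < ncg / 2, "L", "R")
    region_names <- sprintf("REG%02d.%s", seq_len(n_regions), hemi)
  }
  if (length(region_names) != n_regions || anyDuplicated(region_names)) {
    stop_fmt("configuration error: region_names must be %d unique names",
             n_regions)
  }

  rows <- integer(0); cols <- integer(0); reg <- character(0)
  for (r in seq_len(n_regions)) {
    gi <- (r - 1L) %/% ncg
    gj <- (r - 1L) %% ncg
    block <- expand.grid(row = gi * br + seq_len(br),
                         col = gj * bc + seq_len(bc))
    rows <- c(rows, block$row)
    cols <- c(cols, block$col)
    reg  <- c(reg, rep(region_names[r], vpr))
  }
  n <- length(rows)
  ids <- seq_len(n)

  # 4-neighbour grid adjacency via coordinate lookup
  nr <- max(rows); nc <- max(cols)
  idx <- matrix(NA_integer_, nr, nc)
  idx[cbind(rows, cols)] <- ids
  e_right <- cbind(idx[, -nc, drop = FALSE], idx[, -1, drop = FALSE])
  e_down  <- cbind(idx[-nr, , drop = FALSE], idx[-1, , drop = FALSE])
  edges <- rbind(matrix(e_right, ncol = 2), matrix(e_down, ncol = 2))
  edges <- edges[stats::complete.cases(edges), , drop = FALSE]
  storage.mode(edges) <- "integer"

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$name <- as.character(ids)

  atlas <- structure(list(
    vertex_ids = ids,
    coords = data.frame(vertex = ids, row = rows, col = cols),
    region_of_vertex = reg,
    region_names = region_names,
    edges = edges,
    graph = g
  ), class = "surface_atlas")
  validate_atlas(atlas)
  atlas
}

#' Validate a surface atlas
#'
#' Checks the structural invariants: symmetric adjacency with no self-edges,
#' a total one-region-per-vertex labelling, at least one vertex per region,
#' and connectivity of every region's induced subgraph.
#'
#' @param atlas a `surface_atlas`.
#' @return the atlas, invisibly; errors on violation.
#' @export
validate_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "surface_atlas"))
  n <- length(atlas$vertex_ids)
  if (any(atlas$edges[, 1] == atlas$edges[, 2])) {
    stop_fmt("atlas invariant violated: self-edges present")
  }
  if (length(atlas$region_of_vertex) != n || anyNA(atlas$region_of_vertex)) {
    stop_fmt("atlas invariant violated: every vertex must map to one region")
  }
  miss <- setdiff(atlas$region_names, unique(atlas$region_of_vertex))
  if (length(miss)) {
    stop_fmt("atlas invariant violated: region(s) own no vertex: %s",
             paste(miss, collapse = ", "))
  }
  for (r in atlas$region_names) {
    vs <- which(atlas$region_of_vertex == r)
    sub <- igraph::induced_subgraph(atlas$graph, vs)
    if (igraph::components(sub)$no != 1L) {
      stop_fmt("atlas invariant violated: region %s is not connected", r)
    }
  }
  invisible(atlas)
}

#' Vertices belonging to a region
#' @param atlas a `surface_atlas`.
#' @param region region name; must exist in the atlas.
#' @return integer vertex ids.
#' @export
region_vertices <- function(atlas, region) {
  if (!region %in% atlas$region_names) {
    stop_fmt("naming error: unknown region '%s' (atlas has: %s)", region,
             paste(atlas$region_names, collapse = ", "))
  }
  which(atlas$region_of_vertex == region)
}

#' @export
print.surface_atlas <- function(x, ...) {
  cat(sprintf("surface_atlas: %d vertices, %d regions, %d edges (grid mesh)\n",
              length(x$vertex_ids), length(x$region_names), nrow(x$edges)))
  cat("regions:", paste(utils::head(x$region_names, 8), collapse = ", "),
      if (length(x$region_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Connected clusters within a vertex mask
#'
#' Groups the `TRUE` vertices of `mask` into connected components under the
#' atlas adjacency.
#' @return list of integer vertex-id vectors, one per component.
#' @noRd
clusters_from_mask <- function(atlas, mask) {
  vs <- which(mask)
  if (!length(vs)) return(list())
  sub <- igraph::induced_subgraph(atlas$graph, vs)
  memb <- igraph::components(sub)$membership
  ids <- as.integer(igraph::V(sub)$name)
  unname(split(ids, memb))
}
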