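## Labeled tetrahedral meshes ------------------------------------------------
##
## A tet_mesh holds node coordinates in meters, element connectivity (4-node
## linear T4 or 10-node quadratic T10 tetrahedra), and one component and one
## material-region label per element.  Components name anatomical parts
## (periotic, bulla, pedicles, ossicles, ligaments); regions select material
## cards (stiff_bone, flexible_bone, stiff_ligament, flexible_ligament).

REGION_LEVELS <- c("stiff_bone", "flexible_bone", "stiff_ligament", "flexible_ligament")

# T10 midside node k (columns 5..10) lies on the edge between corner columns
# TET10_EDGES[k-4, ].  VTK quadratic-tet convention.
TET10_EDGES <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L),
                     c(1L, 4L), c(2L, 4L), c(3L, 4L))

#' Construct a labeled tetrahedral mesh
#'
#' @param nodes numeric matrix, one row per node, columns x, y, z in meters.
#' @param elements integer matrix, one row per tetrahedron with 4 (linear) or
#'   10 (quadratic, VTK midside ordering) node indices into `nodes`.
#' @param component character vector, one anatomical component name per element.
#' @param region character vector, one material-region name per element; must
#'   be one of `"stiff_bone"`, `"flexible_bone"`, `"stiff_ligament"`,
#'   `"flexible_ligament"`.
#' @param validate check invariants (positive volumes, index ranges)?
#'
#' @return An object of class `tet_mesh` with fields `nodes`, `elements`,
#'   `component`, `region` and a content `hash`.
#' @export
tet_mesh <- function(nodes, elements, component, region, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  if (ncol(nodes) != 3L) stop2("nodes must have 3 columns (x, y, z)")
  if (!ncol(elements) %in% c(4L, 10L))
    stop2("elements must have 4 or 10 columns, got %d", ncol(elements))
  if (nrow(elements) < 1L) stop2("mesh must contain at least one element")
  component <- as.character(component)
  region <- as.character(region)
  if (length(component) != nrow(elements) || length(region) != nrow(elements))
    stop2("component/region labels must have one entry per element")
  bad_region <- setdiff(unique(region), REGION_LEVELS)
  if (length(bad_region))
    stop2("unknown region label(s): %s", paste(bad_region, collapse = ", "))
  m <- structure(
    list(nodes = nodes, elements = elements,
         component = component, region = region,
         order = if (ncol(elements) == 4L) 4L else 10L),
    class = "tet_mesh")
  if (validate) validate_mesh(m)
  m$hash <- mesh_hash(m)
  m
}

mesh_hash <- function(mesh) {
  content_hash(mesh$nodes, mesh$elements, mesh$component, mesh$region)
}

#' @exportS3Method base::print
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d T%d elements\n",
              nrow(x$nodes), nrow(x$elements), x$order))
  tab <- table(x$component)
  for (nm in names(tab))
    cat(sprintf("  %-28s %5d elements (%s)\n", nm, tab[[nm]],
                x$region[match(nm, x$component)]))
  invisible(x)
}

# signed volume of each tetrahedron from its corner nodes
element_volumes <- function(mesh) {
  el <- mesh$elements
  p1 <- mesh$nodes[el[, 1], , drop = FALSE]
  a <- mesh$nodes[el[, 2], , drop = FALSE] - p1
  b <- mesh$nodes[el[, 3], , drop = FALSE] - p1
  c_ <- mesh$nodes[el[, 4], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
   a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

validate_mesh <- function(mesh) {
  el <- mesh$elements
  if (any(el < 1L) || any(el > nrow(mesh$nodes)))
    stop2("element node index out of range")
  if (anyNA(mesh$nodes) || any(!is.finite(mesh$nodes)))
    stop2("non-finite node coordinates")
  v <- element_volumes(mesh)
  bad <- which(v <= 0)
  if (length(bad))
    stop2("element(s) with non-positive volume: %s",
          paste(utils::head(bad, 10), collapse = ", "))
  invisible(TRUE)
}

#' Uniformly scale a mesh about the origin
#'
#' Multiplies every node coordinate by `s`; labels and connectivity are
#' untouched. Frequencies of an elastic body scale as 1/s under this map.
#'
#' @param mesh a [tet_mesh()].
#' @param s positive scale factor.
#' @return the scaled `tet_mesh`.
#' @export
scale_mesh <- function(mesh, s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop2("scale factor must be a single positive number")
  tet_mesh(mesh$nodes * s, mesh$elements, mesh$component, mesh$region,
           validate = FALSE)
}

# element-adjacency connected components via shared nodes
mesh_fragments <- function(elements) {
  ne <- nrow(elements)
  nn <- max(elements)
  # union-find over nodes seeded by element membership
  parent <- seq_len(nn)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(ne)) {
    ids <- elements[e, ]
    r <- find(ids[1])
    for (j in ids[-1]) {
      rj <- find(j)
      if (rj != r) parent[rj] <- r
    }
  }
  roots <- vapply(elements[, 1], find, integer(1))
  match(roots, unique(roots))   # fragment id per element
}

#' Remove named components from a mesh
#'
#' Deletes all elements whose component label is in `names`, prunes orphaned
#' nodes, and renumbers. Two cleanup passes keep the result solvable:
#' ligament elements that lose their bone anchor on one side are dropped
#' (`drop_dangling_ligaments`), and any disconnected fragment that no longer
#' attaches to the main body is pruned with a message.
#'
#' @param mesh a [tet_mesh()].
#' @param names character vector of component labels to delete (may be empty).
#' @param drop_dangling_ligaments also delete ligament-region elements that
#'   touched a removed component (default TRUE).
#' @return list with `mesh` (the reduced `tet_mesh`) and `node_map` (integer
#'   vector, old node id -> new node id, NA for deleted nodes).
#' @export
remove_components <- function(mesh, names, drop_dangling_ligaments = TRUE) {
  names <- as.character(names)
  if (length(names) == 0L)
    return(list(mesh = mesh, node_map = seq_len(nrow(mesh$nodes))))
  unknown <- setdiff(names, unique(mesh$component))
  if (length(unknown))
    stop2("unknown component label(s): %s", paste(unknown, collapse = ", "))
  drop <- mesh$component %in% names
  if (drop_dangling_ligaments) {
    # nodes owned by removed elements
    removed_nodes <- unique(as.vector(mesh$elements[drop, , drop = FALSE]))
    lig <- grepl("ligament", mesh$region) & !drop
    touches <- lig & apply(matrix(mesh$elements %in% removed_nodes,
                                  nrow = nrow(mesh$elements)), 1, any)
    if (any(touches)) {
      message(sprintf("dropping %d dangling ligament element(s) of: %s",
                      sum(touches),
                      paste(unique(mesh$component[touches]), collapse = ", ")))
      drop <- drop | touches
    }
  }
  keep <- !drop
  if (!any(keep)) stop2("removal would produce an empty mesh")
  el <- mesh$elements[keep, , drop = FALSE]
  comp <- mesh$component[keep]
  reg <- mesh$region[keep]
  # prune fragments detached from the largest remaining body (prefer the
  # fragment containing 'periotic', the fixed-base component, if present)
  frag <- mesh_fragments(el)
  if (max(frag) > 1L) {
    root_frag <- if ("periotic" %in% comp) frag[match("periotic", comp)]
                 else which.max(tabulate(frag))
    off <- frag != root_frag
    message(sprintf("pruning %d element(s) in %d detached fragment(s)",
                    sum(off), length(unique(frag[off]))))
    el <- el[!off, , drop = FALSE]
    comp <- comp[!off]
    reg <- reg[!off]
    if (nrow(el) == 0L) stop2("removal would produce an empty mesh")
  }
  used <- sort(unique(as.vector(el)))
  node_map <- rep(NA_integer_, nrow(mesh$nodes))
  node_map[used] <- seq_along(used)
  el[] <- node_map[el]
  out <- tet_mesh(mesh$nodes[used, , drop = FALSE], el, comp, reg,
                  validate = FALSE)
  list(mesh = out, node_map = node_map)
}

#' Select the fixed-base node set
#'
#' Returns the ids of nodes whose three displacement DOFs are constrained to
#' zero. By default this is the set of nodes of `component` lying within
#' `delta` of the component's base plane: the tangent plane, normal to the
#' component's least-variance (PCA) axis, on the side of the component facing
#' away from the rest of the mesh. `delta` defaults to 5% of the component's
#' bounding-box diagonal. A custom `predicate(xyz)` on node coordinates can
#' replace the plane heuristic.
#'
#' @param mesh a [tet_mesh()].
#' @param component component label whose base is fixed (default "periotic").
#' @param predicate optional function taking the n x 3 coordinate matrix of
#'   the component's nodes and returning a logical vector.
#' @param delta distance tolerance in meters (default 5% of the component
#'   bounding-box diagonal).
#' @return integer vector of node ids (at least 3, non-collinear).
#' @export
fixed_node_set <- function(mesh, component = "periotic", predicate = NULL,
                           delta = NULL) {
  in_comp <- mesh$component == component
  if (!any(in_comp)) stop2("no elements with component label '%s'", component)
  ids <- sort(unique(as.vector(mesh$elements[in_comp, , drop = FALSE])))
  xyz <- mesh$nodes[ids, , drop = FALSE]
  if (is.null(predicate)) {
    if (is.null(delta)) {
      bb <- apply(xyz, 2, range)
      delta <- 0.05 * sqrt(sum((bb[2, ] - bb[1, ])^2))
    }
    ctr <- colMeans(xyz)
    pc <- eigen(stats::cov(xyz), symmetric = TRUE)
    normal <- pc$vectors[, 3]                       # least-variance axis
    # orient the normal away from the full-mesh centroid
    if (sum((ctr - colMeans(mesh$nodes)) * normal) < 0) normal <- -normal
    d <- as.vector(xyz %*% normal)
    sel <- d >= max(d) - delta
  } else {
    sel <- predicate(xyz)
    if (!is.logical(sel) || length(sel) != nrow(xyz))
      stop2("predicate must return one logical per component node")
  }
  picked <- ids[sel]
  if (length(picked) < 3L)
    stop2("fixed-base selection has %d node(s); need >= 3 non-collinear",
          length(picked))
  # rank check: nodes must not be collinear or the model keeps a spin DOF
  p <- mesh$nodes[picked, , drop = FALSE]
  p <- sweep(p, 2, colMeans(p))
  if (qr(p)$rank < 2L)
    stop2("fixed-base selection is collinear (rank-deficient constraint)")
  picked
}

# corner faces of each tetrahedron, outward when the tet has positive volume
TET_FACES <- rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(2L, 3L, 4L), c(1L, 4L, 3L))

#' Extract the boundary surface of a tet mesh
#'
#' Boundary triangles are corner-node faces referenced by exactly one
#' tetrahedron. Normals are unit, oriented away from the owning element's
#' centroid. For quadratic meshes the surface uses corner vertices only.
#'
#' @param mesh a [tet_mesh()].
#' @return an object of class `surface_mesh`: `vertices` (m x 3 coordinates),
#'   `triangles` (t x 3 indices into vertices), `normals` (t x 3 unit,
#'   outward), `vertex_normals` (m x 3, area-weighted), `to_volume` (m-vector
#'   of volume node ids), `element` (owning tet per triangle), `mesh_hash`.
#' @export
surface_extract <- function(mesh) {
  el <- mesh$elements
  ne <- nrow(el)
  faces <- matrix(0L, 4L * ne, 3L)
  owner <- integer(4L * ne)
  for (f in 1:4) {
    faces[seq_len(ne) + (f - 1L) * ne, ] <- el[, TET_FACES[f, ], drop = FALSE]
    owner[seq_len(ne) + (f - 1L) * ne] <- seq_len(ne)
  }
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "_"))
  cnt <- table(key)
  on_boundary <- cnt[key] == 1L
  faces <- faces[on_boundary, , drop = FALSE]
  owner <- owner[on_boundary]
  # outward orientation: flip if normal points toward the element centroid
  v1 <- mesh$nodes[faces[, 1], , drop = FALSE]
  v2 <- mesh$nodes[faces[, 2], , drop = FALSE]
  v3 <- mesh$nodes[faces[, 3], , drop = FALSE]
  nrm <- cross3(v2 - v1, v3 - v1)
  cent_el <- (mesh$nodes[el[owner, 1], , drop = FALSE] +
              mesh$nodes[el[owner, 2], , drop = FALSE] +
              mesh$nodes[el[owner, 3], , drop = FALSE] +
              mesh$nodes[el[owner, 4], , drop = FALSE]) / 4
  cent_f <- (v1 + v2 + v3) / 3
  flip <- rowSums(nrm * (cent_f - cent_el)) < 0
  if (any(flip)) {
    faces[flip, 2:3] <- faces[flip, 3:2]
    nrm[flip, ] <- -nrm[flip, ]
  }
  area2 <- sqrt(rowSums(nrm^2))            # 2 * triangle area
  unit <- nrm / area2
  verts <- sort(unique(as.vector(faces)))
  vmap <- match(faces, verts)
  tri <- matrix(vmap, ncol = 3)
  # area-weighted vertex normals
  vn <- matrix(0, length(verts), 3)
  for (c_ in 1:3) {
    for (ax in 1:3) {
      acc <- rowsum(nrm[, ax], tri[, c_], reorder = FALSE)
      idx <- as.integer(rownames(acc))
      vn[idx, ax] <- vn[idx, ax] + acc
    }
  }
  vn <- vn / pmax(sqrt(rowSums(vn^2)), .Machine$double.eps)
  structure(
    list(vertices = mesh$nodes[verts, , drop = FALSE],
         triangles = tri, normals = unit, areas = area2 / 2,
         vertex_normals = vn, to_volume = verts, element = owner,
         mesh_hash = mesh$hash),
    class = "surface_mesh")
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Promote a linear (T4) mesh to quadratic (T10)
#'
#' Inserts midside nodes at the midpoint of each unique edge (straight-sided
#' quadratic elements). Labels are unchanged. Quadratic elements avoid the
#' artificial bending stiffness of linear tetrahedra.
#'
#' @param mesh a 4-node [tet_mesh()].
#' @return a 10-node `tet_mesh`.
#' @export
promote_to_t10 <- function(mesh) {
  if (mesh$order == 10L) return(mesh)
  el <- mesh$elements
  ne <- nrow(el)
  nn <- nrow(mesh$nodes)
  ea <- el[, TET10_EDGES[, 1], drop = FALSE]
  eb <- el[, TET10_EDGES[, 2], drop = FALSE]
  lo <- pmin(ea, eb)
  hi <- pmax(ea, eb)
  key <- paste(lo, hi, sep = "_")
  uk <- unique(key)
  mid_id <- nn + match(key, uk)
  first <- match(uk, key)
  mids <- (mesh$nodes[lo[first], , drop = FALSE] +
           mesh$nodes[hi[first], , drop = FALSE]) / 2
  el10 <- cbind(el, matrix(mid_id, nrow = ne))
  tet_mesh(rbind(mesh$nodes, mids), el10, mesh$component, mesh$region,
           validate = FALSE)
}

# total volume helper
mesh_volume <- function(mesh) sum(element_volumes(mesh))
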