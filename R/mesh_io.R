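## Mesh file I/O -------------------------------------------------------------
##
## Two ASCII dialects are supported, the lingua franca of tet meshes:
##   - Gmsh MSH 4.1 (element type 4 = T4, 11 = T10); component/region labels
##     are embedded as physical-group names of the form "component/region",
##     one volume entity per (component, region) pair.
##   - Legacy VTK unstructured grid (cell type 10 = T4, 24 = T10); labels
##     travel in a CSV sidecar (header: element_id,component,region).
## A sidecar, when supplied, always wins over embedded labels.
## Gmsh and VTK disagree on the order of the last two T10 midside nodes;
## readers/writers convert to the internal (VTK) convention.

GMSH_T10_PERM <- c(1:8, 10L, 9L)   # internal (VTK) column -> gmsh column

#' Read a labeled tetrahedral mesh
#'
#' @param path mesh file.
#' @param format `"msh"` (Gmsh 4.1 ASCII) or `"vtk"` (legacy ASCII); guessed
#'   from the extension when missing.
#' @param sidecar optional CSV with columns element_id, component, region;
#'   required for VTK files and MSH files without physical names.
#' @param units `"m"` (default) or `"mm"`; mm coordinates are converted to
#'   meters (CT exports are commonly in mm).
#' @return a [tet_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "msh", "vtk"), sidecar = NULL,
                      units = c("m", "mm")) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) stop2("mesh file not found: %s", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     msh = "msh", vtk = "vtk",
                     stop2("cannot guess mesh format from '%s'", path))
  parsed <- if (format == "msh") parse_msh(path) else parse_vtk(path)
  nodes <- parsed$nodes
  if (units == "mm") nodes <- nodes / 1000
  comp <- parsed$component
  reg <- parsed$region
  if (!is.null(sidecar)) {
    lab <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    need <- c("element_id", "component", "region")
    if (!all(need %in% names(lab)))
      stop2("sidecar must have columns %s", paste(need, collapse = ", "))
    idx <- match(seq_len(nrow(parsed$elements)), lab$element_id)
    if (anyNA(idx)) stop2("sidecar is missing labels for some elements")
    comp <- lab$component[idx]
    reg <- lab$region[idx]
  }
  if (is.null(comp) || anyNA(comp))
    stop2("mesh has unlabeled elements; supply a label sidecar")
  tet_mesh(nodes, parsed$elements, comp, reg)
}

#' Write a labeled tetrahedral mesh
#'
#' Elements are written in input order (bit-stable round trips). A label
#' sidecar CSV (`<path>.labels.csv`) is always written; MSH files embed the
#' labels as physical names as well and round-trip standalone.
#'
#' @param mesh a [tet_mesh()].
#' @param path output file.
#' @param format `"msh"` or `"vtk"`; guessed from the extension when missing.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "msh", "vtk")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     msh = "msh", vtk = "vtk",
                     stop2("cannot guess mesh format from '%s'", path))
  if (format == "msh") write_msh(mesh, path) else write_vtk(mesh, path)
  utils::write.csv(
    data.frame(element_id = seq_len(nrow(mesh$elements)),
               component = mesh$component, region = mesh$region),
    paste0(path, ".labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- Gmsh MSH 4.1 ----------------------------------------------------------

write_msh <- function(mesh, path) {
  grp <- paste(mesh$component, mesh$region, sep = "/")
  ugrp <- unique(grp)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w("%d", length(ugrp))
  for (i in seq_along(ugrp)) w("3 %d \"%s\"", i, ugrp[i])
  w("$EndPhysicalNames")
  w("$Entities"); w("0 0 0 %d", length(ugrp))
  for (i in seq_along(ugrp)) w("%d 0 0 0 0 0 0 1 %d 0", i, i)
  w("$EndEntities")
  nn <- nrow(mesh$nodes)
  w("$Nodes"); w("1 %d 1 %d", nn, nn)
  w("3 1 0 %d", nn)
  writeLines(format(seq_len(nn)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("$EndNodes")
  etype <- if (mesh$order == 4L) 4L else 11L
  el <- mesh$elements
  if (mesh$order == 10L) el <- el[, GMSH_T10_PERM, drop = FALSE]
  ne <- nrow(el)
  w("$Elements"); w("%d %d 1 %d", length(ugrp), ne, ne)
  eid <- seq_len(ne)
  for (i in seq_along(ugrp)) {
    sel <- which(grp == ugrp[i])
    w("3 %d %d %d", i, etype, length(sel))
    writeLines(paste(eid[sel],
                     apply(el[sel, , drop = FALSE], 1, paste, collapse = " ")),
               con)
  }
  w("$EndElements")
}

msh_section <- function(lines, name) {
  a <- which(lines == paste0("$", name))
  b <- which(lines == paste0("$End", name))
  if (length(a) != 1L || length(b) != 1L) return(NULL)
  lines[(a + 1L):(b - 1L)]
}

split_nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])

parse_msh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fmt <- msh_section(lines, "MeshFormat")
  if (is.null(fmt)) stop2("%s: not a Gmsh MSH file", path)
  ver <- split_nums(fmt[1])[1]
  if (ver < 4) stop2("%s: MSH version %.1f unsupported (need 4.x ASCII)", path, ver)
  if (split_nums(fmt[1])[2] != 0) stop2("%s: binary MSH unsupported", path)

  phys <- list()
  pn <- msh_section(lines, "PhysicalNames")
  if (!is.null(pn)) {
    for (ln in pn[-1]) {
      m <- regmatches(ln, regexec('^\\s*\\d+\\s+(\\d+)\\s+"(.*)"', ln))[[1]]
      if (length(m) == 3) phys[[m[2]]] <- m[3]
    }
  }
  # volume entity tag -> physical tag
  ent2phys <- list()
  ent <- msh_section(lines, "Entities")
  if (!is.null(ent)) {
    counts <- split_nums(ent[1])
    i <- 2 + counts[1] + counts[2] + counts[3]
    for (k in seq_len(counts[4])) {
      v <- split_nums(ent[i])
      nphys <- v[8]
      if (!is.na(nphys) && nphys >= 1) ent2phys[[as.character(v[1])]] <- v[9]
      i <- i + 1
    }
  }

  nd <- msh_section(lines, "Nodes")
  hdr <- split_nums(nd[1])
  nblocks <- hdr[1]; ntot <- hdr[2]
  tags <- integer(0); coords <- matrix(0, 0, 3)
  i <- 2
  for (b in seq_len(nblocks)) {
    bh <- split_nums(nd[i]); nb <- bh[4]; i <- i + 1
    if (nb == 0) next
    btags <- as.integer(nd[i:(i + nb - 1)]); i <- i + nb
    bxyz <- t(vapply(nd[i:(i + nb - 1)], split_nums, numeric(3), USE.NAMES = FALSE))
    i <- i + nb
    tags <- c(tags, btags); coords <- rbind(coords, bxyz[, 1:3, drop = FALSE])
  }
  node_of_tag <- integer(max(tags)); node_of_tag[tags] <- seq_along(tags)

  els <- msh_section(lines, "Elements")
  hdr <- split_nums(els[1]); nblocks <- hdr[1]
  i <- 2
  conn <- NULL; labels <- character(0); etags <- numeric(0)
  order <- NA_integer_
  for (b in seq_len(nblocks)) {
    bh <- split_nums(els[i]); etag <- bh[2]; etype <- bh[3]; nb <- bh[4]
    i <- i + 1
    if (nb == 0) next
    rows <- els[i:(i + nb - 1)]; i <- i + nb
    if (!etype %in% c(4, 11)) next   # skip surface/line elements
    npe <- if (etype == 4) 4L else 10L
    mat <- t(vapply(rows, split_nums, numeric(npe + 1), USE.NAMES = FALSE))
    cn <- matrix(node_of_tag[as.integer(mat[, -1, drop = FALSE])], ncol = npe)
    if (npe == 10L) cn <- cn[, order(GMSH_T10_PERM), drop = FALSE]
    if (is.na(order)) order <- npe
    if (order != npe) stop2("%s: mixed element orders unsupported", path)
    ptag <- ent2phys[[as.character(etag)]]
    lab <- if (!is.null(ptag)) phys[[as.character(ptag)]] else NA_character_
    conn <- rbind(conn, cn)
    labels <- c(labels, rep(lab %||% NA_character_, nb))
    etags <- c(etags, mat[, 1])
  }
  if (is.null(conn)) stop2("%s: no tetrahedral elements found", path)
  # restore the writer's element order (blocks group by physical volume;
  # element tags carry the original sequence)
  ord <- order(etags)
  conn <- conn[ord, , drop = FALSE]
  labels <- labels[ord]
  comp <- reg <- rep(NA_character_, length(labels))
  ok <- !is.na(labels) & grepl("/", labels)
  comp[ok] <- sub("/.*$", "", labels[ok])
  reg[ok] <- sub("^.*/", "", labels[ok])
  list(nodes = coords, elements = conn,
       component = if (all(ok)) comp else NULL,
       region = if (all(ok)) reg else NULL)
}

## ---- legacy VTK ------------------------------------------------------------

write_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("tpcresonance tet mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  nn <- nrow(mesh$nodes)
  w("POINTS %d double", nn)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  ne <- nrow(mesh$elements)
  npe <- mesh$order
  w("CELLS %d %d", ne, ne * (npe + 1L))
  writeLines(paste(npe, apply(mesh$elements - 1L, 1, paste, collapse = " ")), con)
  w("CELL_TYPES %d", ne)
  writeLines(rep(if (npe == 4L) "10" else "24", ne), con)
}

parse_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# vtk DataFile", lines[1])) stop2("%s: not a legacy VTK file", path)
  if (toupper(trimws(lines[3])) != "ASCII") stop2("%s: binary VTK unsupported", path)
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) stop2("%s: no POINTS section", path)
  nn <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  vals <- numeric(0); i <- ip + 1
  while (length(vals) < 3 * nn) {
    vals <- c(vals, split_nums(lines[i])); i <- i + 1
  }
  nodes <- matrix(vals[1:(3 * nn)], ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  ne <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cell_rows <- lapply(lines[(ic + 1):(ic + ne)], split_nums)
  it <- grep("^CELL_TYPES", lines)[1]
  types <- as.integer(unlist(lapply(lines[(it + 1):length(lines)], split_nums)))[1:ne]
  keep <- types %in% c(10L, 24L)
  if (!any(keep)) stop2("%s: no tetrahedral cells", path)
  npe <- unique(vapply(cell_rows[keep], function(r) r[1], numeric(1)))
  if (length(npe) != 1L) stop2("%s: mixed element orders unsupported", path)
  conn <- t(vapply(cell_rows[keep], function(r) r[-1] + 1, numeric(npe)))
  list(nodes = nodes, elements = conn, component = NULL, region = NULL)
}
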