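#' Read a Gmsh MSH mesh with physical-group labels
#'
#' Supports ASCII MSH version 2.2 and 4.1 files containing 2-D triangle
#' elements tagged with physical groups. Physical-group names are mapped to
#' compartments through `region_map`; groups present in the file but absent
#' from the map are an error. The special target `"bleach"` labels nucleus
#' triangles carrying the bleach flag.
#'
#' @param path path to an ASCII `.msh` file.
#' @param region_map named character vector mapping physical-group names to
#'   one of `"cytoplasm"`, `"nucleus"`, `"aggregate_<id>"`, `"bleach"`, e.g.
#'   `c(cyto = "cytoplasm", nuc = "nucleus", ib1 = "aggregate_1")`.
#' @param pixel_size optional um/pixel stored on the mesh.
#' @return a [flip_mesh()].
#' @export
read_gmsh_mesh <- function(path, region_map, pixel_size = NULL) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt)) stop("not an MSH file: missing $MeshFormat")
  ver <- as.numeric(strsplit(trimws(fmt[1]), "\\s+")[[1]][1])

  pn <- sec("PhysicalNames")
  phys_names <- character(0)
  if (!is.null(pn)) {
    n <- as.integer(pn[1])
    for (k in seq_len(n)) {
      f <- strsplit(trimws(pn[k + 1L]), "\\s+")[[1]]
      nm <- gsub("\"", "", paste(f[-(1:2)], collapse = " "))
      phys_names[f[2]] <- nm
    }
  }

  if (ver < 4) {
    nd <- sec("Nodes")
    nn <- as.integer(nd[1])
    nodes <- read.table(text = nd[1L + seq_len(nn)])
    node_id <- nodes[[1]]
    coords <- as.matrix(nodes[, 2:3])
    el <- sec("Elements")
    ne <- as.integer(el[1])
    tri <- list(); phys <- integer(0)
    for (k in seq_len(ne)) {
      f <- as.integer(strsplit(trimws(el[k + 1L]), "\\s+")[[1]])
      type <- f[2]; ntags <- f[3]
      if (type == 2L) {           # 3-node triangle
        tri[[length(tri) + 1L]] <- f[(4L + ntags):(6L + ntags)]
        phys <- c(phys, if (ntags >= 1L) f[4] else NA_integer_)
      } else if (type %in% c(15L, 1L, 8L, 26L, 27L)) {
        next                      # points and edge elements are ignored
      } else {
        stop("unsupported 2-D element type ", type, " (only triangles)")
      }
    }
    tris <- do.call(rbind, tri)
  } else {
    ent <- sec("Entities")
    # map (dim=2, entityTag) -> physical tag
    hdr <- as.integer(strsplit(trimws(ent[1]), "\\s+")[[1]])
    npt <- hdr[1]; ncv <- hdr[2]; nsf <- hdr[3]
    surf_phys <- integer(0)
    row <- 1L + npt + ncv
    for (k in seq_len(nsf)) {
      f <- as.numeric(strsplit(trimws(ent[row + k]), "\\s+")[[1]])
      tag <- as.integer(f[1]); nphys <- as.integer(f[8])
      surf_phys[as.character(tag)] <-
        if (nphys >= 1L) as.integer(f[9]) else NA_integer_
    }
    nd <- sec("Nodes")
    h <- as.integer(strsplit(trimws(nd[1]), "\\s+")[[1]])
    nblocks <- h[1]
    node_id <- integer(0); coords <- NULL
    row <- 1L
    for (b in seq_len(nblocks)) {
      bh <- as.integer(strsplit(trimws(nd[row + 1L]), "\\s+")[[1]])
      nb <- bh[4]
      if (nb > 0L) {
        ids <- as.integer(nd[row + 1L + seq_len(nb)])
        xyz <- read.table(text = nd[row + 1L + nb + seq_len(nb)])
        node_id <- c(node_id, ids)
        coords <- rbind(coords, as.matrix(xyz[, 1:2]))
      }
      row <- row + 1L + 2L * nb
    }
    el <- sec("Elements")
    h <- as.integer(strsplit(trimws(el[1]), "\\s+")[[1]])
    nblocks <- h[1]
    tri <- list(); phys <- integer(0)
    row <- 1L
    for (b in seq_len(nblocks)) {
      bh <- as.integer(strsplit(trimws(el[row + 1L]), "\\s+")[[1]])
      dim <- bh[1]; etag <- bh[2]; type <- bh[3]; nb <- bh[4]
      if (nb > 0L && type == 2L) {
        rows <- el[row + 1L + seq_len(nb)]
        m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.integer))
        tri[[length(tri) + 1L]] <- m[, 2:4, drop = FALSE]
        phys <- c(phys, rep(surf_phys[as.character(etag)], nb))
      } else if (nb > 0L && dim == 2L) {
        stop("unsupported 2-D element type ", type, " (only triangles)")
      }
      row <- row + 1L + nb
    }
    tris <- do.call(rbind, tri)
  }
  if (is.null(tris) || nrow(tris) == 0L) stop("no triangle elements found")

  # renumber nodes, drop dangling vertices
  remap <- match(as.vector(tris), node_id)
  if (any(is.na(remap))) stop("element references an undefined node")
  used <- sort(unique(remap))
  vertices <- coords[used, , drop = FALSE]
  tris <- matrix(match(remap, used), ncol = 3L)

  # resolve physical groups through region_map
  if (any(is.na(phys))) stop("triangle elements without a physical group tag")
  grp_names <- phys_names[as.character(phys)]
  if (any(is.na(grp_names)))
    grp_names[is.na(grp_names)] <- as.character(phys[is.na(grp_names)])
  unknown <- setdiff(unique(grp_names), names(region_map))
  if (length(unknown))
    stop("physical group(s) not in region_map: ", paste(unknown, collapse = ", "))
  target <- unname(region_map[grp_names])

  compartment <- rep("cytoplasm", nrow(tris))
  aggregate_id <- rep(NA_integer_, nrow(tris))
  bleach <- rep(FALSE, nrow(tris))
  compartment[target == "nucleus"] <- "nucleus"
  compartment[target == "bleach"] <- "nucleus"
  bleach[target == "bleach"] <- TRUE
  is_agg <- grepl("^aggregate(_[0-9]+)?$", target)
  compartment[is_agg] <- "aggregate"
  ids <- suppressWarnings(as.integer(sub("^aggregate_?", "", target[is_agg])))
  ids[is.na(ids)] <- 1L
  aggregate_id[is_agg] <- ids
  bad <- !(target %in% c("cytoplasm", "nucleus", "bleach")) & !is_agg
  if (any(bad))
    stop("region_map targets must be cytoplasm/nucleus/aggregate_<id>/bleach")

  flip_mesh(vertices, tris, compartment, aggregate_id, bleach,
            pixel_size = pixel_size)
}

#' Write a mesh as ASCII Gmsh MSH 2.2
#'
#' Physical surface groups are `cytoplasm`, `nucleus`, `aggregate_<id>` and
#' `bleach` (bleach-flagged nucleus triangles). [read_gmsh_mesh()] with the
#' matching map restores the labels exactly.
#'
#' @param mesh a [flip_mesh()].
#' @param path output path.
#' @return invisibly, the named region map usable to read the file back.
#' @export
write_gmsh_mesh <- function(mesh, path) {
  grp <- ifelse(mesh$bleach, "bleach",
                ifelse(mesh$compartment == "aggregate",
                       paste0("aggregate_", mesh$aggregate_id),
                       mesh$compartment))
  names_u <- unique(grp)
  gid <- match(grp, names_u)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  writeLines("$PhysicalNames", con)
  writeLines(as.character(length(names_u)), con)
  writeLines(sprintf("2 %d \"%s\"", seq_along(names_u), names_u), con)
  writeLines("$EndPhysicalNames", con)
  writeLines("$Nodes", con)
  writeLines(as.character(nrow(mesh$vertices)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(nrow(mesh$vertices)),
                     mesh$vertices[, 1], mesh$vertices[, 2]), con)
  writeLines("$EndNodes", con)
  writeLines("$Elements", con)
  writeLines(as.character(nrow(mesh$triangles)), con)
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(nrow(mesh$triangles)),
                     gid, gid, mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  writeLines("$EndElements", con)
  invisible(stats::setNames(names_u, names_u))
}
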