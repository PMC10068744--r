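# Vascular reconstruction and morphometry: skeletonization, radii,
# bifurcations, densities, connectivity domains, SWC export.

#' Skeletonize a binary vessel mask
#'
#' 3D topology-preserving thinning to a 1-voxel-wide medial skeleton
#' (sequential deletion of simple points in six directional sub-iterations;
#' the skeleton has exactly as many connected components as the mask).
#' Thinning necessarily rounds off tube end caps; with `extend_tips` each
#' skeleton endpoint is prolonged along its local direction to the mask
#' boundary so tube lengths are recovered, which matters for length
#' density.
#'
#' Edges connect 26-neighbouring skeleton voxels; redundant triangle
#' chords are pruned so a straight digital line has interior degree 2.
#'
#' @param mask binary volume (post-processed, lumens filled).
#' @param voxel_size_um voxel size metadata carried into the skeleton.
#' @param extend_tips prolong endpoints to the mask boundary.
#' @return An object of class `vessel_skeleton`: `nodes` data frame
#'   (`id, z, y, x` 0-based voxel coordinates, `radius_um` initially `NA`),
#'   `edges` two-column matrix of node ids, plus `shape` and
#'   `voxel_size_um`.
#' @export
skeletonize <- function(mask, voxel_size_um = c(1, 1, 1),
                        extend_tips = TRUE) {
  vs <- if (inherits(mask, "volume_stack")) mask$voxel_size_um
        else as_triple(voxel_size_um)
  m <- as_binary_array(mask)
  sk <- skeletonize3d(m)
  if (extend_tips && sum(sk) > 0) sk <- extend_skeleton_tips(sk, m)
  build_skeleton(sk, vs)
}

build_skeleton <- function(sk, vs) {
  d <- dim(sk)
  lin <- which(sk != 0L)
  n <- length(lin)
  if (n == 0) {
    return(structure(list(nodes = data.frame(id = integer(0), z = integer(0),
                                             y = integer(0), x = integer(0),
                                             radius_um = numeric(0)),
                          edges = matrix(integer(0), 0, 2), shape = d,
                          voxel_size_um = vs), class = "vessel_skeleton"))
  }
  idmap <- integer(prod(d))
  idmap[lin] <- seq_len(n)
  zi <- (lin - 1) %% d[1]
  yi <- ((lin - 1) %/% d[1]) %% d[2]
  xi <- (lin - 1) %/% (d[1] * d[2])
  em <- adjacency26(sk)
  edges <- cbind(idmap[em[, 1]], idmap[em[, 2]])
  edges <- prune_triangle_chords(edges, cbind(zi, yi, xi))
  structure(list(nodes = data.frame(id = seq_len(n), z = zi, y = yi, x = xi,
                                    radius_um = NA_real_),
                 edges = edges, shape = d, voxel_size_um = vs),
            class = "vessel_skeleton")
}

# remove 26-adjacency chords: drop edge (u,v) when a common neighbour w
# exists with both (u,w) and (w,v) strictly shorter than (u,v)
prune_triangle_chords <- function(edges, pos) {
  if (nrow(edges) == 0) return(edges)
  n <- nrow(pos)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  len2 <- function(a, b) sum((pos[a, ] - pos[b, ])^2)
  keep <- rep(TRUE, nrow(edges))
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    l <- len2(u, v)
    if (l == 1) next
    common <- intersect(adj[[u]], adj[[v]])
    for (w in common) {
      if (len2(u, w) < l && len2(w, v) < l) { keep[i] <- FALSE; break }
    }
  }
  edges[keep, , drop = FALSE]
}

# prolong skeleton endpoints along the local chain direction while the
# underlying mask continues
extend_skeleton_tips <- function(sk, m, max_steps = 64) {
  d <- dim(sk)
  em <- adjacency26(sk)
  lin <- which(sk != 0L)
  deg <- tabulate(c(match(em[, 1], lin), match(em[, 2], lin)),
                  nbins = length(lin))
  nbrs <- split(c(match(em[, 2], lin), match(em[, 1], lin)),
                c(match(em[, 1], lin), match(em[, 2], lin)))
  coords <- cbind((lin - 1) %% d[1], ((lin - 1) %/% d[1]) %% d[2],
                  (lin - 1) %/% (d[1] * d[2])) + 1L  # 1-based
  for (i in which(deg == 1)) {
    # walk back up to 3 chain steps for a stable direction estimate
    prev <- i
    cur <- i
    for (s in 1:3) {
      nb <- setdiff(nbrs[[as.character(cur)]] %||% integer(0), prev)
      nxt <- if (s == 1) nbrs[[as.character(cur)]] %||% integer(0) else nb
      nxt <- setdiff(nxt, prev)
      if (length(nxt) != 1) break
      prev <- cur
      cur <- nxt
    }
    dirv <- coords[i, ] - coords[cur, ]
    nr <- sqrt(sum(dirv^2))
    if (nr < 1e-9) next
    dirv <- dirv / nr
    last <- coords[i, ]
    for (t in seq_len(max_steps)) {
      vpos <- round(coords[i, ] + dirv * t)
      if (any(vpos < 1) || any(vpos > d)) break
      if (m[vpos[1], vpos[2], vpos[3]] == 0L) break
      if (all(vpos == last)) next
      if (sk[vpos[1], vpos[2], vpos[3]] == 1L) break
      sk[vpos[1], vpos[2], vpos[3]] <- 1L
      last <- vpos
    }
  }
  sk
}

#' @export
print.vessel_skeleton <- function(x, ...) {
  cat(sprintf("<vessel_skeleton> %d nodes, %d edges in %s volume\n",
              nrow(x$nodes), nrow(x$edges), paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Estimate per-node radii from the distance transform
#'
#' The radius at each skeleton node is the Euclidean distance from the
#' node to the nearest background voxel of the source mask, scaled to
#' micrometres by the voxel size.
#'
#' @param mask the binary mask the skeleton was derived from.
#' @param skeleton a [skeletonize()] result.
#' @param voxel_size_um voxel size (z, y, x) in micrometres; defaults to
#'   the skeleton's.
#' @return The skeleton with `nodes$radius_um` filled in.
#' @export
estimate_radii <- function(mask, skeleton, voxel_size_um = NULL) {
  m <- as_binary_array(mask)
  vs <- as_triple(voxel_size_um %||% skeleton$voxel_size_um)
  if (!identical(dim(m), skeleton$shape)) stop("mask does not match skeleton")
  nd <- skeleton$nodes
  lin <- nd$z + dim(m)[1] * (nd$y + dim(m)[2] * nd$x) + 1
  if (any(m[lin] == 0L))
    stop("skeleton node outside mask: skeleton inconsistent with this mask")
  bg <- array(as.integer(m == 0L), dim(m))
  dt <- edt_from_seeds(bg, as.numeric(vs))
  skeleton$nodes$radius_um <- dt[lin]
  skeleton
}

skeleton_graph <- function(skeleton) {
  igraph::graph_from_edgelist(
    matrix(as.character(skeleton$edges), ncol = 2), directed = FALSE) |>
    (\(g) {
      iso <- setdiff(as.character(skeleton$nodes$id),
                     igraph::V(g)$name %||% character(0))
      igraph::add_vertices(g, length(iso), name = iso)
    })()
}

#' Connectivity domains of a skeleton
#'
#' Connected components of the skeleton graph, with domain ids assigned in
#' decreasing size order (domain 1 is the largest).
#'
#' @param skeleton a [skeletonize()] result.
#' @return Integer vector of domain ids, one per node (in node order).
#' @export
connectivity_domains <- function(skeleton) {
  n <- nrow(skeleton$nodes)
  if (n == 0) return(integer(0))
  g <- skeleton_graph(skeleton)
  comp <- igraph::components(g)
  mem <- comp$membership[as.character(skeleton$nodes$id)]
  sizes <- comp$csize
  rank <- rank(-sizes, ties.method = "first")
  as.integer(rank[mem])
}

#' Vascular morphometry of a skeleton
#'
#' Total centerline length (sum of Euclidean edge lengths), length density
#' and bifurcation density over a region, per-1-um radius histogram, and
#' the number of connectivity domains.  A bifurcation is a skeleton node
#' of degree >= 3.
#'
#' @param skeleton a [skeletonize()] result (radii set for the histogram).
#' @param region_mask binary region of interest; `NULL` uses the whole
#'   volume.
#' @param voxel_size_um voxel size in micrometres; defaults to the
#'   skeleton's.
#' @return An object of class `morphometry_report`:
#'   `total_length_mm`, `length_density_mm_per_mm3`, `n_bifurcations`,
#'   `bifurcation_density_per_mm3`, `radius_histogram`,
#'   `n_connectivity_domains`, `region_volume_mm3`.
#' @export
morphometry <- function(skeleton, region_mask = NULL, voxel_size_um = NULL) {
  vs <- as_triple(voxel_size_um %||% skeleton$voxel_size_um)
  nvox <- if (is.null(region_mask)) prod(skeleton$shape)
          else sum(as_binary_array(region_mask))
  if (nvox == 0) stop("empty region: densities undefined")
  vol_mm3 <- nvox * prod(vs) / 1e9
  nd <- skeleton$nodes
  ed <- skeleton$edges
  if (nrow(nd) == 0) {
    len_um <- 0; nbif <- 0L
    hist <- integer(0)
    ndom <- 0L
  } else {
    dpos <- cbind(nd$z * vs[1], nd$y * vs[2], nd$x * vs[3])
    len_um <- if (nrow(ed) == 0) 0 else
      sum(sqrt(rowSums((dpos[ed[, 1], , drop = FALSE] -
                        dpos[ed[, 2], , drop = FALSE])^2)))
    deg <- tabulate(c(ed[, 1], ed[, 2]), nbins = nrow(nd))
    nbif <- sum(deg >= 3)
    r <- nd$radius_um
    hist <- if (all(is.na(r))) integer(0) else
      tabulate(pmax(1L, floor(r) + 1L), nbins = max(floor(r) + 1L))
    ndom <- length(unique(connectivity_domains(skeleton)))
  }
  structure(list(total_length_mm = len_um / 1000,
                 length_density_mm_per_mm3 = (len_um / 1000) / vol_mm3,
                 n_bifurcations = as.integer(nbif),
                 bifurcation_density_per_mm3 = nbif / vol_mm3,
                 radius_histogram = hist,
                 n_connectivity_domains = as.integer(ndom),
                 region_volume_mm3 = vol_mm3),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf(paste0("<morphometry> length %.4f mm (%.1f mm/mm^3), ",
                     "%d bifurcations (%.1f /mm^3), %d domain(s)\n"),
              x$total_length_mm, x$length_density_mm_per_mm3,
              x$n_bifurcations, x$bifurcation_density_per_mm3,
              x$n_connectivity_domains))
  invisible(x)
}

#' Export a skeleton to SWC
#'
#' Standard 7-column SWC (`id type x y z radius parent`), type code 7
#' (custom, vessels), coordinates in micrometres with `(x, y, z)` column
#' order, one root per connectivity domain with parent -1, parents always
#' preceding children.  Vascular loops are legal in the skeleton graph but
#' not in SWC: each cycle is broken at its lowest-radius edge (maximum
#' spanning tree on the minimum endpoint radius) and the number of broken
#' edges is recorded in a header comment.
#'
#' @param skeleton a [skeletonize()] result (ideally with radii).
#' @param path output file.
#' @return Invisibly, the path.
#' @export
export_swc <- function(skeleton, path) {
  nd <- skeleton$nodes
  vs <- skeleton$voxel_size_um
  g <- skeleton_graph(skeleton)
  rad <- nd$radius_um
  rad[is.na(rad)] <- 1
  if (nrow(skeleton$edges) > 0) {
    emin <- pmin(rad[skeleton$edges[, 1]], rad[skeleton$edges[, 2]])
    g <- igraph::set_edge_attr(g, "weight", value = max(emin) + 1 - emin)
    ncomp <- igraph::components(g)$no
    n_broken <- igraph::ecount(g) - (igraph::vcount(g) - ncomp)
    g <- igraph::mst(g)  # keeps high-radius edges (low weight)
  } else n_broken <- 0
  # BFS order per component from the largest-radius node
  parent <- rep(NA_integer_, nrow(nd))
  order_out <- integer(0)
  comp <- igraph::components(g)$membership
  names(comp) <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                function(v) as.integer(igraph::as_ids(v)))
  names(adj) <- igraph::V(g)$name
  for (cid in unique(comp)) {
    members <- as.integer(names(comp)[comp == cid])
    root <- members[which.max(rad[members])]
    parent[root] <- -1L
    queue <- root
    seen <- root
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      order_out <- c(order_out, u)
      for (v in setdiff(adj[[as.character(u)]], seen)) {
        parent[v] <- u
        seen <- c(seen, v)
        queue <- c(queue, v)
      }
    }
  }
  newid <- integer(nrow(nd))
  newid[order_out] <- seq_along(order_out)
  lines <- c(sprintf("# SWC export; %d cycle edge(s) broken", n_broken),
             "# id type x y z radius parent")
  rows <- vapply(order_out, function(i) {
    par <- if (parent[i] == -1L) -1L else newid[parent[i]]
    sprintf("%d 7 %.3f %.3f %.3f %.3f %d", newid[i],
            nd$x[i] * vs[3], nd$y[i] * vs[2], nd$z[i] * vs[1],
            rad[i], par)
  }, character(1))
  writeLines(c(lines, rows), path)
  invisible(path)
}

#' Read an SWC file
#' @param path an SWC file.
#' @return Data frame with columns `id, type, x, y, z, radius, parent`.
#' @export
read_swc <- function(path) {
  df <- read.table(path, comment.char = "#",
                   col.names = c("id", "type", "x", "y", "z", "radius",
                                 "parent"))
  df
}
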