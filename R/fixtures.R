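#' Geometry configuration for the idealized biventricular mesh
#'
#' Defines a two-ellipsoid biventricular wall: the LV is an ellipsoidal shell
#' (outer semi-axes `lv_axes`, inner shell scaled by `lv_inner_scale`), the RV
#' a thinner shell shifted toward +x that wraps the LV septal side. Nodes are
#' sampled on a regular lattice of spacing chosen to approximate
#' `target_nodes`; the lattice spacing also sets the finite-difference
#' stencil of the conduction operator.
#'
#' @param lv_axes outer LV semi-axes (cm), length 3
#' @param lv_inner_scale inner/outer scale of the LV shell (sets wall
#'   thickness)
#' @param rv_axes outer RV semi-axes (cm)
#' @param rv_inner_scale inner/outer scale of the RV shell
#' @param rv_offset centre of the RV ellipsoid (cm)
#' @param base_frac basal cut plane at `base_frac * lv_axes[3]`
#' @param layer_fractions transmural fractions (endo, mid, epi); must sum
#'   to 1
#' @param target_nodes approximate number of lattice nodes
#' @param jitter_frac coordinate jitter as a fraction of lattice spacing
#'   (cosmetic; connectivity and the conduction stencil stay on the lattice)
#' @param seed integer seed fixing all stochastic choices
#' @return a list of class `geometry_config`
#' @export
geometry_config <- function(lv_axes = c(2.0, 2.0, 2.6),
                            lv_inner_scale = 0.62,
                            rv_axes = c(2.1, 2.0, 2.3),
                            rv_inner_scale = 0.82,
                            rv_offset = c(1.0, 0, -0.1),
                            base_frac = 0.4,
                            layer_fractions = c(1, 1, 1) / 3,
                            target_nodes = 3000,
                            jitter_frac = 0.02,
                            seed = 1L) {
  stopifnot(length(lv_axes) == 3, all(lv_axes > 0),
            length(rv_axes) == 3, all(rv_axes > 0),
            lv_inner_scale > 0, lv_inner_scale < 1,
            rv_inner_scale > 0, rv_inner_scale < 1,
            length(layer_fractions) == 3, all(layer_fractions > 0),
            target_nodes >= 100, jitter_frac >= 0)
  if (abs(sum(layer_fractions) - 1) > 1e-8) {
    stop("layer_fractions must sum to 1")
  }
  structure(list(lv_axes = lv_axes, lv_inner_scale = lv_inner_scale,
                 rv_axes = rv_axes, rv_inner_scale = rv_inner_scale,
                 rv_offset = rv_offset, base_frac = base_frac,
                 layer_fractions = layer_fractions,
                 target_nodes = target_nodes, jitter_frac = jitter_frac,
                 seed = as.integer(seed)),
            class = "geometry_config")
}

# deterministic uniform deviates from a 32-bit xorshift stream; avoids
# touching the global RNG state
local_runif <- function(n, seed) {
  s <- as.integer(seed)
  if (s == 0L) s <- 2463534242
  out <- numeric(n)
  x <- bitwAnd(abs(s), 2147483647L)
  for (i in seq_len(n)) {
    x <- bitwXor(x, bitwAnd(bitwShiftL(x, 13L), 2147483647L))
    x <- bitwXor(x, bitwShiftR(x, 17L))
    x <- bitwXor(x, bitwAnd(bitwShiftL(x, 5L), 2147483647L))
    out[i] <- x / 2147483647
  }
  out
}

ellipsoid_radius <- function(p, centre, axes) {
  sqrt(((p[, 1] - centre[1]) / axes[1])^2 +
       ((p[, 2] - centre[2]) / axes[2])^2 +
       ((p[, 3] - centre[3]) / axes[3])^2)
}

#' Generate the idealized biventricular wall mesh
#'
#' Lattice-sampled two-chamber wall with transmural endo/mid/epi layers,
#' wall/septum region labels and apex/mid/base levels. Deterministic for a
#' given configuration.
#'
#' @param config a [geometry_config()]
#' @return a list of class `tissue_mesh` with node coordinates, lattice
#'   spacing `h`, per-node `cell_type`, `region`, `level`, `ventricle`,
#'   transmural `depth`, and the lattice edge list used by the conduction
#'   operator
#' @export
make_biventricular_mesh <- function(config = geometry_config()) {
  stopifnot(inherits(config, "geometry_config"))
  cfg <- config
  lv_in <- cfg$lv_axes * cfg$lv_inner_scale
  rv_in <- cfg$rv_axes * cfg$rv_inner_scale
  if (any(lv_in >= cfg$lv_axes) || any(rv_in >= cfg$rv_axes)) {
    stop("infeasible wall thickness: inner shell not inside outer")
  }
  z_base <- cfg$base_frac * cfg$lv_axes[3]

  build <- function(h) {
    xr <- seq(-cfg$lv_axes[1] - h, cfg$rv_offset[1] + cfg$rv_axes[1] + h,
              by = h)
    yr <- seq(-max(cfg$lv_axes[2], cfg$rv_axes[2]) - h,
              max(cfg$lv_axes[2], cfg$rv_axes[2]) + h, by = h)
    zr <- seq(-max(cfg$lv_axes[3], cfg$rv_axes[3] + abs(cfg$rv_offset[3])) - h,
              z_base, by = h)
    g <- expand.grid(x = xr, y = yr, z = zr, KEEP.OUT.ATTRS = FALSE)
    p <- as.matrix(g)
    r_lv <- ellipsoid_radius(p, c(0, 0, 0), cfg$lv_axes)
    r_lv_in <- ellipsoid_radius(p, c(0, 0, 0), lv_in)
    r_rv <- ellipsoid_radius(p, cfg$rv_offset, cfg$rv_axes)
    r_rv_in <- ellipsoid_radius(p, cfg$rv_offset, rv_in)
    in_lv_wall <- r_lv <= 1 & r_lv_in >= 1
    in_rv_wall <- r_rv <= 1 & r_rv_in >= 1 & r_lv > 1
    keep <- in_lv_wall | in_rv_wall
    list(p = p, keep = keep, in_lv = in_lv_wall, r_lv = r_lv, r_rv = r_rv,
         xr = xr, yr = yr, zr = zr, g = g)
  }

  # pick lattice spacing to approximate the target node count
  h <- 0.3
  for (it in 1:4) {
    b <- build(h)
    n <- sum(b$keep)
    if (abs(n - cfg$target_nodes) / cfg$target_nodes < 0.05) break
    h <- h * (n / cfg$target_nodes)^(1 / 3)
  }
  b <- build(h)
  keep <- which(b$keep)
  p <- b$p[keep, , drop = FALSE]
  n <- nrow(p)
  in_lv <- b$in_lv[keep]

  # transmural depth: 0 at epicardium, 1 at endocardium
  lam_lv <- ellipsoid_radius(p, c(0, 0, 0), cfg$lv_axes)
  lam_rv <- ellipsoid_radius(p, cfg$rv_offset, cfg$rv_axes)
  depth <- ifelse(in_lv,
                  (1 - lam_lv) / (1 - cfg$lv_inner_scale),
                  (1 - lam_rv) / (1 - cfg$rv_inner_scale))
  depth <- pmin(1, pmax(0, depth))

  # layer labels by wall-volume (node-count) fractions: epi outermost
  fr <- cfg$layer_fractions  # (endo, mid, epi)
  rk <- rank(depth, ties.method = "first") / n
  cell_type <- ifelse(rk <= fr[3], "epi",
                      ifelse(rk <= fr[3] + fr[2], "mid", "endo"))

  # regions: septum = LV wall adjacent to the RV ellipsoid
  near_rv <- ellipsoid_radius(p, cfg$rv_offset, cfg$rv_axes * 1.12) <= 1
  region <- ifelse(!in_lv, "rv_free_wall",
                   ifelse(near_rv & p[, 1] > 0, "septum", "lv_free_wall"))

  zmin <- min(p[, 3]); zmax <- max(p[, 3])
  zq <- (p[, 3] - zmin) / (zmax - zmin)
  level <- ifelse(zq < 0.25, "apex", ifelse(zq > 0.75, "base", "mid"))

  # lattice adjacency from integer indices
  ix <- round((p[, 1] - min(b$xr)) / h)
  iy <- round((p[, 2] - min(b$yr)) / h)
  iz <- round((p[, 3] - min(b$zr)) / h)
  key <- ix + 4096 * (iy + 4096 * iz)
  idx <- seq_len(n)
  lookup <- new.env(hash = TRUE, size = n)
  for (i in idx) assign(as.character(key[i]), i, envir = lookup)
  edge_from <- integer(0); edge_to <- integer(0); edge_axis <- integer(0)
  offs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (a in 1:3) {
    o <- offs[[a]]
    nkey <- (ix + o[1]) + 4096 * ((iy + o[2]) + 4096 * (iz + o[3]))
    nb <- vapply(as.character(nkey), function(k) {
      v <- get0(k, envir = lookup, ifnotfound = NA_integer_)
      if (is.null(v)) NA_integer_ else v
    }, integer(1), USE.NAMES = FALSE)
    has <- !is.na(nb)
    edge_from <- c(edge_from, idx[has])
    edge_to <- c(edge_to, nb[has])
    edge_axis <- c(edge_axis, rep.int(a, sum(has)))
  }

  # enforce transmural ordering across lattice edges: no endocardial node
  # may neighbour an epicardial one (thin-wall spots are relabelled mid)
  lev <- c(endo = 3L, mid = 2L, epi = 1L)
  repeat {
    li <- lev[cell_type[edge_from]]; lj <- lev[cell_type[edge_to]]
    bad <- which(abs(li - lj) > 1L)
    if (!length(bad)) break
    # relabel the epicardial-side endpoint, preserving endocardium for
    # Purkinje terminal placement
    fix <- ifelse(li[bad] > lj[bad], edge_to[bad], edge_from[bad])
    cell_type[unique(fix)] <- "mid"
  }
  # restore the layer balance the relabelling disturbed: promote the most
  # epicardial mid nodes (those without endocardial neighbours) back to epi
  deficit <- round(fr[3] * n) - sum(cell_type == "epi")
  if (deficit > 0) {
    has_endo_nb <- rep(FALSE, n)
    ef2 <- c(edge_from, edge_to); et2 <- c(edge_to, edge_from)
    has_endo_nb[unique(ef2[cell_type[et2] == "endo"])] <- TRUE
    cand <- which(cell_type == "mid" & !has_endo_nb)
    cand <- cand[order(depth[cand])]
    cell_type[cand[seq_len(min(deficit, length(cand)))]] <- "epi"
  }

  # cosmetic jitter (does not affect connectivity or the operator)
  if (cfg$jitter_frac > 0) {
    u <- matrix(local_runif(3 * n, cfg$seed), ncol = 3)
    coords <- p + (u - 0.5) * 2 * cfg$jitter_frac * h
  } else {
    coords <- p
  }

  mesh <- structure(list(
    coords = coords, lattice = p, h = h, n = n,
    cell_type = factor(cell_type, levels = c("endo", "mid", "epi")),
    region = factor(region,
                    levels = c("lv_free_wall", "septum", "rv_free_wall")),
    level = factor(level, levels = c("apex", "mid", "base")),
    ventricle = factor(ifelse(in_lv, "lv", "rv"), levels = c("lv", "rv")),
    depth = depth,
    edges = data.frame(from = edge_from, to = edge_to, axis = edge_axis),
    config = cfg), class = "tissue_mesh")
  mesh_validate(mesh)
  mesh
}

#' Validate a tissue mesh
#'
#' Checks the structural invariants: consistent edge connectivity, all labels
#' assigned, positive spacing.
#'
#' @param mesh a `tissue_mesh`
#' @return invisibly `TRUE`; stops on violation
#' @export
mesh_validate <- function(mesh) {
  stopifnot(inherits(mesh, "tissue_mesh"))
  n <- mesh$n
  if (nrow(mesh$coords) != n) stop("coordinate count mismatch")
  if (any(is.na(mesh$cell_type)) || any(is.na(mesh$region)) ||
      any(is.na(mesh$ventricle))) {
    stop("unassigned node labels")
  }
  e <- mesh$edges
  if (nrow(e) > 0 &&
      (min(e$from, e$to) < 1 || max(e$from, e$to) > n)) {
    stop("edge endpoints outside node range")
  }
  if (!(mesh$h > 0)) stop("non-positive lattice spacing")
  invisible(TRUE)
}

#' Purkinje network configuration
#'
#' @param n_terminals_left,n_terminals_right number of Purkinje-myocardial
#'   junctions per bundle
#' @param cv conduction velocity along the network (cm/s); the default is in
#'   the physiological His-Purkinje range (about 3 m/s), an order faster
#'   than working myocardium
#' @param seed seed for terminal placement
#' @return list of class `purkinje_config`
#' @export
purkinje_config <- function(n_terminals_left = 16, n_terminals_right = 12,
                            cv = 300, seed = 1L) {
  stopifnot(n_terminals_left >= 1, n_terminals_right >= 1, cv > 0)
  structure(list(n_terminals_left = n_terminals_left,
                 n_terminals_right = n_terminals_right,
                 cv = cv, seed = as.integer(seed)),
            class = "purkinje_config")
}

#' Construct a Purkinje tree object
#'
#' Low-level constructor with invariant checks: single root, rooted-tree
#' topology (each non-root node has exactly one parent), positive edge
#' lengths, one tissue binding per terminal.
#'
#' @param nodes numeric matrix of node coordinates (cm)
#' @param edges data.frame with columns `from`, `to`, `length`
#' @param root index of the His-like root node
#' @param terminals data.frame with columns `node` (tree node) and
#'   `tissue_node` (bound mesh node index)
#' @param branch character vector per tree node, `"left"`/`"right"` (root may
#'   be `"his"`)
#' @param cv conduction velocity (cm/s)
#' @return list of class `purkinje_tree`
#' @export
purkinje_tree <- function(nodes, edges, root, terminals, branch, cv = 60) {
  nodes <- as.matrix(nodes)
  n <- nrow(nodes)
  stopifnot(ncol(nodes) == 3, nrow(edges) == n - 1,
            all(edges$length > 0), cv > 0,
            length(branch) == n, root >= 1, root <= n)
  parent_count <- tabulate(edges$to, nbins = n)
  if (parent_count[root] != 0 || any(parent_count[-root] != 1)) {
    stop("edges do not form a tree rooted at the root node")
  }
  if (anyDuplicated(terminals$node)) {
    stop("a terminal may be bound to only one tissue node")
  }
  structure(list(nodes = nodes, edges = edges, root = root,
                 terminals = terminals, branch = branch, cv = cv),
            class = "purkinje_tree")
}

# farthest-point subsample of rows of a coordinate matrix (deterministic)
farthest_points <- function(coords, k, seed) {
  n <- nrow(coords)
  if (k >= n) return(seq_len(n))
  first <- 1L + as.integer(floor(local_runif(1, seed) * n)) %% n
  sel <- integer(k)
  sel[1] <- first
  d2 <- rowSums((coords - matrix(coords[first, ], n, 3, byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    nxt <- which.max(d2)
    sel[i + 1] <- nxt
    d2 <- pmin(d2, rowSums((coords -
                              matrix(coords[nxt, ], n, 3, byrow = TRUE))^2))
  }
  sel
}

#' Build left/right Purkinje trees on a biventricular mesh
#'
#' Terminals are placed on endocardial nodes of each ventricle by
#' farthest-point sampling; each bundle grows from a sub-endocardial anchor
#' by greedy nearest insertion, giving finite positive root-to-terminal path
#' lengths. The root (His-like node) sits at the basal septum.
#'
#' @param mesh a `tissue_mesh` with endocardial nodes in both ventricles
#' @param config a [purkinje_config()]
#' @return a `purkinje_tree`
#' @export
make_purkinje_tree <- function(mesh, config = purkinje_config()) {
  stopifnot(inherits(mesh, "tissue_mesh"), inherits(config, "purkinje_config"))
  endo <- mesh$cell_type == "endo"
  lv_endo <- which(endo & mesh$ventricle == "lv")
  rv_endo <- which(endo & mesh$ventricle == "rv")
  if (length(lv_endo) == 0 || length(rv_endo) == 0) {
    stop("mesh lacks endocardial nodes in one ventricle")
  }
  co <- mesh$lattice

  sept <- which(mesh$region == "septum" & endo)
  if (length(sept) == 0) sept <- lv_endo
  root_node <- sept[which.max(co[sept, 3])]
  root_xyz <- co[root_node, ]

  # grow a bundle as a shortest-path tree: each terminal attaches to the
  # existing node minimizing (root path length + attachment distance), which
  # keeps conduction paths close to geodesic while staying a tree
  grow_branch <- function(cand, k, seed, label, start_offset) {
    term_idx <- cand[farthest_points(co[cand, , drop = FALSE], k, seed)]
    anchor <- colMeans(co[cand, , drop = FALSE])
    anchor[3] <- anchor[3] + start_offset
    pts <- rbind(anchor, co[term_idx, , drop = FALSE])
    m <- nrow(pts)
    in_tree <- c(TRUE, rep(FALSE, m - 1))
    rootlen <- c(0, rep(NA_real_, m - 1))
    from <- integer(0); to <- integer(0); len <- numeric(0)
    for (step in seq_len(m - 1)) {
      best <- Inf; bi <- NA; bj <- NA; blen <- NA
      tre <- which(in_tree)
      for (j in which(!in_tree)) {
        dd <- sqrt(colSums((t(pts[tre, , drop = FALSE]) - pts[j, ])^2))
        cost <- rootlen[tre] + dd
        wmin <- which.min(cost)
        if (cost[wmin] < best) {
          best <- cost[wmin]; bj <- j; bi <- tre[wmin]; blen <- dd[wmin]
        }
      }
      from <- c(from, bi); to <- c(to, bj)
      len <- c(len, max(blen, 1e-6))
      rootlen[bj] <- rootlen[bi] + blen
      in_tree[bj] <- TRUE
    }
    list(pts = pts, from = from, to = to, len = len,
         terminals = term_idx, label = label)
  }

  lb <- grow_branch(lv_endo, config$n_terminals_left, config$seed,
                    "left", 0.3)
  rb <- grow_branch(rv_endo, config$n_terminals_right, config$seed + 1L,
                    "right", 0.3)

  # assemble: node 1 = root, then left branch nodes, then right branch nodes
  n_l <- nrow(lb$pts); n_r <- nrow(rb$pts)
  nodes <- rbind(root_xyz, lb$pts, rb$pts)
  off_l <- 1L; off_r <- 1L + n_l
  d_root_l <- sqrt(sum((root_xyz - lb$pts[1, ])^2))
  d_root_r <- sqrt(sum((root_xyz - rb$pts[1, ])^2))
  edges <- data.frame(
    from = c(1L, 1L, lb$from + off_l, rb$from + off_r),
    to = c(off_l + 1L, off_r + 1L, lb$to + off_l, rb$to + off_r),
    length = c(max(d_root_l, 1e-6), max(d_root_r, 1e-6), lb$len, rb$len))
  branch <- c("his", rep("left", n_l), rep("right", n_r))
  terminals <- data.frame(
    node = c(seq_len(config$n_terminals_left) + 1L + off_l,
             seq_len(config$n_terminals_right) + 1L + off_r),
    tissue_node = c(lb$terminals, rb$terminals))
  purkinje_tree(nodes, edges, root = 1L, terminals = terminals,
                branch = branch, cv = config$cv)
}

#' One-dimensional calibration cable
#'
#' Uniform 1-D strand of endocardial-type cells used for conduction-velocity
#' calibration and planar-wave tests.
#'
#' @param length cable length (cm)
#' @param n_nodes number of nodes (>= 3)
#' @return a `tissue_mesh` with a single x-axis
#' @export
make_cable <- function(length = 2, n_nodes = 201) {
  stopifnot(length > 0, n_nodes >= 3)
  h <- length / (n_nodes - 1)
  x <- seq(0, length, length.out = n_nodes)
  coords <- cbind(x = x, y = 0, z = 0)
  structure(list(
    coords = coords, lattice = coords, h = h, n = n_nodes,
    cell_type = factor(rep("endo", n_nodes), levels = c("endo", "mid", "epi")),
    region = factor(rep("lv_free_wall", n_nodes),
                    levels = c("lv_free_wall", "septum", "rv_free_wall")),
    level = factor(rep("mid", n_nodes), levels = c("apex", "mid", "base")),
    ventricle = factor(rep("lv", n_nodes), levels = c("lv", "rv")),
    depth = rep(1, n_nodes),
    edges = data.frame(from = seq_len(n_nodes - 1),
                       to = seq_len(n_nodes - 1) + 1L,
                       axis = 1L),
    config = NULL), class = "tissue_mesh")
}

#' Idealized calcium transient
#'
#' Smooth single-peak transient (half-cosine rise, exponential decay)
#' repeating at the basic cycle length; used to drive the myofilament model
#' stand-alone.
#'
#' @param peak,diastolic peak and resting free calcium (uM); `peak >
#'   diastolic > 0`
#' @param time_to_peak rise time (ms)
#' @param tau_decay decay constant (ms)
#' @param bcl cycle length (ms)
#' @param dt sampling step of the returned table (ms)
#' @return data.frame with columns `time` (ms) and `ca` (uM) over one cycle
#' @export
make_ca_transient <- function(peak = 1.45, diastolic = 0.09,
                              time_to_peak = 30, tau_decay = 100,
                              bcl = 600, dt = 1) {
  stopifnot(peak >= diastolic, diastolic > 0, time_to_peak > 0,
            tau_decay > 0, bcl > time_to_peak)
  t <- seq(0, bcl, by = dt)
  ca <- ifelse(t <= time_to_peak,
               diastolic + (peak - diastolic) *
                 0.5 * (1 - cos(pi * t / time_to_peak)),
               diastolic + (peak - diastolic) *
                 exp(-(t - time_to_peak) / tau_decay))
  data.frame(time = t, ca = ca)
}
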