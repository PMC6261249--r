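#' Write a tissue mesh to a legacy VTK file
#'
#' ASCII legacy VTK (PolyData with vertices and the lattice edges as lines),
#' with cell type, region, level, ventricle, transmural depth and any extra
#' per-node fields (such as an EAT map) as point data.
#'
#' @param mesh a `tissue_mesh`
#' @param path output file path
#' @param point_data optional named list of numeric per-node vectors
#' @return invisibly `path`
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list()) {
  mesh_validate(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  n <- mesh$n
  writeLines(c("# vtk DataFile Version 3.0",
               "cardioem tissue mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  write(t(mesh$coords), con, ncolumns = 3)
  e <- mesh$edges
  writeLines(sprintf("LINES %d %d", nrow(e), 3 * nrow(e)), con)
  write(t(cbind(2L, e$from - 1L, e$to - 1L)), con, ncolumns = 3)
  fields <- c(list(cell_type = as.integer(mesh$cell_type),
                   region = as.integer(mesh$region),
                   level = as.integer(mesh$level),
                   ventricle = as.integer(mesh$ventricle),
                   depth = mesh$depth), point_data)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm),
                 "LOOKUP_TABLE default"), con)
    v <- as.numeric(fields[[nm]])
    v[is.na(v)] <- -1
    write(v, con, ncolumns = 9)
  }
  invisible(path)
}

#' Read a legacy VTK mesh written by [write_vtk_mesh()]
#'
#' @param path file path
#' @return list with `coords`, `edges` and `point_data`
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  n <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  num <- function(from, count) {
    vals <- numeric(0)
    i <- from
    while (length(vals) < count) {
      vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      i <- i + 1
    }
    list(vals = vals[seq_len(count)], nxt = i)
  }
  pts <- num(ip + 1, 3 * n)
  coords <- matrix(pts$vals, ncol = 3, byrow = TRUE)
  il <- grep("^LINES", lines)[1]
  ne <- as.integer(strsplit(lines[il], " ")[[1]][2])
  ev <- num(il + 1, 3 * ne)$vals
  em <- matrix(ev, ncol = 3, byrow = TRUE)
  edges <- data.frame(from = em[, 2] + 1L, to = em[, 3] + 1L)
  point_data <- list()
  isc <- grep("^SCALARS", lines)
  for (i in isc) {
    nm <- strsplit(lines[i], " ")[[1]][2]
    point_data[[nm]] <- num(i + 2, n)$vals
  }
  list(coords = coords, edges = edges, point_data = point_data)
}

#' Write a Purkinje tree as edge-list tables
#'
#' Two CSV files: `<stem>_edges.csv` (from, to, length, with node
#' coordinates and branch labels) and `<stem>_terminals.csv` (terminal to
#' tissue-node bindings).
#'
#' @param tree a [purkinje_tree()]
#' @param stem output path stem
#' @return invisibly the two file paths
#' @export
write_purkinje_tables <- function(tree, stem) {
  e <- tree$edges
  nodes <- data.frame(node = seq_len(nrow(tree$nodes)),
                      x = tree$nodes[, 1], y = tree$nodes[, 2],
                      z = tree$nodes[, 3], branch = tree$branch)
  ef <- paste0(stem, "_edges.csv")
  tf <- paste0(stem, "_terminals.csv")
  write.csv(merge(e, nodes, by.x = "to", by.y = "node"), ef,
            row.names = FALSE)
  write.csv(tree$terminals, tf, row.names = FALSE)
  invisible(c(ef, tf))
}

#' Write an activation-time map as a flat table
#'
#' @param eat data.frame `node`, `eat` (ms)
#' @param path output CSV path
#' @return invisibly `path`
#' @export
write_eat_table <- function(eat, path) {
  write.csv(eat, path, row.names = FALSE)
  invisible(path)
}

#' Save a parameter set to a YAML configuration file
#'
#' @param params a named parameter vector or list (cell, myofilament or
#'   circulation parameters)
#' @param path output path
#' @return invisibly `path`
#' @export
save_config <- function(params, path) {
  yaml::write_yaml(as.list(unclass(params)), path)
  invisible(path)
}

#' Load a parameter set from a YAML configuration file
#'
#' @param path YAML file
#' @param constructor one of [cell_params()], [myofilament_params()],
#'   [circulation_params()]; the file's entries are applied as overrides
#' @param ... passed to the constructor
#' @return the constructed parameter object
#' @export
load_config <- function(path, constructor = cell_params, ...) {
  vals <- yaml::read_yaml(path)
  constructor(overrides = vals, ...)
}
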