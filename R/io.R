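## Field output (XML VTK unstructured grids), Gmsh MSH import/export, and
## case configuration files (YAML, with JSON accepted).

.vtk_cell_type <- c(quad4 = 9L, hex8 = 12L, tri3 = 5L, tet4 = 10L, line2 = 3L)

#' Write meshes and nodal fields to a VTU file
#'
#' ASCII XML VTK UnstructuredGrid; each mesh becomes one Piece (fluid and
#' solid are written as separate pieces). Fields are named nodal vectors or
#' matrices sized to the mesh's nodes.
#'
#' @param meshes one mesh or a list of meshes.
#' @param fields for each mesh, a named list of nodal fields (or NULL).
#' @param path output file.
#' @export
write_vtu <- function(meshes, fields = NULL, path) {
  if (inherits(meshes, "ifsi_mesh")) {
    meshes <- list(meshes)
    if (!is.null(fields) && !is.null(names(fields))) fields <- list(fields)
  }
  if (is.null(fields)) fields <- vector("list", length(meshes))
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                           collapse = " ")
  cat('<?xml version="1.0"?>\n',
      '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
      '<UnstructuredGrid>\n', sep = "", file = con)
  for (im in seq_along(meshes)) {
    m <- meshes[[im]]
    fl <- fields[[im]]
    pts <- m$nodes
    if (ncol(pts) == 2L) pts <- cbind(pts, 0)
    nen <- ncol(m$elem)
    nel <- nrow(m$elem)
    cat(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">\n',
                nrow(pts), nel), file = con)
    cat('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
        file = con)
    cat(num(t(pts)), "\n</DataArray></Points>\n", file = con)
    cat('<Cells><DataArray type="Int32" Name="connectivity" format="ascii">\n',
        file = con)
    cat(paste(t(m$elem) - 1L, collapse = " "), file = con)
    cat('\n</DataArray><DataArray type="Int32" Name="offsets" format="ascii">\n',
        file = con)
    cat(paste(seq_len(nel) * nen, collapse = " "), file = con)
    cat('\n</DataArray><DataArray type="UInt8" Name="types" format="ascii">\n',
        file = con)
    cat(paste(rep(.vtk_cell_type[[m$elem_type]], nel), collapse = " "),
        file = con)
    cat('\n</DataArray></Cells>\n', file = con)
    if (length(fl)) {
      cat('<PointData>\n', file = con)
      for (nm in names(fl)) {
        f <- fl[[nm]]
        nc <- if (is.null(dim(f))) 1L else ncol(f)
        if (nc == 2L) { f <- cbind(f, 0); nc <- 3L }
        cat(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n',
                    nm, nc), file = con)
        cat(num(if (is.null(dim(f))) f else t(f)), "\n</DataArray>\n", file = con)
      }
      cat('</PointData>\n', file = con)
    }
    cat('</Piece>\n', file = con)
  }
  cat('</UnstructuredGrid>\n</VTKFile>\n', file = con)
  invisible(path)
}

#' Read a VTU file written by \code{\link{write_vtu}}
#'
#' @return a list of meshes (with a \code{point_data} attribute per piece).
#' @export
read_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  pieces <- xml2::xml_find_all(doc, ".//Piece")
  lapply(pieces, function(p) {
    getarr <- function(xp) {
      nd <- xml2::xml_find_first(p, xp)
      scan(text = xml2::xml_text(nd), quiet = TRUE)
    }
    pts <- matrix(getarr(".//Points/DataArray"), ncol = 3, byrow = TRUE)
    conn <- getarr(".//Cells/DataArray[@Name='connectivity']") + 1L
    types <- getarr(".//Cells/DataArray[@Name='types']")
    tlab <- names(.vtk_cell_type)[match(types[1], .vtk_cell_type)]
    info <- .ifsi_elem_info[[tlab]]
    elem <- matrix(as.integer(conn), ncol = info$nen, byrow = TRUE)
    dim <- info$dim
    nodes <- pts[, seq_len(dim), drop = FALSE]
    m <- new_mesh(dim, nodes, elem, tlab,
                  list(facets = matrix(0L, 0, info$nfn), tag = integer(0),
                       tag_names = integer(0)))
    pd <- xml2::xml_find_all(p, ".//PointData/DataArray")
    if (length(pd)) {
      flds <- lapply(pd, function(a) {
        nc <- as.integer(xml2::xml_attr(a, "NumberOfComponents"))
        v <- scan(text = xml2::xml_text(a), quiet = TRUE)
        if (nc > 1L) matrix(v, ncol = nc, byrow = TRUE) else v
      })
      names(flds) <- vapply(pd, function(a) xml2::xml_attr(a, "Name"), "")
      attr(m, "point_data") <- flds
    }
    m
  })
}

## ---- Gmsh MSH ------------------------------------------------------------

.gmsh_types <- c("1" = "line2", "2" = "tri3", "3" = "quad4", "4" = "tet4",
                 "5" = "hex8")

#' Read a Gmsh MSH file (v2.2 or v4.1, ASCII)
#'
#' Volume (or surface, in 2D) cells of a single supported type become the
#' elements; cells one dimension lower become tagged boundary facets
#' (physical tag in v2.2, entity tag in v4.1). Unsupported cell types are
#' rejected with a named error.
#' @export
read_gmsh <- function(path) {
  if (!file.exists(path)) stop("missing mesh file: ", path)
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1))
      stop(sprintf("malformed MSH file: missing $%s section", name))
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- scan(text = sec("MeshFormat")[1], quiet = TRUE)
  ver <- fmt[1]
  if (!(abs(ver - 2.2) < 1e-9 || abs(ver - 4.1) < 1e-9))
    stop("unsupported MSH version: ", ver)
  if (fmt[2] != 0) stop("binary MSH files are not supported")

  if (abs(ver - 2.2) < 1e-9) {
    nl <- sec("Nodes")
    nn <- as.integer(nl[1])
    ntab <- matrix(scan(text = paste(nl[-1], collapse = "\n"), quiet = TRUE),
                   ncol = 4, byrow = TRUE)
    ids <- as.integer(ntab[, 1])
    coords <- ntab[, 2:4, drop = FALSE]
    el <- sec("Elements")
    ne <- as.integer(el[1])
    cells <- lapply(el[-1], function(ln) scan(text = ln, quiet = TRUE))
    types <- vapply(cells, function(x) as.integer(x[2]), 0L)
    tags1 <- vapply(cells, function(x) as.integer(x[4]), 0L)
    nodes_of <- lapply(cells, function(x) as.integer(x[-(1:(3 + x[3]))]))
  } else {
    nl <- sec("Nodes")
    hdr <- scan(text = nl[1], quiet = TRUE)
    nblocks <- hdr[1]; nn <- hdr[2]
    ids <- integer(0); coords <- NULL
    i <- 2L
    for (b in seq_len(nblocks)) {
      bh <- scan(text = nl[i], quiet = TRUE)
      nb <- bh[4]
      if (nb > 0) {
        ids <- c(ids, as.integer(nl[(i + 1L):(i + nb)]))
        cb <- matrix(scan(text = paste(nl[(i + nb + 1L):(i + 2L * nb)],
                                       collapse = "\n"), quiet = TRUE),
                     ncol = 3, byrow = TRUE)
        coords <- rbind(coords, cb)
      }
      i <- i + 2L * nb + 1L
    }
    el <- sec("Elements")
    hdr <- scan(text = el[1], quiet = TRUE)
    nblocks <- hdr[1]
    types <- integer(0); tags1 <- integer(0); nodes_of <- list()
    i <- 2L
    for (b in seq_len(nblocks)) {
      bh <- scan(text = el[i], quiet = TRUE)
      etype <- as.integer(bh[3]); nb <- bh[4]; enttag <- as.integer(bh[2])
      if (nb > 0) {
        for (r in seq_len(nb)) {
          row <- scan(text = el[i + r], quiet = TRUE)
          types <- c(types, etype)
          tags1 <- c(tags1, enttag)
          nodes_of <- c(nodes_of, list(as.integer(row[-1])))
        }
      }
      i <- i + nb + 1L
    }
  }
  # renumber nodes densely
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  keep <- types != 15L            # drop point cells
  types <- types[keep]; tags1 <- tags1[keep]; nodes_of <- nodes_of[keep]
  unknown <- setdiff(unique(types), as.integer(names(.gmsh_types)))
  if (length(unknown))
    stop("unsupported-element error: MSH cell type(s) ",
         paste(unknown, collapse = ", "))
  labs <- .gmsh_types[as.character(types)]
  dims <- vapply(labs, function(l) if (l == "line2") 1L else .ifsi_elem_info[[l]]$dim, 0L)
  mdim <- max(dims)
  etypes <- unique(labs[dims == mdim])
  if (length(etypes) != 1L)
    stop("unsupported-element error: mixed element types ",
         paste(etypes, collapse = ", "))
  is3d <- any(coords[, 3] != 0) || mdim == 3L
  nodes <- coords[, seq_len(if (is3d) 3L else 2L), drop = FALSE]
  elem <- do.call(rbind, lapply(nodes_of[dims == mdim],
                                function(x) remap[x]))
  bsel <- dims == mdim - 1L
  info <- .ifsi_elem_info[[etypes]]
  facets <- if (any(bsel))
    do.call(rbind, lapply(nodes_of[bsel], function(x) remap[x]))
  else matrix(0L, 0, info$nfn)
  btag <- tags1[bsel]
  tn <- sort(unique(btag))
  tnames <- if (length(tn)) setNames(tn, paste0("physical_", tn)) else integer(0)
  new_mesh(if (is3d) 3L else 2L, nodes, elem, etypes,
           list(facets = facets, tag = btag, tag_names = tnames))
}

#' Write a mesh in Gmsh MSH v2.2 ASCII format
#' @export
write_gmsh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("$MeshFormat\n2.2 0 8\n$EndMeshFormat\n$Nodes\n", file = con)
  cat(nrow(mesh$nodes), "\n", sep = "", file = con)
  pts <- mesh$nodes
  if (ncol(pts) == 2L) pts <- cbind(pts, 0)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(pts)),
                     pts[, 1], pts[, 2], pts[, 3]), con)
  cat("$EndNodes\n$Elements\n", file = con)
  tmap <- c(quad4 = 3L, hex8 = 5L, tri3 = 2L, tet4 = 4L, line2 = 1L)
  nf <- nrow(mesh$boundary$facets)
  cat(nrow(mesh$elem) + nf, "\n", sep = "", file = con)
  ftype <- tmap[[.ifsi_elem_info[[mesh$elem_type]]$facet_type]]
  if (nf)
    writeLines(paste(seq_len(nf), ftype, 2L, mesh$boundary$tag,
                     mesh$boundary$tag,
                     apply(mesh$boundary$facets, 1, paste, collapse = " ")), con)
  writeLines(paste(nf + seq_len(nrow(mesh$elem)), tmap[[mesh$elem_type]],
                   2L, 0L, 0L,
                   apply(mesh$elem, 1, paste, collapse = " ")), con)
  cat("$EndElements\n", file = con)
  invisible(path)
}

## ---- case configuration ----------------------------------------------------

.cfg_keys <- list(
  top = c("title", "units", "fluid", "solid", "stabilization", "solver",
          "bc", "output", "t_end"),
  fluid = c("mesh", "density", "viscosity", "body_force"),
  solid = c("mesh", "material", "density", "clamped", "body_force"),
  mesh = c("generator", "msh", "extents", "counts", "origin", "width",
           "height", "nx", "ny", "R", "w", "n_circ", "n_thick", "center",
           "radius", "n_across", "nz", "a", "clamp"),
  material = c("model", "E", "nu", "C0", "kappa_s", "mu_s"),
  stabilization = c("CI", "CT", "s_max", "band_halfwidth"),
  solver = c("dt", "max_newton", "rtol", "atol", "linear_solver", "rho_inf",
             "constraint_rebuilds"),
  bc = c("velocity", "traction"),
  output = c("every", "dir", "fields"))

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key '%s' in %s", bad[1], where))
}

#' Load and validate a case configuration file
#'
#' YAML (or JSON) case description: mesh generators or MSH paths, fluid and
#' solid properties, boundary conditions, stabilization and solver settings.
#' Unknown keys are rejected (fail-fast).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("missing configuration file: ", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  .check_keys(cfg, .cfg_keys$top, "top level")
  if (is.null(cfg$fluid)) stop("configuration requires a 'fluid' section")
  .check_keys(cfg$fluid, .cfg_keys$fluid, "fluid")
  .check_keys(cfg$fluid$mesh, .cfg_keys$mesh, "fluid$mesh")
  if (!is.null(cfg$solid)) {
    .check_keys(cfg$solid, .cfg_keys$solid, "solid")
    .check_keys(cfg$solid$mesh, .cfg_keys$mesh, "solid$mesh")
    .check_keys(cfg$solid$material, .cfg_keys$material, "solid$material")
  }
  if (!is.null(cfg$stabilization))
    .check_keys(cfg$stabilization, .cfg_keys$stabilization, "stabilization")
  if (!is.null(cfg$solver)) .check_keys(cfg$solver, .cfg_keys$solver, "solver")
  if (!is.null(cfg$bc)) .check_keys(cfg$bc, .cfg_keys$bc, "bc")
  if (!is.null(cfg$output)) .check_keys(cfg$output, .cfg_keys$output, "output")
  structure(cfg, class = "ifsi_config")
}

.build_mesh_from_config <- function(mc, role) {
  if (!is.null(mc$msh)) {
    m <- read_gmsh(mc$msh)
    m$role <- role
    return(m)
  }
  gen <- mc$generator
  m <- switch(gen,
    cartesian_grid = build_cartesian_grid(mc$extents, unlist(mc$counts), role),
    annulus = build_annulus_solid(mc$R, mc$w, mc$n_circ, mc$n_thick,
                                  center = unlist(mc$center %||% c(0, 0))),
    beam = build_beam_solid(unlist(mc$origin), mc$width, mc$height, mc$nx, mc$ny),
    cylinder_tets = build_cylinder_tets(mc$radius, mc$height,
                                        n = mc$n_across %||% 8L,
                                        nz = mc$nz %||% 20L),
    sphere = build_sphere_hexes(mc$a, center = unlist(mc$center %||% c(0, 0, 0)),
                                n = mc$n_across %||% 4L),
    stop("unknown mesh generator: ", gen))
  m$role <- role
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.material_from_config <- function(mc) {
  switch(mc$model,
    neo_hookean = material_neo_hookean(mc$E, mc$nu),
    uncoupled_neo_hookean = material_uncoupled_neo_hookean(mc$C0, mc$kappa_s),
    fiber = material_fiber(mc$mu_s),
    stop("unknown material model: ", mc$model))
}

#' Build an executable case (and solver config) from a configuration
#'
#' @param cfg from \code{\link{load_config}}.
#' @return list with \code{case}, \code{cfg} (solver configuration) and
#'   \code{t_end}.
#' @export
build_case <- function(cfg) {
  fm <- .build_mesh_from_config(cfg$fluid$mesh, "fluid")
  props <- fluid_properties(cfg$fluid$density, cfg$fluid$viscosity,
                            body_force = if (!is.null(cfg$fluid$body_force))
                              unlist(cfg$fluid$body_force))
  stab <- do.call(stab_params, cfg$stabilization %||% list())
  sol <- NULL
  if (!is.null(cfg$solid)) {
    sm <- .build_mesh_from_config(cfg$solid$mesh, "solid")
    sol <- solid_state(sm, .material_from_config(cfg$solid$material),
                       rho0 = cfg$solid$density,
                       clamped = cfg$solid$clamped)
  }
  vbc <- lapply(cfg$bc$velocity %||% list(), function(e) {
    v <- e$value
    if (is.character(v) && v == "leaflet_profile")
      v <- function(t, X) leaflet_profile(t, X[, 2])
    list(tag = e$tag, comp = e$comp, value = v)
  })
  trac <- lapply(cfg$bc$traction %||% list(), function(e) {
    if (!is.null(e$pressure)) {
      pr <- e$pressure
      pfn <- if (!is.null(pr$ramp))
        function(t) ramp_pressure(t, p_max = pr$ramp$p_max,
                                  t_ramp = pr$ramp$t_ramp)
      else function(t) pr$constant
      list(tag = e$tag, value = bc_pressure(pfn))
    } else e
  })
  case <- fsi_case(fm, props, stab = stab, solid = sol, vbc = vbc,
                   traction = trac,
                   solid_body_force = if (!is.null(cfg$solid$body_force))
                     unlist(cfg$solid$body_force))
  scfg <- do.call(solver_config, cfg$solver)
  list(case = case, cfg = scfg, t_end = cfg$t_end %||% NA_real_)
}
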