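# Geometry I/O, canonical orientation and slip-stacked dimer construction.
#
# Axis convention: the molecule lies in the xy-plane with the long axis
# along x and the short axis along y.  The mobile monomer of a dimer is an
# exact translated copy of the fixed one.  All user-facing lengths are in
# Angstrom; integral routines convert to Bohr internally.

PLANARITY_TOL <- 1e-3  # Angstrom; absorbs file rounding of planar geometries

#' Construct a Molecule
#'
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param charge integer total charge.
#' @param multiplicity spin multiplicity; only 1 is supported.
#' @return a [Molecule] object.
#' @export
molecule <- function(elements, coords, charge = 0L, multiplicity = 1L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  new("Molecule", elements = as.character(elements), coords = coords,
      charge = as.integer(charge), multiplicity = as.integer(multiplicity))
}

#' @describeIn molecule number of atoms
#' @param x a Molecule.
#' @export
nAtoms <- function(x) length(x@elements)

#' @describeIn molecule element symbols
#' @export
elements <- function(x) x@elements

#' @describeIn molecule coordinate matrix (Angstrom)
#' @export
coords <- function(x) x@coords

#' Molecular formula in Hill order
#' @param mol a [Molecule].
#' @return character scalar, e.g. "C6H6".
#' @export
molecularFormula <- function(mol) {
  tab <- table(mol@elements)
  els <- names(tab)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(hill, function(e) {
    n <- tab[[e]]
    if (n == 1) e else paste0(e, n)
  }, character(1)), collapse = "")
}

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule: %s (%d atoms, charge %d)\n",
              molecularFormula(object), nAtoms(object), object@charge))
})

#' Read a molecule from an XYZ file
#'
#' Standard XYZ convention: atom-count line, comment line, then one
#' "element x y z" line per atom, coordinates in Angstrom.
#'
#' @param path file path.
#' @return a [Molecule].
#' @export
readXYZ <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("malformed atom-count line 1 in ", path, ": '", lines[1], "'")
  if (length(lines) < n + 2)
    stop("XYZ file ", path, " declares ", n, " atoms but has only ",
         max(0, length(lines) - 2), " atom lines")
  els <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- trimws(lines[i + 2])
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) < 4)
      stop("malformed coordinate line ", i + 2, " in ", path, ": '", ln, "'")
    els[i] <- parts[1]
    v <- suppressWarnings(as.numeric(parts[2:4]))
    if (anyNA(v))
      stop("malformed coordinate line ", i + 2, " in ", path, ": '", ln, "'")
    xyz[i, ] <- v
  }
  # trailing non-blank lines beyond the declared count indicate a bad header
  extra <- lines[-seq_len(min(length(lines), n + 2))]
  if (any(nzchar(trimws(extra))))
    stop("XYZ file ", path, " declares ", n,
         " atoms but contains additional atom lines")
  molecule(els, xyz)
}

#' Write a molecule to an XYZ file
#'
#' @param mol a [Molecule].
#' @param path output file path.
#' @param comment comment line content.
#' @return invisibly, the path.
#' @export
writeXYZ <- function(mol, path, comment = molecularFormula(mol)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nAtoms(mol)), con)
  writeLines(comment, con)
  for (i in seq_len(nAtoms(mol)))
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f", mol@elements[i],
                       mol@coords[i, 1], mol@coords[i, 2], mol@coords[i, 3]),
               con)
  invisible(path)
}

#' Maximum out-of-plane deviation after canonical orientation
#' @param mol a [Molecule].
#' @return numeric, Angstrom.
#' @export
planarityDeviation <- function(mol) {
  x <- sweep(mol@coords, 2, colMeans(mol@coords))
  if (nrow(x) <= 2) return(0)
  ev <- eigen(crossprod(x), symmetric = TRUE)
  max(abs(x %*% ev$vectors[, 3]))
}

#' Test planarity of a molecule
#' @param mol a [Molecule].
#' @param tol tolerance in Angstrom.
#' @return logical.
#' @export
isPlanar <- function(mol, tol = PLANARITY_TOL) planarityDeviation(mol) <= tol

#' Canonically orient a planar molecule
#'
#' Moves the centroid to the origin, puts the molecular plane into the
#' xy-plane and aligns the principal axis with the largest coordinate extent
#' with x and the second largest with y.  Ties (e.g. benzene) are broken by
#' taking the direction from the centroid to the farthest atom (lowest index
#' among equals) as x.  Signs are fixed so that the first atom with |x| (and
#' then |y|) above 1e-8 has a positive coordinate.
#'
#' @param mol a [Molecule].
#' @param tol planarity tolerance in Angstrom.
#' @return the re-oriented [Molecule].
#' @export
canonicalOrient <- function(mol, tol = PLANARITY_TOL) {
  x <- sweep(mol@coords, 2, colMeans(mol@coords))
  n <- nrow(x)
  if (n == 1) return(molecule(mol@elements, matrix(0, 1, 3), mol@charge))
  ev <- eigen(crossprod(x), symmetric = TRUE)
  axes <- ev$vectors  # columns, descending spread
  dev <- max(abs(x %*% axes[, 3]))
  if (dev > tol)
    stop(sprintf(
      "molecule is not planar: max out-of-plane deviation %.4g Angstrom (tolerance %.4g)",
      dev, tol))
  proj <- x %*% axes
  ext <- apply(proj, 2, function(v) diff(range(v)))
  ord <- order(ext, decreasing = TRUE)
  # keep the out-of-plane direction (smallest spread) as z
  ord <- c(setdiff(ord, 3L)[1:2][order(ext[setdiff(ord, 3L)[1:2]],
                                       decreasing = TRUE)], 3L)
  axes <- axes[, ord, drop = FALSE]
  # degenerate in-plane extents: x towards the farthest atom
  if (abs(ext[ord[1]] - ext[ord[2]]) < 1e-6) {
    r2 <- rowSums(x^2)
    far <- which(r2 > max(r2) - 1e-8)[1]
    v <- x[far, ]
    v <- v - sum(v * axes[, 3]) * axes[, 3]
    if (sqrt(sum(v^2)) > 1e-8) {
      vx <- v / sqrt(sum(v^2))
      vy <- c(axes[2, 3] * vx[3] - axes[3, 3] * vx[2],
              axes[3, 3] * vx[1] - axes[1, 3] * vx[3],
              axes[1, 3] * vx[2] - axes[2, 3] * vx[1])
      axes[, 1] <- vx
      axes[, 2] <- vy
    }
  }
  y <- x %*% axes
  for (d in 1:2) {
    nz <- which(abs(y[, d]) > 1e-8)
    if (length(nz) && y[nz[1], d] < 0) y[, d] <- -y[, d]
  }
  y[, 3] <- 0  # snap residual out-of-plane rounding
  y[abs(y) < 1e-12] <- 0
  molecule(mol@elements, y, mol@charge)
}

#' Translate a molecule rigidly
#' @param mol a [Molecule].
#' @param shift numeric length-3 translation (Angstrom).
#' @return translated [Molecule].
#' @export
translateMolecule <- function(mol, shift) {
  molecule(mol@elements, sweep(mol@coords, 2, -as.numeric(shift)), mol@charge)
}

#' Build a slip-stacked dimer arrangement
#'
#' The mobile monomer is the fixed monomer translated by (dx, dy, dz).
#'
#' @param mol the fixed monomer, canonically oriented in the xy-plane.
#' @param dx,dy in-plane shifts (Angstrom).
#' @param dz inter-planar distance (Angstrom), must be positive.
#' @return a [DimerArrangement].
#' @export
buildDimer <- function(mol, dx = 0, dy = 0, dz = 3.4) {
  if (dz <= 0) stop("dz must be positive (got ", dz, ")")
  new("DimerArrangement", fixed = mol, dx = as.numeric(dx),
      dy = as.numeric(dy), dz = as.numeric(dz))
}

#' Mobile monomer of an arrangement
#' @param arr a [DimerArrangement].
#' @return the translated [Molecule].
#' @export
mobileMolecule <- function(arr)
  translateMolecule(arr@fixed, c(arr@dx, arr@dy, arr@dz))

#' Shift vector of an arrangement
#' @param arr a [DimerArrangement].
#' @return numeric c(dx, dy, dz) in Angstrom.
#' @export
shifts <- function(arr) c(dx = arr@dx, dy = arr@dy, dz = arr@dz)

setMethod("show", "DimerArrangement", function(object) {
  cat(sprintf(
    "DimerArrangement: %s dimer, dx = %.3f, dy = %.3f, dz = %.3f Angstrom\n",
    molecularFormula(object@fixed), object@dx, object@dy, object@dz))
})

#' Construct a scan grid
#'
#' @param axis one of "x", "y", "x_at_fixed_y".
#' @param start,stop,step grid limits and spacing (Angstrom).
#' @param fixedDy fixed dy for axis "x_at_fixed_y" (Angstrom).
#' @param dz inter-planar distance (Angstrom).
#' @return a [ScanGrid].
#' @export
scanGrid <- function(axis = c("x", "y", "x_at_fixed_y"), start, stop,
                     step = 0.1, fixedDy = NA_real_, dz = 3.4) {
  axis <- match.arg(axis)
  new("ScanGrid", axis = axis, start = as.numeric(start),
      stop = as.numeric(stop), step = as.numeric(step),
      fixedDy = as.numeric(fixedDy), dz = as.numeric(dz))
}

#' Grid point shift values
#' @param grid a [ScanGrid].
#' @return numeric vector start + k*step covering [start, stop].
#' @export
gridShifts <- function(grid) {
  k <- floor((grid@stop - grid@start) / grid@step + 1e-9)
  grid@start + (0:k) * grid@step
}

#' Materialize a scan grid as dimer arrangements
#'
#' @param mol the fixed monomer (canonically oriented).
#' @param grid a [ScanGrid].
#' @return list of [DimerArrangement] in increasing shift order.
#' @export
makeGrid <- function(mol, grid) {
  validObject(grid)
  s <- gridShifts(grid)
  lapply(s, function(v) {
    switch(grid@axis,
      x = buildDimer(mol, dx = v, dy = 0, dz = grid@dz),
      y = buildDimer(mol, dx = 0, dy = v, dz = grid@dz),
      x_at_fixed_y = buildDimer(mol, dx = v, dy = grid@fixedDy, dz = grid@dz))
  })
}
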