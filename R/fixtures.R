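# Built-in fixture geometries.
#
# Acene fixtures use idealized planar geometries (aromatic C-C 1.40 A,
# C-H 1.09 A, 120-degree angles).  These reproduce all integer/combinatorial
# quantities exactly and overlap-feature positions approximately; for
# paper-exact numbers drop replacement XYZ files (e.g. supplementary-table
# coordinates) into the geometry directory or pass them to readXYZ().

.CC_AROMATIC <- 1.40
.CH_BOND <- 1.09

#' Idealized linear acene geometry
#'
#' Fused regular hexagons with aromatic C-C bonds of 1.40 A and C-H bonds
#' of 1.09 A, long axis along x, in the xy-plane.
#'
#' @param nRings number of fused rings (1 = benzene, 5 = pentacene).
#' @return a [Molecule] in canonical orientation.
#' @export
buildIdealAcene <- function(nRings) {
  stopifnot(nRings >= 1)
  a <- .CC_AROMATIC * sqrt(3)
  y1 <- .CC_AROMATIC / 2
  y2 <- .CC_AROMATIC
  centers <- (seq_len(nRings) - (nRings + 1) / 2) * a
  xs <- sort(unique(round(c(centers - a / 2, centers + a / 2), 8)))
  cc <- rbind(
    cbind(rep(xs, 2), rep(c(y1, -y1), each = length(xs))),
    cbind(rep(centers, 2), rep(c(y2, -y2), each = nRings)))
  hh <- rbind(
    cbind(rep(centers, 2), rep(c(y2 + .CH_BOND, -(y2 + .CH_BOND)),
                               each = nRings)))
  xe <- max(xs)
  dxh <- .CH_BOND * sqrt(3) / 2
  dyh <- .CH_BOND / 2
  ends <- rbind(c(xe + dxh, y1 + dyh), c(xe + dxh, -(y1 + dyh)),
                c(-(xe + dxh), y1 + dyh), c(-(xe + dxh), -(y1 + dyh)))
  coords <- rbind(cbind(cc, 0), cbind(rbind(hh, ends), 0))
  els <- c(rep("C", nrow(cc)), rep("H", nrow(hh) + nrow(ends)))
  canonicalOrient(molecule(els, coords))
}

.fixture_defs <- list(
  he2 = list(
    make = function() molecule("He", matrix(0, 1, 3)),
    basis = "cc-pvdz",
    notes = paste("Single He atom; build the dimer with buildDimer(mol, 0, 0, dz).",
                  "Purely sigma system; exchange repulsion decays exponentially with dz.")),
  h2_dimer = list(
    make = function() molecule(c("H", "H"),
                               matrix(c(-0.37, 0, 0, 0.37, 0, 0), 2, 3,
                                      byrow = TRUE)),
    basis = "sto-3g",
    notes = paste("H2 monomer (0.74 A bond along x).  Smallest system with a",
                  "nontrivial cross-overlap scan; all-sigma occupied space.")),
  ethylene_dimer = list(
    make = function() molecule(c("C", "C", "H", "H", "H", "H"),
                               matrix(c(-0.6665, 0, 0, 0.6665, 0, 0,
                                        -1.2115, 0.944, 0, -1.2115, -0.944, 0,
                                        1.2115, 0.944, 0, 1.2115, -0.944, 0),
                                      6, 3, byrow = TRUE)),
    basis = "sto-3g",
    notes = "Ethylene monomer; one occupied pi orbital, smallest pi-stack."),
  benzene = list(rings = 1L, basis = "jun-cc-pvdz",
                 notes = "D6h; 21 occupied (3 pi, 18 sigma); 441 dimer pairs."),
  naphthalene = list(rings = 2L, basis = "jun-cc-pvdz",
                     notes = "D2h; 34 occupied (5 pi)."),
  anthracene = list(rings = 3L, basis = "jun-cc-pvdz",
                    notes = "D2h; 47 occupied (7 pi)."),
  tetracene = list(rings = 4L, basis = "jun-cc-pvdz",
                   notes = "D2h; 60 occupied (9 pi)."),
  pentacene = list(rings = 5L, basis = "jun-cc-pvdz",
                   notes = paste("D2h; 73 occupied (11 pi: 6 S + 5 A); 5329",
                                 "dimer pairs, 121 pi-pi, 3844 sigma-sigma."))
)

#' Retrieve a built-in fixture geometry
#'
#' Fixtures are loaded from the XYZ files shipped under
#' `inst/extdata/geometries/`; replacing one of those files (for example
#' with externally optimized coordinates) changes the fixture accordingly.
#' If a file is absent the geometry is rebuilt from the idealized-geometry
#' generator.
#'
#' @param name one of "he2", "h2_dimer", "ethylene_dimer", "benzene",
#'   "naphthalene", "anthracene", "tetracene", "pentacene".
#' @return a [Fixture].
#' @export
fixture <- function(name) {
  def <- .fixture_defs[[name]]
  if (is.null(def))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_defs), collapse = ", "))
  path <- system.file("extdata", "geometries", paste0(name, ".xyz"),
                      package = "pistack")
  mol <- if (nzchar(path)) canonicalOrient(readXYZ(path))
         else if (!is.null(def$rings)) buildIdealAcene(def$rings)
         else def$make()
  new("Fixture", name = name, molecule = mol, recommendedBasis = def$basis,
      notes = def$notes)
}

#' @describeIn fixture the fixture's molecule
#' @param x a Fixture.
#' @export
fixtureMolecule <- function(x) x@molecule

setMethod("show", "Fixture", function(object) {
  cat(sprintf("Fixture '%s': %s (%d atoms), recommended basis %s\n  %s\n",
              object@name, molecularFormula(object@molecule),
              nAtoms(object@molecule), object@recommendedBasis,
              object@notes))
})
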