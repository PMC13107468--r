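# Shared, lazily computed fixtures.  Expensive SCF solutions and MOPCE
# contexts are built once per test run and reused across files.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

bohr <- 1 / 1.8897261254535

h2Molecule <- function() fixtureMolecule(fixture("h2_dimer"))
heMolecule <- function() fixtureMolecule(fixture("he2"))
ethyleneMolecule <- function() fixtureMolecule(fixture("ethylene_dimer"))

he2Context <- function(dz = 3.0, mode = "monomer")
  memo(paste0("he2ctx_", dz, "_", mode),
       mopceContext(buildDimer(heMolecule(), 0, 0, dz), "cc-pvdz",
                    mode = mode, densityFitting = FALSE))

h2DimerContext <- function(dz = 3.4, mode = "monomer")
  memo(paste0("h2ctx_", dz, "_", mode),
       mopceContext(buildDimer(h2Molecule(), 0, 0, dz), "sto-3g",
                    mode = mode, densityFitting = FALSE))

ethyleneContext <- function(dz = 3.4, dx = 0, mode = "monomer")
  memo(paste0("ethctx_", dx, "_", dz, "_", mode),
       mopceContext(buildDimer(ethyleneMolecule(), dx, 0, dz), "sto-3g",
                    mode = mode, densityFitting = FALSE))

benzeneScfSto <- function()
  memo("benzene_sto_scf",
       runRHF(fixtureMolecule(fixture("benzene")), "sto-3g",
              densityFitting = FALSE))

benzeneLabelsSto <- function()
  memo("benzene_sto_lab", fixPhases(classifyOrbitals(benzeneScfSto())))

pentaceneScfSto <- function()
  memo("pentacene_sto_scf",
       runRHF(fixtureMolecule(fixture("pentacene")), "sto-3g",
              densityFitting = FALSE))

pentaceneLabelsSto <- function()
  memo("pentacene_sto_lab", fixPhases(classifyOrbitals(pentaceneScfSto())))

pentaceneScanSto <- function()
  memo("pentacene_sto_scan",
       runScan(fixtureMolecule(fixture("pentacene")),
               scanGrid("x", 0, 14, 0.1, dz = 3.4), "s:6S,6S", "sto-3g",
               densityFitting = FALSE))

componentCols <- c("eXi", "eXr2", "eXr3", "eXr4", "eXrb", "eTotal")

# density fitting keeps these contexts fast; every identity asserted on
# them is algebraic in whichever integral set is used
benzeneContextSto <- function(dx = 1.3)
  memo(paste0("bzctx_", dx),
       mopceContext(buildDimer(fixtureMolecule(fixture("benzene")), dx, 0, 3.4),
                    "sto-3g", densityFitting = TRUE))
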