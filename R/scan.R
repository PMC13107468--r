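# Scan pipeline: drive observables over shift grids, detect curve features,
# and ingest external SAPT component tables for comparison.

#' Scan observables over a shift grid
#'
#' The monomer SCF is computed once and reused at every grid point (the
#' mobile monomer is a translated copy).  Observables:
#' \describe{
#'   \item{"s:DES1,DES2"}{cross-overlap matrix element between the
#'     orbitals with the given designations (e.g. "s:6S,6S"); orbital
#'     indices ("s:12,12") are also accepted.}
#'   \item{"s2:GROUP"}{grouped squared-overlap sum; GROUP one of "all",
#'     "pipi", "piSpiS", "piApiA", "piSpiA".}
#'   \item{"mopce:groups"}{full orbital-pair decomposition per point
#'     (expensive): columns exr, exr_pipi, exr_pisigma, exr_sigmasigma,
#'     exr_piSpiS, exr_piApiA, exr_piSpiA in kJ/mol.}
#'   \item{"mopce:pair:DES1,DES2"}{single pair total E_xr(a,b), kJ/mol.}
#'   \item{"pib:L,N"}{particle-in-a-box squared-overlap sum S^2_N at box
#'     length L (Angstrom).}
#' }
#'
#' @param mol the fixed monomer (canonically oriented).
#' @param grid a [ScanGrid].
#' @param observables character vector of observable specifications.
#' @param basis a [BasisSpec] or basis name.
#' @param mode "monomer" or "dimer_ghost".
#' @param densityFitting logical or NULL.
#' @param maxGb memory cap (GiB).
#' @return a [ScanResult]; failed grid points carry NA and are listed in
#'   the provenance.
#' @export
runScan <- function(mol, grid, observables, basis,
                    mode = c("monomer", "dimer_ghost"),
                    densityFitting = NULL, maxGb = 4) {
  mode <- match.arg(mode)
  if (!is(basis, "BasisSpec")) basis <- basisSpec(basis)
  arrs <- makeGrid(mol, grid)
  sh <- gridShifts(grid)
  needMopce <- any(grepl("^mopce:", observables))
  needOverlap <- any(grepl("^(s|s2):", observables))

  lab <- NULL
  shellsA <- NULL
  if ((needOverlap || needMopce) && mode == "monomer") {
    scfA <- runRHFCached(mol, basis, densityFitting = densityFitting,
                         maxGb = maxGb)
    lab <- fixPhases(classifyOrbitals(scfA))
    shellsA <- buildShells(mol@elements, mol@coords, basis@name)
  }

  resolveOrb <- function(des, lab) {
    t <- lab@table
    d <- .designation(t)
    i <- which(d == des)
    if (!length(i)) i <- suppressWarnings(as.integer(des))
    if (!length(i) || is.na(i[1]) || i[1] < 1 || i[1] > nrow(t))
      stop("cannot resolve orbital designation '", des, "'")
    i[1]
  }

  units <- setNames(character(0), character(0))
  failed <- integer()
  nP <- length(arrs)
  vals <- list()

  for (ob in observables) {
    nmu <- NULL
    if (grepl("^pib:", ob)) {
      pp <- as.numeric(strsplit(sub("^pib:", "", ob), ",")[[1]])
      cname <- sprintf("pib_s2_sum_L%g_N%d", pp[1], as.integer(pp[2]))
      vals[[cname]] <- pibSqSum(as.integer(pp[2]), sh / pp[1])
      units[cname] <- "dimensionless"
    }
  }

  perPoint <- setdiff(observables, observables[grepl("^pib:", observables)])
  if (length(perPoint)) {
    store <- function(cname, k, v, unit) {
      if (is.null(vals[[cname]])) {
        vals[[cname]] <<- rep(NA_real_, nP)
        units[cname] <<- unit
      }
      vals[[cname]][k] <<- v
    }
    for (k in seq_len(nP)) {
      ok <- tryCatch({
        arr <- arrs[[k]]
        if (needMopce) {
          ctx <- mopceContext(arr, basis, mode = mode,
                              densityFitting = densityFitting, maxGb = maxGb)
          Sab <- ctx@Sab
          labA <- ctx@labelsA; labB <- ctx@labelsB
        } else {
          shellsB <- .translateShells(shellsA,
                                      c(arr@dx, arr@dy, arr@dz) *
                                        BOHR_PER_ANGSTROM)
          Scross <- cpp_cross_overlap(shellsA, shellsB)
          C <- lab@coefficients
          Sab <- crossprod(C, Scross %*% C)
          labA <- labB <- lab
        }
        for (ob in perPoint) {
          if (grepl("^s:", ob)) {
            dd <- strsplit(sub("^s:", "", ob), ",")[[1]]
            i <- resolveOrb(dd[1], labA); j <- resolveOrb(dd[2], labB)
            store(paste0("s_", gsub(",", "_", sub("^s:", "", ob))), k,
                  Sab[i, j], "dimensionless")
          } else if (grepl("^s2:", ob)) {
            grp <- sub("^s2:", "", ob)
            s2 <- squaredOverlapSums(Sab, labA, labB)
            store(paste0("s2_", grp), k, s2[[grp]], "dimensionless")
          } else if (identical(ob, "mopce:groups")) {
            gt <- groupSums(pairTable(ctx), labA, labB)
            store("exr", k, gt@eTotal, "kJ/mol")
            store("exr_pipi", k, gt@ePiPi, "kJ/mol")
            store("exr_pisigma", k, gt@ePiSigma, "kJ/mol")
            store("exr_sigmasigma", k, gt@eSigmaSigma, "kJ/mol")
            store("exr_piSpiS", k, gt@ePiSPiS, "kJ/mol")
            store("exr_piApiA", k, gt@ePiAPiA, "kJ/mol")
            store("exr_piSpiA", k, gt@ePiSPiA, "kJ/mol")
          } else if (grepl("^mopce:pair:", ob)) {
            dd <- strsplit(sub("^mopce:pair:", "", ob), ",")[[1]]
            i <- resolveOrb(dd[1], labA); j <- resolveOrb(dd[2], labB)
            pc <- pairComponents(i, j, ctx)
            store(paste0("exr_", dd[1], "_", dd[2]), k,
                  pc$eTotal * KJMOL_PER_HARTREE, "kJ/mol")
          } else stop("unknown observable '", ob, "'")
        }
        TRUE
      }, error = function(e) {
        warning("scan point ", k, " (shift ", sh[k], " A) failed: ",
                conditionMessage(e))
        FALSE
      })
      if (!ok) failed <- c(failed, k)
    }
  }

  d <- data.frame(shift = sh)
  for (nm in names(vals)) d[[nm]] <- vals[[nm]]
  new("ScanResult", data = d, axis = grid@axis, units = units,
      provenance = list(basis = basis@name, mode = mode,
                        geometry = .geomKey(mol), dz = grid@dz,
                        fixedDy = grid@fixedDy, failed = failed))
}

#' @describeIn runScan scan data accessor
#' @param x a ScanResult.
#' @export
scanData <- function(x) x@data

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult: %d points on axis %s, observables: %s\n",
              nrow(object@data), object@axis,
              paste(setdiff(names(object@data), "shift"), collapse = ", ")))
  if (length(object@provenance$failed))
    cat("  failed points:", length(object@provenance$failed), "\n")
})

#' Export a scan as CSV with unit header comments
#'
#' @param x a [ScanResult].
#' @param path output path.
#' @return invisibly, the path.
#' @export
exportScan <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# shift: Angstrom",
               sprintf("# %s: %s", names(x@units), x@units)), con)
  write.csv(x@data, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect zeros and extrema of a scanned curve
#'
#' Zero crossings are located from sign changes and refined with a local
#' quadratic through the three surrounding points; extrema are located
#' from discrete differences and refined by the quadratic vertex.
#' Positions are reported to 0.01 Angstrom.
#'
#' @param scan a [ScanResult] (or data.frame with a `shift` column).
#' @param column observable column name (default: the first).
#' @return a [FeatureReport].
#' @export
findFeatures <- function(scan, column = NULL) {
  d <- if (is(scan, "ScanResult")) scan@data else scan
  if (is.null(column)) column <- setdiff(names(d), "shift")[1]
  x <- d$shift
  y <- d[[column]]
  if (is.null(y)) stop("no column '", column, "' in scan")
  keep <- is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  feats <- data.frame(observable = character(), type = character(),
                      position = numeric(), value = numeric())
  if (n >= 3) {
    quadVertex <- function(i) {
      # parabola through points i-1, i, i+1
      xs <- x[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
      co <- tryCatch(solve(cbind(1, xs, xs^2), ys), error = function(e) NULL)
      if (is.null(co) || abs(co[3]) < 1e-300) return(c(x[i], y[i]))
      xv <- -co[2] / (2 * co[3])
      if (xv < xs[1] || xv > xs[3]) return(c(x[i], y[i]))
      c(xv, co[1] + co[2] * xv + co[3] * xv^2)
    }
    quadRoot <- function(i) {
      # sign change in [x_i, x_i+1]; parabola through a bracketing triple
      j <- if (i + 2 <= n) i:(i + 2) else (i - 1):(i + 1)
      co <- tryCatch(solve(cbind(1, x[j], x[j]^2), y[j]), error = function(e) NULL)
      lin <- x[i] - y[i] * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
      if (is.null(co)) return(lin)
      if (abs(co[3]) < 1e-14) {
        if (abs(co[2]) < 1e-300) return(lin)
        r <- -co[1] / co[2]
        return(if (r >= x[i] && r <= x[i + 1]) r else lin)
      }
      disc <- co[2]^2 - 4 * co[3] * co[1]
      if (disc < 0) return(lin)
      r <- (-co[2] + c(1, -1) * sqrt(disc)) / (2 * co[3])
      r <- r[r >= x[i] - 1e-12 & r <= x[i + 1] + 1e-12]
      if (length(r)) r[1] else lin
    }
    for (i in seq_len(n - 1)) {
      if (y[i] == 0 && (i == 1 || y[max(1, i - 1)] != 0)) {
        feats <- rbind(feats, data.frame(observable = column, type = "zero",
                                         position = x[i], value = 0))
      } else if (y[i] * y[i + 1] < 0) {
        feats <- rbind(feats, data.frame(observable = column, type = "zero",
                                         position = quadRoot(i), value = 0))
      }
    }
    for (i in 2:(n - 1)) {
      if (y[i] > y[i - 1] && y[i] >= y[i + 1]) {
        v <- quadVertex(i)
        feats <- rbind(feats, data.frame(observable = column,
                                         type = "maximum", position = v[1],
                                         value = v[2]))
      } else if (y[i] < y[i - 1] && y[i] <= y[i + 1]) {
        v <- quadVertex(i)
        feats <- rbind(feats, data.frame(observable = column,
                                         type = "minimum", position = v[1],
                                         value = v[2]))
      }
    }
  }
  feats$position <- round(feats$position, 2)
  feats <- feats[order(feats$position), , drop = FALSE]
  rownames(feats) <- NULL
  new("FeatureReport", features = feats, method = "3-point quadratic")
}

#' @describeIn findFeatures feature table accessor
#' @param x a FeatureReport.
#' @export
featureTable <- function(x) x@features

#' @describeIn findFeatures positions of one feature type
#' @param type "zero", "minimum" or "maximum".
#' @export
featurePositions <- function(x, type)
  x@features$position[x@features$type == type]

setMethod("show", "FeatureReport", function(object) {
  cat(sprintf("FeatureReport (%s): %d zero(s), %d minimum(s), %d maximum(s)\n",
              object@method, sum(object@features$type == "zero"),
              sum(object@features$type == "minimum"),
              sum(object@features$type == "maximum")))
})

#' Ingest an external SAPT component-energy table
#'
#' Expects a CSV with shift columns (dx, dy) and component columns
#' (E_int, E_el, E_ind, E_dsp, E_exch, case/underscore-insensitive) in
#' kJ/mol, e.g. exported from a SAPT engine.  Each row must satisfy
#' E_int = E_el + E_ind + E_dsp + E_exch to 0.01 kJ/mol.
#'
#' @param path CSV file path.
#' @param tol additivity tolerance in kJ/mol.
#' @return a [SAPTComponents]; zero-row input gives an empty object with a
#'   warning.
#' @export
ingestSAPTTable <- function(path, tol = 0.01) {
  if (!file.exists(path)) stop("SAPT table not found: ", path)
  raw <- tryCatch(read.csv(path, strip.white = TRUE),
                  error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    warning("empty SAPT table: ", path)
    return(new("SAPTComponents",
               table = data.frame(dx = numeric(), dy = numeric(),
                                  Eint = numeric(), Eel = numeric(),
                                  Eind = numeric(), Edsp = numeric(),
                                  Eexch = numeric())))
  }
  nm <- tolower(gsub("[._]", "", names(raw)))
  pick <- function(key) {
    i <- which(nm == key)
    if (!length(i)) stop("SAPT table lacks required column '", key, "'")
    as.numeric(raw[[i[1]]])
  }
  out <- data.frame(dx = pick("dx"), dy = pick("dy"), Eint = pick("eint"),
                    Eel = pick("eel"), Eind = pick("eind"),
                    Edsp = pick("edsp"), Eexch = pick("eexch"))
  if ("system" %in% nm) out$system <- raw[[which(nm == "system")[1]]]
  resid <- abs(out$Eint - (out$Eel + out$Eind + out$Edsp + out$Eexch))
  bad <- which(resid > tol + 1e-9)  # inclusive bound, robust to rounding
  if (length(bad))
    stop("SAPT component additivity violated beyond ", tol,
         " kJ/mol in row(s) ", paste(bad, collapse = ", "),
         " (max residual ", format(max(resid), digits = 3), ")")
  new("SAPTComponents", table = out)
}

#' @describeIn ingestSAPTTable component table accessor
#' @param x a SAPTComponents object.
#' @export
saptTable <- function(x) x@table
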