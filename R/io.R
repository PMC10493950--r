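## File I/O: multi-page TIFF stacks, psi-trace and mass-series CSVs with
## JSON sidecar metadata, Newick trees, trait/climate tables.

#' Write an image stack as a multi-page 16-bit grayscale TIFF
#'
#' Frame times are stored alongside in `<path>.times.csv` (columns `frame`,
#' `time_s`), since baseline TIFF has no standard per-page timestamp.
#'
#' @param stack an [ImageStack-class] with intensities in `[0, 1]`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeImageStack <- function(stack, path) {
  f <- frames(stack)
  pages <- lapply(seq_len(dim(f)[3]), function(j)
    pmin(pmax(f[, , j], 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  write.csv(data.frame(frame = seq_len(dim(f)[3]),
                       time_s = frameTimes(stack)),
            paste0(path, ".times.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' @param path TIFF path written by [writeImageStack()]; frame times are
#'   read from `<path>.times.csv` when present, else assumed at 180 s
#'   spacing.
#' @return An [ImageStack-class].
#' @export
readImageStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                          length(pages)))
  for (j in seq_along(pages)) {
    pg <- pages[[j]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # grayscale stored per-channel
    arr[, , j] <- pg
  }
  tpath <- paste0(path, ".times.csv")
  times <- if (file.exists(tpath)) read.csv(tpath)$time_s
           else (seq_len(length(pages)) - 1) * 180
  newImageStack(arr, times)
}

#' Write / read a water-potential trace CSV
#'
#' Columns `time_s`, `psi_MPa`.
#'
#' @param trace a [PsiTrace-class].
#' @param path CSV path.
#' @return `path` invisibly (write); a [PsiTrace-class] (read).
#' @export
writePsiTrace <- function(trace, path) {
  write.csv(data.frame(time_s = trace@times, psi_MPa = trace@psi), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname writePsiTrace
#' @export
readPsiTrace <- function(path) {
  d <- read.csv(path)
  stopIfNot(all(c("time_s", "psi_MPa") %in% names(d)),
            "psi trace CSV needs columns time_s, psi_MPa")
  newPsiTrace(d$time_s, d$psi_MPa)
}

#' Write / read a drydown mass series (CSV plus JSON sidecar)
#'
#' The CSV holds `time_s`, `mass_g`; the JSON sidecar
#' (`<path>.meta.json`) holds `temperature_C`, `rh_percent`,
#' `leaf_dry_mass_g`, `sla_m2_per_kg`.
#'
#' @param series a [MassSeries-class].
#' @param path CSV path.
#' @return `path` invisibly (write); a [MassSeries-class] (read).
#' @export
writeMassSeries <- function(series, path) {
  write.csv(data.frame(time_s = series@times, mass_g = series@masses),
            path, row.names = FALSE)
  jsonlite::write_json(
    list(temperature_C = series@temperature, rh_percent = series@rh,
         leaf_dry_mass_g = series@leafDryMass,
         sla_m2_per_kg = series@sla),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMassSeries
#' @export
readMassSeries <- function(path) {
  d <- read.csv(path)
  stopIfNot(all(c("time_s", "mass_g") %in% names(d)),
            "mass series CSV needs columns time_s, mass_g")
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  newMassSeries(d$time_s, d$mass_g, meta$temperature_C, meta$rh_percent,
                meta$leaf_dry_mass_g, meta$sla_m2_per_kg)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Wraps `ape::read.tree` with the structural checks the comparative stage
#' relies on: a rooted tree with branch lengths (polytomies allowed,
#' zero-length branches preserved).
#'
#' @param path Newick file path.
#' @return An `ape::phylo` tree.
#' @export
readPhylogeny <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("could not parse Newick file '", path, "': ",
         conditionMessage(e), call. = FALSE))
  stopIfNot(inherits(tr, "phylo"), paste0("no tree found in '", path, "'"))
  stopIfNot(!is.null(tr$edge.length),
            paste0("tree in '", path, "' has no branch lengths"))
  stopIfNot(ape::is.rooted(tr), paste0("tree in '", path, "' is unrooted"))
  tr
}

#' Read / write a trait-climate table CSV
#'
#' @param path CSV path with columns `species`, `subgenus` and trait or
#'   climate columns.
#' @param table a [TraitClimateTable-class].
#' @return A [TraitClimateTable-class] (read); `path` invisibly (write).
#' @export
readTraitClimateTable <- function(path) {
  newTraitClimateTable(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readTraitClimateTable
#' @export
writeTraitClimateTable <- function(table, path) {
  write.csv(traitData(table), path, row.names = FALSE)
  invisible(path)
}

#' Species means of climate and hydraulic traits for 14 Tasmanian eucalypts
#'
#' The packaged species-mean table: per species, the sampling-site maximum
#' temperature in the warmest month (`maxT`, degrees C), minimum
#' temperature in the coldest month (`minT`, degrees C) and precipitation
#' in the driest quarter (`Pdq`, mm), together with the trait means `p50`
#' (MPa, with `p50_se`), `gmin` (mmol m^-2 s^-1, with `gmin_se`) and `tp`
#' (degrees C; extracted from a mean curve across replicates, so no SE),
#' and the subgenus of each species.
#'
#' @return A [TraitClimateTable-class] with 14 species.
#' @examples
#' tab <- eucalyptTraits()
#' head(traitData(tab))
#' @export
eucalyptTraits <- function() {
  path <- system.file("extdata", "eucalypt_traits.csv",
                      package = "hydrophylo", mustWork = TRUE)
  readTraitClimateTable(path)
}
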