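.locHeader <- c("frame", "x_nm", "y_nm", "z_nm", "sigma_x_nm",
                "sigma_y_nm", "sigma_z_nm")

#' Read a 3D localization table
#'
#' Reads the package's localization CSV dialect: header
#' `frame,x_nm,y_nm,z_nm,sigma_x_nm,sigma_y_nm,sigma_z_nm`, coordinates
#' and Cramer-Rao precisions in nm. Malformed rows are reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @return Validated localization data.frame.
#' @export
readLocalizations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.locHeader, names(tab))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  tab <- tab[, .locHeader]
  validateLocalizations(tab)
  tab
}

#' Validate a localization table
#'
#' Checks column presence, finite coordinates and positive precisions;
#' offending rows are reported by line number (header = line 1).
#'
#' @param locs Localization data.frame.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validateLocalizations <- function(locs) {
  missing <- setdiff(.locHeader, names(locs))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  num <- vapply(locs[.locHeader], is.numeric, TRUE)
  if (!all(num))
    stop("non-numeric columns: ", paste(.locHeader[!num], collapse = ", "))
  bad <- which(!stats::complete.cases(locs[, c("x_nm", "y_nm", "z_nm")]) |
               !is.finite(locs$x_nm) | !is.finite(locs$y_nm) |
               !is.finite(locs$z_nm))
  if (length(bad))
    stop("non-finite coordinates at data line(s) ",
         paste(utils::head(bad + 1, 5), collapse = ", "))
  badSig <- which(!(locs$sigma_x_nm > 0 & locs$sigma_y_nm > 0 &
                      locs$sigma_z_nm > 0))
  if (length(badSig))
    stop("non-positive precisions at data line(s) ",
         paste(utils::head(badSig + 1, 5), collapse = ", "))
  invisible(TRUE)
}

#' Write a localization table
#'
#' Writes the package CSV dialect with full double precision, so a
#' write-read round trip is bit-exact.
#'
#' @param locs Localization data.frame.
#' @param path Output path.
#' @export
writeLocalizations <- function(locs, path) {
  validateLocalizations(locs)
  out <- locs[, .locHeader]
  for (cc in .locHeader[-1]) out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write ROI line definitions
#'
#' ROI files are CSV with header `roi_id,x0,y0,z0,x1,y1,z1` (nm); each
#' row one straight microtubule segment.
#'
#' @param path File path.
#' @return data.frame of ROI lines.
#' @export
readRois <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "x0", "y0", "z0", "x1", "y1", "z1")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  tab
}

#' @rdname readRois
#' @param rois ROI data.frame.
#' @export
writeRois <- function(rois, path) {
  utils::write.csv(rois, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.degInterval <- function(x, default) {
  if (is.null(x)) return(default)
  if (length(x) == 1) x <- c(x, x)
  sort(as.numeric(x)) * pi / 180
}

#' Read an antibody chain model from a YAML config
#'
#' The config carries lengths in nm and angles in degrees; angles are
#' converted to radians. Schema:
#' \preformatted{
#' model:
#'   name: direct-igg
#'   d_min: 1.0           # nm
#'   arc_res: 0.5         # nm
#'   microtubule: {outer_radius: 12.5}
#'   epitope: {y0: 0.0, z0: 12.5, phi1_deg: [0, 360], theta1_deg: [-60, 60]}
#'   segments:
#'     - name: CDR-Hinge
#'       lengths: [7.8, 8.3]      # finite set, nm (or range: [lo, hi])
#'       phi_deg: [-80, 80]
#'       theta_deg: [-80, 80]
#' }
#'
#' @param path YAML file path.
#' @return List with `chain` ([ChainModel-class]), `epitope`
#'   ([EpitopeGeometry-class]), `mt` ([MicrotubuleGeometry-class]),
#'   `name`, and `hash` (MD5 of the file).
#' @export
readModelConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  m <- cfg$model
  if (is.null(m)) stop("config must have a top-level 'model' key")
  if (is.null(m$segments) || !length(m$segments))
    stop("model config must list segments")
  segs <- lapply(m$segments, function(s) {
    if (is.null(s$lengths) == is.null(s$range))
      stop("segment '", s$name, "': supply exactly one of lengths/range")
    SegmentSpec(name = if (is.null(s$name)) "segment" else s$name,
                lengths = if (!is.null(s$lengths)) as.numeric(s$lengths),
                range = if (!is.null(s$range)) as.numeric(s$range),
                phiBounds = .degInterval(s$phi_deg, c(-pi, pi)),
                thetaBounds = .degInterval(s$theta_deg, c(-pi, pi)))
  })
  ep <- m$epitope
  epitope <- EpitopeGeometry(
    y0 = if (is.null(ep$y0)) 0 else ep$y0,
    z0 = if (is.null(ep$z0)) 12.5 else ep$z0,
    phi1Bounds = .degInterval(ep$phi1_deg, c(0, 2 * pi)),
    theta1Bounds = .degInterval(ep$theta1_deg, c(0, 0)))
  mt <- MicrotubuleGeometry(
    if (is.null(m$microtubule$outer_radius)) 12.5
    else m$microtubule$outer_radius)
  chain <- ChainModel(segs,
                      dMin = if (is.null(m$d_min)) 0 else m$d_min,
                      arcRes = if (is.null(m$arc_res)) 0.5 else m$arc_res)
  list(chain = chain, epitope = epitope, mt = mt,
       name = if (is.null(m$name)) basename(path) else m$name,
       hash = unname(tools::md5sum(path)))
}

#' Path to a bundled antibody model config
#'
#' The package ships reconstructed, approximate geometry configs for
#' direct (`"direct"`) and indirect (`"indirect"`) immunolabeling of
#' microtubules by IgG antibodies. Segment lengths derive from published
#' IgG crystal-structure dimensions; angle bounds encode hinge
#' flexibility and steric restriction. See the methods vignette for how
#' these values were chosen.
#'
#' @param which `"direct"` or `"indirect"`.
#' @return File path.
#' @export
modelConfigPath <- function(which = c("direct", "indirect")) {
  which <- match.arg(which)
  system.file("extdata", paste0("model_", which, ".yaml"),
              package = "epilink", mustWork = TRUE)
}

#' Export batch endpoints as CSV
#'
#' @param batch A [ConformationBatch-class].
#' @param path Output path.
#' @export
writeEndpoints <- function(batch, path) {
  ep <- endpoints(batch)
  out <- data.frame(x_nm = ep[, 1], y_nm = ep[, 2], z_nm = ep[, 3])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a radial distribution as CSV
#'
#' @param dist A [RadialDistribution-class].
#' @param path Output path.
#' @export
writeRadialDistribution <- function(dist, path) {
  mids <- dist@binEdges[-length(dist@binEdges)] + diff(dist@binEdges) / 2
  utils::write.csv(data.frame(r_nm = mids, density = dist@density),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a ring-fit result (with linkage errors) as JSON
#'
#' @param fit A [RingFit-class].
#' @param path Output path.
#' @param mtRadius Microtubule outer radius for the linkage errors, nm.
#' @param seed Seed to record.
#' @param configHash Config hash to record.
#' @export
writeFitJson <- function(fit, path, mtRadius = 12.5, seed = NA,
                         configHash = NA_character_) {
  le <- linkageErrors(fit, mtRadius = mtRadius)
  obj <- list(r = fit@r, sigma = fit@sigma, w = fit@w,
              ci95_r = fit@ci95R, ci95_w = fit@ci95W,
              n_sections = fit@nSections,
              linkage_min = le$minimum, linkage_max = le$maximum,
              linkage_ci95 = le$ci95,
              seed = seed, config_hash = configHash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ring-fit JSON back as a list
#'
#' @param path JSON path written by [writeFitJson()].
#' @export
readFitJson <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
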