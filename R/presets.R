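#' Built-in acquisition schedule presets
#'
#' \code{"paper_3T"} encodes the 3 T protocol the package emulates:
#' B1 = 1 uT, rectangular pulses of 250 ms separated by 250 ms, 10 startup
#' pulses plus one maintenance pulse per offset, offsets from -8 to +8 ppm
#' in 0.5 ppm steps with the amide band (3 to 4 ppm, both signs) densified
#' to 0.1 ppm — 49 unique offsets. (The source protocol's offset count is
#' quoted elsewhere as 51; the reconstruction from the stated increments
#' yields 49. The schedule is fully configurable.)
#'
#' @param name preset name, currently \code{"paper_3T"}.
#' @return An \linkS4class{OffsetSchedule}.
#' @examples
#' length(offsets(schedulePreset("paper_3T")))  # 49
#' @export
schedulePreset <- function(name = "paper_3T") {
  if (name != "paper_3T") stop("unknown schedule preset: ", name)
  offs <- sort(unique(round(c(seq(-8, 8, by = 0.5),
                              seq(3, 4, by = 0.1),
                              seq(-4, -3, by = 0.1)), 6)))
  offsetSchedule(offs, B1 = 1, tp = 0.25, td = 0.25,
                 nStartupPulses = 10, nPulsesPerOffset = 1,
                 B0 = 3, gamma = .GAMMA_H)
}

#' Default exchange pools for brain tissue
#'
#' Water plus amide (+3.5 ppm), a broad semisolid MT pool centered at
#' -2.4 ppm (super-Lorentzian lineshape approximated by a very short-T2
#' Lorentzian) and an aliphatic NOE pool at -3.5 ppm. Fractions are
#' literature-typical at 3 T and configurable per tissue class.
#'
#' @param amideFraction,mtFraction,noeFraction proton fractions relative to
#'   water.
#' @param amideK amide exchange rate at the tissue's pH (1/s); usually set
#'   downstream from pH via [amideExchangeRate()].
#' @return list of \linkS4class{Pool} objects.
#' @export
brainPools <- function(amideFraction = 9e-4, mtFraction = 0.08,
                       noeFraction = 3e-3, amideK = 30) {
  pools <- list()
  if (amideFraction > 0)
    pools <- c(pools, Pool("amide", 3.5, amideFraction, R1 = 1, R2 = 30,
                           kExch = amideK))
  if (mtFraction > 0)
    pools <- c(pools, Pool("MT", -2.4, mtFraction, R1 = 1, R2 = 1.1e5,
                           kExch = 40))
  if (noeFraction > 0)
    pools <- c(pools, Pool("NOE", -3.5, noeFraction, R1 = 1, R2 = 40,
                           kExch = 16))
  pools
}

# per-class defaults at 3 T: T1/T2 literature-typical, pH package defaults
# inside the physiological/tumor range; relative proton density (M0).
.CLASS_TABLE <- list(
  WM            = list(t1 = 1.1, t2 = 0.070, ph = 7.00, m0 = 0.72,
                       amide = 9e-4, mt = 0.100, noe = 3.0e-3),
  GM            = list(t1 = 1.6, t2 = 0.090, ph = 7.03, m0 = 0.85,
                       amide = 9e-4, mt = 0.060, noe = 2.5e-3),
  CSF           = list(t1 = 4.3, t2 = 1.500, ph = 7.00, m0 = 1.00,
                       amide = 0,    mt = 0,     noe = 0),
  tumor_rim     = list(t1 = 1.8, t2 = 0.110, ph = 7.15, m0 = 0.90,
                       amide = 9e-4, mt = 0.045, noe = 1.5e-3),
  necrotic_core = list(t1 = 2.2, t2 = 0.250, ph = 7.25, m0 = 0.95,
                       amide = 9e-4, mt = 0.020, noe = 1.0e-3)
)

#' Tissue-class parameter presets
#'
#' Default 3 T relaxation, pool and pH parameters for the phantom's tissue
#' classes (\code{"WM"}, \code{"GM"}, \code{"CSF"}, \code{"tumor_rim"},
#' \code{"necrotic_core"}). Tumor classes carry elevated pH, consistent with
#' the intracellular alkalinization of tumors; CSF has no exchange pools.
#'
#' @param class tissue class name.
#' @param pH optional pH override.
#' @return A \linkS4class{TissueParams}.
#' @examples
#' tissuePreset("tumor_rim")
#' @export
tissuePreset <- function(class, pH = NULL) {
  p <- .CLASS_TABLE[[class]]
  if (is.null(p)) stop("unknown tissue class: ", class)
  ph <- if (is.null(pH)) p$ph else pH
  tissueParams(waterR1 = 1 / p$t1, waterR2 = 1 / p$t2,
               pools = brainPools(p$amide, p$mt, p$noe,
                                  amideK = amideExchangeRate(ph)),
               pH = ph)
}

# relative proton density for a class name
.classM0 <- function(class) .CLASS_TABLE[[class]]$m0

#' Read / write schedule and tissue configurations
#'
#' Schedules and tissue parameter sets are serialized as JSON so that a run
#' is fully described by plain-text configuration.
#'
#' @param x an \linkS4class{OffsetSchedule} or \linkS4class{TissueParams}.
#' @param path file path.
#' @return \code{readSchedule}/\code{readTissue} return the reconstructed
#'   object; the writers return \code{path} invisibly.
#' @name configIO
NULL

#' @rdname configIO
#' @export
writeSchedule <- function(x, path) {
  jsonlite::write_json(list(
    offsets = x@offsets, B1 = x@B1, tp = x@tp, td = x@td,
    nStartupPulses = x@nStartupPulses, nPulsesPerOffset = x@nPulsesPerOffset,
    B0 = x@B0, gamma = x@gamma), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname configIO
#' @export
readSchedule <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  offsetSchedule(j$offsets, B1 = j$B1, tp = j$tp, td = j$td,
                 nStartupPulses = j$nStartupPulses,
                 nPulsesPerOffset = j$nPulsesPerOffset,
                 B0 = j$B0, gamma = j$gamma)
}

#' @rdname configIO
#' @export
writeTissue <- function(x, path) {
  jsonlite::write_json(list(
    waterR1 = x@waterR1, waterR2 = x@waterR2, pH = x@pH,
    pools = lapply(x@pools, function(p) list(
      name = p@name, chemicalShift = p@chemicalShift, fraction = p@fraction,
      R1 = p@R1, R2 = p@R2, kExch = p@kExch))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname configIO
#' @export
readTissue <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  pools <- lapply(j$pools, function(p)
    Pool(p$name, p$chemicalShift, p$fraction, p$R1, p$R2, p$kExch))
  tissueParams(j$waterR1, j$waterR2, pools, j$pH)
}

# stable hash of an offset schedule (used to tag model checkpoints)
.scheduleHash <- function(schedule) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeSchedule(schedule, tf)
  unname(tools::md5sum(tf))
}
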