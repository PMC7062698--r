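# Idealized 10-10 electrode geometry on a unit sphere.
#
# The scalp is modelled as the upper part of a unit sphere with the vertex
# (Cz) at +z, the right preauricular direction at +x and the nasion direction
# at +y. The outer 10-10 ring lies on the equator at 18-degree azimuthal
# steps; midline and intermediate electrodes are placed by spherical (great
# circle) interpolation between the vertex, the midline row positions and the
# row's equatorial end point. PO9/PO10 (and Iz) sit 18 degrees below the
# equatorial ring, as in extended caps.

.sph <- function(inclDeg, azDeg) {
  i <- inclDeg * pi / 180; a <- azDeg * pi / 180
  c(sin(i) * cos(a), sin(i) * sin(a), cos(i))
}

# spherical linear interpolation between unit vectors
.slerp <- function(p, q, frac) {
  w <- acos(max(-1, min(1, sum(p * q))))
  if (w < 1e-12) return(p)
  (sin((1 - frac) * w) * p + sin(frac * w) * q) / sin(w)
}

.montageMaster <- local({
  build <- function() {
    pos <- list()
    add <- function(name, p) pos[[name]] <<- p / sqrt(sum(p^2))

    # equatorial ring, azimuth from +x (right ear), 18-degree steps
    ring <- c(Fpz = 90, Fp2 = 72, AF8 = 54, F8 = 36, FT8 = 18, T8 = 0,
              TP8 = -18, P8 = -36, PO8 = -54, O2 = -72, Oz = -90,
              Fp1 = 108, AF7 = 126, F7 = 144, FT7 = 162, T7 = 180,
              TP7 = 198, P7 = 216, PO7 = 234, O1 = 252)
    for (nm in names(ring)) add(nm, .sph(90, ring[[nm]]))

    cz <- .sph(0, 0); add("Cz", cz)
    # midline rows by interpolation vertex -> Fpz / Oz
    for (x in list(c("FCz", "Fpz", 1/4), c("Fz", "Fpz", 2/4),
                   c("AFz", "Fpz", 3/4), c("CPz", "Oz", 1/4),
                   c("Pz", "Oz", 2/4), c("POz", "Oz", 3/4)))
      add(x[[1]], .slerp(cz, pos[[x[[2]]]], as.numeric(x[[3]])))

    # lateral chains: midline electrode -> equatorial end point of the row
    chain <- function(mid, endL, endR, namesL, namesR, fracs) {
      for (i in seq_along(namesL)) {
        add(namesL[i], .slerp(pos[[mid]], pos[[endL]], fracs[i]))
        add(namesR[i], .slerp(pos[[mid]], pos[[endR]], fracs[i]))
      }
    }
    chain("Fz", "F7", "F8", c("F1", "F3", "F5"), c("F2", "F4", "F6"),
          c(1, 2, 3) / 4)
    chain("FCz", "FT7", "FT8", c("FC1", "FC3", "FC5"), c("FC2", "FC4", "FC6"),
          c(1, 2, 3) / 4)
    chain("Cz", "T7", "T8", c("C1", "C3", "C5"), c("C2", "C4", "C6"),
          c(1, 2, 3) / 4)
    chain("CPz", "TP7", "TP8", c("CP1", "CP3", "CP5"), c("CP2", "CP4", "CP6"),
          c(1, 2, 3) / 4)
    chain("Pz", "P7", "P8", c("P1", "P3", "P5"), c("P2", "P4", "P6"),
          c(1, 2, 3) / 4)
    chain("AFz", "AF7", "AF8", "AF3", "AF4", 1 / 2)
    chain("POz", "PO7", "PO8", "PO3", "PO4", 1 / 2)

    # inferior row (18 degrees below the equator)
    add("PO9", .sph(108, 234)); add("PO10", .sph(108, -54))
    add("Iz", .sph(108, -90))

    do.call(rbind, pos)
  }
  build()
})

.montageLayouts <- list(
  `8`  = c("Fz", "Cz", "Pz", "Oz", "C3", "C4", "PO9", "PO10"),
  `16` = c("Fp1", "Fp2", "F3", "F4", "F8", "FC1", "C3", "Cz", "C4",
           "P3", "Pz", "P4", "PO9", "PO10", "O1", "O2"),
  `32` = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2",
           "FC6", "T7", "C3", "Cz", "C4", "T8", "CP5", "CP1", "CP2", "CP6",
           "P7", "P3", "Pz", "P4", "P8", "PO3", "PO4", "PO9", "PO10",
           "O1", "Oz", "O2"),
  `60` = setdiff(rownames(.montageMaster), c("Iz", "AFz", "AF3", "AF4")),
  `64` = rownames(.montageMaster))

#' Construct a standard 10-10 montage
#'
#' Returns one of the supported cap layouts (8, 16, 32, 60 or 64 channels)
#' with standard 10-10 names projected onto the unit sphere. Layouts of 16
#' channels and above contain the channels the analysis relies on
#' (PO9, PO10, F8, FC1, C3, C4, Cz); the default 60-channel cap matches the
#' recording setup the pipeline emulates.
#'
#' @param nChannels one of 8, 16, 32, 60, 64.
#' @return A [Montage-class].
#' @export
#' @examples
#' m <- makeMontage(60)
#' all(c("PO9", "PO10", "F8", "FC1") %in% channelNames(m))
makeMontage <- function(nChannels = 60) {
  key <- as.character(nChannels)
  if (!key %in% names(.montageLayouts))
    stop("unsupported montage size ", nChannels, "; supported layouts: ",
         paste(names(.montageLayouts), collapse = ", "))
  ch <- .montageLayouts[[key]]
  pos <- .montageMaster[ch, , drop = FALSE]
  new("Montage", channels = ch, positions = pos)
}
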