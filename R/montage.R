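# Electrode montage: standard 10-10 subset with 2-D disc coordinates.
#
# Positions are built on the unit sphere: the midline runs from Fpz to Oz
# in 18-degree (10%) polar steps through the vertex Cz, the circumferential
# ring (Fpz, Fp1, ..., T7, ..., Oz) sits at 72 degrees polar, and
# intermediate electrodes are spaced equally along the great circle joining
# their midline and ring anchors. The 2-D layout is the azimuthal
# equidistant projection (vertex at the origin, nose up, ring at radius 1),
# used for spatial adjacency and topographic weighting, not for source
# modelling.

ten_ten_positions <- function() {
  deg <- function(a) a * pi / 180
  sph <- function(pol, az) c(sin(pol) * cos(az), sin(pol) * sin(az), cos(pol))
  proj <- function(p) {
    th <- acos(max(min(p[3], 1), -1))
    r <- th / deg(72)
    az <- atan2(p[2], p[1])
    r * c(cos(az), sin(az))
  }
  slerp <- function(A, B, f) {
    O <- acos(max(min(sum(A * B), 1), -1))
    (sin((1 - f) * O) * A + sin(f * O) * B) / sin(O)
  }
  rows <- list(
    list(mid = "Fpz", mpol = 72, maz = 90, louter = "Fp1", oaz = 108, inner = character(0)),
    list(mid = "AFz", mpol = 54, maz = 90, louter = "AF7", oaz = 126, inner = "AF3"),
    list(mid = "Fz",  mpol = 36, maz = 90, louter = "F7",  oaz = 144, inner = c("F1", "F3", "F5")),
    list(mid = "FCz", mpol = 18, maz = 90, louter = "FT7", oaz = 162, inner = c("FC1", "FC3", "FC5")),
    list(mid = "Cz",  mpol = 0,  maz = 90, louter = "T7",  oaz = 180, inner = c("C1", "C3", "C5")),
    list(mid = "CPz", mpol = 18, maz = -90, louter = "TP7", oaz = 198, inner = c("CP1", "CP3", "CP5")),
    list(mid = "Pz",  mpol = 36, maz = -90, louter = "P7",  oaz = 216, inner = c("P1", "P3", "P5")),
    list(mid = "POz", mpol = 54, maz = -90, louter = "PO7", oaz = 234, inner = "PO3"),
    list(mid = "Oz",  mpol = 72, maz = -90, louter = "O1",  oaz = 252, inner = character(0))
  )
  outer_mirror <- c(Fp1 = "Fp2", AF7 = "AF8", F7 = "F8", FT7 = "FT8",
                    T7 = "T8", TP7 = "TP8", P7 = "P8", PO7 = "PO8", O1 = "O2")
  lab <- character(0); xs <- numeric(0); ys <- numeric(0)
  add <- function(l, p) { lab <<- c(lab, l); xs <<- c(xs, p[1]); ys <<- c(ys, p[2]) }
  mirror <- function(l) {
    # left-hemisphere label -> right-hemisphere label (odd -> even numbering)
    num <- as.integer(sub("^[A-Za-z]+", "", l))
    paste0(sub("[0-9]+$", "", l), num + 1L)
  }
  for (r in rows) {
    M <- sph(deg(r$mpol), deg(r$maz))
    add(r$mid, proj(M))
    O <- sph(deg(72), deg(r$oaz))
    po <- proj(O)
    add(r$louter, po)
    add(outer_mirror[[r$louter]], po * c(-1, 1))
    k <- length(r$inner)
    if (k > 0) {
      for (i in seq_len(k)) {
        # inner labels ordered midline-out (e.g. F1, F3, F5)
        p <- proj(slerp(M, O, i / (k + 1)))
        add(r$inner[i], p)
        add(mirror(r$inner[i]), p * c(-1, 1))
      }
    }
  }
  data.frame(label = lab, x = xs, y = ys, stringsAsFactors = FALSE)
}

# Order in which channels are drawn from the full 10-10 table. The leading
# entries guarantee the frontal-central reporting subset (FC1, FCz, FC2) at
# any montage size >= 4 and reproduce a conventional 32-channel cap at the
# default size.
montage_priority <- c(
  "FC1", "FCz", "FC2", "Cz", "Fz", "Pz", "F3", "F4", "C3", "C4",
  "P3", "P4", "O1", "O2", "Fp1", "Fp2", "F7", "F8", "T7", "T8",
  "P7", "P8", "FC5", "FC6", "CP5", "CP6", "FT7", "FT8", "TP7", "TP8",
  "Oz", "POz"
)

#' Generate an electrode montage
#'
#' Builds a montage of `n_channels` electrodes drawn from a standard 10-10
#' layout with schematic 2-D scalp coordinates. The frontal-central
#' reporting electrodes FC1, FCz and FC2 are always included; they are the
#' subset conventionally used for waveform reporting because they are least
#' affected by myogenic and ocular artifacts.
#'
#' @param n_channels Number of electrodes (4 to 61).
#' @return An object of class `eeg_montage`: a data frame with columns
#'   `label`, `x`, `y`, plus attribute `reporting` naming the
#'   frontal-central subset.
#' @examples
#' m <- generate_montage(32)
#' all(c("FC1", "FCz", "FC2") %in% m$label)
#' @export
generate_montage <- function(n_channels = 32) {
  full <- ten_ten_positions()
  if (n_channels < 4) stop("n_channels must be at least 4")
  if (n_channels > nrow(full)) {
    stop("n_channels exceeds the ", nrow(full), " positions of the 10-10 layout")
  }
  order_all <- c(montage_priority, setdiff(full$label, montage_priority))
  keep <- order_all[seq_len(n_channels)]
  m <- full[match(keep, full$label), , drop = FALSE]
  rownames(m) <- NULL
  stopifnot(!anyDuplicated(m$label))
  structure(m, class = c("eeg_montage", "data.frame"),
            reporting = c("FC1", "FCz", "FC2"))
}

#' Spatial channel adjacency from montage coordinates
#'
#' Two electrodes are neighbours when their 2-D distance is below `radius`.
#' The default radius is 1.3 times the median nearest-neighbour distance,
#' enlarged when the montage is spatially uneven to just past every
#' channel's second-nearest neighbour, so each electrode keeps at least
#' two neighbours (an electrode with a single neighbour could anchor only
#' one two-electrode cluster); this yields 2--8 neighbours per channel
#' across montage sizes. The resulting matrix defines the spatial dimension of
#' spatio-temporal clustering. An explicitly supplied radius is used as
#' given, and isolating a channel with it is an error.
#'
#' @param montage An `eeg_montage`.
#' @param radius Neighbourhood radius; `NULL` for the default rule.
#' @return Symmetric logical matrix (zero diagonal) with channel labels as
#'   dimnames.
#' @export
channel_adjacency <- function(montage, radius = NULL) {
  if (nrow(montage) < 2) stop("need at least 2 channels with coordinates")
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  dimnames(d) <- list(montage$label, montage$label)
  if (is.null(radius)) {
    dd <- d + diag(Inf, nrow(d))
    nn1 <- apply(dd, 1, min)
    nn2 <- apply(dd, 1, function(v) sort(v)[2])
    radius <- max(1.3 * stats::median(nn1), 1.001 * max(nn2))
  }
  adj <- d <= radius
  diag(adj) <- FALSE
  if (any(rowSums(adj) == 0)) {
    stop("channel(s) ", paste(montage$label[rowSums(adj) == 0], collapse = ", "),
         " have no neighbour at radius ", signif(radius, 4),
         "; increase the radius")
  }
  adj
}

#' Topography weights for an ERP source
#'
#' Gaussian spatial falloff around a focal electrode, used by the simulator
#' to spread a component over neighbouring channels.
#'
#' @param montage An `eeg_montage`.
#' @param center Label of the focal electrode.
#' @param sigma Spatial standard deviation in montage units.
#' @return Named numeric vector of weights in (0, 1], 1 at the focus.
#' @export
topography_weights <- function(montage, center = "FCz", sigma = 0.45) {
  if (!center %in% montage$label) stop("center channel not in montage")
  cp <- montage[montage$label == center, c("x", "y")]
  d2 <- (montage$x - cp$x)^2 + (montage$y - cp$y)^2
  w <- exp(-d2 / (2 * sigma^2))
  names(w) <- montage$label
  w
}
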