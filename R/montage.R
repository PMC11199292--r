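#' Sensor montages
#'
#' A montage is a set of uniquely labelled sensors with positions on the unit
#' sphere (head-centred coordinates: +x towards the nasion, +y towards the left
#' ear, +z through the vertex). The packaged 64-channel montage follows the
#' extended 10-10 placement scheme on a spherical head model: electrodes sit on
#' a peripheral circle at 72 degrees inclination from the vertex, on the
#' sagittal midline, and on coronal arcs interpolated between the two.
#'
#' @name montage
NULL

# slerp between two unit vectors; f in [0, 1]
.slerp <- function(p, q, f) {
  w <- acos(max(-1, min(1, sum(p * q))))
  if (w < 1e-12) return(p)
  (sin((1 - f) * w) * p + sin(f * w) * q) / sin(w)
}

.sph <- function(incl_deg, azim_deg) {
  i <- incl_deg * pi / 180
  a <- azim_deg * pi / 180
  c(sin(i) * cos(a), sin(i) * sin(a), cos(i))
}

# Full extended 10-10 grid on the spherical head model.
.ten_ten_grid <- function() {
  pos <- list()
  # peripheral circle, inclination 72 deg; azimuth from nasion, + to the left
  periph <- c(
    Fpz = 0, Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
    TP7 = 108, P7 = 126, PO7 = 144, O1 = 162, Oz = 180,
    O2 = -162, PO8 = -144, P8 = -126, TP8 = -108, T8 = -90,
    FT8 = -72, F8 = -54, AF8 = -36, Fp2 = -18
  )
  for (nm in names(periph)) pos[[nm]] <- .sph(72, periph[[nm]])
  # sagittal midline
  mid <- list(AFz = c(54, 0), Fz = c(36, 0), FCz = c(18, 0), Cz = c(0, 0),
              CPz = c(18, 180), Pz = c(36, 180), POz = c(54, 180))
  for (nm in names(mid)) pos[[nm]] <- .sph(mid[[nm]][1], mid[[nm]][2])
  # coronal arcs: interpolate left-periphery -> midline -> right-periphery
  arcs <- list(
    AF = list(l = "AF7", z = "AFz", r = "AF8", n = 1),  # AF3 / AF4 only
    F  = list(l = "F7",  z = "Fz",  r = "F8",  n = 3),
    FC = list(l = "FT7", z = "FCz", r = "FT8", n = 3),
    C  = list(l = "T7",  z = "Cz",  r = "T8",  n = 3),
    CP = list(l = "TP7", z = "CPz", r = "TP8", n = 3),
    P  = list(l = "P7",  z = "Pz",  r = "P8",  n = 3),
    PO = list(l = "PO7", z = "POz", r = "PO8", n = 1)   # PO3 / PO4 only
  )
  for (row in names(arcs)) {
    a <- arcs[[row]]
    odd <- if (a$n == 3) c(5, 3, 1) else 3
    for (j in seq_len(a$n)) {
      f <- j / (a$n + 1)
      pos[[paste0(row, odd[j])]] <- .slerp(pos[[a$l]], pos[[a$z]], f)
      pos[[paste0(row, odd[j] + 1)]] <- .slerp(pos[[a$r]], pos[[a$z]], f)
    }
  }
  # inferior temporal ring (10% below the peripheral circle)
  inf <- c(FT9 = 72, TP9 = 108, TP10 = -108, FT10 = -72)
  for (nm in names(inf)) pos[[nm]] <- .sph(90, inf[[nm]])
  pos
}

# Standard 64-channel cap label set (extended 10-10, TP9 online reference).
.labels_64 <- c(
  "Fp1", "Fp2",
  "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "Oz", "O2"
)

#' Build a sensor montage
#'
#' For `n_channels = 64` the packaged extended 10-10 cap is returned (unique
#' standard labels, deterministic positions). For `n_channels = 2` two
#' antipodal sensors are returned. Any other count of at least 2 yields a
#' deterministic Fibonacci spiral over the upper hemisphere with generic
#' labels.
#'
#' @param n_channels Number of sensors (>= 2).
#' @return An object of class `sensor_montage`: list with `labels` (character)
#'   and `positions` (n x 3 matrix of unit vectors, rownames = labels).
#' @examples
#' m <- make_montage(64)
#' nrow(m$positions)
#' @export
make_montage <- function(n_channels) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 ||
      n_channels != round(n_channels) || n_channels < 2) {
    stop("n_channels must be a single integer >= 2")
  }
  n_channels <- as.integer(n_channels)
  if (n_channels == 64) {
    grid <- .ten_ten_grid()
    labels <- .labels_64
    positions <- t(vapply(labels, function(l) grid[[l]], numeric(3)))
  } else if (n_channels == 2) {
    labels <- c("E1", "E2")
    positions <- rbind(c(1, 0, 0), c(-1, 0, 0))
  } else {
    # Fibonacci spiral over the upper hemisphere (z in (0, 1])
    k <- seq_len(n_channels)
    z <- (k - 0.5) / n_channels            # heights in (0, 1)
    phi <- k * pi * (3 - sqrt(5))          # golden-angle azimuths
    r <- sqrt(1 - z^2)
    positions <- cbind(r * cos(phi), r * sin(phi), z)
    labels <- sprintf("E%02d", k)
  }
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions),
            class = "sensor_montage")
}

#' @export
print.sensor_montage <- function(x, ...) {
  cat("<sensor_montage> ", length(x$labels), " channels: ",
      paste(utils::head(x$labels, 6), collapse = ", "),
      if (length(x$labels) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Angular (geodesic) distance matrix between montage positions, radians.
.montage_geodesic <- function(montage) {
  g <- tcrossprod(montage$positions)
  acos(pmin(pmax(g, -1), 1))   # g first: pmin/pmax keep its dim attributes
}
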