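# Approximate 2-D projected coordinates for the 10-10 electrode system.

# 64-channel actiCAP-style 10-10 label set, in recording order.
.labels_64 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
  "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
  "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
  "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6", "FT9", "FT7", "FC3",
  "FC4", "FT8", "FT10", "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4",
  "TP8", "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8"
)

# Priority ordering used when fewer than 64 channels are requested: central,
# temporal and frontal sites first so that reduced montages still cover the
# sensorimotor and articulatory regions the signal model modulates.
.labels_priority <- c(
  "C3", "C4", "Cz", "T7", "T8", "FC1", "FC2", "CP1", "CP2", "F3", "F4",
  "Fz", "P3", "P4", "Pz", "Oz", "F7", "F8", "FC5", "FC6", "CP5", "CP6",
  "P7", "P8", "Fp1", "Fp2", "O1", "O2", "FT7", "FT8", "TP7", "TP8"
)

.row_y <- c(Fp = 4, AF = 3.4, F = 2.6, FT = 1.6, FC = 1.4, T = 0, C = 0,
            TP = -1.6, CP = -1.4, P = -2.6, PO = -3.4, O = -4)
.num_x <- c(`1` = 0.2, `2` = 0.2, `3` = 0.45, `4` = 0.45, `5` = 0.65,
            `6` = 0.65, `7` = 0.85, `8` = 0.85, `9` = 1.05, `10` = 1.05)

.label_xy <- function(label) {
  if (label %in% c("Fpz", "AFz", "Fz", "FCz", "Cz", "CPz", "Pz", "POz",
                   "Oz")) {
    row <- sub("z$", "", label)
    return(c(0, .row_y[[row]] / 4))
  }
  m <- regmatches(label, regexec("^([A-Za-z]+?)(10|[1-9])$", label))[[1]]
  if (length(m) != 3) stopf("unrecognized 10-10 label: %s", label)
  row <- m[2]
  num <- m[3]
  if (row %in% c("T", "TP", "FT") == FALSE && !row %in% names(.row_y)) {
    stopf("unrecognized 10-10 row: %s", row)
  }
  x <- .num_x[[num]]
  if (as.integer(num) %% 2 == 1) x <- -x  # odd = left hemisphere
  # T7/T8 sit on the C ring at full laterality
  if (row == "T") x <- sign(x) * 1.05
  c(x, .row_y[[row]] / 4)
}

#' 2-D montage coordinates for a 10-10 channel subset
#'
#' Returns approximate top-view scalp-plane coordinates (nose up, left ear at
#' negative x) for `n_channels` electrodes of the 64-channel 10-10 set. For
#' fewer than 64 channels, sites are picked in a fixed priority order that
#' retains central/temporal coverage. Coordinates are schematic — adequate
#' for building smooth synthetic topographies, not for source localization.
#'
#' @param n_channels Number of electrodes, between 2 and 64.
#' @return A data.frame with columns `label`, `x`, `y`.
#' @export
#' @examples
#' head(montage_1010(16))
montage_1010 <- function(n_channels = 64) {
  if (!is_count(n_channels) || n_channels < 2 || n_channels > 64) {
    stopf("n_channels must be an integer in [2, 64]")
  }
  labels <- if (n_channels == 64) {
    .labels_64
  } else {
    pool <- c(.labels_priority, setdiff(.labels_64, .labels_priority))
    sel <- pool[seq_len(n_channels)]
    .labels_64[.labels_64 %in% sel]  # keep recording order
  }
  xy <- t(vapply(labels, .label_xy, numeric(2)))
  data.frame(label = labels, x = xy[, 1], y = xy[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Smooth unit-norm spatial kernel over the montage: Gaussian bump(s) of width
# `sigma` centered at the given (x, y) points (summed, then normalized).
.topography <- function(montage, centers, sigma = 0.35) {
  if (!is.matrix(centers)) centers <- matrix(centers, ncol = 2, byrow = TRUE)
  w <- rep(0, nrow(montage))
  for (i in seq_len(nrow(centers))) {
    d2 <- (montage$x - centers[i, 1])^2 + (montage$y - centers[i, 2])^2
    w <- w + exp(-d2 / (2 * sigma^2))
  }
  w / sqrt(sum(w^2))
}
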