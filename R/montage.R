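# 10-10 montage used by the study design: 58 scalp electrodes plus bipolar
# VEOG/HEOG. The analysis grid is the 6 x 7 matrix of anterior-posterior rows
# F, FC, C, CP, P, PO crossed with lateral-medial lines 5, 3, 1, z, 2, 4, 6
# (odd = left, even = right). The remaining 16 scalp channels complete the
# montage but carry no grid position.

.matrix_rows <- c("F", "FC", "C", "CP", "P", "PO")
.matrix_cols <- c("5", "3", "1", "z", "2", "4", "6")

#' Electrode matrix used for topographic amplitude analyses
#'
#' Returns the 6 x 7 grid of channel labels: anterior-posterior levels
#' (frontal to parieto-occipital) by lateral-medial lines (line 5 left to
#' line 6 right, midline `z` in the middle).
#'
#' @return A 6 x 7 character matrix with dimnames `ap` (F, FC, C, CP, P, PO)
#'   and `lm` (L5, L3, L1, z, L2, L4, L6).
#' @export
#' @examples
#' electrode_matrix()["P", "z"]   # "Pz"
electrode_matrix <- function() {
  labs <- outer(.matrix_rows, .matrix_cols, paste0)
  dimnames(labs) <- list(ap = .matrix_rows,
                         lm = c("L5", "L3", "L1", "z", "L2", "L4", "L6"))
  labs
}

#' Default channel set
#'
#' The 58 scalp labels of the montage (the 6 x 7 analysis grid plus frontal
#' pole, lateral temporal and occipital sites) followed by the two bipolar
#' ocular channels.
#'
#' @param eog Include `"VEOG"`/`"HEOG"` at the end (default `TRUE`).
#' @return Character vector of channel labels.
#' @export
default_channels <- function(eog = TRUE) {
  scalp <- c(t(electrode_matrix()),
             "Fp1", "Fpz", "Fp2", "F7", "F8", "T7", "T8", "TP7", "TP8",
             "P7", "P8", "PO7", "PO8", "O1", "Oz", "O2")
  if (eog) c(scalp, "VEOG", "HEOG") else scalp
}

eog_channels <- function() c("VEOG", "HEOG")

# Idealized 2-D scalp coordinates per label: y runs anterior (0) to posterior
# (7), x runs left (negative) to right. Used only to build smooth simulated
# topographies; this is not a forward model.
channel_grid_xy <- function(labels) {
  row_y <- c(Fp = 0, F = 1, FT = 1.5, FC = 2, T = 3, C = 3, TP = 4, CP = 4,
             P = 5, PO = 6, O = 7)
  xy <- t(vapply(labels, function(lab) {
    if (lab %in% eog_channels()) return(c(NA_real_, NA_real_))
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    row <- m[2]; col <- m[3]
    y <- row_y[[row]]
    x <- if (col == "z") 0 else {
      k <- as.numeric(col)
      side <- if (k %% 2 == 1) -1 else 1
      side * ceiling(k / 2)
    }
    c(x, y)
  }, numeric(2)))
  colnames(xy) <- c("x", "y")
  xy
}

# Gaussian spatial weight centred on a focus electrode; weights are 1 at the
# focus and fall off with grid distance. EOG channels get weight 0.
topography_weights <- function(labels, focus, spread = 2.5) {
  xy <- channel_grid_xy(labels)
  fxy <- channel_grid_xy(focus)
  w <- exp(-((xy[, "x"] - fxy[1, "x"])^2 + (xy[, "y"] - fxy[1, "y"])^2) /
             (2 * spread^2))
  w[is.na(w)] <- 0
  names(w) <- labels
  w
}

# Blink propagation: fraction of the VEOG deflection reaching each scalp
# channel, largest at the frontal pole and decaying towards occipital sites,
# with a small floor everywhere (volume conduction).
blink_propagation_factors <- function(labels) {
  xy <- channel_grid_xy(labels)
  p <- 0.05 + 0.30 * exp(-(xy[, "y"] / 2)^2)
  p[is.na(p)] <- 0
  names(p) <- labels
  p[labels %in% eog_channels()] <- 0
  p
}
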