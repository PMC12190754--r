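#' Dynamic cross-correlation matrix of residue motions
#'
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>), with dr_i(t) = r_i(t) -
#' <r_i> and averages over all frames of the aligned trajectory: the average
#' dot product of centered coordinates, normalized to [-1, +1]. Residues with
#' zero displacement variance get 0 off-diagonal, 1 on the diagonal, and are
#' flagged.
#'
#' @param traj an aligned [Trajectory-class] with >= 2 frames.
#' @return A [DCCMatrix-class].
#' @export
dccm <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  if (nFrames(traj) < 2L) stop("DCCM needs >= 2 frames")
  if (!isAligned(traj))
    warning("trajectory carries no alignment provenance; ",
            "rigid-body motion will contaminate the correlations")
  nf <- nFrames(traj); nr <- nResidues(traj)
  mu <- apply(traj@coords, c(2, 3), mean)
  dev <- sweep(traj@coords, c(2, 3), mu)      # nf x nr x 3
  ## <dr_i . dr_j> = (1/nf) sum_t sum_axis dev[t,i,a] dev[t,j,a]
  flat <- rbind(dev[, , 1], dev[, , 2], dev[, , 3])   # (3 nf) x nr
  G <- crossprod(flat) / nf                   # nr x nr, <dr_i . dr_j>
  v <- diag(G)
  zero <- which(v <= 0)
  s <- sqrt(ifelse(v > 0, v, 1))
  C <- G / tcrossprod(s)
  if (length(zero)) {
    C[zero, ] <- 0; C[, zero] <- 0
  }
  diag(C) <- 1
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  new("DCCMatrix", values = C, residueLabels = traj@residueIndex,
      zeroVarianceResidues = as.integer(traj@residueIndex[zero]))
}

setMethod("show", "DCCMatrix", function(object) {
  cat("DCCMatrix:", nrow(object@values), "x", ncol(object@values),
      "residue cross-correlations in [-1, 1]\n")
  off <- object@values[upper.tri(object@values)]
  cat("  off-diagonal range:", format(min(off), digits = 3), "..",
      format(max(off), digits = 3), "\n")
  if (length(object@zeroVarianceResidues))
    cat("  zero-variance residues:",
        paste(object@zeroVarianceResidues, collapse = ", "), "\n")
})

#' Summarize a DCCM into coordinated residue-range blocks
#'
#' Residues are first segmented into maximal contiguous runs in which
#' consecutive residues are positively coupled (C[i, i+1] >= threshold);
#' singleton runs are dropped. Every pair of segments (including a segment
#' with itself) whose mean correlation exceeds +threshold or falls below
#' -threshold is reported with its sign and mean |C| (self-pairs use
#' off-diagonal entries only).
#'
#' @param d a [DCCMatrix-class].
#' @param threshold |threshold| < 1.
#' @return data.frame (from_1, to_1, from_2, to_2, sign, mean_abs_c); zero rows
#'   when no coordinated blocks exist.
#' @export
dccmBlocks <- function(d, threshold = 0.5) {
  stopifnot(is(d, "DCCMatrix"), abs(threshold) < 1)
  C <- d@values
  n <- nrow(C)
  coupled <- vapply(seq_len(n - 1L), function(i) C[i, i + 1L] >= threshold,
                    logical(1))
  ## maximal runs of consecutively coupled residues, length >= 2
  segs <- list()
  i <- 1L
  while (i < n) {
    if (coupled[i]) {
      j <- i
      while (j < n && coupled[j]) j <- j + 1L
      segs[[length(segs) + 1L]] <- c(i, j)
      i <- j
    } else i <- i + 1L
  }
  empty <- data.frame(from_1 = integer(0), to_1 = integer(0),
                      from_2 = integer(0), to_2 = integer(0),
                      sign = integer(0), mean_abs_c = numeric(0))
  if (length(segs) == 0L) return(empty)
  out <- list()
  for (a in seq_along(segs)) for (b in a:length(segs)) {
    ia <- segs[[a]][1]:segs[[a]][2]
    ib <- segs[[b]][1]:segs[[b]][2]
    block <- C[ia, ib, drop = FALSE]
    if (a == b) {
      vals <- block[upper.tri(block)]
    } else vals <- as.numeric(block)
    m <- mean(vals)
    if (m >= threshold || m <= -threshold)
      out[[length(out) + 1L]] <- data.frame(
        from_1 = d@residueLabels[ia[1]], to_1 = d@residueLabels[ia[length(ia)]],
        from_2 = d@residueLabels[ib[1]], to_2 = d@residueLabels[ib[length(ib)]],
        sign = ifelse(m > 0, 1L, -1L), mean_abs_c = abs(m))
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Write a DCCM as labelled CSV
#' @param d a [DCCMatrix-class].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
writeDCCMCSV <- function(d, path) {
  m <- as.data.frame(d@values)
  names(m) <- paste0("r", d@residueLabels)
  utils::write.csv(cbind(residue = d@residueLabels, m), path, row.names = FALSE)
  invisible(path)
}

#' Plot a DCCM heatmap (red +1, white 0, blue -1)
#' @param d a [DCCMatrix-class].
#' @param ... passed to [graphics::image()].
#' @export
plotDCCM <- function(d, ...) {
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  graphics::image(d@residueLabels, d@residueLabels, d@values,
                  zlim = c(-1, 1), col = pal,
                  xlab = "Residue", ylab = "Residue",
                  main = "Dynamic cross-correlation", ...)
  invisible(d)
}

#' Porcupine vector field from a PC eigenvector
#'
#' One arrow per residue: the (x, y, z) loading triplet of the chosen
#' component scaled by `scale`, anchored at the reference Calpha position.
#' The default scale makes the longest arrow 10 Angstrom.
#'
#' @param res an [EssentialDynamicsResult-class].
#' @param component which PC (must be <= kRetained).
#' @param reference a [Frame-class] giving the arrow base positions.
#' @param scale positive multiplier; NULL picks 10 / max residue loading norm.
#' @return A [PorcupineField-class].
#' @export
porcupineField <- function(res, component, reference, scale = NULL) {
  stopifnot(is(res, "EssentialDynamicsResult"), is(reference, "Frame"))
  if (component < 1L || component > res@kRetained)
    stop("parameter error: component ", component, " out of retained range 1..",
         res@kRetained)
  v <- res@loadings[, component]
  n <- length(v) / 3L
  if (n != nrow(reference@coords))
    stop("loading length must equal 3 x residue count of the reference")
  trip <- matrix(v, ncol = 3, byrow = TRUE)   # columns x, y, z per residue
  norms <- sqrt(rowSums(trip^2))
  if (is.null(scale))
    scale <- if (max(norms) > 0) 10 / max(norms) else 1
  if (scale <= 0) stop("parameter error: scale must be positive")
  arrows <- trip * scale
  new("PorcupineField", base = reference@coords, arrows = arrows,
      magnitude = sqrt(rowSums(arrows^2)), component = as.integer(component),
      scale = scale, residueIndex = reference@residueIndex)
}

setMethod("show", "PorcupineField", function(object) {
  cat("PorcupineField: PC", object@component, ",", nrow(object@arrows),
      "arrows, scale", format(object@scale, digits = 4), "\n")
  cat("  longest arrow:", format(max(object@magnitude), digits = 4),
      "Angstrom\n")
})

#' Export porcupine arrows to BILD or CSV
#'
#' BILD writes one `.arrow` record per residue (tip = base + arrow) loadable
#' by molecular viewers; CSV writes residue, base xyz, tip xyz and magnitude
#' and round-trips exactly through [readArrowsCSV()].
#'
#' @param field a [PorcupineField-class].
#' @param path output file path.
#' @param format "bild" or "csv".
#' @return Invisibly, `path`.
#' @export
exportArrows <- function(field, path, format = c("bild", "csv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("parameter error: unknown format"))
  tip <- field@base + field@arrows
  if (format == "csv") {
    df <- data.frame(residue_index = field@residueIndex,
                     base_x = field@base[, 1], base_y = field@base[, 2],
                     base_z = field@base[, 3],
                     tip_x = tip[, 1], tip_y = tip[, 2], tip_z = tip[, 3],
                     magnitude = field@magnitude)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    lines <- c(".color red",
               sprintf(".arrow %.6f %.6f %.6f %.6f %.6f %.6f 0.15",
                       field@base[, 1], field@base[, 2], field@base[, 3],
                       tip[, 1], tip[, 2], tip[, 3]))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a porcupine arrow CSV back into a PorcupineField
#' @param path CSV written by [exportArrows()] with `format = "csv"`.
#' @param component,scale metadata to attach (not stored in the CSV).
#' @return A [PorcupineField-class].
#' @export
readArrowsCSV <- function(path, component = 1L, scale = 1) {
  df <- utils::read.csv(path)
  base <- as.matrix(df[, c("base_x", "base_y", "base_z")])
  tip <- as.matrix(df[, c("tip_x", "tip_y", "tip_z")])
  arrows <- tip - base
  new("PorcupineField", base = unname(base), arrows = unname(arrows),
      magnitude = sqrt(rowSums(arrows^2)), component = as.integer(component),
      scale = scale, residueIndex = as.integer(df$residue_index))
}

#' Per-residue arrow difference between two porcupine fields
#'
#' Testable counterpart of overlaying two variants' porcupine plots against a
#' common reference: reports, per residue, both magnitudes, the magnitude of
#' the arrow difference, and the angle between the arrows (degrees; NA when
#' either arrow is zero).
#'
#' @param fieldA,fieldB [PorcupineField-class] objects over the same residues.
#' @return data.frame (residue_index, magnitude_a, magnitude_b,
#'   diff_magnitude, angle_deg).
#' @export
arrowDifferenceTable <- function(fieldA, fieldB) {
  stopifnot(identical(fieldA@residueIndex, fieldB@residueIndex))
  dif <- fieldA@arrows - fieldB@arrows
  dot <- rowSums(fieldA@arrows * fieldB@arrows)
  denom <- fieldA@magnitude * fieldB@magnitude
  cosang <- ifelse(denom > 0, pmin(1, pmax(-1, dot / denom)), NA_real_)
  data.frame(residue_index = fieldA@residueIndex,
             magnitude_a = fieldA@magnitude,
             magnitude_b = fieldB@magnitude,
             diff_magnitude = sqrt(rowSums(dif^2)),
             angle_deg = acos(cosang) * 180 / pi)
}
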