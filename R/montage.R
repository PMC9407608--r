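## Built-in 10-10 montage and electrode->region mapping.

slerp <- function(a, b, f) {
  om <- acos(max(-1, min(1, sum(a * b))))
  if (om < 1e-12) return(a)
  (sin((1 - f) * om) * a + sin(f * om) * b) / sin(om)
}

#' Built-in 60-electrode 10-10 montage
#'
#' Generates unit-sphere positions for a 60-channel variant of the
#' international 10-10 system (Fp1/Fpz/Fp2 through O1/Oz/O2, mastoid
#' references excluded) from the system's geometric rules: midline electrodes
#' sit on the nasion-inion arc at 10% steps; each transverse row runs along a
#' great-circle arc from its midline point to its outermost electrode on the
#' 10% circumference circle (polar angle 72 deg from the vertex), with the
#' electrodes of a 9-electrode row at fractions 1/4, 1/2, 3/4 and 1 of the
#' half-arc. Odd-numbered electrodes are on the left (y > 0).
#'
#' @return A [Montage-class] with 60 electrodes ordered anterior to
#'   posterior, left to right.
#' @examples
#' montage1010()
#' @export
montage1010 <- function() {
  rows <- list(
    list(t = 0.1, mid = "Fpz", stem = "Fp", fr = 1, idx = 1),
    list(t = 0.2, mid = NA, stem = "AF", fr = 0.5, idx = 3),
    list(t = 0.3, mid = "Fz", stem = "F", fr = c(0.25, 0.5, 0.75, 1),
         idx = c(1, 3, 5, 7)),
    list(t = 0.4, mid = "FCz", stem = "FC", fr = c(0.25, 0.5, 0.75, 1),
         idx = c(1, 3, 5, 7), outerStem = "FT"),
    list(t = 0.5, mid = "Cz", stem = "C", fr = c(0.25, 0.5, 0.75, 1),
         idx = c(1, 3, 5, 7), outerLab = c("T7", "T8")),
    list(t = 0.6, mid = "CPz", stem = "CP", fr = c(0.25, 0.5, 0.75, 1),
         idx = c(1, 3, 5, 7), outerStem = "TP"),
    list(t = 0.7, mid = "Pz", stem = "P", fr = c(0.25, 0.5, 0.75, 1),
         idx = c(1, 3, 5, 7)),
    list(t = 0.8, mid = "POz", stem = "PO", fr = c(0.5, 0.75, 1),
         idx = c(3, 5, 7)),
    list(t = 0.9, mid = "Oz", stem = "O", fr = 1, idx = 1))
  polarOuter <- 0.4 * pi  # 72 deg: the 10% circumference circle
  labels <- character()
  pos <- NULL
  for (row in rows) {
    alpha <- (0.5 - row$t) * pi          # polar angle along the midline
    mid <- c(sin(alpha), 0, cos(alpha))
    psi <- row$t * pi                    # azimuth of the row's outer anchor
    if (!is.na(row$mid)) {
      labels <- c(labels, row$mid)
      pos <- rbind(pos, mid)
    }
    for (side in c(1, -1)) {             # +1 = left (odd), -1 = right (even)
      out <- c(sin(polarOuter) * cos(psi), side * sin(polarOuter) * sin(psi),
               cos(polarOuter))
      for (k in seq_along(row$fr)) {
        f <- row$fr[k]
        lab <- if (f == 1 && !is.null(row$outerLab)) {
          if (side == 1) row$outerLab[1] else row$outerLab[2]
        } else {
          stem <- if (f == 1 && !is.null(row$outerStem)) row$outerStem
                  else row$stem
          paste0(stem, if (side == 1) row$idx[k] else row$idx[k] + 1)
        }
        labels <- c(labels, lab)
        pos <- rbind(pos, slerp(mid, out, f))
      }
    }
  }
  pos <- pos / sqrt(rowSums(pos^2))
  ord <- order(vapply(labels, rowRank, numeric(1)),
               vapply(labels, lateralRank, numeric(1)))
  Montage(labels[ord], pos[ord, , drop = FALSE])
}

# anterior-to-posterior row rank of a 10-10 label
rowRank <- function(lab) {
  if (grepl("^Fp", lab)) 1 else
  if (grepl("^AF", lab)) 2 else
  if (grepl("^(FC|FT)", lab)) 4 else
  if (grepl("^(CP|TP)", lab)) 6 else
  if (grepl("^PO", lab)) 8 else
  if (grepl("^F", lab)) 3 else
  if (grepl("^(C|T)", lab)) 5 else
  if (grepl("^P", lab)) 7 else 9
}

# left-to-right rank within a row: odd numbers left (descending), z, even
lateralRank <- function(lab) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", lab)))
  if (is.na(num)) return(0)
  if (num %% 2 == 1) -num else num
}

#' Default electrode-to-region map
#'
#' Maps 10-10 electrode labels onto nine scalp regions by label prefix:
#' `Fp*` pre-frontal; `AF*`, `F<digit>`, `Fz` frontal; `FC*` fronto-central;
#' `C<digit>`, `Cz` central; `CP*` central-parietal; `P<digit>`, `Pz`
#' parietal; `PO*` parietal-occipital; `O*` occipital; `FT*`, `T<digit>`,
#' `TP*` temporal.
#'
#' @param labels electrode labels to map.
#' @return Named character vector: label -> region.
#' @seealso [anteriorRegions()], [posteriorRegions()], [readRegionMap()]
#' @export
defaultRegionMap <- function(labels) {
  rules <- list(
    c("^Fp", "pre-frontal"),
    c("^AF", "frontal"),
    c("^(FT|TP|T[0-9])", "temporal"),
    c("^FC", "fronto-central"),
    c("^CP", "central-parietal"),
    c("^PO", "parietal-occipital"),
    c("^F([0-9]|z)", "frontal"),
    c("^C([0-9]|z)", "central"),
    c("^P([0-9]|z)", "parietal"),
    c("^O", "occipital"))
  out <- rep(NA_character_, length(labels))
  for (r in rules) {
    hit <- is.na(out) & grepl(r[1], labels)
    out[hit] <- r[2]
  }
  if (anyNA(out))
    stop("no region rule matches label(s): ",
         paste(labels[is.na(out)], collapse = ", "))
  stats::setNames(out, labels)
}

#' Anterior and posterior region groups
#'
#' Anterior = pre-frontal, frontal, fronto-central; posterior = parietal,
#' parietal-occipital, occipital.
#'
#' @return Character vector of region names.
#' @export
anteriorRegions <- function() c("pre-frontal", "frontal", "fronto-central")

#' @rdname anteriorRegions
#' @export
posteriorRegions <- function() c("parietal", "parietal-occipital", "occipital")

#' Read a montage position file
#'
#' Accepts a whitespace-separated text table with either three columns
#' `label theta phi` (spherical, degrees: theta = polar angle from the
#' vertex, phi = azimuth from the anterior midline, positive left) or four
#' columns `label x y z` (unit vectors; re-normalised on read).
#'
#' @param path file path.
#' @return A [Montage-class].
#' @export
readMontage <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) == 3) {
    th <- tab[[2]] * pi / 180
    ph <- tab[[3]] * pi / 180
    pos <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  } else if (ncol(tab) == 4) {
    pos <- as.matrix(tab[, 2:4])
    pos <- pos / sqrt(rowSums(pos^2))
  } else {
    stop("montage file must have 3 (label theta phi) or 4 (label x y z) columns")
  }
  Montage(tab[[1]], pos)
}

#' Read an electrode-to-region map file
#'
#' @param path tab-separated file with columns `label` and `region`.
#' @return Named character vector: label -> region.
#' @export
readRegionMap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab[[2]], tab[[1]])
}
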