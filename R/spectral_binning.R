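#' Construct a shift record
#'
#' A shift record holds the predicted chemical shifts of one nucleus
#' (\code{"C13"} or \code{"N15"}) for one compound. Nitrogen-free compounds
#' are represented by an empty shift vector (or by simply omitting the
#' record); they receive all-zero nitrogen features downstream.
#'
#' @param compound_id Opaque compound identifier (single string).
#' @param nucleus Either \code{"C13"} or \code{"N15"}.
#' @param shifts_ppm Numeric vector of chemical shifts in ppm. May be empty.
#' @return An object of class \code{"shift_record"}.
#' @examples
#' shift_record("mol1", "C13", c(12.3, 45.7, 128.1))
#' @export
shift_record <- function(compound_id, nucleus, shifts_ppm = numeric()) {
  nucleus <- match.arg(nucleus, c("C13", "N15"))
  if (!is.character(compound_id) || length(compound_id) != 1L || is.na(compound_id)) {
    stop("compound_id must be a single non-missing string")
  }
  shifts_ppm <- as.numeric(shifts_ppm)
  if (length(shifts_ppm) && any(!is.finite(shifts_ppm))) {
    stop(sprintf("non-finite chemical shift for compound '%s'", compound_id))
  }
  structure(
    list(compound_id = compound_id, nucleus = nucleus, shifts_ppm = shifts_ppm),
    class = "shift_record"
  )
}

#' Define a spectral bin grid
#'
#' Bins are half-open, lower-edge-inclusive intervals
#' \eqn{[k w + o, (k+1) w + o)} tiling the ppm axis, anchored at the origin
#' (0 ppm by default). The schemes used for CYP modeling pair carbon widths
#' of 1, 2, 3 ppm with nitrogen widths of 5, 10, 15 ppm (C1&N5, C2&N10,
#' C3&N15); other widths are accepted with a warning.
#'
#' @param nucleus \code{"C13"} or \code{"N15"}.
#' @param width_ppm Positive bin width in ppm.
#' @param origin_ppm Lower edge of bin 0 (default 0).
#' @return An object of class \code{"bin_grid"}.
#' @export
bin_grid <- function(nucleus, width_ppm, origin_ppm = 0) {
  nucleus <- match.arg(nucleus, c("C13", "N15"))
  stopifnot(is.numeric(width_ppm), length(width_ppm) == 1L, width_ppm > 0)
  supported <- if (nucleus == "C13") c(1, 2, 3) else c(5, 10, 15)
  if (!width_ppm %in% supported) {
    warning(sprintf("unusual %s bin width %g ppm (standard schemes use %s)",
                    nucleus, width_ppm, paste(supported, collapse = "/")))
  }
  structure(
    list(nucleus = nucleus, width_ppm = width_ppm, origin_ppm = origin_ppm),
    class = "bin_grid"
  )
}

# Index of the half-open interval a shift falls in: k such that
# k*w + origin <= x < (k+1)*w + origin. Edge shifts belong to the interval
# whose lower edge they equal; guard floating-point edge cases explicitly.
bin_index <- function(shifts, grid) {
  k <- floor((shifts - grid$origin_ppm) / grid$width_ppm)
  upper <- (k + 1) * grid$width_ppm + grid$origin_ppm
  k <- ifelse(shifts >= upper, k + 1, k)
  lower <- k * grid$width_ppm + grid$origin_ppm
  k <- ifelse(shifts < lower, k - 1, k)
  as.integer(k)
}

# "C1 (45)" for unit-width carbon bins, "C3 (48-51)" / "N5 (235-240)"
# (en dash) otherwise; the prefix is the nucleus letter plus the width.
bin_label <- function(nucleus, width, k, origin = 0) {
  lo <- k * width + origin
  prefix <- paste0(if (nucleus == "C13") "C" else "N", fmt_num(width))
  if (width == 1) {
    sprintf("%s (%s)", prefix, fmt_num(lo))
  } else {
    sprintf("%s (%s–%s)", prefix, fmt_num(lo), fmt_num(lo + width))
  }
}

fmt_num <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

#' Bin one compound's shifts on a grid
#'
#' Each shift increments exactly one bin; the counts therefore sum to the
#' number of shifts. Only occupied bins are returned (a sparse
#' representation): a named integer vector labelled in the
#' \code{"C3 (48–51)"} style.
#'
#' @param record A [shift_record()].
#' @param grid A [bin_grid()] for the same nucleus.
#' @return Named integer vector of counts over the occupied bins, with
#'   attribute \code{"bin_index"} holding the integer bin indices.
#' @export
bin_shifts <- function(record, grid) {
  stopifnot(inherits(record, "shift_record"), inherits(grid, "bin_grid"))
  if (record$nucleus != grid$nucleus) {
    stop(sprintf("grid nucleus %s does not match record nucleus %s",
                 grid$nucleus, record$nucleus))
  }
  if (length(record$shifts_ppm) == 0L) {
    return(structure(integer(0), names = character(0), bin_index = integer(0)))
  }
  k <- bin_index(record$shifts_ppm, grid)
  tab <- table(k)
  idx <- as.integer(names(tab))
  counts <- as.integer(tab)
  names(counts) <- bin_label(grid$nucleus, grid$width_ppm, idx, grid$origin_ppm)
  attr(counts, "bin_index") <- idx
  counts
}

#' Build a compounds-by-bins occupancy matrix
#'
#' Converts a list of shift records into the SDAR feature matrix: the carbon
#' block (ascending ppm) concatenated with the nitrogen block. Bins that are
#' empty across every compound are dropped from the "available" columns; the
#' dropped labels are kept in the metadata so the selected/available
#' accounting stays honest. Counts are raw integers (occupancies above one
#' per compound are retained, not binarized).
#'
#' @param records List of [shift_record()] objects; a compound may contribute
#'   one record per nucleus. Compounds appearing only with a carbon record
#'   get all-zero nitrogen features and vice versa.
#' @param labels Binary activity labels (inhibitor = 1): either a named
#'   vector (names = compound ids) or a data.frame with columns
#'   \code{compound_id}, \code{label}.
#' @param c_width,n_width Carbon/nitrogen bin widths in ppm.
#' @param origin_ppm Shared grid origin (default 0).
#' @return An object of class \code{"occupancy_matrix"}: a list with
#'   \code{counts} (integer matrix, rownames = compound ids, colnames = bin
#'   labels), \code{labels} (integer 0/1 per compound), and \code{meta}
#'   (widths, origin, per-column nucleus, dropped empty-bin labels).
#' @export
build_occupancy_matrix <- function(records, labels, c_width = 3, n_width = 15,
                                   origin_ppm = 0) {
  stopifnot(length(records) > 0L)
  ids <- vapply(records, function(r) r$compound_id, character(1))
  nuc <- vapply(records, function(r) r$nucleus, character(1))
  if (anyDuplicated(paste(ids, nuc))) {
    dup <- ids[duplicated(paste(ids, nuc))][1L]
    stop(sprintf("duplicate record for compound '%s'", dup))
  }
  compound_ids <- unique(ids)
  y <- canonical_labels(labels, compound_ids)

  grids <- list(C13 = bin_grid("C13", c_width, origin_ppm),
                N15 = bin_grid("N15", n_width, origin_ppm))
  # standard spectral spans; out-of-range shifts extend the grid as needed
  span <- list(C13 = c(0, 240), N15 = c(0, 600))

  blocks <- lapply(c("C13", "N15"), function(nu) {
    grid <- grids[[nu]]
    sub <- records[nuc == nu]
    sub_ids <- ids[nuc == nu]
    binned <- lapply(sub, bin_shifts, grid = grid)
    k_lo <- bin_index(span[[nu]][1], grid)
    k_hi <- bin_index(span[[nu]][2] - 1e-9, grid)
    occupied <- unlist(lapply(binned, attr, "bin_index"))
    if (length(occupied)) {
      k_lo <- min(k_lo, min(occupied))
      k_hi <- max(k_hi, max(occupied))
    }
    ks <- seq.int(k_lo, k_hi)
    m <- matrix(0L, nrow = length(compound_ids), ncol = length(ks),
                dimnames = list(compound_ids,
                                bin_label(nu, grid$width_ppm, ks, origin_ppm)))
    for (i in seq_along(sub)) {
      v <- binned[[i]]
      if (length(v)) {
        m[sub_ids[i], match(attr(v, "bin_index"), ks)] <- as.integer(v)
      }
    }
    m
  })
  counts <- cbind(blocks[[1]], blocks[[2]])
  nucleus_of <- rep(c("C13", "N15"), times = c(ncol(blocks[[1]]), ncol(blocks[[2]])))

  empty <- colSums(counts) == 0L
  dropped <- colnames(counts)[empty]
  counts <- counts[, !empty, drop = FALSE]
  nucleus_of <- nucleus_of[!empty]

  structure(
    list(
      counts = counts,
      labels = y,
      meta = list(c_width = c_width, n_width = n_width,
                  origin_ppm = origin_ppm, nucleus = nucleus_of,
                  dropped_empty_bins = dropped)
    ),
    class = "occupancy_matrix"
  )
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("occupancy_matrix: %d compounds x %d available bins (C%g & N%g)\n",
              nrow(x$counts), ncol(x$counts), x$meta$c_width, x$meta$n_width))
  cat(sprintf("  positives (inhibitors): %d of %d; %d empty bins dropped\n",
              sum(x$labels == 1L), length(x$labels),
              length(x$meta$dropped_empty_bins)))
  invisible(x)
}

#' Per-class mean bin occupancy
#'
#' Mean occupancy is reported scaled by 100: a value of 100 means one
#' chemical shift in that ppm range for every compound of the class; values
#' above 100 arise when compounds carry several shifts in the range.
#'
#' @param x An [build_occupancy_matrix()] result.
#' @return A data.frame with columns \code{bin}, \code{mean_occupancy_0}
#'   (non-inhibitors) and \code{mean_occupancy_1} (inhibitors).
#' @export
class_mean_occupancy <- function(x) {
  stopifnot(inherits(x, "occupancy_matrix"))
  if (!all(c(0L, 1L) %in% x$labels)) {
    stop("both classes must be non-empty to compute class means")
  }
  m0 <- 100 * colMeans(x$counts[x$labels == 0L, , drop = FALSE])
  m1 <- 100 * colMeans(x$counts[x$labels == 1L, , drop = FALSE])
  data.frame(bin = colnames(x$counts), mean_occupancy_0 = unname(m0),
             mean_occupancy_1 = unname(m1), stringsAsFactors = FALSE)
}

# Accepts a named 0/1 vector or a (compound_id, label) data.frame and
# returns an integer 0/1 vector aligned with compound_ids.
canonical_labels <- function(labels, compound_ids) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("compound_id", "label") %in% names(labels)))
    labels <- stats::setNames(labels$label, labels$compound_id)
  }
  if (is.null(names(labels))) {
    if (length(labels) != length(compound_ids)) {
      stop("unnamed labels must match the number of compounds")
    }
    names(labels) <- compound_ids
  }
  missing <- setdiff(compound_ids, names(labels))
  if (length(missing)) {
    stop(sprintf("missing labels for compounds: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  }
  y <- as.integer(labels[compound_ids])
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1 (inhibitor = 1)")
  stats::setNames(y, compound_ids)
}
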