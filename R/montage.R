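#' Default 31-channel 10-10 montage
#'
#' A 31-label scalp montage arranged in seven longitudinal rows from
#' occipital to prefrontal, used as the package default for simulation,
#' region parcellation and the neighboring-electrode QC. Any other montage
#' can be supplied wherever channel labels are accepted; this one exists so
#' the simulator and the region map have a concrete, documented geometry.
#'
#' @return Character vector of 31 channel labels, ordered back to front and
#'   left to right within a row.
#' @export
#' @examples
#' default_montage()
default_montage <- function() {
  c("O1", "Oz", "O2",
    "P7", "P3", "Pz", "P4", "P8",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "T7", "C3", "Cz", "C4", "T8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "F7", "F3", "Fz", "F4", "F8",
    "Fp1", "Fpz", "Fp2")
}

# Planar grid coordinates (row = longitudinal band 1..7 from occipital,
# col = lateral position, 0 = midline) for the default montage. Used to
# derive montage adjacency; approximate but adequate for neighbor QC.
montage_grid <- function(labels = default_montage()) {
  rows <- list(
    c("O1", "Oz", "O2"),
    c("P7", "P3", "Pz", "P4", "P8"),
    c("TP7", "CP3", "CPz", "CP4", "TP8"),
    c("T7", "C3", "Cz", "C4", "T8"),
    c("FT7", "FC3", "FCz", "FC4", "FT8"),
    c("F7", "F3", "Fz", "F4", "F8"),
    c("Fp1", "Fpz", "Fp2")
  )
  coord <- do.call(rbind, lapply(seq_along(rows), function(r) {
    labs <- rows[[r]]
    ncol_r <- length(labs)
    cols <- seq_len(ncol_r) - (ncol_r + 1) / 2
    if (ncol_r == 3) cols <- cols  # -1, 0, 1
    data.frame(label = labs, row = r, col = cols, stringsAsFactors = FALSE)
  }))
  missing <- setdiff(labels, coord$label)
  if (length(missing))
    stop("no grid coordinates for channel(s): ", paste(missing, collapse = ", "))
  coord[match(labels, coord$label), , drop = FALSE]
}

#' Default region parcellation of the montage
#'
#' Assigns the montage channels to seven longitudinal scalp regions
#' (occipital to prefrontal): O, P, Cp, C, Fc, F, Fp. Regions are disjoint
#' and jointly cover the montage; each spans both hemispheres.
#'
#' @param labels Channel labels to parcellate (default [default_montage()]).
#' @return Named list mapping region name to a character vector of channel
#'   labels (class `"region_map"`).
#' @export
#' @examples
#' names(default_region_map())
default_region_map <- function(labels = default_montage()) {
  grid <- montage_grid(labels)
  region_names <- c("O", "P", "Cp", "C", "Fc", "F", "Fp")
  map <- lapply(seq_len(7), function(r) grid$label[grid$row == r])
  names(map) <- region_names
  map <- map[vapply(map, length, 1L) > 0]
  structure(map, class = "region_map")
}

validate_region_map <- function(map, labels) {
  all_ch <- unlist(map, use.names = FALSE)
  if (anyDuplicated(all_ch))
    stop("region map assigns some channel to more than one region")
  missing <- setdiff(labels, all_ch)
  if (length(missing))
    stop("region map does not cover channel(s): ", paste(missing, collapse = ", "))
  invisible(map)
}

#' Montage adjacency pairs
#'
#' Pairs of spatially neighboring electrodes in the default-montage grid:
#' two channels are neighbors when their grid distance (longitudinal row,
#' lateral column) does not exceed 1.5 units, i.e. horizontal, vertical and
#' diagonal nearest neighbors.
#'
#' @param labels Channel labels (default montage).
#' @return Two-column character matrix; one row per unordered neighbor pair.
#' @export
montage_adjacency <- function(labels = default_montage()) {
  grid <- montage_grid(labels)
  n <- nrow(grid)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt((grid$row[pairs[, 1]] - grid$row[pairs[, 2]])^2 +
            (grid$col[pairs[, 1]] - grid$col[pairs[, 2]])^2)
  keep <- d <= 1.5
  cbind(grid$label[pairs[keep, 1]], grid$label[pairs[keep, 2]])
}
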