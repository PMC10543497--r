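#' Tissuetype label codes
#'
#' Integer codes used in [tissue_labels()] maps. `Background` (0) marks
#' voxels outside the brain mask; every in-mask voxel carries exactly one of
#' the other eight codes.
#'
#' @format Named integer vector of length 9.
#' @export
TISSUE_CODES <- c(
  Background = 0L,
  GM         = 1L,
  WM         = 2L,
  Fluid      = 3L,
  BV         = 4L,
  CE         = 5L,
  Edema1     = 6L,
  Edema2     = 7L,
  Hemorrhage = 8L
)

#' Display colors for tissuetype maps
#'
#' The conventional colormap: red = blood vessel, yellow = contrast-enhancing
#' tumor, brown = Edema1, cyan = Edema2, purple = hemorrhage, blue = fluid,
#' dark green = gray matter, off-white = white matter.
#'
#' @format Named character vector of hex colors.
#' @export
TISSUE_COLORS <- c(
  Background = "#000000",
  GM         = "#006400",
  WM         = "#F5F5EB",
  Fluid      = "#0000FF",
  BV         = "#FF0000",
  CE         = "#FFFF00",
  Edema1     = "#8B4513",
  Edema2     = "#00FFFF",
  Hemorrhage = "#800080"
)

tissue_name <- function(code) names(TISSUE_CODES)[match(code, TISSUE_CODES)]

#' Write a plain-text legend mapping label integers to tissuetype names
#'
#' Written as a sidecar beside every label-map NIfTI so downstream viewers
#' can decode the integer codes.
#'
#' @param path Output text file path.
#' @return `path`, invisibly.
#' @export
write_label_legend <- function(path) {
  df <- data.frame(
    code = unname(TISSUE_CODES),
    tissuetype = names(TISSUE_CODES),
    color = unname(TISSUE_COLORS[names(TISSUE_CODES)])
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
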