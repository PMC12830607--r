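# Nucleus counting and cell density per tissue compartment. Nuclei are
# connected components of the nucleus label; each is assigned to the
# compartment of the tissue immediately surrounding its centroid. Touching
# nuclei are not split (no watershed) -- adequate for the synthetic rasters,
# a documented limitation for real H&E material.

nucleus_components <- function(image, min_area_px) {
  codes <- label_codes()
  nuc <- image$labels == codes[["nucleus"]]
  if (!any(nuc))
    return(tibble(row = numeric(), col = numeric(), area_px = integer(),
                  compartment = character()))
  comp <- EBImage::bwlabel(nuc)
  ids <- seq_len(max(comp))
  areas <- tabulate(comp[comp > 0], nbins = max(comp))
  idx <- which(comp > 0, arr.ind = TRUE)
  lab_of <- comp[comp > 0]
  cent_r <- tapply(idx[, 1], lab_of, mean)
  cent_c <- tapply(idx[, 2], lab_of, mean)
  keep <- ids[areas >= min_area_px]

  lab <- image$labels
  H <- nrow(lab); W <- ncol(lab)
  tissue <- c(codes[["stroma"]], codes[["epithelium"]])
  # compartment of the nearest non-nucleus tissue pixel around the centroid
  assign_comp <- function(r0, c0) {
    for (rad in 0:50) {
      rr <- max(1, round(r0) - rad):min(H, round(r0) + rad)
      cc <- max(1, round(c0) - rad):min(W, round(c0) + rad)
      sub <- lab[rr, cc, drop = FALSE]
      hit <- sub[sub %in% tissue]
      if (length(hit))
        return(names(codes)[match(
          as.integer(names(sort(table(hit), decreasing = TRUE))[1]), codes)])
    }
    NA_character_
  }
  tibble(
    row = as.numeric(cent_r[as.character(keep)]),
    col = as.numeric(cent_c[as.character(keep)]),
    area_px = areas[keep],
    compartment = vapply(keep, function(k)
      assign_comp(cent_r[[as.character(k)]], cent_c[[as.character(k)]]),
      character(1))
  )
}

#' Count nuclei within a tissue compartment
#'
#' Nuclei are connected components of the nucleus label whose centroid lies
#' inside the given compartment; components below `min_area_px` are discarded
#' as noise.
#'
#' @param image a [labeled_image()].
#' @param compartment `"stroma"` or `"epithelium"`.
#' @param min_area_px minimum component area retained, default 4 px.
#' @return Integer count, with attribute `centroids` (tibble row/col).
#' @export
count_nuclei <- function(image, compartment = c("stroma", "epithelium"),
                         min_area_px = 4) {
  stopifnot(inherits(image, "labeled_image"))
  compartment <- match.arg(compartment)
  codes <- label_codes()
  if (!any(image$labels == codes[[compartment]]))
    stopf("compartment '%s' absent from image", compartment)
  comps <- nucleus_components(image, min_area_px)
  inside <- comps[!is.na(comps$compartment) &
                    comps$compartment == compartment, ]
  structure(nrow(inside), centroids = inside[c("row", "col")])
}

#' Cell density of a tissue compartment
#'
#' Density = nucleus count / compartment area. The compartment area includes
#' the pixels occupied by its own nuclei (nucleus disks overwrite the tissue
#' label when rasterized), converted as
#' `area_mm2 = pixels * um_per_px^2 / 1e6`.
#'
#' @inheritParams count_nuclei
#' @return One-row tibble: `compartment`, `area_mm2`, `cell_count`,
#'   `density_per_mm2`.
#' @export
cell_density <- function(image, compartment = c("stroma", "epithelium"),
                         min_area_px = 4) {
  stopifnot(inherits(image, "labeled_image"))
  compartment <- match.arg(compartment)
  codes <- label_codes()
  comp_px <- sum(image$labels == codes[[compartment]])
  if (comp_px == 0) stopf("compartment '%s' absent from image", compartment)
  comps <- nucleus_components(image, min_area_px)
  own <- comps[!is.na(comps$compartment) & comps$compartment == compartment, ]
  nuc_px <- sum(own$area_px)
  area_mm2 <- (comp_px + nuc_px) * image$um_per_px^2 / 1e6
  if (area_mm2 <= 0) stopf("zero-area compartment '%s'", compartment)
  tibble(compartment = compartment,
         area_mm2 = area_mm2,
         cell_count = nrow(own),
         density_per_mm2 = nrow(own) / area_mm2)
}
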