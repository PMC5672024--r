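#' Write a two-channel image as a multi-page TIFF
#'
#' Page 1 holds the nuclear-stain channel, page 2 the GR channel, stored as
#' 16-bit integers. Intensities must fit in `[0, 65535]`.
#'
#' @param nuclear,gr numeric intensity matrices, same dimensions.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_translocation_tiff <- function(nuclear, gr, path) {
  stopifnot(all(dim(nuclear) == dim(gr)),
            min(nuclear) >= 0, min(gr) >= 0,
            max(nuclear) <= 65535, max(gr) <= 65535)
  tiff::writeTIFF(list(nuclear / 65535, gr / 65535), path,
                  bits.per.sample = 16)
  invisible(path)
}

#' Read a two-channel translocation TIFF
#'
#' Inverse of [write_translocation_tiff()]: reads a two-page 16-bit TIFF
#' and returns the channels on the original intensity scale.
#'
#' @param path TIFF path.
#' @param nuclear_page page index of the nuclear-stain channel (default 1;
#'   the GR channel is the other page).
#' @return list with matrices `nuclear` and `gr`.
#' @export
read_translocation_tiff <- function(path, nuclear_page = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a two-page TIFF")
  gr_page <- if (nuclear_page == 1L) 2L else 1L
  list(nuclear = pages[[nuclear_page]] * 65535,
       gr = pages[[gr_page]] * 65535)
}

#' Write ground-truth pixel masks as a long CSV
#'
#' One row per truth pixel with columns `cell_id`, `row`, `col`,
#' `compartment` (`nucleus` or `cytoplasm`), 0-based pixel coordinates.
#'
#' @param truth the `truth` element of [gen_translocation_image()] output.
#' @param shape image dimensions (rows, cols).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, shape, path) {
  rows <- lapply(truth, function(t) {
    idx <- c(t$nucleus_idx, t$cyto_idx)
    data.frame(
      cell_id = t$cell_id,
      row = (idx - 1L) %% shape[1],
      col = (idx - 1L) %/% shape[1],
      compartment = rep(c("nucleus", "cytoplasm"),
                        c(length(t$nucleus_idx), length(t$cyto_idx)))
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
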