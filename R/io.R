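# Plain-text / TIFF interchange for the pipeline's containers.

#' Read and write trajectory tables
#'
#' Trajectory CSVs carry one row per (track, frame) with columns
#' `track_id`, `frame`, `t_hours`, `x_um`, `y_um`.
#'
#' @param tracks a `trajectory_set` data frame.
#' @param path CSV file path.
#' @return `read_tracks` returns a `trajectory_set`; `write_tracks` its
#'   path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- utils::read.csv(path)
  need <- c("track_id", "frame", "t_hours", "x_um", "y_um")
  if (!all(need %in% names(out)))
    stop_param("trajectory CSV needs columns: ", paste(need, collapse = ", "))
  class(out) <- c("trajectory_set", "data.frame")
  out
}

#' Read and write binary mask stacks
#'
#' Stacks are stored as multi-page 8-bit TIFF (0/255) with a JSON sidecar
#' `<path>.json` holding `pixel_size_um`, `frame_interval_h` and `gap_axis`.
#'
#' @param stack a [mask_stack()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `read_mask_stack` returns a [mask_stack()]; `write_mask_stack`
#'   its path, invisibly.
#' @export
write_mask_stack <- function(stack, path) {
  if (!inherits(stack, "mask_stack")) stop_param("expected a mask_stack")
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(i) stack$frames[, , i] * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size,
                            frame_interval_h = stack$frame_interval,
                            gap_axis = stack$gap_axis),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_stack
#' @export
read_mask_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0L, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- (pages[[i]] > 0.5) * 1L
  mask_stack(frames, pixel_size = meta$pixel_size_um,
             frame_interval = meta$frame_interval_h,
             gap_axis = meta$gap_axis %||% "x")
}

#' Read and write long-format ECM adhesion tables
#'
#' CSV with columns `condition`, `composition`, `replicate`, `count`.
#'
#' @param x an `adhesion_matrix` data frame.
#' @param path CSV file path.
#' @export
write_ecm <- function(x, path) {
  check_adhesion(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecm
#' @export
read_ecm <- function(path) {
  out <- utils::read.csv(path)
  check_adhesion(out)
  class(out) <- c("adhesion_matrix", "data.frame")
  out
}

#' Read and write count matrices with gene lengths
#'
#' TSV with columns `gene_id`, `length_bp`, then one column per sample.
#'
#' @param counts genes x samples matrix (rownames = gene ids).
#' @param gene_lengths lengths in bp, one per gene.
#' @param path TSV file path.
#' @return `read_counts` returns a list with `counts` and `gene_lengths`;
#'   `write_counts` its path, invisibly.
#' @export
write_counts <- function(counts, gene_lengths, path) {
  df <- data.frame(gene_id = rownames(counts), length_bp = gene_lengths,
                   as.data.frame(counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(df)))
    stop_param("counts TSV needs gene_id and length_bp columns")
  counts <- as.matrix(df[setdiff(names(df), c("gene_id", "length_bp"))])
  rownames(counts) <- df$gene_id
  list(counts = counts, gene_lengths = df$length_bp)
}
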