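#' Write / read an image stack as multi-frame TIFF
#'
#' Stacks are stored as 32-bit float frames scaled to \[0, 1\], with the
#' scale factor recorded in a JSON sidecar (`<path>.json`) so intensities
#' round-trip exactly up to float precision.
#'
#' @param stack 3-D array (height x width x frames).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (length(dim(stack)) != 3) stop("stack must be a 3-D array")
  lo <- min(stack); hi <- max(stack)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(f) (stack[, , f] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  jsonlite::write_json(list(offset = lo, scale = scale,
                            dim = dim(stack)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @return for `read_stack_tiff`, the 3-D array.
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    arr[, , f] <- m
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    arr <- arr * meta$scale + meta$offset
  }
  arr
}

#' Write / read a spot table as CSV
#'
#' Columns `frame`, `x_px`, `y_px`, `intensity`.
#' @param spots spot data.frame.
#' @param path CSV path.
#' @export
write_spot_table <- function(spots, path) {
  write.csv(spots[, c("frame", "x_px", "y_px", "intensity")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) read.csv(path)

#' Write / read a kymograph as delimited text plus a JSON metadata sidecar
#'
#' @param kymo a `kymograph`.
#' @param path TSV path (bins x frames); metadata goes to `<path>.json`.
#' @export
write_kymograph <- function(kymo, path) {
  utils::write.table(kymo$intensity, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(bin_width_px = kymo$bin_width_px,
                            pixel_size_um = kymo$pixel_size_um,
                            frame_interval_s = kymo$frame_interval_s),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(intensity = m, count = NULL,
                 bin_width_px = meta$bin_width_px,
                 bin_width_um = meta$bin_width_px * meta$pixel_size_um,
                 pixel_size_um = meta$pixel_size_um,
                 frame_interval_s = meta$frame_interval_s),
            class = "kymograph")
}

#' Write / read a count matrix in MatrixMarket layout
#'
#' One directory per condition/replicate, CellRanger-style: `matrix.mtx`
#' (genes x cells), `genes.tsv` (id, category), `barcodes.tsv`, and
#' `cell_meta.tsv` with the per-cell metadata.
#'
#' @param x a `count_matrix`.
#' @param dir output directory (created if needed).
#' @export
write_counts_mtx <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(x$counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(x$gene_meta, file.path(dir, "genes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(x$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(counts) <- list(genes[[1]], barcodes)
  meta_path <- file.path(dir, "cell_meta.tsv")
  cell_meta <- if (file.exists(meta_path)) {
    utils::read.table(meta_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else {
    data.frame(barcode = barcodes)
  }
  gene_meta <- data.frame(gene = genes[[1]],
                          category = if (ncol(genes) > 1) genes[[2]] else NA,
                          stringsAsFactors = FALSE)
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta), class = "count_matrix")
}

#' Write / read a simulation configuration as YAML
#'
#' @param cfg a `niche_config`, `colony_config` or `counts_config`.
#' @param path YAML path.
#' @export
write_config_yaml <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$.config_class <- class(cfg)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.config_class
  obj$.config_class <- NULL
  maker <- switch(cls,
    niche_config = niche_config,
    colony_config = colony_config,
    counts_config = counts_config,
    stop_config("unknown config class: %s", cls)
  )
  do.call(maker, obj[intersect(names(obj), names(formals(maker)))])
}

#' @importFrom methods as
NULL
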