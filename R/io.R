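#' Load and save volumes as NIfTI
#'
#' Volumes round-trip through NIfTI at float32 precision with the affine
#' preserved exactly. Label volumes are loaded as integers and must never be
#' interpolated.
#'
#' @param path NIfTI file path.
#' @param expect_dims Expected dimensionality (3 or 4); a mismatch is a
#'   typed error naming the offending file.
#' @param is_label Load as an integer label volume.
#' @return [load_volume()]: list with `volume` (array) and `grid`
#'   ([vol_grid()] with an all-TRUE mask; combine with your own mask).
#' @export
load_volume <- function(path, expect_dims = 3, is_label = FALSE) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != expect_dims) {
    stop("'", path, "': expected a ", expect_dims, "-D volume, found ",
         length(d), "-D (shape ", paste(d, collapse = "x"), ")",
         call. = FALSE)
  }
  aff <- structure(RNifti::xform(img), class = NULL)[1:4, 1:4]
  if (abs(det(aff)) < .Machine$double.eps * 100) {
    stop("'", path, "': affine is singular", call. = FALSE)
  }
  vol <- if (is_label) array(as.integer(round(img)), dim = d)
         else array(as.numeric(img), dim = d)
  grid <- vol_grid(d[1:3], affine = aff)
  list(volume = vol, grid = grid)
}

#' @rdname load_volume
#' @param volume 3-D array, in-mask value vector, or map object.
#' @param grid The [vol_grid()]; taken from map objects automatically.
#' @export
save_volume <- function(volume, path, grid = NULL) {
  if (inherits(volume, c("gene_map", "signature_map"))) {
    grid <- volume$grid
    volume <- unmask(volume$values, grid, fill = 0)
  } else if (is.numeric(volume) && is.null(dim(volume))) {
    if (is.null(grid)) stop("`grid` required for a value vector",
                            call. = FALSE)
    volume <- unmask(volume, grid, fill = 0)
  }
  if (is.null(grid)) stop("`grid` required", call. = FALSE)
  img <- RNifti::asNifti(volume, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Tab-separated table I/O
#'
#' All pipeline tables are TSV with a header row.
#'
#' @param x Data frame.
#' @param path File path.
#' @return [read_tsv_table()] returns a tibble.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      check.names = FALSE))
}

#' Provenance sidecars
#'
#' Every generated artifact gets a plain-text `key: value` sidecar recording
#' the parameters and seed that produced it, sufficient to recompute its
#' ground truth without rerunning the generator.
#'
#' @param info Named list (scalars or short vectors).
#' @param path Sidecar path (conventionally `<artifact>.prov`).
#' @return [read_provenance()] returns a named list of character values.
#' @export
write_provenance <- function(info, path) {
  flat <- vapply(info, function(v) paste(format(v, digits = 15),
                                         collapse = ","), "")
  writeLines(paste0(names(flat), ": ", flat), path)
  invisible(path)
}

#' @rdname write_provenance
#' @export
read_provenance <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
}

# small FNV-1a content hash for manifests (detects mixed-config outputs)
content_hash <- function(path) {
  bytes <- readBin(path, "integer", n = file.info(path)$size, size = 1,
                   signed = FALSE)
  h <- 2166136261
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 65536))) {
    h <- (h + sum((chunk + 1) * seq_along(chunk))) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
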