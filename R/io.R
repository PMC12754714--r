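# NIfTI and tabular input/output.

#' Read masked NIfTI images into a response matrix
#'
#' Applies a binary mask to a set of participant volumes (one file per
#' participant, or a single 4-D file) and flattens them to an `N` by `V`
#' matrix with a spatial domain built from the masked voxel coordinates.
#'
#' @param paths character vector of NIfTI files, or one 4-D file.
#' @param mask_path binary mask volume on the same grid.
#' @param coords `"index"` (voxel indices, default) or `"mm"` (apply the
#'   mask affine).
#' @return List with `Y` (`N` by `V`) and `domain` ([spatial_domain()]
#'   carrying the grid geometry for [write_maps()]).
#' @export
read_images <- function(paths, mask_path, coords = c("index", "mm")) {
  coords <- match.arg(coords)
  mask_img <- RNifti::readNifti(mask_path)
  mask <- as.array(mask_img) > 0
  if (!any(mask)) stop("empty mask")
  mdim <- dim(mask)
  idx <- which(mask)
  co <- arrayInd(idx, mdim)
  if (coords == "mm") {
    aff <- RNifti::xform(mask_img)
    co <- t(aff %*% rbind(t(co) - 1, 1))[, seq_along(mdim), drop = FALSE]
  }
  imgs <- lapply(paths, RNifti::readNifti)
  ref_x <- RNifti::xform(imgs[[1]])
  rows <- list()
  for (k in seq_along(imgs)) {
    a <- as.array(imgs[[k]])
    if (!isTRUE(all.equal(dim(a)[seq_along(mdim)], mdim, check.attributes = FALSE)))
      stop(sprintf("grid mismatch for '%s'", paths[k]))
    if (max(abs(RNifti::xform(imgs[[k]]) - ref_x)) > 1e-4)
      stop(sprintf("affine mismatch for '%s'", paths[k]))
    if (length(dim(a)) == length(mdim)) {
      rows[[length(rows) + 1L]] <- a[idx]
    } else {                      # 4-D: one volume per participant
      n4 <- dim(a)[length(dim(a))]
      flat <- matrix(a, prod(mdim), n4)
      for (t in seq_len(n4)) rows[[length(rows) + 1L]] <- flat[idx, t]
    }
  }
  Y <- do.call(rbind, rows)
  dom <- spatial_domain(co, grid = list(dim = mdim, mask_idx = idx,
                                        reference = mask_path))
  list(Y = Y, domain = dom)
}

#' Write per-location maps back to NIfTI volumes
#'
#' Each map is embedded into the source grid recorded in the domain
#' (unmasked voxels 0, or `NA` with `background = NA`) and written as one
#' file per map.  Evidence maps are clamped to `[-1, 1]`; logical maps are
#' written as 0/1 integer volumes.
#'
#' @param maps named list of length-V numeric or logical vectors, or a
#'   [summary.bsir()] object (writes `mean`, `sd`, `p_plus`, `es`,
#'   `active` per covariate).
#' @param domain a [spatial_domain()] with grid geometry.
#' @param out_dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param background value outside the mask (default 0).
#' @return Invisibly, the written file paths.
#' @export
write_maps <- function(maps, domain, out_dir, prefix = "map",
                       background = 0) {
  stopifnot(inherits(domain, "bsir_domain"))
  if (is.null(domain$grid)) stop("domain carries no grid geometry")
  if (inherits(maps, "summary.bsir")) {
    flat <- list()
    for (j in seq_along(maps$effects)) {
      nm <- gsub("[^A-Za-z0-9]+", "", maps$covariate_names[j])
      e <- maps$effects[[j]]
      for (w in c("mean", "sd", "p_plus", "es", "active"))
        flat[[paste(nm, w, sep = "_")]] <- e[[w]]
    }
    maps <- flat
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (nm in names(maps)) {
    v <- maps[[nm]]
    if (length(v) != domain$V) stop("map length does not match the domain")
    if (grepl("(^|_)es$", nm)) v <- pmin(pmax(v, -1), 1)
    if (is.logical(v)) v <- as.integer(v)
    vol <- array(background, domain$grid$dim)
    vol[domain$grid$mask_idx] <- v
    f <- file.path(out_dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(RNifti::asNifti(vol), f)
    written <- c(written, f)
  }
  invisible(written)
}

#' Read a participant covariate table
#'
#' @param path CSV or TSV file.
#' @param id_col optional participant-ID column name; with `ids` given,
#'   rows are reordered to match the image order and missing IDs are an
#'   error.
#' @param ids expected participant IDs in image order.
#' @return Data frame of covariates.
#' @export
read_covariates <- function(path, id_col = NULL, ids = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!is.null(id_col)) {
    if (!id_col %in% names(df)) stop("id column not found: ", id_col)
    if (!is.null(ids)) {
      pos <- match(ids, df[[id_col]])
      if (anyNA(pos)) stop("covariate table is missing participant IDs")
      df <- df[pos, , drop = FALSE]
    }
  }
  if (anyNA(df)) stop("missing covariate values are not supported")
  df
}
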