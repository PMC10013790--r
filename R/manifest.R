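# Dataset manifests: typed CSV lists of (image, mask, split, stage, ...)
# records tying synthesized / rotated / pseudo-labeled datasets to files on
# disk. Columns: id, image_path, mask_path, split, stage, domain, seed, and
# the optional online_aug flag set by rotation datasets.

manifest_columns <- c("id", "image_path", "mask_path", "split", "stage",
                      "domain", "seed")

new_manifest <- function(rows) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

empty_manifest <- function() {
  data.frame(id = character(), image_path = character(),
             mask_path = character(), split = character(),
             stage = character(), domain = character(), seed = integer(),
             stringsAsFactors = FALSE)
}

manifest_row <- function(id, image_path, mask_path, split, stage,
                         domain = "synthetic", seed = NA_integer_,
                         online_aug = 0L) {
  data.frame(id = id, image_path = image_path, mask_path = mask_path,
             split = split, stage = stage, domain = domain,
             seed = as.integer(seed), online_aug = as.integer(online_aug),
             stringsAsFactors = FALSE)
}

#' Write a dataset manifest to CSV
#' @param manifest manifest data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest from CSV
#' @param path CSV path written by [write_manifest()]
#' @return manifest data.frame
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(manifest_columns, "seed"), names(df))
  if (length(missing) > 0)
    stop("manifest ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  if (is.null(df$online_aug)) df$online_aug <- 0L
  df
}

# Assert every referenced file exists; mask_path may be NA for unlabeled
# frame manifests.
validate_manifest <- function(manifest, what = "manifest") {
  paths <- c(manifest$image_path,
             manifest$mask_path[!is.na(manifest$mask_path)])
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop(what, " references missing files, e.g. ", missing[1])
  if (anyDuplicated(manifest$image_path))
    stop(what, " has duplicated image paths")
  invisible(manifest)
}
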