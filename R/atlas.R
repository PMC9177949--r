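## Fixed anatomical atlas: AAL90 region labels, six-lobe module lookup, and a
## schematic centroid table used only for viewer-file export.

#' AAL90 atlas lookup
#'
#' Returns the packaged 90-region automated-anatomical-labelling lookup:
#' region label, six-lobe module (frontal, prefrontal, subcortical, temporal,
#' occipital, parietal) and schematic centroid coordinates. The coordinates
#' are a synthetic layout intended only for BrainNet-Viewer-style `.node`
#' exports; they are not measured MNI centroids.
#'
#' @param with_coordinates logical; if `TRUE`, join the schematic centroid
#'   columns `x`, `y`, `z`.
#' @return A data.frame with columns `roi_label`, `module` (and optionally
#'   `x`, `y`, `z`), one row per region in atlas order.
#' @examples
#' atlas <- aal90_atlas()
#' table(atlas$module)
#' @export
aal90_atlas <- function(with_coordinates = FALSE) {
  tab <- read.csv(system.file("extdata", "aal90_modules.csv",
                              package = "presbynet"),
                  stringsAsFactors = FALSE)
  if (with_coordinates) {
    xyz <- read.csv(system.file("extdata", "aal90_centroids_synthetic.csv",
                                package = "presbynet"),
                    stringsAsFactors = FALSE)
    tab <- merge(tab, xyz, by = "roi_label", sort = FALSE)
    tab <- tab[match(aal90_labels(), tab$roi_label), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' AAL90 region labels in atlas order
#' @return Character vector of 90 unique region labels.
#' @export
aal90_labels <- function() {
  read.csv(system.file("extdata", "aal90_modules.csv", package = "presbynet"),
           stringsAsFactors = FALSE)$roi_label
}

#' Build a module partition from an atlas lookup table
#'
#' Validates a `roi_label,module` table and turns it into a named partition
#' mapping every ROI to exactly one module. The default atlas yields the six
#' anatomical lobe modules over 90 regions.
#'
#' @param atlas_table data.frame with columns `roi_label` and `module`;
#'   defaults to the packaged AAL90 lookup.
#' @return An object of class `module_partition`: a named factor (names are
#'   ROI labels, levels are module names in first-appearance order).
#' @examples
#' part <- module_partition()
#' nlevels(part)  # 6
#' @export
module_partition <- function(atlas_table = aal90_atlas()) {
  if (!all(c("roi_label", "module") %in% names(atlas_table))) {
    pn_stop("atlas table needs columns `roi_label` and `module`",
            "presbynet_atlas_error")
  }
  lab <- as.character(atlas_table$roi_label)
  if (anyDuplicated(lab)) {
    pn_stop(sprintf("duplicated ROI rows in atlas table: %s",
                    paste(unique(lab[duplicated(lab)]), collapse = ", ")),
            "presbynet_atlas_error")
  }
  mod <- as.character(atlas_table$module)
  if (anyNA(mod) || any(!nzchar(mod))) {
    pn_stop("every ROI must be assigned a module", "presbynet_atlas_error")
  }
  part <- factor(mod, levels = unique(mod))
  names(part) <- lab
  class(part) <- c("module_partition", class(part))
  part
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d ROIs in %d modules\n",
              length(x), nlevels(x)))
  print(table(factor(as.character(x), levels = levels(x)), dnn = NULL))
  invisible(x)
}
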