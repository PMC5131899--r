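#' AAL-90 region table
#'
#' The 90 cortical and subcortical regions of the Automated Anatomical
#' Labeling (AAL) atlas used as source seeds (cerebellar regions excluded),
#' ordered by lobe for display: Frontal, Temporal, Limbic, Parietal,
#' Occipital. Left/right homologues are adjacent, left first. MNI seed
#' coordinates are metadata for labelling and plotting only; they take no
#' part in any computation.
#'
#' @return A tibble with columns `order`, `name`, `x_mm`, `y_mm`, `z_mm`,
#'   `lobe` (factor in display order).
#' @export
#' @examples
#' regions <- aal_regions()
#' nrow(regions)
#' table(regions$lobe)
aal_regions <- function() {
  path <- system.file("extdata", "aal90_regions.csv", package = "plvnet",
                      mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$lobe <- factor(out$lobe,
                     levels = c("Frontal", "Temporal", "Limbic",
                                "Parietal", "Occipital"))
  out
}

# Default region names: the AAL fixture when n_regions = 90, otherwise
# generic labels.
default_region_names <- function(n_regions) {
  if (n_regions == 90) aal_regions()$name else sprintf("R%02d", seq_len(n_regions))
}
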