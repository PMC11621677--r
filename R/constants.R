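#' The frozen food label vocabulary
#'
#' The 15 food categories the pipeline recognises, in the fixed
#' alphabetical order that defines the one-hot (FT) encoding and the
#' feature-table column layout. Containers carry the separate label
#' \code{"container"}. Label matching is case-insensitive after trimming.
#'
#' @return Character vector of length 15.
#' @examples
#' foodLabels()
#' @export
foodLabels <- function() {
  c("avocado", "banku", "beef stew", "chapati", "chicken drumstick",
    "onions", "onions & tomato salad", "rice dish", "roasted beef",
    "salted fish", "spinach stew", "tilapia fish", "tomato soup",
    "ugali", "yam")
}

#' Canonicalise a category label
#'
#' Lower-cases and trims a label so matching against the frozen vocabulary
#' is case-insensitive.
#'
#' @param x Character vector of labels.
#' @return Canonical labels.
#' @export
normalizeCategory <- function(x) tolower(trimws(x))

#' The frozen feature column order
#'
#' Column order every \linkS4class{PortionModel} is trained with:
#' the 15 one-hot food-type columns \code{ft_0..ft_14} (alphabetical label
#' order), then \code{frr}, \code{vc}, \code{np}, \code{par}, \code{awr}.
#'
#' @return Character vector of length 20.
#' @export
featureOrder <- function() {
  c(paste0("ft_", 0:14), "frr", "vc", "np", "par", "awr")
}

# Full feature-table column layout (metadata + features + weight).
featureTableColumns <- function() {
  c("episode_id", "frame_id", "category", featureOrder(), "weight_g")
}
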