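# Pet pseudo-elements and standard-element van der Waals radii.

#' The pet element registry
#'
#' Pet atoms are artificial spherical pseudo-elements used to approximate
#' molecules at one tenth of their linear size. There are exactly twelve,
#' with symbols "O1".."O9", "OA", "OB", "OC" and van der Waals radii from
#' 0.1 to 1.2 Angstrom in 0.1 Angstrom steps (radius of index k is k/10).
#'
#' @return data.frame with columns `symbol`, `index` (1..12), `radius`
#'   (Angstrom), `type` (lowercase force-field atom type, "o1".."oc").
#' @examples
#' pet_elements()
#' @export
pet_elements <- function() {
  sym <- c(paste0("O", 1:9), "OA", "OB", "OC")
  data.frame(symbol = sym, index = 1:12, radius = (1:12) / 10,
             type = tolower(sym), stringsAsFactors = FALSE)
}

#' Is an element symbol a pet element?
#' @param element character vector of element symbols.
#' @return logical vector.
#' @export
is_pet_element <- function(element) {
  toupper(element) %in% pet_elements()$symbol
}

#' Van der Waals radius of a pet element symbol
#' @param element character vector of pet element symbols.
#' @return numeric radii in Angstrom.
#' @export
pet_radius <- function(element) {
  reg <- pet_elements()
  i <- match(toupper(element), reg$symbol)
  if (anyNA(i)) stop("unknown pet element symbol: ",
                     paste(element[is.na(i)], collapse = ", "))
  reg$radius[i]
}

# Pet element symbol for a radius index 1..12.
pet_symbol <- function(index) pet_elements()$symbol[index]

# vdW radii (Bondi) for the standard elements that occur in the fixtures
# and in typical protein/nucleic structures.
.std_vdw <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
              F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, MG = 1.73,
              NA. = 2.27, K = 2.75, ZN = 1.39, FE = 1.4, CA = 2.31,
              SE = 1.9)

#' Van der Waals radius of any supported element
#'
#' Standard elements use Bondi radii; pet elements use their defining
#' radius (index/10 Angstrom). Unknown symbols are an error.
#' @param element character vector of element symbols.
#' @return numeric radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  el <- toupper(element)
  out <- numeric(length(el))
  pet <- is_pet_element(el)
  out[pet] <- pet_radius(el[pet])
  if (any(!pet)) {
    key <- ifelse(el[!pet] == "NA", "NA.", el[!pet])
    r <- .std_vdw[key]
    if (anyNA(r)) stop("unknown element symbol: ",
                       paste(unique(el[!pet][is.na(r)]), collapse = ", "))
    out[!pet] <- r
  }
  out
}
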