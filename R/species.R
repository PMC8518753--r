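#' Species of the propargyl acetate hydrogenation network
#'
#' The hydrogenation of propargyl acetate over the cationic rhodium catalyst
#' Rh(dppb)(COD)BF4 is described by ten species: the catalyst precursor
#' (`1`), the active catalyst (`1a`), dissolved hydrogen (`2`), the substrate
#' propargyl acetate (`3`), the catalyst-substrate complex (`3a`), the first
#' hydrogenation product allyl acetate (`4`), the catalyst-allyl complex
#' (`4a`), spin-relaxed allyl acetate (`4rx`, the sink that book-keeps loss
#' of hyperpolarisation), the second hydrogenation product propyl acetate
#' (`5`), and cyclooctene (`6`) released on catalyst activation.
#'
#' @return A data frame with columns `id`, `name` and `role`
#'   (`catalyst`, `gas`, `substrate`, `product` or `sink`), one row per
#'   species, in the canonical state-vector order.
#' @export
#' @examples
#' phip_species()
phip_species <- function() {
  data.frame(
    id = c("1", "1a", "2", "3", "3a", "4", "4a", "4rx", "5", "6"),
    name = c(
      "precursor catalyst Rh(dppb)(COD)+",
      "active catalyst",
      "hydrogen",
      "propargyl acetate",
      "catalyst-propargyl complex",
      "allyl acetate (hyperpolarised)",
      "catalyst-allyl complex",
      "allyl acetate (relaxed)",
      "propyl acetate",
      "cyclooctene"
    ),
    role = c(
      "catalyst", "catalyst", "gas", "substrate", "catalyst",
      "product", "catalyst", "sink", "product", "product"
    ),
    stringsAsFactors = FALSE
  )
}

# canonical ordering helpers used throughout the package
.species_ids <- function() phip_species()$id
.n_species <- function() 10L

# species groups for the conservation laws
.catalyst_ids <- c("1", "1a", "3a", "4a")
.backbone_ids <- c("3", "3a", "4", "4a", "4rx", "5")

#' Expand a partial concentration specification to the full state vector
#'
#' @param conc Named numeric vector (names are species ids); missing species
#'   default to 0.
#' @return Named numeric vector of length 10 in canonical order.
#' @export
phip_state <- function(conc = c()) {
  ids <- .species_ids()
  out <- stats::setNames(numeric(length(ids)), ids)
  if (length(conc)) {
    if (is.null(names(conc)) || !all(names(conc) %in% ids)) {
      stop("concentrations must be named with species ids: ",
           paste(ids, collapse = ", "))
    }
    out[names(conc)] <- conc
  }
  out
}
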