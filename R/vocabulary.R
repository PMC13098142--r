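## Controlled vocabulary for T6SS structural components.

#' Canonical T6SS component vocabulary
#'
#' The fourteen canonical structural components of the type VI secretion
#' system, their common synonyms (hcp, vgrG, clpV, PAAR), and the assignment
#' of components to structural subcomplexes (membrane complex, baseplate,
#' sheath, spike-and-tube, ATPase).
#'
#' @return A list with elements:
#'   \describe{
#'     \item{components}{character vector of the 14 canonical names.}
#'     \item{synonyms}{named character vector mapping recognized labels
#'       (lower-cased) to canonical names.}
#'     \item{subcomplexes}{named list partitioning the 14 components into the
#'       six structural subcomplexes.}
#'   }
#' @examples
#' vocab <- t6ss_vocabulary()
#' vocab$synonyms[["hcp"]]   # "tssD"
#' @export
t6ss_vocabulary <- function() {
  components <- c("tssA", "tssB", "tssC", "tssD", "tssE", "tssF", "tssG",
                  "tssH", "tssI", "tssJ", "tssK", "tssL", "tssM", "evpJ")
  synonyms <- c(
    stats::setNames(components, tolower(components)),
    hcp = "tssD", vgrg = "tssI", clpv = "tssH", paar = "evpJ",
    icmf = "tssM", dotu = "tssL"
  )
  subcomplexes <- list(
    ATPase         = "tssH",
    spike_and_tube = c("evpJ", "tssI", "tssD"),
    membrane       = c("tssJ", "tssL", "tssM"),
    baseplate      = c("tssE", "tssF", "tssG", "tssK"),
    sheath         = c("tssB", "tssC"),
    tssA           = "tssA"
  )
  list(components = components, synonyms = synonyms, subcomplexes = subcomplexes)
}

#' Normalize component labels to canonical names
#'
#' Maps labels through the synonym table of [t6ss_vocabulary()]
#' (case-insensitively). Labels that are not recognized T6SS components are
#' returned as `NA`.
#'
#' @param labels character vector of gene labels.
#' @return character vector of canonical component names, `NA` for
#'   non-components.
#' @export
normalize_component <- function(labels) {
  vocab <- t6ss_vocabulary()
  out <- unname(vocab$synonyms[tolower(labels)])
  out
}
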