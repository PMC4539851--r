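#' Default product-description pattern lists
#'
#' The lexicon used to decide whether a product description denotes a
#' hypothetical (orphan) product or a conserved-hypothetical one. Matching is
#' case-insensitive substring matching; anything that matches neither list is
#' treated as a functional assignment. The lists are deliberately explicit and
#' user-replaceable rather than hidden inside the classifier.
#'
#' @return A list with character vectors `hypothetical` and `conserved`.
#' @examples
#' default_product_patterns()$hypothetical
#' @export
default_product_patterns <- function() {
  list(
    hypothetical = c(
      "hypothetical protein", "uncharacterized", "unknown function",
      "predicted protein", "hypothetical"
    ),
    conserved = c(
      "conserved hypothetical", "domain of unknown function", "DUF"
    )
  )
}

#' Classify a gene-product description
#'
#' Assigns each product description to one of three categories:
#' `"hypothetical"` (orphan gene: product absent or matching a hypothetical
#' pattern), `"conserved-hypothetical"` (matches a conserved pattern, checked
#' first since conserved patterns are refinements of hypothetical ones) or
#' `"functional"` (everything else). This is a total function: any input,
#' including `NA`, yields a category.
#'
#' @param product character vector of product descriptions (`NA` allowed).
#' @param note optional character vector of /note qualifiers, consulted with
#'   the same patterns when the product alone does not match.
#' @param patterns pattern list as returned by [default_product_patterns()].
#' @return character vector of categories, same length as `product`.
#' @examples
#' classify_product("hypothetical protein")
#' classify_product("DNA polymerase III subunit alpha")
#' classify_product("conserved hypothetical protein")
#' @export
classify_product <- function(product, note = NULL,
                             patterns = default_product_patterns()) {
  n <- length(product)
  if (is.null(note)) note <- rep(NA_character_, n)
  stopifnot(length(note) == n)
  text <- ifelse(is.na(product), "", product)
  extra <- ifelse(is.na(note), "", note)

  matches_any <- function(x, pats) {
    hit <- rep(FALSE, length(x))
    for (p in pats) hit <- hit | grepl(p, x, ignore.case = TRUE, fixed = FALSE)
    hit
  }
  conserved <- matches_any(text, patterns$conserved) |
    matches_any(extra, patterns$conserved)
  hypo <- is.na(product) | !nzchar(trimws(text)) |
    matches_any(text, patterns$hypothetical) |
    matches_any(extra, patterns$hypothetical)

  out <- rep("functional", n)
  out[hypo] <- "hypothetical"
  out[conserved] <- "conserved-hypothetical"
  out
}
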