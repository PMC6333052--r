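#' The nine registered model recipes
#'
#' The classification stage trains nine models, one per recipe: per-region
#' class-similarity models for the whole sequence and each of the four
#' domains, the two single-encoding domain models (BindN-style M encoding,
#' COILS K encoding) and the two combined domain models. A recipe lists
#' the regions a query must contain to be routed to it; whole-sequence
#' models require the full MIKC architecture.
#'
#' @return List of `model_recipe` objects in registration order; each has
#'   `recipe_id`, `required_regions`, `blocks`.
#' @export
registered_recipes <- function() {
  mk <- function(id, required, blocks) {
    structure(list(recipe_id = id, required_regions = required,
                   blocks = blocks),
              class = "model_recipe")
  }
  list(
    mk("WHOLE-sim",    c("M", "I", "K", "C_TERM"), "sim:WHOLE"),
    mk("M-sim",        "M",      "sim:M"),
    mk("I-sim",        "I",      "sim:I"),
    mk("K-sim",        "K",      "sim:K"),
    mk("C-sim",        "C_TERM", "sim:C_TERM"),
    mk("M-BindN",      "M",      "bindn"),
    mk("K-COILS",      "K",      "coils"),
    mk("M-sim+BindN",  "M",      c("sim:M", "bindn")),
    mk("K-sim+COILS",  "K",      c("sim:K", "coils"))
  )
}

get_recipe <- function(recipe_id) {
  recipes <- registered_recipes()
  ids <- vapply(recipes, `[[`, character(1), "recipe_id")
  i <- match(recipe_id, ids)
  if (is.na(i)) {
    stop("unknown recipe '", recipe_id, "'; registered: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  recipes[[i]]
}

#' Feature length of a recipe
#'
#' @param recipe_id registered recipe id.
#' @param m_length BindN layout length (default 57).
#' @return Integer feature-vector length.
#' @export
recipe_feature_length <- function(recipe_id, m_length = 57L) {
  recipe <- get_recipe(recipe_id)
  sum(vapply(recipe$blocks, function(b) {
    if (startsWith(b, "sim:")) 8L
    else if (b == "bindn") 3L * as.integer(m_length)
    else if (b == "coils") 3L
    else stop("unknown block ", b)
  }, integer(1)))
}
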