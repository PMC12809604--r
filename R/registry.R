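#' Analysis categories for food groups
#'
#' The ten categories used throughout the descriptive analyses.  Every food
#' group in a registry must carry exactly one of these.
#'
#' @return Character vector of the ten category names.
#' @export
food_categories <- function() {
  c("foods rich in carbohydrates", "fruits", "vegetables", "meat", "fish",
    "milk and dairy products", "eggs", "oils and fats", "sweets and snacks",
    "others")
}

#' Build a food-group registry
#'
#' Validates and orders the master list of food groups used to dimension every
#' other table in the pipeline.  Groups are identified by opaque 5-digit
#' ECOICOP-style codes; no hierarchy logic is applied.  Groups named in
#' \code{exclude} (e.g. alcoholic beverages, baby food) are dropped before any
#' validation of the retained set.
#'
#' @param groups data.frame with columns \code{code}, \code{name},
#'   \code{category} and optionally \code{tag} (free marker such as
#'   \code{"coffee"}, \code{"tea"}, \code{"water"} used by food-based rules).
#' @param exclude character vector of codes to drop.
#' @return A \code{food_registry}: a data.frame ordered stably by code, with
#'   attribute \code{excluded} recording the dropped codes.
#' @export
food_registry <- function(groups, exclude = character()) {
  stopifnot(is.data.frame(groups))
  need <- c("code", "name", "category")
  miss <- setdiff(need, names(groups))
  if (length(miss))
    stop("registry config lacks column(s): ", paste(miss, collapse = ", "))
  groups$code <- as.character(groups$code)
  if (anyDuplicated(groups$code))
    stop("duplicate food-group codes: ",
         paste(unique(groups$code[duplicated(groups$code)]), collapse = ", "))
  if (is.null(groups$tag)) groups$tag <- ""
  groups$tag[is.na(groups$tag)] <- ""
  keep <- !(groups$code %in% exclude)
  reg <- groups[keep, c("code", "name", "category", "tag"), drop = FALSE]
  bad <- is.na(reg$category) | !(reg$category %in% food_categories())
  if (any(bad))
    stop("retained group(s) without a valid category: ",
         paste(reg$code[bad], collapse = ", "))
  reg <- reg[order(reg$code, method = "radix"), , drop = FALSE]
  rownames(reg) <- NULL
  attr(reg, "excluded") <- intersect(exclude, groups$code)
  class(reg) <- c("food_registry", "data.frame")
  reg
}

#' Read a food-group registry from a YAML config
#'
#' The config holds the full classification (all groups with their category
#' assignment) plus an exclusion list, so that the same file documents both
#' what exists and what was deliberately left out of the analysis.
#'
#' @param path YAML file with keys \code{groups} (list of \code{code},
#'   \code{name}, \code{category}, optional \code{tag}) and optional
#'   \code{exclude} (list of codes).
#' @param exclude extra codes to exclude on top of the file's own list.
#' @return A \code{food_registry}.
#' @export
read_registry <- function(path, exclude = character()) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups)) stop("registry config has no 'groups' key: ", path)
  g <- do.call(rbind, lapply(cfg$groups, function(x)
    data.frame(code = x$code, name = x$name,
               category = if (is.null(x$category)) NA_character_ else x$category,
               tag = if (is.null(x$tag)) "" else x$tag,
               stringsAsFactors = FALSE)))
  food_registry(g, exclude = unique(c(unlist(cfg$exclude), exclude)))
}

#' Write a registry back to YAML
#' @param registry a \code{food_registry}
#' @param path output file
#' @return \code{path}, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "food_registry"))
  cfg <- list(
    groups = lapply(seq_len(nrow(registry)), function(i)
      list(code = registry$code[i], name = registry$name[i],
           category = registry$category[i], tag = registry$tag[i])),
    exclude = as.list(attr(registry, "excluded")))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# The illustrative 62-group master classification.  The true 5-digit ECOICOP
# list used with licensed household-budget-survey data is not distributable;
# this stand-in mirrors its shape: ~62 commodity-based groups, two of which
# (spirits, baby food) are excluded from diet modelling by default.
master_classification <- function() {
  g <- function(code, name, category, tag = "")
    data.frame(code = code, name = name, category = category, tag = tag,
               stringsAsFactors = FALSE)
  rbind(
    # foods rich in carbohydrates
    g("01.1.1.1", "rice", "foods rich in carbohydrates"),
    g("01.1.1.2", "flours and other cereals", "foods rich in carbohydrates"),
    g("01.1.1.3", "bread", "foods rich in carbohydrates"),
    g("01.1.1.4", "other bakery products", "foods rich in carbohydrates"),
    g("01.1.1.5", "pizza and quiche", "foods rich in carbohydrates"),
    g("01.1.1.6", "pasta products and couscous", "foods rich in carbohydrates"),
    g("01.1.1.7", "breakfast cereals", "foods rich in carbohydrates"),
    g("01.1.7.3", "potatoes", "foods rich in carbohydrates"),
    g("01.1.7.4", "other tubers and products of tuber vegetables",
      "foods rich in carbohydrates"),
    # meat
    g("01.1.2.1", "beef and veal", "meat"),
    g("01.1.2.2", "pork", "meat"),
    g("01.1.2.3", "lamb and goat", "meat"),
    g("01.1.2.4", "poultry", "meat"),
    g("01.1.2.5", "other meats and edible offal", "meat"),
    g("01.1.2.6", "dried, salted or smoked meat", "meat"),
    g("01.1.2.7", "other meat preparations", "meat"),
    # fish
    g("01.1.3.1", "fresh or chilled fish", "fish"),
    g("01.1.3.2", "frozen fish", "fish"),
    g("01.1.3.3", "seafood", "fish"),
    g("01.1.3.4", "preserved or processed fish and seafood", "fish"),
    # milk, cheese and eggs
    g("01.1.4.1", "whole milk", "milk and dairy products"),
    g("01.1.4.2", "low fat milk", "milk and dairy products"),
    g("01.1.4.3", "preserved milk and milk products", "milk and dairy products"),
    g("01.1.4.4", "yoghurt", "milk and dairy products"),
    g("01.1.4.5", "cheese and curd", "milk and dairy products"),
    g("01.1.4.6", "other milk products", "milk and dairy products"),
    g("01.1.4.7", "eggs", "eggs"),
    # oils and fats
    g("01.1.5.1", "butter", "oils and fats"),
    g("01.1.5.2", "margarine and other vegetable fats", "oils and fats"),
    g("01.1.5.3", "olive oil", "oils and fats"),
    g("01.1.5.4", "other edible oils", "oils and fats"),
    g("01.1.5.5", "other edible animal fats", "oils and fats"),
    # fruits
    g("01.1.6.1", "citrus fruits", "fruits"),
    g("01.1.6.2", "bananas", "fruits"),
    g("01.1.6.3", "apples and pears", "fruits"),
    g("01.1.6.4", "stone fruits", "fruits"),
    g("01.1.6.5", "berries", "fruits"),
    g("01.1.6.6", "other fresh fruits", "fruits"),
    g("01.1.6.7", "dried fruit and nuts", "fruits"),
    # vegetables
    g("01.1.7.1", "leaf and stem vegetables", "vegetables"),
    g("01.1.7.2", "cabbages", "vegetables"),
    g("01.1.7.5", "fruit-bearing vegetables", "vegetables"),
    g("01.1.7.6", "root crops and mushrooms", "vegetables"),
    g("01.1.7.7", "dried vegetables and pulses", "vegetables"),
    g("01.1.7.8", "preserved or processed vegetables", "vegetables"),
    # sugar, jam, confectionery
    g("01.1.8.1", "sugar", "sweets and snacks"),
    g("01.1.8.2", "jams, marmalades and honey", "sweets and snacks"),
    g("01.1.8.3", "chocolate", "sweets and snacks"),
    g("01.1.8.4", "confectionery products", "sweets and snacks"),
    g("01.1.8.5", "edible ices and ice cream", "sweets and snacks"),
    # other food products
    g("01.1.9.1", "sauces and condiments", "others"),
    g("01.1.9.2", "salt, spices and culinary herbs", "others"),
    g("01.1.9.3", "ready-made meals", "others"),
    g("01.1.9.4", "baby food", "others"),
    g("01.1.9.5", "other food products n.e.c.", "others"),
    # non-alcoholic beverages
    g("01.2.1.1", "coffee", "others", tag = "coffee"),
    g("01.2.1.2", "tea", "others", tag = "tea"),
    g("01.2.1.3", "cocoa and powdered chocolate", "others"),
    g("01.2.2.1", "mineral or spring waters", "others", tag = "water"),
    g("01.2.2.2", "soft drinks", "others"),
    g("01.2.2.3", "fruit and vegetable juices", "others"),
    # alcoholic beverages
    g("02.1.1.1", "spirits and liqueurs", "others")
  )
}

#' Default illustrative food-group registry
#'
#' A 62-group ECOICOP-style classification with the standard two exclusions
#' (alcoholic beverages and baby food), leaving 60 modelling groups.  The real
#' survey classifications are licensed and not distributable, so this registry
#' is synthetic: codes and structure are realistic, the exact list is not the
#' survey's.
#'
#' @param exclude codes to drop; default excludes spirits and baby food.
#' @return A \code{food_registry} with 60 groups under the default exclusions.
#' @export
default_registry <- function(exclude = c("02.1.1.1", "01.1.9.4")) {
  food_registry(master_classification(), exclude = exclude)
}

#' @export
print.food_registry <- function(x, ...) {
  cat("Food-group registry:", nrow(x), "groups",
      sprintf("(%d excluded)\n", length(attr(x, "excluded"))))
  tab <- table(x$category)
  for (cat_ in names(tab)) cat("  ", cat_, ": ", tab[[cat_]], "\n", sep = "")
  invisible(x)
}
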