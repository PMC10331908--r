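#' The seven nest-material categories
#'
#' Nest materials are scored into seven broad categories: `binder` (adhesive
#' matrix such as mud, saliva or droppings), `fibre` (soft strands such as
#' feathers, fur, moss), `grass` (filamentous grass-like material, including
#' seaweed and Spanish moss), `leaf`, `mineral` (hard inorganic items such as
#' shell or pebbles), `silk` and `twig` (woody elements).
#'
#' @return Character vector of the seven category labels, in alphabetical order.
#' @export
#' @examples
#' material_categories()
material_categories <- function() {
  c("binder", "fibre", "grass", "leaf", "mineral", "silk", "twig")
}

#' Load a descriptor-to-category lexicon
#'
#' The lexicon maps normalized free-text material descriptors (lower-cased,
#' whitespace-trimmed) to the seven material categories. The packaged default
#' is seeded with the exemplar terms of each category definition and is meant
#' to be extended by the user as new descriptors are encountered; matching is
#' exact on normalized tokens — no fuzzy matching — so every coding decision
#' is auditable.
#'
#' @param path Path to a two-column CSV (`term`, `category`). Defaults to the
#'   lexicon shipped with the package.
#' @return Named character vector mapping normalized term to category.
#' @export
material_lexicon <- function(path = system.file("extdata", "material_lexicon.csv",
                                                package = "beaknest")) {
  lex <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "category") %in% names(lex))) {
    stop("lexicon file must have columns 'term' and 'category'")
  }
  bad <- setdiff(unique(lex$category), material_categories())
  if (length(bad) > 0) {
    stop("lexicon contains unknown categories: ", paste(bad, collapse = ", "))
  }
  terms <- normalize_descriptor(lex$term)
  if (anyDuplicated(terms)) {
    stop("duplicated lexicon terms after normalization: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  }
  stats::setNames(lex$category, terms)
}

normalize_descriptor <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Categorize a free-text material descriptor
#'
#' Case-insensitive exact lookup of a descriptor against the lexicon. Unmapped
#' terms return `"unknown"` rather than a guess; callers are expected to log
#' unknowns and extend the lexicon.
#'
#' @param descriptor Character vector of free-text material terms.
#' @param lexicon Named character vector from [material_lexicon()].
#' @return Character vector of category labels, `"unknown"` where unmapped.
#' @export
#' @examples
#' lex <- material_lexicon()
#' categorize_material(c("mud", "Spanish moss", "feathers"), lex)
categorize_material <- function(descriptor, lexicon = material_lexicon()) {
  key <- normalize_descriptor(descriptor)
  if (any(!nzchar(key))) {
    stop("empty descriptor after whitespace normalization")
  }
  out <- unname(lexicon[key])
  out[is.na(out)] <- "unknown"
  out
}

#' Resolve a species' material profile from source descriptions
#'
#' Applies the primary-material scoring rule to one species' literature
#' records. Per source, the primary candidate is (in order of precedence) the
#' category of the descriptor the source flags as most commonly used; the only
#' category represented, if a single one is; otherwise the category of the
#' first categorizable descriptor listed. Across sources, the species' primary
#' material is the unanimous candidate, or the sentinel `"mixed"` when sources
#' disagree. The set of used categories is the union over all sources, and a
#' species is a material specialist exactly when that union has size one.
#'
#' @param records Data frame with columns `species_id`, `source_id`,
#'   `descriptors` (list-column or semicolon-separated character) and
#'   `emphasized` (the descriptor flagged as most commonly used, `NA` or `""`
#'   when the source flags none). All rows must share one `species_id`.
#' @param lexicon Named character vector from [material_lexicon()].
#' @return A list with elements `species_id`, `used` (character vector of
#'   categories), `primary` (a category or `"mixed"`), `specialist` (logical),
#'   `omit` (logical; `TRUE` when no descriptor in any record could be
#'   categorized, in which case the species must be excluded downstream) and
#'   `unknown_terms` (descriptors that failed lookup).
#' @export
resolve_primary <- function(records, lexicon = material_lexicon()) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  sp <- unique(records$species_id)
  if (length(sp) != 1) {
    stop("all records must share one species_id; got: ", paste(sp, collapse = ", "))
  }
  desc_list <- parse_descriptors(records$descriptors)
  emph <- if ("emphasized" %in% names(records)) records$emphasized else rep(NA_character_, nrow(records))

  candidates <- character(0)
  used <- character(0)
  unknown <- character(0)
  for (i in seq_len(nrow(records))) {
    d <- desc_list[[i]]
    if (length(d) == 0) next
    cats <- categorize_material(d, lexicon)
    unknown <- c(unknown, d[cats == "unknown"])
    ok <- cats != "unknown"
    if (!any(ok)) next
    used <- union(used, cats[ok])
    e <- emph[i]
    if (!is.na(e) && nzchar(trimws(e))) {
      if (!normalize_descriptor(e) %in% normalize_descriptor(d)) {
        stop("emphasized descriptor '", e, "' does not appear among the source's descriptors")
      }
      ec <- categorize_material(e, lexicon)
      cand <- if (ec == "unknown") cats[ok][1] else ec
    } else if (length(unique(cats[ok])) == 1) {
      cand <- cats[ok][1]
    } else {
      cand <- cats[ok][1]
    }
    candidates <- c(candidates, cand)
  }

  if (length(used) == 0) {
    return(list(species_id = sp, used = character(0), primary = NA_character_,
                specialist = NA, omit = TRUE, unknown_terms = unique(unknown)))
  }
  primary <- if (length(unique(candidates)) == 1) candidates[1] else "mixed"
  list(species_id = sp,
       used = sort(used),
       primary = primary,
       specialist = length(used) == 1,
       omit = FALSE,
       unknown_terms = unique(unknown))
}

parse_descriptors <- function(x) {
  if (is.list(x)) {
    lapply(x, function(d) trimws(as.character(d)))
  } else {
    lapply(strsplit(as.character(x), ";", fixed = TRUE),
           function(d) {
             d <- trimws(d)
             d[nzchar(d)]
           })
  }
}

#' Code a corpus of nest-material descriptions into material profiles
#'
#' Vectorized front end to [resolve_primary()]: groups source records by
#' species and returns one profile row per species. Species with no
#' categorizable descriptor in any source are flagged `omit` (not silently
#' dropped); they carry `NA` profiles and must be excluded from all models.
#'
#' @param records Data frame with columns `species_id`, `source_id`,
#'   `descriptors`, `emphasized` (see [resolve_primary()]), possibly covering
#'   many species.
#' @param lexicon Named character vector from [material_lexicon()].
#' @return A `material_profiles` data frame with columns `species_id`, seven
#'   indicator columns `used_<category>`, `primary`, `specialist`, `omit`.
#'   Unknown descriptors encountered during coding are attached as the
#'   `unknown_terms` attribute.
#' @export
code_materials <- function(records, lexicon = material_lexicon()) {
  stopifnot(is.data.frame(records))
  need <- c("species_id", "source_id", "descriptors")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  split_rec <- split(records, records$species_id)
  profiles <- lapply(split_rec, resolve_primary, lexicon = lexicon)
  cats <- material_categories()
  out <- data.frame(
    species_id = vapply(profiles, `[[`, character(1), "species_id"),
    stringsAsFactors = FALSE
  )
  for (cat in cats) {
    out[[paste0("used_", cat)]] <- vapply(profiles, function(p) {
      if (p$omit) NA else as.integer(cat %in% p$used)
    }, integer(1))
  }
  out$primary <- vapply(profiles, `[[`, character(1), "primary")
  out$specialist <- vapply(profiles, function(p) as.logical(p$specialist), logical(1))
  out$omit <- vapply(profiles, `[[`, logical(1), "omit")
  rownames(out) <- NULL
  unk <- unique(unlist(lapply(profiles, `[[`, "unknown_terms")))
  if (length(unk) > 0) {
    message("descriptors not in lexicon (returned 'unknown'): ",
            paste(unk, collapse = ", "))
  }
  attr(out, "unknown_terms") <- unk
  class(out) <- c("material_profiles", "data.frame")
  out
}

#' Read and write material profiles
#'
#' @param profiles A `material_profiles` data frame from [code_materials()].
#' @param path File path for the CSV.
#' @return `read_material_profiles` returns a `material_profiles` data frame.
#' @export
write_material_profiles <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_material_profiles
#' @export
read_material_profiles <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("material_profiles", "data.frame")
  out
}
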