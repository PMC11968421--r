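#' Read a taxonomy table
#'
#' One row per taxon with columns `taxon_id`, the seven Linnaean ranks
#' `kingdom` ... `species` (empty strings allowed) and an `identity_flag`
#' in `annotated`, `unidentified`, `host`. Missing rank columns are added
#' empty; a missing `identity_flag` defaults to `annotated` except where
#' the phylum is empty (then `unidentified`).
#'
#' @param path TSV/CSV path.
#' @param sep Field separator; sniffed if `NULL`.
#' @return Data frame with the canonical columns.
#' @export
read_taxonomy <- function(path, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  names(df)[1] <- "taxon_id"
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")
  for (r in ranks) if (!r %in% names(df)) df[[r]] <- ""
  if (!"identity_flag" %in% names(df)) {
    df$identity_flag <- ifelse(is.na(df$phylum) | df$phylum == "",
                               "unidentified", "annotated")
  }
  bad <- setdiff(unique(df$identity_flag), c("annotated", "unidentified", "host"))
  if (length(bad) > 0) stopf("unknown identity_flag value(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(df$taxon_id)) stopf("duplicate taxon ids in taxonomy")
  df[, c("taxon_id", ranks, "identity_flag")]
}

#' Read stomach-sample metadata
#'
#' Expects columns `sample_id` and `group` (both required) and optionally
#' `standard_length` (cm), `body_weight` (g), `sex` (`M`/`F`/`unknown`),
#' `fullness_grade` (integer 0-5), `latitude`, `longitude` (decimal degrees)
#' and `date`. Range invariants are enforced where the fields are present.
#'
#' @inheritParams read_taxonomy
#' @return Data frame, one row per sample.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  validate_sample_metadata(df)
}

#' Validate stomach-sample metadata
#' @param df Data frame of per-sample metadata.
#' @return `df` (with `sex` normalized), or an error naming the violation.
#' @export
validate_sample_metadata <- function(df) {
  for (req in c("sample_id", "group"))
    if (!req %in% names(df)) stopf("metadata is missing required column '%s'", req)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample ids in metadata")
  chk <- function(col, ok, what) {
    if (col %in% names(df)) {
      v <- df[[col]]
      bad <- !is.na(v) & !ok(v)
      if (any(bad)) stopf("invalid %s for sample(s): %s", what,
                          paste(df$sample_id[bad], collapse = ", "))
    }
  }
  chk("fullness_grade", function(v) v %in% 0:5, "fullness_grade (must be 0-5)")
  chk("latitude", function(v) v >= -90 & v <= 90, "latitude")
  chk("longitude", function(v) v >= -180 & v <= 180, "longitude")
  chk("standard_length", function(v) v > 0, "standard_length")
  if ("sex" %in% names(df)) {
    df$sex <- ifelse(df$sex %in% c("M", "F"), df$sex, "unknown")
  }
  df
}

#' Read an environmental table
#'
#' One row per analysis unit (population/season) or per sample; the first
#' column is the unit id and the remaining columns are numeric environmental
#' variables (e.g. TEMP, DO, pH, COND, TD, PI, AN, TP, TN).
#'
#' @inheritParams read_taxonomy
#' @return Data frame with rownames set to the unit ids.
#' @export
read_env_table <- function(path, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  ids <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  if (!all(vapply(df, is.numeric, logical(1))))
    stopf("environmental variables must all be numeric")
  if (any(!is.finite(as.matrix(df)))) stopf("environmental table has non-finite values")
  rownames(df) <- ids
  df
}

#' Default phylum-to-food-category map
#'
#' The five stomach-content food categories conventionally used for
#' omnivorous freshwater fish (phytoplankton, protozoa, zooplankton,
#' zoobenthos, detritus); phyla not in the map fall back to `"other"`.
#'
#' @return Named character vector, `phylum -> category`.
#' @export
default_food_category_map <- function() {
  c(Chlorophyta = "phytoplankton", Bacillariophyta = "phytoplankton",
    Haptophyta = "phytoplankton", Cryptophyta = "phytoplankton",
    Cyanobacteria = "phytoplankton", Ochrophyta = "phytoplankton",
    Ciliophora = "protozoa", Microsporidia = "protozoa", Cercozoa = "protozoa",
    Picozoa = "protozoa", Apicomplexa = "protozoa", Euglenozoa = "protozoa",
    Imbricatea = "protozoa", Heterolobosea = "protozoa", Endomyxa = "protozoa",
    Tubulinea = "protozoa", Perkinsozoa = "protozoa", Foraminifera = "protozoa",
    Evosea = "protozoa", Discosea = "protozoa",
    Arthropoda = "zooplankton", Rotifera = "zooplankton", Cnidaria = "zooplankton",
    Bryozoa = "zoobenthos", Annelida = "zoobenthos", Nemertea = "zoobenthos",
    Gastrotricha = "zoobenthos", Nematoda = "zoobenthos", Mollusca = "zoobenthos",
    Platyhelminthes = "zoobenthos", Tardigrada = "zoobenthos", Porifera = "zoobenthos",
    Ascomycota = "detritus", Streptophyta = "detritus", Oomycota = "detritus",
    Basidiomycota = "detritus", Cryptomycota = "detritus",
    Chytridiomycota = "detritus", Mucoromycota = "detritus",
    Blastocladiomycota = "detritus", Zoopagomycota = "detritus")
}

#' Read a phylum-to-food-category map from TSV
#'
#' Two columns: phylum, category. Categories must be one of the five food
#' categories or `"other"`.
#'
#' @inheritParams read_taxonomy
#' @return Named character vector, `phylum -> category`.
#' @export
read_food_category_map <- function(path, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ok <- c("phytoplankton", "protozoa", "zooplankton", "zoobenthos", "detritus", "other")
  bad <- setdiff(unique(df[[2]]), ok)
  if (length(bad) > 0) stopf("unknown food categories: %s", paste(bad, collapse = ", "))
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a rooted phylogenetic tree over taxa
#'
#' Newick input via \pkg{ape}; checks finite non-negative branch lengths.
#'
#' @param path Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_taxon_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stopf("tree must have finite branch lengths")
  if (any(tree$edge.length < 0)) stopf("tree has negative branch lengths")
  tree
}
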