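#' Packaged diet-report fixtures
#'
#' Returns the published diet-composition report tables shipped with the
#' package as structured objects: `"table1"` — phylum-level FO/RRA of five
#' populations from two habitat types; `"table2"` — phylum-level FO/RRA of
#' four seasons from one reservoir; `"table3"` — group mean +/- SE of the
#' trophic diversity indices H', J and B. Tables 1-2 come back as
#' `diet_profile` objects (with the "Unidentified" row included and
#' phylum-to-category assignments attached) ready for [category_rra()],
#' [overlap_matrix()] and [feeding_strategy()].
#'
#' @param name `"table1"`, `"table2"` or `"table3"`.
#' @return A `diet_profile` (tables 1-2) or a data frame (table 3).
#' @export
paper_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", switch(name,
    table1 = "table1_habitat_fo_rra.tsv",
    table2 = "table2_season_fo_rra.tsv",
    table3 = "table3_diversity.tsv"), package = "dietbarcode", mustWork = TRUE)
  if (name == "table3") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", fill = TRUE,
                            stringsAsFactors = FALSE, quote = "\"")
    df$letters[is.na(df$letters)] <- ""
    return(df)
  }
  read_diet_profile_tsv(path,
    n = if (name == "table1") c(DJ = 5L, NDJ = 5L, QDH = 3L, SKSK = 5L, XJ = 5L)
        else c(Spring = 15L, Summer = 15L, Autumn = 15L, Winter = 15L))
}

#' Read a group-level diet profile from TSV
#'
#' Profile-mode input: a table with columns `category`, `phylum` and then
#' `<GROUP>_FO` / `<GROUP>_RRA` pairs per group, i.e. the layout of a
#' published diet-composition table. Percent RRA columns should each sum
#' to ~100.
#'
#' @param path TSV path.
#' @param n Optional named integer vector of per-group sample sizes.
#' @return A `diet_profile` at phylum rank with the `category` column
#'   attached as the profile's category map.
#' @export
read_diet_profile_tsv <- function(path, n = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  if (!all(c("category", "phylum") %in% names(df)))
    stopf("profile table needs 'category' and 'phylum' columns")
  fo_cols <- grep("_FO$", names(df), value = TRUE)
  rra_cols <- grep("_RRA$", names(df), value = TRUE)
  groups <- sub("_FO$", "", fo_cols)
  if (!identical(groups, sub("_RRA$", "", rra_cols)))
    stopf("FO and RRA columns must come in matched <GROUP>_FO / <GROUP>_RRA pairs")
  if (length(groups) == 0) stopf("no <GROUP>_FO/_RRA column pairs found")
  if (anyDuplicated(df$phylum)) stopf("duplicate phylum rows in profile table")
  fo <- as.matrix(df[, fo_cols, drop = FALSE])
  rra <- as.matrix(df[, rra_cols, drop = FALSE])
  dimnames(fo) <- dimnames(rra) <- list(df$phylum, groups)
  structure(list(rank = "phylum", groups = groups,
                 n = if (is.null(n)) rep(NA_integer_, length(groups))
                     else as.integer(n[groups]),
                 fo = fo, rra = rra,
                 categories = stats::setNames(df$category, df$phylum)),
            class = "diet_profile")
}
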