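#' Read a sample-to-population map
#'
#' The popmap is a TSV with header columns `sample`, `population`, `species`
#' (extra columns such as `latitude`, `longitude`, `altitude` are carried
#' along). Every analyzed sample must appear exactly once.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` of class `hap_popmap` with one row per sample.
#' @export
read_popmap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  as_popmap(df)
}

#' Build a popmap from a data frame
#'
#' @param df data frame with character columns `sample`, `population`,
#'   `species`.
#' @return A `data.frame` of class `hap_popmap`.
#' @export
as_popmap <- function(df) {
  need <- c("sample", "population", "species")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("popmap is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in need) {
    if (any(is.na(df[[col]]) | !nzchar(df[[col]])))
      stop("popmap has empty values in column '", col, "'", call. = FALSE)
  }
  if (anyDuplicated(df$sample))
    stop("duplicate sample in popmap: ",
         df$sample[duplicated(df$sample)][1], call. = FALSE)
  # a population code must not span two species
  sp_per_pop <- tapply(df$species, df$population, function(s) length(unique(s)))
  if (any(sp_per_pop > 1))
    stop("population assigned to more than one species: ",
         names(sp_per_pop)[sp_per_pop > 1][1], call. = FALSE)
  class(df) <- c("hap_popmap", "data.frame")
  df
}

#' Look up populations for samples
#'
#' Phased sequence copies named `<sample>_a` / `<sample>_b` are mapped back
#' to their individual's entry.
#'
#' @param popmap a `hap_popmap`.
#' @param ids sample (or phased copy) ids.
#' @param field which column to return.
#' @return character vector parallel to `ids`.
#' @export
popmap_lookup <- function(popmap, ids, field = "population") {
  base <- ifelse(ids %in% popmap$sample, ids, sub("_[ab]$", "", ids))
  idx <- match(base, popmap$sample)
  if (anyNA(idx))
    stop("sample(s) missing from popmap: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  popmap[[field]][idx]
}
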