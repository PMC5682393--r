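#' Read a haplotype count table
#'
#' Reads the compact per-population haplotype frequency encoding used for the
#' published count tables: a CSV with columns `population`, `species`, `n`
#' and `haplotypes`, the last holding `"H2:8;H3:2"`-style copy counts. Each
#' row's counts must sum to its `n`.
#'
#' @param path path to the CSV file.
#' @return An object of class `hap_count_table`: a data frame with columns
#'   `population`, `species`, `n`, plus a list column `counts` of named
#'   integer vectors (haplotype label -> copy count).
#' @export
read_haplotype_count_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character",
                                       "integer", "character"))
  need <- c("population", "species", "n", "haplotypes")
  if (!all(need %in% names(df)))
    stop("count table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  counts <- lapply(seq_len(nrow(df)), function(i) {
    parts <- strsplit(df$haplotypes[i], ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    if (any(lengths(kv) != 2))
      stop("malformed haplotype field in row ", i, call. = FALSE)
    cts <- as.integer(vapply(kv, `[`, "", 2))
    names(cts) <- vapply(kv, `[`, "", 1)
    if (any(is.na(cts)) || any(cts < 0))
      stop("counts must be non-negative integers (row ", i, ")", call. = FALSE)
    if (sum(cts) != df$n[i])
      stop("row ", i, " (", df$population[i], "): counts sum to ", sum(cts),
           " but n = ", df$n[i], call. = FALSE)
    cts
  })
  out <- df[c("population", "species", "n")]
  out$counts <- counts
  class(out) <- c("hap_count_table", "data.frame")
  out
}

#' Distinct haplotype labels in a count table
#'
#' @param hct a `hap_count_table`.
#' @return character vector of labels in first-occurrence order.
#' @export
count_table_labels <- function(hct) {
  labs <- unlist(lapply(hct$counts, names), use.names = FALSE)
  labs[!duplicated(labs)]
}

#' Expand a count table into a synthetic alignment and popmap
#'
#' Constructs a synthetic realization of a printed haplotype count table:
#' each distinct label is assigned a distinct synthetic sequence (all-`A`
#' background with a private `T` at the label's own site, so all haplotypes
#' are mutually distinct), and each population row contributes the stated
#' number of copies. The sequences are placeholders for bookkeeping checks
#' (label counting, collapsing, diversity from counts); they carry no real
#' distance structure.
#'
#' @param hct a `hap_count_table`.
#' @param locus_name label for the synthetic alignment.
#' @return list with elements `alignment` ([hap_alignment()]) and `popmap`.
#' @export
expand_count_table <- function(hct, locus_name = "synthetic") {
  labs <- count_table_labels(hct)
  L <- length(labs)
  hap_seq <- matrix("A", nrow = L, ncol = L, dimnames = list(labs, NULL))
  hap_seq[cbind(seq_len(L), seq_len(L))] <- "T"
  ids <- character(0); pops <- character(0); sps <- character(0)
  rows <- list()
  for (i in seq_len(nrow(hct))) {
    cts <- hct$counts[[i]]
    for (lab in names(cts)) {
      k <- cts[[lab]]
      if (k == 0) next
      new_ids <- sprintf("%s_%s_%d", hct$population[i], lab, seq_len(k))
      ids <- c(ids, new_ids)
      rows <- c(rows, rep(list(hap_seq[lab, ]), k))
      pops <- c(pops, rep(hct$population[i], k))
      sps <- c(sps, rep(hct$species[i], k))
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  list(alignment = hap_alignment(m, locus_name),
       popmap = as_popmap(data.frame(sample = ids, population = pops,
                                     species = sps,
                                     stringsAsFactors = FALSE)))
}
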