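#' Aligned haploid sequence sets
#'
#'
#' @description
#' An alignment is stored as a character matrix (rows = samples, columns =
#' aligned sites) over the IUPAC alphabet used here: `A C G T`, the six
#' heterozygote codes `R Y M K S W`, missing `N`, and the gap `-`. All
#' coordinates inside the package are 0-based half-open; only printed reports
#' use 1-based site numbers.
#'
#' @param seq_matrix character matrix of single uppercase characters with
#'   unique non-empty rownames (sample ids).
#' @param locus_name label for the locus the alignment covers.
#' @return An object of class `hap_alignment`: a list with elements `seq`
#'   (the matrix), `locus_name`, and `length` (number of sites).
#' @export
hap_alignment <- function(seq_matrix, locus_name = "locus") {
  if (!is.matrix(seq_matrix) || !is.character(seq_matrix))
    stop("seq_matrix must be a character matrix", call. = FALSE)
  ids <- rownames(seq_matrix)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all samples must have non-empty ids", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1], call. = FALSE)
  bad <- setdiff(unique(as.vector(seq_matrix)), ALN_ALPHABET)
  if (length(bad))
    stop("illegal alignment character(s): ", paste(bad, collapse = " "),
         call. = FALSE)
  structure(list(seq = seq_matrix, locus_name = locus_name,
                 length = ncol(seq_matrix)),
            class = "hap_alignment")
}

ALN_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "M", "K", "S", "W", "N", "-")

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> locus '%s': %d samples x %d sites\n",
              x$locus_name, nrow(x$seq), x$length))
  invisible(x)
}

n_samples <- function(aln) nrow(aln$seq)
sample_ids <- function(aln) rownames(aln$seq)

#' Read an aligned FASTA file
#'
#' Sample ids are the header token up to the first whitespace. Sequences are
#' uppercased and validated against the package alphabet; all records must
#' have equal length.
#'
#' @param path path to a FASTA file with at least two records.
#' @param locus_name label attached to the alignment.
#' @return A [hap_alignment()].
#' @export
read_alignment <- function(path, locus_name = "locus") {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  if (length(recs) < 2)
    stop("alignment must contain at least 2 records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1], call. = FALSE)
  chars <- lapply(recs, function(s) strsplit(toupper(s), "")[[1]])
  lens <- lengths(chars)
  if (length(unique(lens)) != 1)
    stop("sequences are not aligned: lengths ",
         paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
  m <- do.call(rbind, chars)
  dimnames(m) <- list(ids, NULL)
  hap_alignment(m, locus_name)
}

#' Write an alignment to FASTA
#'
#' Lines are wrapped at 70 columns.
#'
#' @param aln a [hap_alignment()].
#' @param path output file path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  seqinr::write.fasta(as.list(unname(seqs)), names = rownames(aln$seq),
                      file.out = path, nbchar = 70, as.string = TRUE)
  invisible(path)
}

#' Concatenate alignments of the same samples
#'
#' Per-sample concatenation of several loci (e.g. the three chloroplast
#' fragments) into one alignment, in the order the loci are given. The sample
#' sets must be identical; rows are matched by id, using the first
#' alignment's sample order.
#'
#' @param alignments list of [hap_alignment()] objects.
#' @param locus_name label for the combined alignment.
#' @return A [hap_alignment()] whose length is the sum of the input lengths.
#' @export
concatenate_loci <- function(alignments, locus_name = "concatenated") {
  stopifnot(length(alignments) >= 1)
  if (length(alignments) == 1) return(alignments[[1]])
  ids <- sample_ids(alignments[[1]])
  for (a in alignments[-1]) {
    if (!setequal(sample_ids(a), ids))
      stop("sample sets differ between loci", call. = FALSE)
  }
  m <- do.call(cbind, lapply(alignments, function(a) a$seq[ids, , drop = FALSE]))
  rownames(m) <- ids
  hap_alignment(m, locus_name)
}

#' Subset an alignment to a set of samples
#'
#' @param aln a [hap_alignment()].
#' @param ids sample ids to keep, in the order given.
#' @return A [hap_alignment()].
#' @export
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, sample_ids(aln))
  if (length(missing))
    stop("samples not in alignment: ", paste(missing, collapse = ", "),
         call. = FALSE)
  hap_alignment(aln$seq[ids, , drop = FALSE], aln$locus_name)
}
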