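IUPAC_HET <- list(R = c("A", "G"), Y = c("C", "T"), M = c("A", "C"),
                  K = c("G", "T"), S = c("C", "G"), W = c("A", "T"))

#' Split IUPAC heterozygote codes into two sequence copies
#'
#' Each individual carrying at least one of the six heterozygote codes
#' (R, Y, M, K, S, W) is resolved into two pseudo-haplotype copies `_a` and
#' `_b`. The phasing rule is a deterministic heuristic, not a statistical
#' phasing algorithm: at the individual's first ambiguous site the
#' alphabetically smaller base goes to copy `_a`; at every later ambiguous
#' site the two possible base-to-copy assignments are scored by the summed
#' Hamming distance of each partially resolved copy to its nearest fully
#' resolved (ambiguity-free) sequence in the sample, and the smaller score
#' wins (ties resolve alphabetically, smaller base to `_a`). Unambiguous
#' individuals are duplicated when `ploidy = 2` (the nuclear-locus
#' convention) or passed through once when `ploidy = 1`.
#'
#' @param aln a [hap_alignment()]; codes other than the six listed (plus
#'   `A C G T N -`) raise an error.
#' @param ploidy 2 to emit two copies for every individual, 1 to emit
#'   unambiguous individuals once.
#' @return A [hap_alignment()] with ids suffixed `_a`/`_b` for split
#'   individuals.
#' @export
phase_ambiguities <- function(aln, ploidy = 2) {
  m <- aln$seq
  bad <- setdiff(unique(as.vector(m)),
                 c("A", "C", "G", "T", "N", "-", names(IUPAC_HET)))
  if (length(bad))
    stop("unsupported ambiguity code(s): ", paste(bad, collapse = " "),
         call. = FALSE)
  amb_rows <- apply(m, 1, function(x) any(x %in% names(IUPAC_HET)))
  refs <- m[!amb_rows, , drop = FALSE]  # fully resolved individuals
  out <- list()
  for (id in rownames(m)) {
    x <- m[id, ]
    amb <- which(x %in% names(IUPAC_HET))
    if (!length(amb)) {
      if (ploidy == 2) {
        out[[paste0(id, "_a")]] <- x
        out[[paste0(id, "_b")]] <- x
      } else out[[id]] <- x
      next
    }
    a <- b <- x
    first <- amb[1]
    bases <- IUPAC_HET[[x[first]]]  # already sorted alphabetically
    a[first] <- bases[1]; b[first] <- bases[2]
    resolved <- setdiff(seq_along(x), amb)  # sites comparable so far
    resolved <- c(resolved, first)
    for (s in amb[-1]) {
      bases <- IUPAC_HET[[x[s]]]
      if (nrow(refs)) {
        sc <- vapply(1:2, function(opt) {
          aa <- a; bb <- b
          aa[s] <- bases[if (opt == 1) 1 else 2]
          bb[s] <- bases[if (opt == 1) 2 else 1]
          idx <- c(resolved, s)
          min(apply(refs[, idx, drop = FALSE], 1,
                    function(r) sum(r != aa[idx]))) +
            min(apply(refs[, idx, drop = FALSE], 1,
                      function(r) sum(r != bb[idx])))
        }, 0)
        opt <- if (sc[2] < sc[1]) 2L else 1L
      } else opt <- 1L
      a[s] <- bases[if (opt == 1) 1 else 2]
      b[s] <- bases[if (opt == 1) 2 else 1]
      resolved <- c(resolved, s)
    }
    out[[paste0(id, "_a")]] <- a
    out[[paste0(id, "_b")]] <- b
  }
  m2 <- do.call(rbind, out)
  rownames(m2) <- names(out)
  hap_alignment(m2, aln$locus_name)
}

#' Remove gapped or missing alignment columns
#'
#' Under `complete_deletion` (the default used for all statistics) every
#' column containing `-` or `N` in any sequence is dropped, yielding one
#' deterministic alignment length for downstream diversity and mismatch
#' computations. Under `pairwise` all columns are kept and `-`/`N` handling
#' is deferred to [hamming_matrix()].
#'
#' @param aln a [hap_alignment()].
#' @param policy `"complete_deletion"` or `"pairwise"`.
#' @return A [hap_alignment()] with attribute `site_policy` set.
#' @export
filter_sites <- function(aln, policy = c("complete_deletion", "pairwise")) {
  policy <- match.arg(policy)
  m <- aln$seq
  if (policy == "complete_deletion") {
    keep <- !apply(m == "-" | m == "N", 2, any)
    if (!any(keep))
      stop("all columns removed by complete deletion", call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  out <- hap_alignment(m, aln$locus_name)
  attr(out, "site_policy") <- policy
  out
}

#' Collapse identical sequences into haplotypes
#'
#' Identical sequences are merged; haplotype labels `H1, H2, ...` are
#' assigned in order of first occurrence (sample order in the alignment).
#'
#' @param aln a [hap_alignment()], normally after [filter_sites()].
#' @param popmap a `hap_popmap` covering every sample (phased copies are
#'   mapped through their individual).
#' @param ploidy_factor copies per individual the alignment represents
#'   (1 = haploid chloroplast, 2 = phased nuclear).
#' @return An object of class `haplotype_set`: list with `seq` (haplotype x
#'   site character matrix), `counts` (population x haplotype integer
#'   matrix), `provenance` (list of sample ids per haplotype), `pop_species`
#'   (species of each population row) and `ploidy_factor`.
#' @export
collapse_haplotypes <- function(aln, popmap, ploidy_factor = 1) {
  m <- aln$seq
  key <- apply(m, 1, paste, collapse = "")
  first <- !duplicated(key)
  labels <- paste0("H", seq_len(sum(first)))
  names(labels) <- key[first]
  hap_of <- unname(labels[key])
  labels <- unname(labels)
  pops <- popmap_lookup(popmap, rownames(m))
  pop_levels <- unique(popmap$population)
  pop_levels <- pop_levels[pop_levels %in% pops]
  counts <- table(factor(pops, levels = pop_levels),
                  factor(hap_of, levels = labels))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  seqm <- m[first, , drop = FALSE]
  rownames(seqm) <- labels
  prov <- split(rownames(m), factor(hap_of, levels = labels))
  sp <- popmap$species[match(pop_levels, popmap$population)]
  structure(list(seq = seqm, counts = counts, provenance = prov,
                 pop_species = stats::setNames(sp, pop_levels),
                 ploidy_factor = ploidy_factor),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes, %d populations, %d copies\n",
              nrow(x$seq), nrow(x$counts), sum(x$counts)))
  invisible(x)
}

#' Build a haplotype set directly from a count table
#'
#' Convenience wrapper: [expand_count_table()] then [collapse_haplotypes()].
#' Used to treat printed count tables as first-class inputs. Haplotype labels
#' follow first occurrence in the table's row order.
#'
#' @param hct a `hap_count_table`.
#' @param ploidy_factor copies per individual.
#' @return A `haplotype_set`.
#' @export
hapset_from_count_table <- function(hct, ploidy_factor = 1) {
  ex <- expand_count_table(hct)
  collapse_haplotypes(ex$alignment, ex$popmap, ploidy_factor)
}

#' Pairwise Hamming distances between haplotypes
#'
#' `d[i, j]` is the number of differing sites between haplotypes i and j.
#' Under the `pairwise` site policy, sites with `-` or `N` in either
#' sequence are skipped for that pair; under `complete_deletion` the
#' alignment has no such sites left.
#'
#' @param hs a `haplotype_set` (or a [hap_alignment()], whose rows are then
#'   compared directly).
#' @param policy how `-`/`N` are treated, see above.
#' @return symmetric integer matrix with zero diagonal, labelled by
#'   haplotype.
#' @export
hamming_matrix <- function(hs, policy = c("complete_deletion", "pairwise")) {
  policy <- match.arg(policy)
  m <- if (inherits(hs, "haplotype_set")) hs$seq else hs$seq
  H <- nrow(m)
  d <- matrix(0L, H, H, dimnames = list(rownames(m), rownames(m)))
  if (H < 2) return(d)
  miss <- m == "-" | m == "N"
  for (i in seq_len(H - 1)) {
    for (j in (i + 1):H) {
      cmp <- m[i, ] != m[j, ]
      if (policy == "pairwise") cmp <- cmp & !miss[i, ] & !miss[j, ]
      d[i, j] <- d[j, i] <- sum(cmp)
    }
  }
  d
}

#' Per-haplotype total copy counts
#'
#' @param hs a `haplotype_set`.
#' @return named integer vector of copies per haplotype.
#' @export
haplotype_counts <- function(hs) colSums(hs$counts)
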