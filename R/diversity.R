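#' Construct a genotype matrix
#'
#' Container for diploid allele-pair calls (KASPar-style) across samples
#' and loci.  Calls are strings \code{"A:G"} (allele codes separated by a
#' colon, order ignored) or \code{NA} for a missed call.
#'
#' @param calls Character matrix, samples in rows, loci in columns.
#' @param sample_ids,locus_ids Row/column identifiers (default from
#'   dimnames).
#' @param groups Optional character vector of group labels per sample
#'   (e.g. \code{"wild"} / \code{"cultivated"}); \code{NA} for
#'   unassigned.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            locus_ids = colnames(calls), groups = NULL) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(calls)))
  stopifnot(length(sample_ids) == nrow(calls),
            length(locus_ids) == ncol(calls))
  dimnames(calls) <- list(sample_ids, locus_ids)
  if (is.null(groups)) groups <- rep(NA_character_, nrow(calls))
  stopifnot(length(groups) == nrow(calls))
  structure(list(calls = calls, sample_ids = sample_ids,
                 locus_ids = locus_ids,
                 groups = stats::setNames(as.character(groups), sample_ids)),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      length(x$locus_ids), "loci\n")
  grp <- table(x$groups, useNA = "ifany")
  cat("groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# split "A:G" calls into a 2-column matrix of allele codes
split_calls <- function(calls) {
  parts <- strsplit(calls, ":", fixed = TRUE)
  bad <- !is.na(calls) & lengths(parts) != 2L
  if (any(bad)) stop("malformed genotype call(s): ",
                     paste(utils::head(calls[bad]), collapse = ", "))
  a1 <- vapply(parts, function(p) if (length(p) == 2L) p[1] else NA_character_, "")
  a2 <- vapply(parts, function(p) if (length(p) == 2L) p[2] else NA_character_, "")
  cbind(a1, a2)
}

#' Allele frequency spectrum at one locus
#'
#' Counts both alleles of every non-missing diploid call; missing calls do
#' not enter the denominator.
#'
#' @param calls Character vector of \code{"X:Y"} calls (with \code{NA}
#'   for missing) at a single locus.
#' @return A named numeric vector of allele frequencies, decreasing,
#'   summing to 1.
#' @export
allele_frequencies <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) stop("locus has no non-missing calls")
  al <- as.vector(split_calls(calls))
  tab <- table(al)
  p <- as.numeric(tab) / sum(tab)
  sort(stats::setNames(p, names(tab)), decreasing = TRUE)
}

#' Botstein polymorphism information content (PIC)
#'
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}
#' where \eqn{p_i} are the locus allele frequencies.  PIC measures the
#' informativeness of a marker for linkage studies; it is bounded above
#' by the gene diversity and is 0 for a monomorphic locus.
#'
#' @param p Numeric vector of allele frequencies (sums to 1).
#' @return The PIC value in [0, 1).
#' @examples
#' pic(c(0.5, 0.5))   # 0.375
#' pic(c(0.8, 0.2))   # 0.2688
#' @export
pic <- function(p) {
  check_spectrum(p)
  s2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p_i^2)^2 - sum p_i^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Gene diversity (expected heterozygosity)
#'
#' \deqn{H_e = 1 - \sum_i p_i^2}
#'
#' @param p Numeric vector of allele frequencies (sums to 1).
#' @return Expected heterozygosity in [0, 1).
#' @export
gene_diversity <- function(p) {
  check_spectrum(p)
  1 - sum(p^2)
}

check_spectrum <- function(p) {
  if (length(p) < 1L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("allele frequencies must be nonnegative and sum to 1")
  invisible(p)
}

#' Observed heterozygosity at one locus
#'
#' Fraction of non-missing calls whose two alleles differ.
#'
#' @param calls Character vector of \code{"X:Y"} calls at one locus.
#' @return Proportion heterozygous in [0, 1].
#' @export
observed_heterozygosity <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) stop("locus has no non-missing calls")
  al <- split_calls(calls)
  mean(al[, 1] != al[, 2])
}

#' Round half away from zero
#'
#' Report-style rounding in which 0.375 becomes 0.38 at two decimals
#' (base R's banker's rounding would give 0.38 here too, but 0.125 -> 0.13
#' versus base R's 0.12).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Quality-control filter for a genotype matrix
#'
#' Drops samples whose missing-call fraction exceeds
#' \code{max_sample_missing} (strictly), then loci whose missing fraction
#' exceeds \code{max_locus_missing} (strictly) or, optionally, that are
#' monomorphic across the retained samples.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param max_sample_missing Sample missingness threshold (default 0.80).
#' @param max_locus_missing Locus missingness threshold (default 0.90).
#' @param drop_monomorphic Drop loci with a single observed allele
#'   (default TRUE).
#' @return A list: \code{matrix} (the filtered \code{genotype_matrix})
#'   and \code{exclusions} (data.frame of id, kind, reason).
#' @export
qc_filter <- function(gm, max_sample_missing = 0.80,
                      max_locus_missing = 0.90, drop_monomorphic = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  excl <- list()
  smiss <- rowMeans(is.na(gm$calls))
  bad_s <- smiss > max_sample_missing
  for (id in gm$sample_ids[bad_s])
    excl[[length(excl) + 1L]] <- data.frame(
      id = id, kind = "sample",
      reason = sprintf("missing fraction %.3f > %.2f",
                       smiss[[id]], max_sample_missing),
      stringsAsFactors = FALSE)
  calls <- gm$calls[!bad_s, , drop = FALSE]

  lmiss <- colMeans(is.na(calls))
  n_alleles <- apply(calls, 2, function(cl) {
    cl <- cl[!is.na(cl)]
    if (length(cl) == 0L) return(0L)
    length(unique(as.vector(split_calls(cl))))
  })
  bad_l <- lmiss > max_locus_missing |
    (drop_monomorphic & n_alleles <= 1L)
  for (id in gm$locus_ids[bad_l]) {
    reason <- if (lmiss[[id]] > max_locus_missing)
      sprintf("missing fraction %.3f > %.2f", lmiss[[id]], max_locus_missing)
    else "monomorphic across retained samples"
    excl[[length(excl) + 1L]] <- data.frame(
      id = id, kind = "locus", reason = reason, stringsAsFactors = FALSE)
  }
  calls <- calls[, !bad_l, drop = FALSE]
  if (nrow(calls) == 0L || ncol(calls) == 0L)
    stop("QC removed every sample or locus; check thresholds and input")
  out <- genotype_matrix(calls, groups = gm$groups[rownames(calls)])
  exclusions <- if (length(excl)) do.call(rbind, excl)
  else data.frame(id = character(), kind = character(),
                  reason = character(), stringsAsFactors = FALSE)
  list(matrix = out, exclusions = exclusions)
}

#' Per-locus diversity summary
#'
#' One row per locus: major allele frequency, allele number, gene
#' diversity, observed heterozygosity, overall PIC, and PIC within each
#' sample group.  A group PIC is \code{NA} when the locus is monomorphic
#' (or entirely missing) within that group, the usual "N/A" convention of
#' marker validation tables.
#'
#' @param gm A QC-passed \code{\link{genotype_matrix}}.
#' @return A data.frame with columns \code{locus}, \code{maf}, \code{k},
#'   \code{gene_diversity}, \code{ho}, \code{pic}, and one
#'   \code{pic_<group>} column per group label present.
#' @export
locus_summary <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  grp_levels <- sort(unique(gm$groups[!is.na(gm$groups)]))
  rows <- lapply(gm$locus_ids, function(lid) {
    cl <- gm$calls[, lid]
    p <- allele_frequencies(cl)
    row <- data.frame(locus = lid, maf = unname(p[1]), k = length(p),
                      gene_diversity = gene_diversity(p),
                      ho = observed_heterozygosity(cl),
                      pic = pic(p), stringsAsFactors = FALSE)
    for (g in grp_levels) {
      gcl <- cl[gm$groups[gm$sample_ids] %in% g]
      gcl <- gcl[!is.na(gcl)]
      val <- NA_real_
      if (length(gcl) > 0L) {
        gp <- allele_frequencies(gcl)
        if (length(gp) > 1L) val <- pic(gp)
      }
      row[[paste0("pic_", g)]] <- val
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Column means of a locus summary
#'
#' Arithmetic means over the defined (non-\code{NA}) entries of each
#' numeric column, as printed in validation table footers.
#'
#' @param summary A \code{\link{locus_summary}} table.
#' @return Named numeric vector of column means.
#' @export
summary_means <- function(summary) {
  num <- vapply(summary, is.numeric, TRUE)
  colMeans(summary[, num & names(summary) != "k", drop = FALSE],
           na.rm = TRUE)
}

#' Number of loci polymorphic within a group
#'
#' A locus counts as polymorphic within a group when its group PIC is
#' defined (more than one allele observed among that group's samples).
#'
#' @param summary A \code{\link{locus_summary}} table.
#' @param group Group label.
#' @return Integer count.
#' @export
polymorphic_count <- function(summary, group) {
  col <- paste0("pic_", group)
  if (!col %in% names(summary))
    stop("unknown group: ", group)
  sum(!is.na(summary[[col]]))
}
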