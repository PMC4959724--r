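#' SSR mining parameters
#'
#' Thresholds for perfect microsatellite (SSR) detection.  The defaults
#' target di- to tetra-nucleotide motifs repeated at least five times and
#' spanning at least 10 bp, the criteria commonly used for marker-grade
#' SSRs in plant genome surveys.
#'
#' @param min_unit Smallest motif length considered (bp).  Mononucleotide
#'   runs are never mined, so this must be at least 2.
#' @param max_unit Largest motif length considered (bp), at most 4.
#' @param min_repeats Minimum number of complete tandem copies of the motif.
#' @param min_length Minimum total span of the repeat (bp).
#' @return An object of class \code{ssr_params}.
#' @export
ssr_params <- function(min_unit = 2L, max_unit = 4L,
                       min_repeats = 5L, min_length = 10L) {
  min_unit <- as.integer(min_unit); max_unit <- as.integer(max_unit)
  min_repeats <- as.integer(min_repeats); min_length <- as.integer(min_length)
  if (min_unit < 2L || max_unit > 4L || min_unit > max_unit)
    stop("unit sizes must satisfy 2 <= min_unit <= max_unit <= 4")
  if (min_repeats < 2L) stop("min_repeats must be >= 2")
  if (min_length < 2L * min_unit)
    stop("min_length must be at least twice min_unit")
  structure(list(min_unit = min_unit, max_unit = max_unit,
                 min_repeats = min_repeats, min_length = min_length),
            class = "ssr_params")
}

# TRUE when the motif is a whole-number repetition of a shorter unit
# (e.g. "ATAT" of "AT", "AAA" of "A"); such motifs belong to the shorter
# unit size (or, for mononucleotides, are excluded altogether).
is_reducible_motif <- function(motif) {
  u <- nchar(motif)
  ch <- strsplit(motif, "")[[1]]
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (all(ch == rep_len(ch[seq_len(d)], u))) return(TRUE)
  }
  FALSE
}

#' Canonical strand-pair class of an SSR motif
#'
#' SSR motifs that are rotations of each other, or that lie on opposite
#' strands, describe the same repeat locus.  The canonical class collapses
#' all of these into one label: the lexicographic minimum over all
#' rotations of the motif and of its reverse complement, rendered as
#' \code{"X/Y"} with the smaller member first (or a single \code{"X"} when
#' both strands reduce to the same rotation minimum, as for "AT").
#' Under this convention "GA", "AG", "CT" and "TC" all map to "AG/CT".
#'
#' @param motif A DNA motif of length 2--4 over ACGT, not reducible to a
#'   shorter repeated unit.
#' @return A single class label string.
#' @examples
#' canonical_class("GA")   # "AG/CT"
#' canonical_class("TTG")  # "AAC/GTT" (the AG-rotation-minimal CAA/TTG class)
#' @export
canonical_class <- function(motif) {
  motif <- toupper(motif)
  u <- nchar(motif)
  if (u < 2L || u > 4L) stop("motif length must be 2-4")
  if (grepl("[^ACGT]", motif)) stop("motif must be over ACGT: ", motif)
  if (is_reducible_motif(motif))
    stop("motif reduces to a shorter unit: ", motif)
  rotmin <- function(m) {
    ch <- strsplit(m, "")[[1]]
    n <- length(ch)
    rots <- vapply(seq_len(n), function(i)
      paste(ch[c(i:n, seq_len(i - 1L))[seq_len(n)]], collapse = ""), "")
    min(rots)
  }
  fwd <- rotmin(motif)
  rev <- rotmin(revcomp_string(motif))
  if (fwd == rev) fwd else paste(sort(c(fwd, rev)), collapse = "/")
}

revcomp_string <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Find perfect SSRs in a DNA sequence
#'
#' Scans one sequence for maximal perfect tandem repeats with unit size in
#' \code{[min_unit, max_unit]}, at least \code{min_repeats} complete
#' copies, and total span of at least \code{min_length} bp.  Runs never
#' extend across an \code{N}; a trailing partial unit is not counted.
#' When runs of different unit sizes overlap, the smaller unit wins, and a
#' motif that is itself a repetition of a shorter unit is never reported
#' at the larger unit size (so poly-A stretches, whose "di-nucleotide"
#' motif would be "AA", are not reported at all).
#'
#' @param seq A single DNA sequence (character scalar or
#'   \code{\link[Biostrings]{DNAString}}), alphabet ACGTN.
#' @param params An \code{\link{ssr_params}} object.
#' @param contig_id Identifier recorded in the output.
#' @return A data.frame with one row per SSR locus: \code{contig_id},
#'   \code{start} (0-based inclusive), \code{end} (exclusive),
#'   \code{motif}, \code{class} (see \code{\link{canonical_class}}),
#'   \code{n_repeats} and \code{length}.
#' @export
find_ssrs <- function(seq, params = ssr_params(), contig_id = "seq1") {
  s <- toupper(as.character(seq))
  if (nchar(s) == 0L) return(empty_ssr_table())
  if (grepl("[^ACGTN]", s)) stop("sequence contains non-ACGTN characters")
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  usable <- ch != "N"

  hits <- list()
  for (u in seq(params$min_unit, params$max_unit)) {
    if (n < 2L * u) next
    # eq[i] <=> ch[i] == ch[i + u], both non-N: positions i = 1 .. n-u
    eq <- ch[seq_len(n - u)] == ch[(u + 1L):n] &
      usable[seq_len(n - u)] & usable[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    for (j in keep) {
      m <- r$lengths[j]                 # matched comparisons
      total <- m + u                    # periodic stretch length
      reps <- total %/% u
      if (reps < params$min_repeats) next
      span <- reps * u
      if (span < params$min_length) next
      start0 <- starts[j] - 1L          # 0-based
      motif <- substr(s, start0 + 1L, start0 + u)
      if (is_reducible_motif(motif)) next
      hits[[length(hits) + 1L]] <- data.frame(
        contig_id = contig_id, start = start0, end = start0 + span,
        motif = motif, class = canonical_class(motif),
        n_repeats = reps, length = span, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty_ssr_table())
  out <- do.call(rbind, hits)
  out <- out[order(nchar(out$motif), out$start), , drop = FALSE]
  # smallest-unit priority: drop larger-unit loci overlapping an accepted
  # smaller-unit locus
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i == nrow(out)) break
    later <- (i + 1L):nrow(out)
    ov <- keep[later] &
      nchar(out$motif[later]) > nchar(out$motif[i]) &
      out$start[later] < out$end[i] & out$end[later] > out$start[i]
    keep[later][ov] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start, nchar(out$motif)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_ssr_table <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             motif = character(), class = character(),
             n_repeats = integer(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Mine SSRs across a set of sequences
#'
#' @param seqs A named character vector or
#'   \code{\link[Biostrings]{DNAStringSet}} of contigs.
#' @param params An \code{\link{ssr_params}} object.
#' @return Row-bound \code{\link{find_ssrs}} tables for all contigs.
#' @export
find_ssrs_set <- function(seqs, params = ssr_params()) {
  if (inherits(seqs, "DNAStringSet")) {
    ids <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- ids
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  tabs <- lapply(names(seqs), function(id)
    find_ssrs(seqs[[id]], params, contig_id = id))
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Format a marker frequency as "1 per X kb"
#'
#' One marker per \code{total_bp / count} bases, printed to one decimal in
#' kb, switching to Mb above 1,000 kb.
#'
#' @param count Number of markers.
#' @param total_bp Size of the sequence space searched (bp).
#' @return A string such as \code{"1 per 9.3 kb"}, or \code{NA} for zero
#'   markers.
#' @export
marker_frequency <- function(count, total_bp) {
  if (total_bp <= 0) stop("total_bp must be positive")
  if (count == 0) return(NA_character_)
  bp_per <- total_bp / count
  kb <- bp_per / 1000
  if (kb > 1000) sprintf("1 per %.1f Mb", kb / 1000)
  else sprintf("1 per %.1f kb", kb)
}

#' Summarize mined SSR loci
#'
#' Counts loci by motif unit size and by canonical class, and reports the
#' genomic frequency of each group as "1 per X kb" of searched sequence.
#'
#' @param loci An SSR locus table from \code{\link{find_ssrs_set}}.
#' @param total_bp Total length of sequence searched (bp).
#' @return A list with components \code{by_unit} (data.frame: unit size,
#'   count, frequency), \code{by_class} (data.frame: class, unit, count,
#'   frequency), \code{total} (count) and \code{total_frequency}.
#' @export
summarize_ssrs <- function(loci, total_bp) {
  if (total_bp <= 0) stop("total_bp must be positive")
  unit <- nchar(loci$motif)
  units <- c(di = 2L, tri = 3L, tetra = 4L)
  by_unit <- data.frame(
    unit_size = unname(units),
    unit_name = names(units),
    count = vapply(units, function(u) sum(unit == u), 0L),
    stringsAsFactors = FALSE)
  by_unit$frequency <- vapply(by_unit$count, marker_frequency, "",
                              total_bp = total_bp)
  if (nrow(loci) > 0L) {
    cls <- table(loci$class)
    by_class <- data.frame(class = names(cls),
                           count = as.integer(cls),
                           stringsAsFactors = FALSE)
    by_class$unit_size <- nchar(sub("/.*$", "", by_class$class))
    by_class$frequency <- vapply(by_class$count, marker_frequency, "",
                                 total_bp = total_bp)
    by_class <- by_class[order(by_class$unit_size, -by_class$count), ]
    rownames(by_class) <- NULL
  } else {
    by_class <- data.frame(class = character(), count = integer(),
                           unit_size = integer(), frequency = character(),
                           stringsAsFactors = FALSE)
  }
  total <- nrow(loci)
  stopifnot(sum(by_unit$count) == total, sum(by_class$count) == total)
  list(by_unit = by_unit, by_class = by_class, total = total,
       total_frequency = marker_frequency(total, total_bp),
       total_bp = total_bp)
}
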