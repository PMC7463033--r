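#' In silico digestion of a DNA sequence into a label map
#'
#' Finds every occurrence of the recognition motif on either strand of the
#' sequence and records one label per occurrence at the 1-based start of the
#' occurrence in forward coordinates. Occurrences found on both strands at
#' the same position (palindromic motifs such as \code{CTTAAG}) collapse to a
#' single label. `N` bases never match.
#'
#' @param sequence a character string or [Biostrings::DNAString] over
#'   `A,C,G,T,N`.
#' @param motif recognition sequence, e.g. `"CTTAAG"` (DLE-1) or
#'   `"GCTCTTC"` (Nt.BspQI).
#' @param map_id identifier for the resulting map.
#' @param offset constant bp shift added to each motif start (default 0; a
#'   constant shift cancels in downstream length-difference scores).
#' @return a [label_map] of length equal to the sequence length.
#' @export
digest_sequence <- function(sequence, motif, map_id = "digest", offset = 0) {
  if (!methods::is(sequence, "DNAString"))
    sequence <- Biostrings::DNAString(as.character(sequence))
  len <- length(sequence)
  if (len == 0) stop("digest_sequence: empty sequence")
  fwd <- Biostrings::start(Biostrings::matchPattern(motif, sequence, fixed = TRUE))
  rcm <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  rev <- Biostrings::start(Biostrings::matchPattern(rcm, sequence, fixed = TRUE))
  pos <- sort(unique(c(fwd, rev))) + offset
  pos <- pos[pos > 0 & pos <= len]
  label_map(map_id, len, pos)
}

#' Digest every breakpoint-graph segment against a reference
#'
#' @param graph a [breakpoint_graph].
#' @param reference a named [Biostrings::DNAStringSet] (names are
#'   chromosomes) resolving every segment's coordinates.
#' @param motif recognition sequence.
#' @param offset see [digest_sequence].
#' @return a named list of [label_map], one per segment, names and map ids
#'   equal to the segment ids; positions are relative to the segment start.
#' @export
digest_graph_segments <- function(graph, reference, motif, offset = 0) {
  segs <- graph$segments
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    chrom <- segs$chrom[i]
    if (!chrom %in% names(reference))
      stop("digest_graph_segments: chromosome ", chrom,
           " not in reference (segment ", segs$segment_id[i], ")")
    if (segs$start[i] < 1 || segs$end[i] > length(reference[[chrom]]))
      stop("digest_graph_segments: coordinates outside contig for segment ",
           segs$segment_id[i])
    s <- Biostrings::subseq(reference[[chrom]], segs$start[i], segs$end[i])
    out[[i]] <- digest_sequence(s, motif, map_id = as.character(segs$segment_id[i]),
                                offset = offset)
  }
  names(out) <- as.character(segs$segment_id)
  out
}

#' Extract the oriented sequence of one graph segment
#' @noRd
segment_sequence <- function(reference, chrom, start, end, orientation = "+") {
  s <- Biostrings::subseq(reference[[chrom]], start, end)
  if (orientation == "-") s <- Biostrings::reverseComplement(s)
  s
}
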