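#' Copy-number annotated breakpoint graph
#'
#' Nodes are genomic segments with estimated copy numbers; edges are
#' oriented junctions (concordant = consistent with reference adjacency,
#' discordant = rearranged) between segment sides.
#'
#' @param segments data.frame with columns `segment_id`, `chrom`, `start`,
#'   `end`, `copy_number` (1-based inclusive coordinates, `start < end`,
#'   `copy_number >= 0`).
#' @param edges data.frame with columns `from_id`, `from_side`, `to_id`,
#'   `to_side` (`"left"`/`"right"`), `type`
#'   (`"concordant"`/`"discordant"`), `multiplicity`.
#' @return an object of class `breakpoint_graph`.
#' @export
breakpoint_graph <- function(segments, edges = NULL) {
  segments$segment_id <- as.character(segments$segment_id)
  if (is.null(edges) || !nrow(edges))
    edges <- data.frame(from_id = character(0), from_side = character(0),
                        to_id = character(0), to_side = character(0),
                        type = character(0), multiplicity = numeric(0),
                        stringsAsFactors = FALSE)
  edges$from_id <- as.character(edges$from_id)
  edges$to_id <- as.character(edges$to_id)
  if (any(segments$start >= segments$end))
    stop("breakpoint_graph: every segment needs start < end")
  if (any(segments$copy_number < 0))
    stop("breakpoint_graph: copy numbers must be non-negative")
  ids <- segments$segment_id
  if (anyDuplicated(ids)) stop("breakpoint_graph: duplicated segment ids")
  if (nrow(edges)) {
    if (!all(c(edges$from_id, edges$to_id) %in% ids))
      stop("breakpoint_graph: edge references unknown segment")
    if (!all(c(edges$from_side, edges$to_side) %in% c("left", "right")))
      stop("breakpoint_graph: edge sides must be 'left' or 'right'")
  }
  structure(list(segments = segments, edges = edges),
            class = "breakpoint_graph")
}

#' @export
print.breakpoint_graph <- function(x, ...) {
  cat(sprintf("<breakpoint_graph> %d segments (%.2f Mbp), %d edges (%d discordant)\n",
              nrow(x$segments),
              sum(x$segments$end - x$segments$start + 1) / 1e6,
              nrow(x$edges), sum(x$edges$type == "discordant")))
  invisible(x)
}

#' Segment length lookup (bp, 1-based inclusive)
#' @noRd
segment_lengths <- function(graph) {
  setNames(graph$segments$end - graph$segments$start + 1,
           graph$segments$segment_id)
}

endpoint_to_side <- function(sign) if (sign == "+") "right" else "left"
side_to_sign <- function(side) if (side == "right") "+" else "-"

#' Read a breakpoint graph file
#'
#' The dialect is a documented minimal text form: one line per segment,
#' `sequence <chr>:<start>-<end> <copy_number>`, then one line per junction,
#' `edge <chr>:<pos><s>-><chr>:<pos><s> <type> <multiplicity>` where the
#' sign `+` attaches the junction at the segment whose *end* is `<pos>`
#' (right side) and `-` at the segment whose *start* is `<pos>` (left side).
#' Segment ids are assigned in file order starting at 1.
#'
#' @param path file path.
#' @return a [breakpoint_graph].
#' @export
read_breakpoint_graph <- function(path) {
  if (!file.exists(path)) stop("read_breakpoint_graph: file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines[!startsWith(lines, "#") & nzchar(lines)])
  seq_lines <- lines[startsWith(lines, "sequence")]
  edge_lines <- lines[startsWith(lines, "edge")]
  if (!length(seq_lines)) stop("read_breakpoint_graph: no sequence lines")
  parse_seq <- function(ln) {
    m <- regexec("^sequence\\s+(\\S+):(\\d+)-(\\d+)\\s+(\\S+)\\s*$", ln)
    g <- regmatches(ln, m)[[1]]
    if (length(g) != 5)
      stop("read_breakpoint_graph: malformed or CN-less sequence line: ", ln)
    cn <- suppressWarnings(as.numeric(g[5]))
    if (is.na(cn)) stop("read_breakpoint_graph: missing copy number in: ", ln)
    data.frame(chrom = g[2], start = as.numeric(g[3]), end = as.numeric(g[4]),
               copy_number = cn, stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, lapply(seq_lines, parse_seq))
  segs <- cbind(segment_id = as.character(seq_len(nrow(segs))), segs,
                stringsAsFactors = FALSE)
  find_endpoint <- function(chrom, pos, sign, ln) {
    hit <- if (sign == "+") which(segs$chrom == chrom & segs$end == pos)
           else which(segs$chrom == chrom & segs$start == pos)
    if (length(hit) != 1)
      stop("read_breakpoint_graph: edge endpoint ", chrom, ":", pos, sign,
           " does not match exactly one segment (line: ", ln, ")")
    list(id = segs$segment_id[hit], side = endpoint_to_side(sign))
  }
  edges <- NULL
  if (length(edge_lines)) {
    parse_edge <- function(ln) {
      m <- regexec(
        "^edge\\s+(\\S+):(\\d+)([+-])->(\\S+):(\\d+)([+-])\\s+(\\S+)\\s+(\\S+)\\s*$",
        ln)
      g <- regmatches(ln, m)[[1]]
      if (length(g) != 9)
        stop("read_breakpoint_graph: malformed edge line: ", ln)
      a <- find_endpoint(g[2], as.numeric(g[3]), g[4], ln)
      b <- find_endpoint(g[5], as.numeric(g[6]), g[7], ln)
      data.frame(from_id = a$id, from_side = a$side, to_id = b$id,
                 to_side = b$side, type = g[8],
                 multiplicity = as.numeric(g[9]), stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, lapply(edge_lines, parse_edge))
  }
  breakpoint_graph(segs, edges)
}

#' Write a breakpoint graph file
#'
#' Inverse of [read_breakpoint_graph]; segments are written in id order so a
#' round trip preserves ids.
#'
#' @param graph a [breakpoint_graph].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_breakpoint_graph <- function(graph, path) {
  segs <- graph$segments
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(segs)))
    writeLines(sprintf("sequence %s:%d-%d %g", segs$chrom[i],
                       as.integer(segs$start[i]), as.integer(segs$end[i]),
                       segs$copy_number[i]), con)
  ed <- graph$edges
  endpoint_str <- function(id, side) {
    j <- match(id, segs$segment_id)
    if (side == "right") sprintf("%s:%d+", segs$chrom[j], as.integer(segs$end[j]))
    else sprintf("%s:%d-", segs$chrom[j], as.integer(segs$start[j]))
  }
  for (i in seq_len(nrow(ed)))
    writeLines(sprintf("edge %s->%s %s %g",
                       endpoint_str(ed$from_id[i], ed$from_side[i]),
                       endpoint_str(ed$to_id[i], ed$to_side[i]),
                       ed$type[i], ed$multiplicity[i]), con)
  invisible(path)
}
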