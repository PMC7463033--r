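#' Ordered, oriented segment path reconstructed from the data
#'
#' @param elements data.frame with columns `segment_id`, `orientation`.
#' @param cyclic logical: does the path close on itself?
#' @param total_alignment_score summed alignment (and imputation) score
#'   supporting the path.
#' @param supporting_contigs character vector of contig ids.
#' @param copy_count optional copy-number annotation used when writing the
#'   cycles file.
#' @return object of class `reconstructed_path`.
#' @export
reconstructed_path <- function(elements, cyclic = FALSE,
                               total_alignment_score = NA_real_,
                               supporting_contigs = character(0),
                               copy_count = 1) {
  elements$segment_id <- as.character(elements$segment_id)
  if (!nrow(elements)) stop("reconstructed_path: empty path")
  if (!all(elements$orientation %in% c("+", "-")))
    stop("reconstructed_path: orientations must be '+' or '-'")
  structure(list(elements = elements[, c("segment_id", "orientation")],
                 cyclic = cyclic,
                 total_alignment_score = total_alignment_score,
                 supporting_contigs = supporting_contigs,
                 copy_count = copy_count),
            class = "reconstructed_path")
}

#' @export
print.reconstructed_path <- function(x, ...) {
  cat(sprintf("<reconstructed_path> %s%s (score %.1f)\n",
              paste0(x$elements$segment_id, x$elements$orientation,
                     collapse = ","),
              if (x$cyclic) " [cyclic]" else "",
              x$total_alignment_score))
  invisible(x)
}

#' Write reconstructed paths in the cycles format
#'
#' Linear paths are flanked by the sentinel element `0+`; cyclic paths have
#' no sentinels.
#'
#' @param paths list of [reconstructed_path].
#' @param segments segment table (`segment_id`, `chrom`, `start`, `end`).
#' @param path output file path.
#' @return invisibly, the file path.
#' @export
write_cycles <- function(paths, segments, path) {
  ids <- unique(unlist(lapply(paths, function(p) p$elements$segment_id)))
  if (!all(ids %in% as.character(segments$segment_id)))
    stop("write_cycles: path references a segment absent from the table")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(segments)))
    writeLines(sprintf("Segment %s %s %d %d", segments$segment_id[i],
                       segments$chrom[i], as.integer(segments$start[i]),
                       as.integer(segments$end[i])), con)
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    toks <- paste0(p$elements$segment_id, p$elements$orientation)
    if (!p$cyclic) toks <- c("0+", toks, "0+")
    writeLines(sprintf("Cycle=%d;Copy_count=%g;Segments=%s", k, p$copy_count,
                       paste(toks, collapse = ",")), con)
  }
  invisible(path)
}

#' Read a cycles file
#'
#' @param path file path.
#' @return list with `segments` (data.frame) and `paths` (list of
#'   [reconstructed_path]).
#' @export
read_cycles <- function(path) {
  if (!file.exists(path)) stop("read_cycles: file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(lines) & !startsWith(lines, "#")])
  seg_lines <- lines[startsWith(lines, "Segment")]
  cyc_lines <- lines[startsWith(lines, "Cycle=")]
  segments <- NULL
  if (length(seg_lines)) {
    parts <- strsplit(seg_lines, "\\s+")
    segments <- data.frame(
      segment_id = vapply(parts, `[`, "", 2),
      chrom = vapply(parts, `[`, "", 3),
      start = as.numeric(vapply(parts, `[`, "", 4)),
      end = as.numeric(vapply(parts, `[`, "", 5)),
      stringsAsFactors = FALSE)
  }
  paths <- lapply(cyc_lines, function(ln) {
    fields <- strsplit(ln, ";")[[1]]
    get <- function(key) sub(paste0("^", key, "="), "",
                             fields[startsWith(fields, paste0(key, "="))])
    toks <- strsplit(get("Segments"), ",")[[1]]
    cyclic <- !(toks[1] == "0+" && toks[length(toks)] == "0+")
    if (!cyclic) toks <- toks[-c(1, length(toks))]
    reconstructed_path(
      data.frame(segment_id = sub("[+-]$", "", toks),
                 orientation = sub("^.*([+-])$", "\\1", toks),
                 stringsAsFactors = FALSE),
      cyclic = cyclic, copy_count = as.numeric(get("Copy_count")))
  })
  list(segments = segments, paths = paths)
}
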