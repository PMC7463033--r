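CMAP_COLS <- c("CMapId", "ContigLength", "NumSites", "SiteID", "LabelChannel",
               "Position", "StdDev", "Coverage", "Occurrence")

#' Read a CMAP file
#'
#' Parses the standard Bionano consensus-map format: tab-separated with
#' `#`-prefixed header lines, one row per label site plus a terminal
#' channel-0 "end" row per map whose position is the map length.
#'
#' @param path file path.
#' @return a named list of [label_map] (names are CMapIds).
#' @export
read_cmap <- function(path) {
  if (!file.exists(path)) stop("read_cmap: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(list())
  df <- read.table(text = lines, sep = "\t", header = FALSE,
                   col.names = CMAP_COLS, colClasses = c(
                     "character", "numeric", "integer", "integer", "integer",
                     "numeric", "numeric", "numeric", "numeric"))
  maps <- list()
  for (id in unique(df$CMapId)) {
    rows <- df[df$CMapId == id, , drop = FALSE]
    nsites <- rows$NumSites[1]
    lab <- rows[rows$LabelChannel == 1L, , drop = FALSE]
    if (nrow(lab) != nsites)
      stop("read_cmap: map ", id, " has ", nrow(lab),
           " label rows but NumSites=", nsites)
    endrow <- rows[rows$LabelChannel == 0L, , drop = FALSE]
    len <- if (nrow(endrow)) endrow$Position[1] else rows$ContigLength[1]
    pos <- lab$Position[order(lab$SiteID)]
    if (length(pos) > 1 && any(diff(pos) <= 0))
      stop("read_cmap: non-monotone positions in map ", id)
    maps[[id]] <- label_map(id, len, pos)
  }
  maps
}

#' Write label maps as a CMAP file
#'
#' @param maps a list of [label_map].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cmap <- function(maps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# CMAP File Version:\t0.1",
               paste0("#h ", paste(CMAP_COLS, collapse = "\t")),
               "#f string\tfloat\tint\tint\tint\tfloat\tfloat\tfloat\tfloat"),
             con)
  for (m in maps) {
    n <- n_labels(m)
    if (n) {
      for (i in seq_len(n)) {
        writeLines(sprintf("%s\t%.1f\t%d\t%d\t1\t%.1f\t1.0\t1.0\t1.0",
                           m$map_id, m$length_bp, n, i, m$positions[i]), con)
      }
    }
    writeLines(sprintf("%s\t%.1f\t%d\t%d\t0\t%.1f\t0.0\t1.0\t0.0",
                       m$map_id, m$length_bp, n, n + 1L, m$length_bp), con)
  }
  invisible(path)
}
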