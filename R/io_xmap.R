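XMAP_COLS <- c("XmapEntryID", "QryContigID", "RefContigID", "QryStartPos",
               "QryEndPos", "RefStartPos", "RefEndPos", "Orientation",
               "Confidence", "HitEnum", "QryLen", "RefLen", "LabelChannel",
               "Alignment")

#' Write alignments as an XMAP file
#'
#' The segment is the query, the contig the reference. The Alignment column
#' holds `(refsite,qrysite)` pairs; for a `-` orientation the query site ids
#' descend, per the XMAP convention.
#'
#' @param alignments list of [segment_alignment].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_xmap <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# XMAP File Version:\t0.2",
               paste0("#h ", paste(XMAP_COLS, collapse = "\t"))), con)
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    astr <- paste0(sprintf("(%d,%d)", a$pairs[, "contig"], a$pairs[, "segment"]),
                   collapse = "")
    qp <- a$seg_pos %||% rep(NA_real_, nrow(a$pairs))
    rp <- a$contig_pos %||% rep(NA_real_, nrow(a$pairs))
    writeLines(sprintf(
      "%d\t%s\t%s\t%.1f\t%.1f\t%.1f\t%.1f\t%s\t%.2f\t%dM\t%.1f\t%.1f\t1\t%s",
      i, a$segment_id, a$contig_id,
      qp[1], qp[length(qp)], rp[1], rp[length(rp)],
      a$orientation, a$score, nrow(a$pairs),
      a$seg_len, a$contig_len, astr), con)
  }
  invisible(path)
}

#' Read an XMAP file
#'
#' @param path file path.
#' @return list of [segment_alignment] (scores taken from the Confidence
#'   column; per-step scores are not part of XMAP).
#' @export
read_xmap <- function(path) {
  if (!file.exists(path)) stop("read_xmap: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(list())
  df <- read.table(text = lines, sep = "\t", header = FALSE,
                   col.names = XMAP_COLS,
                   colClasses = c("integer", "character", "character",
                                  "numeric", "numeric", "numeric", "numeric",
                                  "character", "numeric", "character",
                                  "numeric", "numeric", "integer", "character"))
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    astr <- df$Alignment[i]
    toks <- regmatches(astr, gregexpr("\\((\\d+),(\\d+)\\)", astr))[[1]]
    if (!length(toks))
      stop("read_xmap: unparseable Alignment string at row ", i)
    nums <- regmatches(toks, regexec("\\((\\d+),(\\d+)\\)", toks))
    pr <- t(vapply(nums, function(z) as.integer(z[2:3]), integer(2)))
    n <- nrow(pr)
    qpos <- rep(NA_real_, n); qpos[1] <- df$QryStartPos[i]; qpos[n] <- df$QryEndPos[i]
    rpos <- rep(NA_real_, n); rpos[1] <- df$RefStartPos[i]; rpos[n] <- df$RefEndPos[i]
    out[[i]] <- segment_alignment(
      segment_id = df$QryContigID[i], contig_id = df$RefContigID[i],
      orientation = df$Orientation[i],
      pairs = cbind(contig = pr[, 1], segment = pr[, 2]),
      score = df$Confidence[i],
      seg_len = df$QryLen[i], contig_len = df$RefLen[i],
      seg_pos = qpos, contig_pos = rpos)
  }
  out
}
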