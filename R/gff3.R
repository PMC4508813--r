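# GFF3 serialization of element calls (via rtracklayer).
#
# Calls are data frames with columns seqid, start, end (1-based inclusive),
# kind, and optionally strand plus per-detector evidence columns; evidence
# travels in GFF3 attributes. Feature types use Sequence Ontology terms.

.SO_TYPE <- c(
  helitron = "helitron",
  mule = "terminal_inverted_repeat_element",
  stowaway = "MITE",
  tourist = "MITE",
  mite = "MITE",
  generic_repeat = "repeat_region"
)

#' Write element calls to a GFF3 file
#'
#' @param calls data frame with columns `seqid`, `start`, `end`, `kind` and
#'   optionally `strand`; any further columns are emitted as GFF3
#'   attributes. An empty data frame yields a header-only file.
#' @param path output path.
#' @param seqlens optional named vector of sequence lengths; when given,
#'   intervals outside the sequence bounds are an error.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(calls, path, seqlens = NULL) {
  if (nrow(calls) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  stopifnot(all(c("seqid", "start", "end", "kind") %in% names(calls)))
  if (any(calls$start < 1L) || any(calls$end < calls$start))
    stop("write_gff3: invalid interval (start < 1 or end < start)")
  if (!is.null(seqlens)) {
    lens <- seqlens[as.character(calls$seqid)]
    if (any(is.na(lens)))
      stop("write_gff3: call on unknown sequence id")
    if (any(calls$end > lens))
      stop("write_gff3: interval outside sequence bounds")
  }
  strand <- if ("strand" %in% names(calls)) calls$strand else "+"
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(calls$seqid),
    ranges = IRanges::IRanges(calls$start, calls$end),
    strand = strand
  )
  type <- .SO_TYPE[as.character(calls$kind)]
  type[is.na(type)] <- "repeat_region"
  S4Vectors::mcols(gr)$source <- "strucTE"
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- sprintf("%s_%06d", as.character(calls$kind),
                                     seq_len(nrow(calls)))
  S4Vectors::mcols(gr)$kind <- as.character(calls$kind)
  extra <- setdiff(names(calls), c("seqid", "start", "end", "strand", "kind"))
  for (col in extra) S4Vectors::mcols(gr)[[col]] <- calls[[col]]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read element calls from a GFF3 file
#'
#' Inverse of [write_gff3()] for the columns it writes: recovers `seqid`,
#' `start`, `end`, `strand`, `kind` and any attribute columns.
#'
#' @param path path to a GFF3 file.
#' @return data frame of calls (zero rows for a header-only file).
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) NULL)
  if (is.null(gr) || length(gr) == 0L) {
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if ("kind" %in% names(mc)) {
    df$kind <- as.character(mc$kind)
  } else if ("type" %in% names(mc)) {
    rev_map <- c(helitron = "helitron",
                 terminal_inverted_repeat_element = "mule", MITE = "mite")
    df$kind <- unname(rev_map[as.character(mc$type)])
  } else {
    df$kind <- NA_character_
  }
  for (col in setdiff(names(mc), c("type", "score", "phase", "source", "kind")))
    df[[col]] <- mc[[col]]
  df
}
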