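# Repeat records and the sequence-header codec.
#
# A complete-element insertion is serialized into a FASTA header of the form
#
#   [code]_#[Order/Superfamily]_[Species][FamilyId1]_fam[FamilyId2]_
#       [Chromosome]_[Start]_[End] [known family] [FL|Fragment]
#
# e.g. "RLG_#LTR/Gypsy_Ojapo1_fam7_Chr4_7056110_7070993 hopi FL": a Gypsy
# LTR retrotransposon, species tag Ojapo, within-species family 1, global
# family 7, located on Chr4 at 7056110-7070993 (1-based), homologous to the
# known family "hopi", full length. The species tag and within-species
# family id are concatenated without a delimiter; the parser splits the
# trailing integer off that token.

#' Construct a repeat record
#'
#' @param code classification code (must be registered).
#' @param order_superfamily order/superfamily label, e.g. `"LTR/Gypsy"`.
#' @param species species tag, e.g. `"Ojapo"` (must not end in a digit).
#' @param family_id_within within-species family id (integer).
#' @param family_id_global whole-dataset family id (integer).
#' @param seqid chromosome/contig name.
#' @param start,end 1-based inclusive genomic coordinates, `start <= end`.
#' @param known_family optional known-family label (e.g. a Retroryza name).
#' @param completeness `"FL"` (full length) or `"Fragment"`.
#' @param seq optional element sequence.
#' @param registry code registry used for validation.
#' @return an object of class `repeat_record`.
#' @export
repeat_record <- function(code, order_superfamily, species,
                          family_id_within, family_id_global,
                          seqid, start, end,
                          known_family = NULL,
                          completeness = c("FL", "Fragment"),
                          seq = NULL,
                          registry = te_code_registry()) {
  completeness <- match.arg(completeness)
  if (!is_registered_code(registry, code))
    stop("unregistered classification code: ", code)
  if (grepl("[0-9]$", species))
    stop("species tag must not end in a digit: ", species)
  if (grepl("_| ", species) || grepl(" ", order_superfamily) ||
      grepl("_", order_superfamily))
    stop("species and order/superfamily labels must not contain '_' or spaces")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid coordinates: start=", start, " end=", end)
  fam1 <- as.integer(family_id_within); fam2 <- as.integer(family_id_global)
  if (is.na(fam1) || is.na(fam2)) stop("family ids must be integers")
  structure(list(
    code = code, order_superfamily = order_superfamily, species = species,
    family_id_within = fam1, family_id_global = fam2,
    seqid = seqid, start = start, end = end,
    known_family = known_family, completeness = completeness, seq = seq
  ), class = "repeat_record")
}

#' Encode a repeat record as a sequence header
#'
#' @param r a [repeat_record()].
#' @return a single header string.
#' @export
encode_header <- function(r) {
  stopifnot(inherits(r, "repeat_record"))
  req <- c("code", "order_superfamily", "species", "family_id_within",
           "family_id_global", "seqid", "start", "end", "completeness")
  miss <- req[vapply(req, function(f) is.null(r[[f]]) || is.na(r[[f]][1]),
                     logical(1))]
  if (length(miss)) stop("repeat record is missing field(s): ",
                         paste(miss, collapse = ", "))
  h <- paste0(r$code, "_#", r$order_superfamily, "_",
              r$species, r$family_id_within, "_fam", r$family_id_global, "_",
              r$seqid, "_", r$start, "_", r$end)
  if (!is.null(r$known_family)) h <- paste(h, r$known_family)
  paste(h, r$completeness)
}

#' Parse a sequence header into a repeat record
#'
#' Inverse of [encode_header()]: `encode_header(parse_header(h)) == h` for
#' every valid header.
#'
#' @param h a single header string.
#' @param registry code registry used for validation.
#' @return a [repeat_record()] (without sequence).
#' @export
parse_header <- function(h, registry = te_code_registry()) {
  stopifnot(is.character(h), length(h) == 1L)
  toks <- strsplit(trimws(h), "[[:space:]]+")[[1]]
  if (length(toks) < 2L || length(toks) > 3L)
    stop("malformed header (expected 'MAIN [known] FL|Fragment'): ", h)
  completeness <- toks[length(toks)]
  if (!completeness %in% c("FL", "Fragment"))
    stop("malformed header: final token '", completeness,
         "' is not FL or Fragment")
  known <- if (length(toks) == 3L) toks[2] else NULL
  main <- toks[1]

  m <- regmatches(main, regexec("^([A-Z]{3}m?)_#([^_]+)_(.+)$", main))[[1]]
  if (length(m) != 4L)
    stop("malformed header: cannot split code/order token in '", main, "'")
  code <- m[2]; osf <- m[3]; rest <- m[4]
  if (!is_registered_code(registry, code))
    stop("malformed header: unregistered code token '", code, "'")

  parts <- strsplit(rest, "_", fixed = TRUE)[[1]]
  if (length(parts) < 5L)
    stop("malformed header: expected species, fam, chromosome, start, end ",
         "in '", rest, "'")
  sp_tok <- parts[1]
  fam_tok <- parts[2]
  n <- length(parts)
  seqid <- paste(parts[3:(n - 2L)], collapse = "_")
  start_tok <- parts[n - 1L]; end_tok <- parts[n]

  spm <- regmatches(sp_tok, regexec("^(.*[^0-9])([0-9]+)$", sp_tok))[[1]]
  if (length(spm) != 3L)
    stop("malformed header: species token '", sp_tok,
         "' lacks a trailing family id")
  if (!grepl("^fam[0-9]+$", fam_tok))
    stop("malformed header: family token '", fam_tok, "' is not fam<id>")
  if (!grepl("^[0-9]+$", start_tok) || !grepl("^[0-9]+$", end_tok))
    stop("malformed header: coordinate tokens '", start_tok, "_", end_tok,
         "' are not integers")

  repeat_record(
    code = code, order_superfamily = osf,
    species = spm[2], family_id_within = as.integer(spm[3]),
    family_id_global = as.integer(sub("^fam", "", fam_tok)),
    seqid = seqid, start = as.integer(start_tok), end = as.integer(end_tok),
    known_family = known, completeness = completeness, registry = registry
  )
}

#' @export
print.repeat_record <- function(x, ...) {
  cat("<repeat_record>", encode_header(x), "\n")
  invisible(x)
}
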