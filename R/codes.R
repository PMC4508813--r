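# Classification-code registry.
#
# Codes follow the three-letter class/order/superfamily convention
# (e.g. RLG = retrotransposon / LTR / Gypsy), extended with:
#   * a fourth letter "m" marking non-autonomous DNA transposons,
#   * "X" at any position denoting classification ambiguity,
#   * DTX for DNA transposons of unknown superfamily,
#   * BRN / BTN for ribosomal DNA and tRNA sequences,
#   * codes starting with "S" for structural repeats (centromeric,
#     telomeric, tandem and low-complexity sequence).
# The shipped registry covers the codes the detectors emit plus the common
# Wicker superfamilies; further codes can be registered by the user.

.DEFAULT_CODES <- c(
  RLC = "LTR retrotransposon, Copia",
  RLG = "LTR retrotransposon, Gypsy",
  RLX = "LTR retrotransposon, unknown superfamily",
  RIX = "LINE, unknown superfamily",
  RSX = "SINE, unknown superfamily",
  RXX = "retrotransposon, unknown order",
  DTA = "DNA transposon, TIR, hAT",
  DTC = "DNA transposon, TIR, CACTA",
  DTH = "DNA transposon, TIR, PIF-Harbinger",
  DTM = "DNA transposon, TIR, Mutator",
  DTT = "DNA transposon, TIR, Tc1-Mariner",
  DTX = "DNA transposon, unknown superfamily",
  DHH = "Helitron",
  DXX = "DNA transposon, unknown order",
  DTAm = "non-autonomous hAT",
  DTCm = "non-autonomous CACTA",
  DTHm = "non-autonomous PIF-Harbinger (Tourist-like MITE)",
  DTMm = "non-autonomous Mutator (MULE-derived)",
  DTTm = "non-autonomous Tc1-Mariner (Stowaway-like MITE)",
  DTXm = "non-autonomous DNA transposon, unknown superfamily",
  DHHm = "non-autonomous Helitron",
  BRN = "ribosomal DNA",
  BTN = "tRNA sequence",
  SCM = "structural repeat, centromeric",
  STM = "structural repeat, telomeric",
  SSR = "structural repeat, tandem repeat",
  SLX = "structural repeat, low complexity",
  XXX = "unclassified repeat"
)

.valid_code_string <- function(code) {
  grepl("^[A-Z]{3}m?$", code)
}

#' Classification-code registry
#'
#' Returns the default registry of repeat classification codes, optionally
#' extended with user codes.
#'
#' @param extra optional named character vector of additional codes
#'   (`code = description`).
#' @return an object of class `te_code_registry`.
#' @export
te_code_registry <- function(extra = NULL) {
  codes <- .DEFAULT_CODES
  reg <- structure(list(codes = codes), class = "te_code_registry")
  if (!is.null(extra)) {
    for (i in seq_along(extra)) {
      reg <- register_code(reg, names(extra)[i], extra[[i]])
    }
  }
  reg
}

#' Register an additional classification code
#'
#' @param registry a `te_code_registry`.
#' @param code a 3-character code, optionally with a fourth letter `m`
#'   marking a non-autonomous element.
#' @param description free-text description.
#' @return the updated registry.
#' @export
register_code <- function(registry, code, description = "") {
  stopifnot(inherits(registry, "te_code_registry"))
  if (!.valid_code_string(code)) {
    stop("invalid classification code: '", code,
         "' (expected three uppercase letters, optional fourth letter 'm')")
  }
  registry$codes[code] <- description
  registry
}

#' Is a code registered?
#'
#' @param registry a `te_code_registry`.
#' @param code character vector of codes.
#' @return logical vector.
#' @export
is_registered_code <- function(registry, code) {
  stopifnot(inherits(registry, "te_code_registry"))
  code %in% names(registry$codes)
}

#' Decompose a classification code
#'
#' @param code a single registered-style code string.
#' @return list with `class_level`, `order_level`, `superfamily_level`
#'   characters, the `nonautonomous` flag (fourth letter m), and logical
#'   `structural` (code starts with S) and `ambiguous` (contains X).
#' @export
code_info <- function(code) {
  if (!.valid_code_string(code)) stop("invalid classification code: ", code)
  ch <- .chars(code)
  list(
    class_level = ch[1],
    order_level = ch[2],
    superfamily_level = ch[3],
    nonautonomous = length(ch) == 4L,
    structural = ch[1] == "S",
    ambiguous = any(ch[1:3] == "X")
  )
}

#' @export
print.te_code_registry <- function(x, ...) {
  cat("<te_code_registry> with", length(x$codes), "codes\n")
  invisible(x)
}
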