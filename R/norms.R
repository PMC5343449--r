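# Norm representation ---------------------------------------------------
#
# A norm is a 4-locus binary assessment genotype. Each locus says how an
# observer judges a donor given the donor's action (C/D) and the observer's
# current image (Good/Bad) of the donor's recipient:
#
#   locus 1: donor cooperated with a Good recipient
#   locus 2: donor cooperated with a Bad recipient
#   locus 3: donor defected against a Good recipient
#   locus 4: donor defected against a Bad recipient
#
# Internally a norm is an integer code 0..15 with locus 1 as the most
# significant bit and G = 1, so ALLG = GGGG = 15 and ALLB = BBBB = 0.

.norm_gb_strings <- vapply(0:15, function(code) {
  bits <- bitwAnd(bitwShiftR(code, 3:0), 1L)
  paste(c("B", "G")[bits + 1L], collapse = "")
}, character(1))

.norm_special <- c(
  GGGG = "ALLG", BBBB = "ALLB", GBBB = "SH", GBBG = "SJ",
  GGBB = "IS", GGBG = "ST"
)

.norm_canonical <- {
  lab <- .norm_gb_strings
  hit <- match(lab, names(.norm_special))
  lab[!is.na(hit)] <- .norm_special[hit[!is.na(hit)]]
  lab
}

#' Canonical labels of the sixteen assessment norms
#'
#' Returns the canonical label of each norm, ordered by integer code
#' 0 to 15 (locus 1 is the most significant bit, G = 1). The six norms
#' with established names are labelled `ALLB`, `SH`, `SJ`, `IS`, `ST`
#' and `ALLG`; the remaining ten are labelled by their four-letter
#' G/B genotype string.
#'
#' @return A character vector of length 16.
#' @examples
#' norm_labels()
#' @export
norm_labels <- function() .norm_canonical

#' Convert a norm label to its integer code
#'
#' Accepts a four-character G/B genotype string (e.g. `"GBBG"`), one of the
#' canonical names (`ALLG`, `ALLB`, `SH`, `SJ`, `IS`, `ST`;
#' case-insensitive), or an integer code 0-15 (returned unchanged).
#'
#' @param x Character or integer vector of norm identifiers.
#' @return Integer vector of norm codes in 0-15.
#' @examples
#' norm_code("SJ")      # 9, genotype GBBG
#' norm_code("GGBG")    # 13, Simple Standing
#' @export
norm_code <- function(x) {
  if (is.numeric(x)) {
    code <- as.integer(x)
    bad <- is.na(code) | code < 0L | code > 15L | code != x
    if (any(bad)) {
      stop("invalid norm code(s): ", paste(unique(x[bad]), collapse = ", "),
           call. = FALSE)
    }
    return(code)
  }
  if (!is.character(x)) stop("norms must be labels or integer codes", call. = FALSE)
  up <- toupper(x)
  code <- match(up, .norm_gb_strings) - 1L
  named <- match(up, .norm_canonical) - 1L
  code[is.na(code)] <- named[is.na(code)]
  if (anyNA(code)) {
    stop("unknown norm label(s): ",
         paste(unique(x[is.na(code)]), collapse = ", "), call. = FALSE)
  }
  code
}

#' @rdname norm_code
#' @details `norm_from_string()` is an alias of `norm_code()` returning the
#'   canonical label rather than the integer code.
#' @export
norm_from_string <- function(x) norm_label(norm_code(x))

#' Canonical label of a norm code
#'
#' @param code Integer vector of norm codes (0-15), or labels (normalised).
#' @param genotype If `TRUE`, return the four-letter G/B string even for the
#'   six named norms.
#' @return Character vector of labels.
#' @examples
#' norm_label(9)            # "SJ"
#' norm_label(9, genotype = TRUE)  # "GBBG"
#' @export
norm_label <- function(code, genotype = FALSE) {
  code <- norm_code(code)
  if (genotype) .norm_gb_strings[code + 1L] else .norm_canonical[code + 1L]
}

# locus bit for (action, image-of-recipient); a, g in {0, 1}, 1 = C / Good.
# Bit position 2*a + g: (C,G) -> locus 1 (bit 3), (C,B) -> locus 2,
# (D,G) -> locus 3, (D,B) -> locus 4 (bit 0).
assess_bit <- function(code, a, g) {
  bitwAnd(bitwShiftR(code, 2L * a + g), 1L)
}

.as_action <- function(action) {
  if (is.character(action)) {
    a <- match(toupper(action), c("D", "C")) - 1L
    if (anyNA(a)) stop("actions must be \"C\" or \"D\"", call. = FALSE)
    return(a)
  }
  a <- as.integer(action)
  if (any(is.na(a) | (a != 0L & a != 1L))) {
    stop("actions must be \"C\"/\"D\" or 1/0", call. = FALSE)
  }
  a
}

.as_image <- function(image) {
  if (is.character(image)) {
    g <- match(toupper(substr(image, 1, 1)), c("B", "G")) - 1L
    if (anyNA(g)) stop("images must be \"G\"(ood) or \"B\"(ad)", call. = FALSE)
    return(g)
  }
  g <- as.integer(image)
  if (any(is.na(g) | (g != 0L & g != 1L))) {
    stop("images must be \"G\"/\"B\" or 1/0", call. = FALSE)
  }
  g
}

#' Assess a donor's action under a norm
#'
#' Pure lookup into the norm's four loci: the new image assigned to a donor
#' is determined by the donor's action and the observer's image of the
#' donor's recipient. No error noise is applied here.
#'
#' @param norm Norm label(s) or integer code(s).
#' @param action `"C"`/`"D"` (or 1/0): the donor's action.
#' @param image_of_recipient `"G"`/`"B"` (or 1/0): the observer's image of
#'   the donor's recipient.
#' @return Character vector of new images, `"G"` or `"B"`.
#' @examples
#' assess("SH", "C", "B")  # "B": Shunning condemns any action toward Bad
#' assess("ST", "C", "B")  # "G": Simple Standing forgives it
#' assess("IS", "D", "G")  # "B": Image Scoring judges the action alone
#' @export
assess <- function(norm, action, image_of_recipient) {
  bit <- assess_bit(norm_code(norm), .as_action(action),
                    .as_image(image_of_recipient))
  c("B", "G")[bit + 1L]
}

#' Match norms against a G/B/* pattern
#'
#' Norm families such as `**BB` (judge defection Bad regardless of the
#' recipient's image) or `GG**` (judge cooperation Good regardless) are
#' written as four-character patterns over `{G, B, *}`, where `*` matches
#' either allele.
#'
#' @param norm Norm label(s) or code(s).
#' @param pattern A single four-character pattern over `{G, B, *}`.
#' @return Logical vector: does each norm match the pattern?
#' @examples
#' norm_family_matches("SH", "**BB")  # TRUE
#' norm_family_matches("IS", "GG**")  # TRUE; IS belongs to both families
#' @export
norm_family_matches <- function(norm, pattern) {
  if (length(pattern) != 1L || !is.character(pattern) || nchar(pattern) != 4L) {
    stop("pattern must be a single 4-character string over {G, B, *}",
         call. = FALSE)
  }
  chars <- toupper(strsplit(pattern, "")[[1]])
  if (!all(chars %in% c("G", "B", "*"))) {
    stop("invalid pattern alphabet in ", pattern, ": use only G, B and *",
         call. = FALSE)
  }
  code <- norm_code(norm)
  ok <- rep(TRUE, length(code))
  for (l in 1:4) {
    if (chars[l] == "*") next
    want <- if (chars[l] == "G") 1L else 0L
    ok <- ok & (bitwAnd(bitwShiftR(code, 4L - l), 1L) == want)
  }
  ok
}
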