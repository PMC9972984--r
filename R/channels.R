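# 96-channel trinucleotide mutation space: six pyrimidine-centered
# substitution classes x 16 flanking-base combinations.

SS_BASES <- c("A", "C", "G", "T")
SS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical 96-channel labels
#'
#' Returns the fixed, lexicographic channel order used everywhere in the
#' package: substitution class first (C>A, C>G, C>T, T>A, T>C, T>G), then
#' 5' flanking base, then 3' flanking base. Labels follow the COSMIC
#' convention, e.g. `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(channel_labels())
channel_labels <- function() {
  grid <- expand.grid(three = SS_BASES, five = SS_BASES, sub = SS_SUBSTITUTIONS,
                      stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reorder so substitution is
  # the outer loop, then 5' base, then 3' base
  sprintf("%s[%s]%s", grid$five, grid$sub, grid$three)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

#' Normalize a substitution to the pyrimidine-centered strand
#'
#' Single-base substitutions with a purine reference (A or G) are mapped to
#' the reverse-complement strand so the mutated base is always a pyrimidine
#' (C or T); the trinucleotide context is reverse-complemented accordingly.
#' Pyrimidine-reference inputs are returned unchanged, so the operation is
#' an involution fixed point on already-normalized input.
#'
#' @param ref,alt single reference/alternate bases (vectorized).
#' @param context3 3-mer context centered on the substituted base, or `NA`.
#' @return data.frame with columns `ref`, `alt`, `context3`.
#' @export
normalize_pyrimidine <- function(ref, alt, context3 = NA_character_) {
  n <- max(length(ref), length(alt), length(context3))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  context3 <- rep_len(context3, n)
  flip <- ref %in% c("A", "G")
  out <- data.frame(ref = ref, alt = alt, context3 = context3,
                    stringsAsFactors = FALSE)
  if (any(flip)) {
    out$ref[flip] <- chartr("ACGT", "TGCA", ref[flip])
    out$alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    has_ctx <- flip & !is.na(context3)
    out$context3[has_ctx] <- revcomp(context3[has_ctx])
  }
  out
}

#' Map substitutions to 96-channel labels
#'
#' @param ref,alt single bases; purine-reference records are strand-normalized
#'   first.
#' @param context3 3-mer trinucleotide context centered on the substituted
#'   base (on the same strand as `ref`).
#' @return character vector of channel labels as in [channel_labels()].
#' @export
#' @examples
#' channel_of("G", "A", "AGT")  # reverse-complemented to "A[C>T]T"
channel_of <- function(ref, alt, context3) {
  bad <- is.na(context3) | nchar(context3) != 3L
  if (any(bad)) {
    stop("context3 must be a 3-base string for every substitution (",
         sum(bad), " offending record(s))")
  }
  norm <- normalize_pyrimidine(ref, alt, context3)
  mid <- substr(norm$context3, 2, 2)
  if (any(mid != norm$ref)) {
    stop("context3 middle base disagrees with the reference allele after ",
         "pyrimidine normalization")
  }
  lab <- sprintf("%s[%s>%s]%s",
                 substr(norm$context3, 1, 1), norm$ref, norm$alt,
                 substr(norm$context3, 3, 3))
  unknown <- !(lab %in% channel_labels())
  if (any(unknown)) stop("substitution does not map to a canonical channel: ",
                         paste(head(lab[unknown]), collapse = ", "))
  lab
}

# TRUE for rows that are single-base substitutions
is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% SS_BASES & alt %in% SS_BASES
}
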